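#' Scan the opposite strand of annotated genes for Psi sites
#'
#' Because the assay is unstranded, a Psi call on the strand opposite an
#' annotated gene implies an antisense transcript. Candidates are
#' high-confidence calls (supported by at least `min_samples` treated
#' libraries) that overlap a gene's interval on the opposite strand; a call
#' overlapping genes on both strands is excluded as of ambiguous origin.
#'
#' @param calls Call `data.frame` (carrying `strand` and `n_supporting`).
#' @param annotation An [annotation_set()].
#' @param min_samples Minimum supporting samples (default 2).
#' @return A `data.frame` of antisense candidates: `gene_id` (sense gene),
#'   `ref`, `pos`, `strand` (the antisense strand), `psi_proportion`,
#'   `n_supporting`, plus empty slots `distance_to_known_tss`,
#'   `promoter_score`, `tts_score`, `predicted_tss`, `predicted_length`
#'   filled by the downstream steps.
#' @export
scan_antisense <- function(calls, annotation, min_samples = 2L) {
  stopifnot(inherits(annotation, "annotation_set"))
  empty <- data.frame(gene_id = character(), ref = character(),
                      pos = integer(), strand = character(),
                      psi_proportion = numeric(), n_supporting = integer(),
                      distance_to_known_tss = numeric(),
                      promoter_score = numeric(), tts_score = numeric(),
                      predicted_tss = integer(), predicted_length = numeric(),
                      stringsAsFactors = FALSE)
  calls <- calls[calls$n_supporting >= min_samples, , drop = FALSE]
  if (!nrow(calls)) return(empty)
  call_gr <- GenomicRanges::GRanges(calls$ref,
                                    IRanges::IRanges(calls$pos, calls$pos))
  gene_gr <- GenomicRanges::GRanges(
    annotation$ref, IRanges::IRanges(annotation$start, annotation$end))
  hits <- GenomicRanges::findOverlaps(call_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(unique(qh), function(i) {
    genes <- sh[qh == i]
    g_strands <- unique(annotation$strand[genes])
    if (length(g_strands) > 1L) return(NULL)  # genes on both strands
    anti <- genes[annotation$strand[genes] != calls$strand[i]]
    if (!length(anti)) return(NULL)
    data.frame(gene_id = annotation$gene_id[anti],
               ref = calls$ref[i], pos = calls$pos[i],
               strand = calls$strand[i],
               psi_proportion = calls$psi_proportion[i],
               n_supporting = calls$n_supporting[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$distance_to_known_tss <- NA_real_
  out$promoter_score <- NA_real_
  out$tts_score <- NA_real_
  out$predicted_tss <- NA_integer_
  out$predicted_length <- NA_real_
  out <- out[order(out$ref, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance from known transcription start sites to antisense Psi sites
#'
#' For each candidate, the transcription-direction offset from the nearest
#' same-strand known TSS to the Psi site: on `+` the site must lie at or
#' beyond the TSS coordinate, on `-` at or below it ("downstream" is in the
#' direction of antisense transcription). Distances are reported when
#' `0 <= distance <= window` (bounds inclusive); otherwise the field stays
#' missing.
#'
#' @param candidates Output of [scan_antisense()].
#' @param known_tss `data.frame` with `ref`, `position`, `strand`.
#' @param window Maximum downstream distance (default 200 nt).
#' @return `candidates` with `distance_to_known_tss` filled.
#' @export
tss_proximity <- function(candidates, known_tss, window = 200L) {
  if (!nrow(candidates)) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    tss <- known_tss[known_tss$strand == candidates$strand[i] &
                       known_tss$ref == candidates$ref[i], , drop = FALSE]
    if (!nrow(tss)) next
    d <- if (candidates$strand[i] == "+") {
      candidates$pos[i] - tss$position
    } else {
      tss$position - candidates$pos[i]
    }
    d <- d[d >= 0 & d <= window]
    if (length(d)) candidates$distance_to_known_tss[i] <- min(d)
  }
  candidates
}

#' Attach external promoter and terminator prediction scores
#'
#' Promoter predictions are searched in the 200 bp upstream of the Psi site
#' and terminator (TTS) predictions in the 150 bp downstream, both in the
#' antisense transcript's orientation. Score windows qualify when they
#' overlap the search region with probability at least `min_score`; the
#' highest-scoring qualifying window is attached, and candidates with none
#' keep the field missing. The predicted TSS is the qualifying promoter
#' window's edge nearest the Psi site; when both a promoter and a TTS
#' window qualify the sRNA span is computed with [predict_srna_span()].
#'
#' @param candidates Output of [scan_antisense()].
#' @param promoter_scores,tts_scores Predictor tables
#'   ([read_predictor_scores()] format); either may be `NULL`.
#' @param min_score Probability cutoff (default 0.9).
#' @param promoter_window Upstream search span in nt (default 200).
#' @param tts_window Downstream search span in nt (default 150), starting
#'   at the first base past the Psi site.
#' @return `candidates` with `promoter_score`, `tts_score`,
#'   `predicted_tss`, `predicted_length` filled where available.
#' @export
attach_predictor_scores <- function(candidates, promoter_scores = NULL,
                                    tts_scores = NULL, min_score = 0.9,
                                    promoter_window = 200L,
                                    tts_window = 150L) {
  if (!nrow(candidates)) return(candidates)
  check_tbl <- function(tbl) {
    if (!is.null(tbl)) assert_fraction(tbl$score, "predictor score")
    tbl
  }
  promoter_scores <- check_tbl(promoter_scores)
  tts_scores <- check_tbl(tts_scores)
  best_in <- function(tbl, ref, lo, hi) {
    if (is.null(tbl) || !nrow(tbl)) return(NULL)
    hit <- tbl[tbl$ref == ref & tbl$window_start <= hi &
                 tbl$window_end >= lo & tbl$score >= min_score, ,
               drop = FALSE]
    if (!nrow(hit)) return(NULL)
    hit[which.max(hit$score), , drop = FALSE]
  }
  for (i in seq_len(nrow(candidates))) {
    p <- candidates$pos[i]; s <- candidates$strand[i]
    prom_reg <- if (s == "+") c(p - promoter_window, p - 1L)
                else c(p + 1L, p + promoter_window)
    tts_reg <- if (s == "+") c(p + 1L, p + tts_window)
               else c(p - tts_window, p - 1L)
    bp <- best_in(promoter_scores, candidates$ref[i], prom_reg[1], prom_reg[2])
    if (!is.null(bp)) {
      candidates$promoter_score[i] <- bp$score
      candidates$predicted_tss[i] <-
        if (s == "+") as.integer(bp$window_end) else as.integer(bp$window_start)
    }
    bt <- best_in(tts_scores, candidates$ref[i], tts_reg[1], tts_reg[2])
    if (!is.null(bt)) {
      candidates$tts_score[i] <- bt$score
      if (!is.na(candidates$predicted_tss[i])) {
        len <- tryCatch(
          predict_srna_span(candidates$predicted_tss[i],
                            bt$window_start, bt$window_end, s),
          error = function(e) NA_real_)
        candidates$predicted_length[i] <- len
      }
    }
  }
  candidates
}

#' Predicted antisense sRNA length from TSS to TTS-window midpoint
#'
#' The putative sRNA spans from the predicted TSS to the midpoint of the
#' subsequence containing the TTS, counted inclusively. On the `+` strand
#' an even-length window's midpoint floors to the lower coordinate; on the
#' `-` strand it rounds up, so mirrored inputs give identical lengths.
#'
#' @param tss 1-based TSS position.
#' @param tts_start,tts_end 1-based inclusive TTS window, downstream of the
#'   TSS in transcription direction.
#' @param strand `"+"` or `"-"`.
#' @return Length in nucleotides (inclusive count).
#' @export
predict_srna_span <- function(tss, tts_start, tts_end, strand) {
  stopifnot(tts_start <= tts_end, strand %in% c("+", "-"))
  if (strand == "+") {
    if (tts_start < tss) stop_data("TTS window upstream of TSS")
    mid <- floor((tts_start + tts_end) / 2)
    mid - tss + 1
  } else {
    if (tts_end > tss) stop_data("TTS window upstream of TSS")
    mid <- ceiling((tts_start + tts_end) / 2)
    tss - mid + 1
  }
}
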