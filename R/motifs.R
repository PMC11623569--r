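#' Extract sequence context (k-mers) around Psi sites
#'
#' Returns the `k_up + 1 + k_down`-mer around each call in transcript
#' orientation: minus-strand sites are reverse-complemented before
#' extraction, DNA T is written as RNA U, and the Psi residue sits at
#' 0-based offset `k_up`. Sites too close to a contig edge are skipped with
#' a warning. The default 5-mer window (2 up, 2 down) matches the length of
#' the dominant pseudouridylation motifs (e.g. GGUAU); shorter published
#' consensus motifs are recovered by [consensus_from_motifs()], not by
#' shrinking the window.
#'
#' @param calls Call `data.frame` with `ref`, `pos`, `strand` and
#'   (optionally) `psi_proportion` / `treated_frac`.
#' @param reference Named character vector of reference sequences.
#' @param k_up,k_down Flank lengths upstream/downstream of Psi (defaults 2).
#' @return A `data.frame` with `kmer`, `ref`, `pos`, `strand`, `fraction`
#'   (the site's deletion fraction, `NA` when absent from `calls`).
#' @export
extract_motifs <- function(calls, reference, k_up = 2L, k_down = 2L) {
  if (!nrow(calls)) {
    return(data.frame(kmer = character(), ref = character(),
                      pos = integer(), strand = character(),
                      fraction = numeric()))
  }
  frac <- if ("treated_frac" %in% names(calls)) calls$treated_frac
          else if ("psi_proportion" %in% names(calls)) calls$psi_proportion
          else rep(NA_real_, nrow(calls))
  kmer <- character(nrow(calls))
  ok <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    seqc <- reference[[calls$ref[i]]]
    p <- calls$pos[i]
    if (calls$strand[i] == "+") {
      lo <- p - k_up; hi <- p + k_down
    } else {
      lo <- p - k_down; hi <- p + k_up
    }
    if (lo < 1L || hi > nchar(seqc)) next
    s <- substr(seqc, lo, hi)
    if (calls$strand[i] == "-") s <- revcomp(s)
    kmer[i] <- chartr("T", "U", s)
    ok[i] <- TRUE
  }
  if (any(!ok)) {
    warning(sum(!ok), " site(s) too close to a contig edge were skipped")
  }
  data.frame(kmer = kmer[ok], ref = calls$ref[ok], pos = calls$pos[ok],
             strand = calls$strand[ok], fraction = frac[ok],
             stringsAsFactors = FALSE)
}

#' Filter motif sites by deletion fraction and motif occurrence
#'
#' Keeps sites whose deletion fraction is strictly above `min_fraction`
#' (default: the empirical median of the input, the data-derived threshold
#' used for motif analysis), then drops motifs observed fewer than
#' `min_occurrences` times among the retained sites.
#'
#' @param motif_sites Output of [extract_motifs()] (needs `kmer`,
#'   `fraction`).
#' @param min_fraction Fraction cutoff; `NULL` recomputes the median of the
#'   input fractions.
#' @param min_occurrences Minimum retained sites per motif (default 5).
#' @return The filtered `data.frame`; the threshold actually used is
#'   attached as attribute `min_fraction`.
#' @export
filter_motif_sites <- function(motif_sites, min_fraction = NULL,
                               min_occurrences = 5L) {
  if (!nrow(motif_sites)) {
    attr(motif_sites, "min_fraction") <- min_fraction %||% NA_real_
    return(motif_sites)
  }
  thr <- min_fraction %||% stats::median(motif_sites$fraction, na.rm = TRUE)
  kept <- motif_sites[!is.na(motif_sites$fraction) &
                        motif_sites$fraction > thr, , drop = FALSE]
  tab <- table(kept$kmer)
  kept <- kept[kept$kmer %in% names(tab)[tab >= min_occurrences], ,
               drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "min_fraction") <- thr
  kept
}

#' Two-sided rank-sum test between genotype deletion fractions
#'
#' Wilcoxon rank-sum comparison of per-site deletion fractions between wild
#' type and a PUS mutant for one motif: exact p for small tie-free groups
#' (both sizes <= 10), normal approximation with tie correction otherwise.
#' Identical data in both groups gives p = 1.
#'
#' @param wt_fractions,mutant_fractions Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
motif_genotype_test <- function(wt_fractions, mutant_fractions) {
  if (!length(wt_fractions) || !length(mutant_fractions)) {
    stop_data("both groups must be non-empty")
  }
  pooled <- c(wt_fractions, mutant_fractions)
  if (length(unique(pooled)) == 1L) return(1.0)
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(wt_fractions) <= 10L &&
    length(mutant_fractions) <= 10L
  suppressWarnings(
    stats::wilcox.test(wt_fractions, mutant_fractions, exact = exact,
                       correct = !exact)$p.value)
}

#' Motif-level genotype contrast with FDR adjustment
#'
#' Tests every motif shared between a wild-type and a mutant motif-site
#' table with [motif_genotype_test()] and adjusts p-values across motifs
#' (Benjamini-Hochberg by default). A motif significantly decreased in the
#' mutant (p below `alpha` and lower mutant median) is a sequence
#' preference of the knocked-out PUS.
#'
#' @param wt_sites,mutant_sites Motif-site tables ([extract_motifs()] or
#'   [filter_motif_sites()] output) for the two genotypes.
#' @param adjust `"BH"` or `"none"`.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A `data.frame` per motif: `kmer`, `occurrences` (wild-type
#'   sites), `n_mutant`, `p_value`, `q_value`, `decreased`, `significant`.
#' @export
motif_contrast <- function(wt_sites, mutant_sites, adjust = c("BH", "none"),
                           alpha = 0.05) {
  adjust <- match.arg(adjust)
  kmers <- intersect(unique(wt_sites$kmer), unique(mutant_sites$kmer))
  if (!length(kmers)) {
    return(data.frame(kmer = character(), occurrences = integer(),
                      n_mutant = integer(), p_value = numeric(),
                      q_value = numeric(), decreased = logical(),
                      significant = logical()))
  }
  res <- lapply(kmers, function(k) {
    w <- wt_sites$fraction[wt_sites$kmer == k]
    m <- mutant_sites$fraction[mutant_sites$kmer == k]
    data.frame(kmer = k, occurrences = length(w), n_mutant = length(m),
               p_value = motif_genotype_test(w, m),
               decreased = stats::median(m) < stats::median(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH")
                 else out$p_value
  out$significant <- out$q_value < alpha & out$decreased
  out <- out[, c("kmer", "occurrences", "n_mutant", "p_value", "q_value",
                 "decreased", "significant")]
  out[order(out$q_value, out$kmer), , drop = FALSE]
}

#' Position-frequency summary and consensus of significant motifs
#'
#' Transparent modal consensus over equal-length k-mers: per-offset base
#' counts, consensus = modal base per offset, written lowercase when the
#' modal frequency is below 0.5.
#'
#' @param kmers Character vector (with multiplicities) of equal-length
#'   k-mers over A/C/G/U.
#' @return A list with `pfm` (4 x k count matrix, rows A/C/G/U, columns
#'   summing to `length(kmers)`) and `consensus` (character scalar).
#' @export
consensus_from_motifs <- function(kmers) {
  if (!length(kmers)) stop_data("no motifs supplied")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop_data("k-mers must all have the same length")
  mat <- do.call(rbind, strsplit(kmers, ""))
  bases <- c("A", "C", "G", "U")
  pfm <- vapply(seq_len(k), function(j) {
    vapply(bases, function(b) sum(mat[, j] == b), numeric(1))
  }, numeric(4))
  rownames(pfm) <- bases
  colnames(pfm) <- as.character(seq_len(k))
  cons <- vapply(seq_len(k), function(j) {
    col <- pfm[, j]
    b <- bases[which.max(col)]
    if (max(col) / sum(col) < 0.5) tolower(b) else b
  }, character(1))
  list(pfm = pfm, consensus = paste(cons, collapse = ""))
}
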