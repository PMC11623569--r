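#' Calling thresholds
#'
#' Bundles the filters a uridine position must pass to be called
#' pseudouridylated. Isolate defaults: coverage depth >= 20 in both treated
#' and untreated samples, deletion count >= 5 in treated, deletion fraction
#' >= 5% in treated and < 1% in untreated. Microbiome defaults relax the
#' untreated cap (strain heterogeneity inflates untreated deletions) and
#' instead require the treated fraction >= 2%, at least 2-fold above the
#' untreated fraction, and a one-sided Fisher exact p < 0.01.
#'
#' @param mode `"isolate"` or `"microbiome"`; selects the default set.
#' @param min_depth Minimum depth in both samples.
#' @param min_del_count Minimum treated deletion count.
#' @param min_treated_fraction Minimum treated deletion fraction.
#' @param max_untreated_fraction Untreated fraction must be strictly below
#'   this (isolate mode only; `NA` disables).
#' @param min_fold Treated fraction must be at least this multiple of the
#'   untreated fraction (microbiome mode only; `NA` disables).
#' @param max_p Fisher exact p must be strictly below this (microbiome mode
#'   only; `NA` disables).
#' @param min_samples_high_conf Samples required for high confidence.
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(mode = c("isolate", "microbiome"),
                            min_depth = 20L,
                            min_del_count = 5L,
                            min_treated_fraction = NULL,
                            max_untreated_fraction = NULL,
                            min_fold = NULL,
                            max_p = NULL,
                            min_samples_high_conf = 2L) {
  mode <- match.arg(mode)
  th <- list(
    mode = mode,
    min_depth = as.integer(min_depth),
    min_del_count = as.integer(min_del_count),
    min_treated_fraction = min_treated_fraction %||%
      if (mode == "isolate") 0.05 else 0.02,
    max_untreated_fraction = max_untreated_fraction %||%
      if (mode == "isolate") 0.01 else NA_real_,
    min_fold = min_fold %||% if (mode == "microbiome") 2.0 else NA_real_,
    max_p = max_p %||% if (mode == "microbiome") 0.01 else NA_real_,
    min_samples_high_conf = as.integer(min_samples_high_conf))
  stopifnot(th$min_depth > 0, th$min_del_count > 0,
            th$min_treated_fraction > 0, th$min_treated_fraction <= 1)
  class(th) <- "call_thresholds"
  th
}

#' One-sided Fisher exact test for deletion enrichment
#'
#' Exact hypergeometric upper-tail probability that the treated sample shows
#' at least the observed number of deletions, given the margins of the 2x2
#' table (deleted / non-deleted reads x treated / untreated). One-sided in
#' the direction of treated enrichment, the biological hypothesis of the
#' bisulfite assay. Vectorised over sites.
#'
#' @param del_treated,nondel_treated,del_untreated,nondel_untreated
#'   Non-negative integer cell counts.
#' @return P-values in `[0, 1]`.
#' @export
fisher_exact_one_sided <- function(del_treated, nondel_treated,
                                   del_untreated, nondel_untreated) {
  a <- as.numeric(del_treated);    b <- as.numeric(nondel_treated)
  c_ <- as.numeric(del_untreated); d <- as.numeric(nondel_untreated)
  if (any(c(a, b, c_, d) < 0)) stop_data("cell counts must be >= 0")
  n_total <- a + b + c_ + d
  if (any(n_total == 0)) stop_data("table total must be > 0")
  ## P(X >= a), X ~ Hypergeom(N, K = total deletions, n = treated depth)
  stats::phyper(a - 1, m = a + c_, n = b + d, k = a + b, lower.tail = FALSE)
}

## shared filter core for both calling modes; the library is unstranded, so a
## genomic position is a U candidate on + when the reference base is T and on
## - when it is A
call_sites_engine <- function(treated, untreated, thresholds,
                              reference = NULL) {
  stopifnot(inherits(treated, "pileup_table"),
            inherits(untreated, "pileup_table"),
            inherits(thresholds, "call_thresholds"))
  th <- thresholds
  t_df <- as.data.frame(treated)
  key_u <- paste(untreated$ref, untreated$pos)
  idx <- match(paste(t_df$ref, t_df$pos), key_u)
  depth_u <- ifelse(is.na(idx), 0L, untreated$depth[idx])
  del_u <- ifelse(is.na(idx), 0L, untreated$del_count[idx])

  strand <- ifelse(t_df$base == "T", "+",
                   ifelse(t_df$base == "A", "-", NA_character_))
  ok <- !is.na(strand) &
    t_df$depth >= th$min_depth & depth_u >= th$min_depth &
    t_df$del_count >= th$min_del_count
  frac_t <- ifelse(t_df$depth > 0, t_df$del_count / t_df$depth, 0)
  frac_u <- ifelse(depth_u > 0, del_u / depth_u, 0)
  ok <- ok & frac_t >= th$min_treated_fraction
  if (!is.na(th$max_untreated_fraction)) {
    ok <- ok & frac_u < th$max_untreated_fraction
  }
  if (!is.na(th$min_fold)) {
    ok <- ok & (frac_u == 0 | frac_t >= th$min_fold * frac_u)
  }
  p_val <- rep(NA_real_, nrow(t_df))
  if (!is.na(th$max_p)) {
    cand <- which(ok)
    if (length(cand)) {
      p_val[cand] <- fisher_exact_one_sided(
        t_df$del_count[cand], t_df$depth[cand] - t_df$del_count[cand],
        del_u[cand], depth_u[cand] - del_u[cand])
      ok[cand] <- ok[cand] & p_val[cand] < th$max_p
    }
  }
  keep <- which(ok)
  calls <- data.frame(
    ref = t_df$ref[keep], pos = t_df$pos[keep], strand = strand[keep],
    base = t_df$base[keep],
    depth_treated = t_df$depth[keep], del_treated = t_df$del_count[keep],
    depth_untreated = depth_u[keep], del_untreated = del_u[keep],
    treated_frac = frac_t[keep], untreated_frac = frac_u[keep],
    psi_proportion = psi_proportion(frac_t[keep], frac_u[keep],
                                    mode = th$mode),
    p_value = p_val[keep],
    n_supporting = rep(1L, length(keep)),
    supporting_samples = rep(attr(treated, "sample_id") %||% "sample",
                             length(keep)),
    high_confidence = rep(FALSE, length(keep)),
    homopolymer = rep(NA, length(keep)),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$ref, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(reference) && nrow(calls)) {
    calls <- flag_homopolymer_ambiguity(calls, reference, reposition = FALSE)
  }
  calls
}

#' Call Psi sites, isolate mode
#'
#' Hard-threshold caller for clonal isolates: a uridine position is called
#' iff the reference base on the examined strand is U (genomic T on `+`,
#' genomic A on `-`), depth >= `min_depth` in both samples, treated deletion
#' count >= `min_del_count`, treated deletion fraction >=
#' `min_treated_fraction`, and untreated fraction strictly below
#' `max_untreated_fraction`. A position absent from the untreated table
#' counts as depth 0 there and fails the depth filter. The reported Psi
#' proportion is the treated deletion fraction.
#'
#' @param treated,untreated Paired [pileup_table()]s from the same
#'   condition/replicate (bisulfite-treated and untreated halves).
#' @param thresholds A [call_thresholds()]; defaults to isolate defaults.
#' @param reference Optional named character vector of reference sequences;
#'   when given, calls are annotated with the U-homopolymer ambiguity flag.
#' @return A `data.frame` of calls sorted by (ref, pos), one row per site.
#' @export
call_sites_isolate <- function(treated, untreated,
                               thresholds = call_thresholds("isolate"),
                               reference = NULL) {
  if (thresholds$mode != "isolate") stop_data("thresholds are not isolate-mode")
  call_sites_engine(treated, untreated, thresholds, reference)
}

#' Call Psi sites, microbiome mode
#'
#' Caller for complex communities, where strain-heterogeneity indels inflate
#' untreated deletion rates: requires depth >= 20 in both samples, treated
#' deletion count >= 5, treated fraction >= 2%, treated fraction at least
#' 2-fold above the untreated fraction (an untreated fraction of 0 passes),
#' and a one-sided Fisher exact p < 0.01 comparing deletions and depth
#' between samples. The Psi proportion is the delta deletion fraction
#' (treated minus untreated, floored at 0).
#'
#' @inheritParams call_sites_isolate
#' @return A `data.frame` of calls sorted by (ref, pos).
#' @export
call_sites_microbiome <- function(treated, untreated,
                                  thresholds = call_thresholds("microbiome"),
                                  reference = NULL) {
  if (thresholds$mode != "microbiome") {
    stop_data("thresholds are not microbiome-mode")
  }
  call_sites_engine(treated, untreated, thresholds, reference)
}

#' Aggregate per-sample calls into high-confidence sites
#'
#' A site is high-confidence when it is called at the identical (ref,
#' position, strand) in at least `min_samples` treated libraries, whether
#' biological replicates or different conditions. The merged record carries
#' the union of supporting samples, mean fractions across supporting
#' samples, and the smallest per-sample p-value.
#'
#' @param calls_by_sample Named list of call `data.frame`s, one per treated
#'   sample; names are sample ids (fallback: each table's
#'   `supporting_samples`).
#' @param min_samples Minimum number of supporting samples (default 2);
#'   `min_samples = 1` returns the union of the inputs.
#' @return A call `data.frame` with `n_supporting`, comma-separated
#'   `supporting_samples`, and `high_confidence = TRUE`.
#' @export
aggregate_high_confidence <- function(calls_by_sample, min_samples = 2L) {
  stopifnot(is.list(calls_by_sample), length(calls_by_sample) >= 1L)
  ids <- names(calls_by_sample) %||% paste0("sample", seq_along(calls_by_sample))
  if (is.null(names(calls_by_sample))) names(calls_by_sample) <- ids
  stacked <- do.call(rbind, lapply(ids, function(s) {
    df <- calls_by_sample[[s]]
    if (!nrow(df)) return(NULL)
    df$.sample <- s
    df
  }))
  if (is.null(stacked) || !nrow(stacked)) {
    empty <- calls_by_sample[[1L]][0, , drop = FALSE]
    return(empty)
  }
  key <- paste(stacked$ref, stacked$pos, stacked$strand, sep = "\r")
  grp <- split(seq_len(nrow(stacked)), key)
  rows <- lapply(grp, function(i) {
    sub <- stacked[i, , drop = FALSE]
    n <- length(unique(sub$.sample))
    if (n < min_samples) return(NULL)
    out <- sub[1L, setdiff(names(sub), ".sample"), drop = FALSE]
    out$depth_treated <- as.integer(round(mean(sub$depth_treated)))
    out$del_treated <- as.integer(round(mean(sub$del_treated)))
    out$depth_untreated <- as.integer(round(mean(sub$depth_untreated)))
    out$del_untreated <- as.integer(round(mean(sub$del_untreated)))
    out$treated_frac <- mean(sub$treated_frac)
    out$untreated_frac <- mean(sub$untreated_frac)
    out$psi_proportion <- mean(sub$psi_proportion)
    out$p_value <- if (all(is.na(sub$p_value))) NA_real_
                   else min(sub$p_value, na.rm = TRUE)
    out$n_supporting <- n
    out$supporting_samples <- paste(sort(unique(sub$.sample)), collapse = ",")
    out$high_confidence <- TRUE
    out$homopolymer <- if (all(is.na(sub$homopolymer))) NA
                       else any(sub$homopolymer, na.rm = TRUE)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(stacked[0, setdiff(names(stacked), ".sample")])
  res <- res[order(res$ref, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag calls inside uridine homopolymer runs
#'
#' When a Psi site sits in a run of >= 2 consecutive uridines, the aligner
#' left-aligns the deletion and the exact modified position cannot be
#' resolved. Such calls are flagged; with `reposition = TRUE` (the
#' standalone contract) the reported position is moved to the leftmost U of
#' the run, matching left-aligned indels. The callers attach the flag
#' without repositioning, since aligned data is already left-aligned.
#'
#' @param calls A call `data.frame` with `ref`, `pos`, `strand`.
#' @param reference Named character vector of reference sequences.
#' @param reposition Move flagged calls to the leftmost U of their run.
#' @return `calls` with logical column `homopolymer` (and adjusted `pos`
#'   when repositioned).
#' @export
flag_homopolymer_ambiguity <- function(calls, reference, reposition = TRUE) {
  if (!nrow(calls)) {
    calls$homopolymer <- logical(0)
    return(calls)
  }
  target <- ifelse(calls$strand == "+", "T", "A")
  runs <- vapply(seq_len(nrow(calls)), function(i) {
    seqc <- reference[[calls$ref[i]]]
    p <- calls$pos[i]
    if (substr(seqc, p, p) != target[i]) return(c(p, p))
    l <- p
    while (l > 1L && substr(seqc, l - 1L, l - 1L) == target[i]) l <- l - 1L
    r <- p
    n <- nchar(seqc)
    while (r < n && substr(seqc, r + 1L, r + 1L) == target[i]) r <- r + 1L
    c(l, r)
  }, numeric(2))
  run_len <- runs[2L, ] - runs[1L, ] + 1L
  calls$homopolymer <- run_len >= 2L
  if (reposition) calls$pos <- as.integer(runs[1L, ])
  calls
}
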