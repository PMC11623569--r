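#' Per-site deletion fraction
#'
#' Deletions divided by spanning-read depth. Under bisulfite treatment the
#' deletion fraction at a uridine is proportional to the fraction of
#' transcript molecules carrying Psi at that site (stoichiometry): a fraction
#' of 0.5 means half the transcripts are modified.
#'
#' @param depth Integer spanning-read depth (> 0).
#' @param del_count Integer deletion count.
#' @return Numeric fraction in `[0, 1]`, vectorised.
#' @export
deletion_fraction <- function(depth, del_count) {
  if (any(depth <= 0)) {
    stop_data("deletion fraction undefined at depth 0; filter sites first")
  }
  if (any(del_count < 0) || any(del_count > depth)) {
    stop_data("del_count must satisfy 0 <= del_count <= depth")
  }
  del_count / depth
}

#' Psi stoichiometry from treated/untreated deletion fractions
#'
#' In isolate mode the untreated fraction is already forced near zero by the
#' calling filter (< 1%), so the treated deletion fraction itself is reported
#' as the Psi proportion. In microbiome mode strain-heterogeneity indels
#' inflate untreated deletions, so the proportion is the difference in
#' deletion fraction between treated and untreated samples (the delta
#' deletion fraction), floored at zero.
#'
#' @param treated_fraction,untreated_fraction Deletion fractions in `[0, 1]`.
#' @param mode `"isolate"` or `"microbiome"`.
#' @return Psi proportion in `[0, 1]`, vectorised.
#' @export
psi_proportion <- function(treated_fraction, untreated_fraction = 0,
                           mode = c("isolate", "microbiome")) {
  mode <- match.arg(mode)
  assert_fraction(treated_fraction, "treated_fraction")
  assert_fraction(untreated_fraction, "untreated_fraction")
  if (mode == "isolate") treated_fraction
  else pmax(0, treated_fraction - untreated_fraction)
}

#' Genome-wide per-base deletion profile (deletion-ratio diagnostic)
#'
#' Aggregates deletion and depth counts by reference base over all covered
#' positions and reports, per base B, the mean of the pairwise frequency
#' ratios freq(B)/freq(X) against the other three bases. For a genome near
#' 50% GC with base-independent (random) deletions every ratio is ~1;
#' bisulfite treatment of Psi-containing RNA drives the U (reference T)
#' ratio far above 1. This is the library-quality diagnostic run before
#' calling.
#'
#' @param pileup A [pileup_table()]; the `base` column supplies reference
#'   bases, so no FASTA is needed.
#' @return A `data.frame` with one row per base (`A`, `C`, `G`, `T`):
#'   aggregate `depth`, `deletions`, deletion `frequency`, and mean pairwise
#'   `ratio`. A base class absent from the data has `NA` frequency and ratio.
#' @export
base_deletion_profile <- function(pileup) {
  stopifnot(inherits(pileup, "pileup_table"))
  if (!nrow(pileup)) stop_data("empty pileup table")
  keep <- pileup$depth > 0 & pileup$base %in% c("A", "C", "G", "T")
  p <- pileup[keep, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  depth <- vapply(bases, function(b) sum(as.numeric(p$depth[p$base == b])),
                  numeric(1))
  dels <- vapply(bases, function(b) sum(as.numeric(p$del_count[p$base == b])),
                 numeric(1))
  freq <- ifelse(depth > 0, dels / depth, NA_real_)
  ratio <- vapply(seq_along(bases), function(i) {
    others <- freq[-i]
    others <- others[!is.na(others) & others > 0]
    if (is.na(freq[i]) || !length(others)) return(NA_real_)
    mean(freq[i] / others)
  }, numeric(1))
  data.frame(base = bases, depth = depth, deletions = dels,
             frequency = freq, ratio = ratio, row.names = NULL)
}

#' Uridine deletion ratio from a profile
#'
#' Convenience accessor: the mean pairwise deletion ratio of U (reference
#' base T) against A, C and G from [base_deletion_profile()].
#'
#' @param profile Output of [base_deletion_profile()].
#' @return A single numeric ratio.
#' @export
uridine_deletion_ratio <- function(profile) {
  profile$ratio[profile$base == "T"]
}
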