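#' Transcript-level Psi-strength
#'
#' The sum of deletion fractions over all Psi sites within one RNA: the
#' transcript's total modification load. An empty site list has strength 0.
#'
#' @param fractions Numeric vector of per-site deletion fractions in
#'   `[0, 1]`.
#' @return A single numeric sum.
#' @export
psi_strength <- function(fractions) {
  if (!length(fractions)) return(0)
  assert_fraction(fractions, "deletion fraction")
  sum(fractions)
}

#' Transcripts-per-million normalisation with pseudocount
#'
#' `rate_g = (count_g + pseudocount) / length_g`;
#' `TPM_g = rate_g / sum(rates) * 1e6`, so columns always sum to one
#' million. With `min_reads_prefilter` set (microbiome mode), genes whose
#' raw count is below the threshold in every sample are removed before
#' normalisation.
#'
#' @param counts Named numeric vector (one sample) or genes x samples
#'   matrix/data.frame of raw unique read counts.
#' @param lengths Named numeric vector of gene lengths in nucleotides.
#' @param pseudocount Added to every gene's count (default 1).
#' @param min_reads_prefilter Optional integer; drop genes with raw count
#'   `<` this value in all samples before normalising.
#' @return TPM values with the same shape and names as `counts` (minus
#'   prefiltered genes).
#' @export
tpm <- function(counts, lengths, pseudocount = 1,
                min_reads_prefilter = NULL) {
  vec_in <- is.null(dim(counts))
  m <- if (vec_in) matrix(counts, ncol = 1, dimnames = list(names(counts)))
       else as.matrix(counts)
  if (is.null(rownames(m))) stop_data("counts must be named by gene")
  missing_len <- setdiff(rownames(m), names(lengths))
  if (length(missing_len)) {
    stop_data("no length for gene(s): ", paste(missing_len, collapse = ", "))
  }
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop_data("gene lengths must be > 0")
  if (any(m < 0)) stop_data("counts must be >= 0")
  if (!is.null(min_reads_prefilter)) {
    keep <- apply(m, 1L, function(x) any(x >= min_reads_prefilter))
    m <- m[keep, , drop = FALSE]
    len <- len[keep]
    if (!nrow(m)) stop_data("prefilter removed every gene")
  }
  rates <- (m + pseudocount) / len
  out <- sweep(rates, 2L, colSums(rates), "/") * 1e6
  if (vec_in) out[, 1L] else out
}

#' Per-gene Psi profiles from called sites
#'
#' Assigns calls to genes by same-strand interval overlap and summarises
#' each gene: number of sites, Psi-strength (sum of per-site Psi
#' proportions), sites per kb, mean site proportion, and (optionally) TPM.
#' Genes without calls are included with zero sites so that downstream
#' genotype/condition contrasts see the absence of a site as strength 0.
#'
#' @param calls Call `data.frame` with `ref`, `pos`, `strand`,
#'   `psi_proportion`.
#' @param annotation An [annotation_set()].
#' @param tpm_values Optional named vector of TPM per gene.
#' @return A `data.frame` with one row per gene: `gene_id`, `length`,
#'   `n_sites`, `psi_strength`, `sites_per_kb`, `mean_site_proportion`,
#'   `tpm`.
#' @export
transcript_psi_profiles <- function(calls, annotation, tpm_values = NULL) {
  stopifnot(inherits(annotation, "annotation_set"))
  gene_gr <- GenomicRanges::GRanges(
    annotation$ref, IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  strength <- sites <- numeric(nrow(annotation))
  if (nrow(calls)) {
    call_gr <- GenomicRanges::GRanges(
      calls$ref, IRanges::IRanges(calls$pos, calls$pos),
      strand = calls$strand)
    hits <- GenomicRanges::findOverlaps(call_gr, gene_gr)
    by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    for (g in names(by_gene)) {
      i <- as.integer(g)
      idx <- by_gene[[g]]
      sites[i] <- length(idx)
      strength[i] <- sum(calls$psi_proportion[idx])
    }
  }
  len <- annotation$end - annotation$start + 1L
  data.frame(
    gene_id = annotation$gene_id,
    length = len,
    n_sites = as.integer(sites),
    psi_strength = strength,
    sites_per_kb = sites * 1000 / len,
    mean_site_proportion = ifelse(sites > 0, strength / pmax(sites, 1),
                                  NA_real_),
    tpm = if (is.null(tpm_values)) NA_real_
          else unname(tpm_values[annotation$gene_id]),
    stringsAsFactors = FALSE)
}

## per-replicate gene-level strength delta, shared by the PUS and stress
## contrasts; profiles are lists (one element per replicate) of data.frames
## with gene_id and psi_strength; a gene absent from one side contributes 0
strength_delta <- function(a_profiles, b_profiles) {
  if (length(a_profiles) != length(b_profiles)) {
    stop_data("replicate mismatch: ", length(a_profiles), " vs ",
              length(b_profiles), " profiles")
  }
  genes <- unique(unlist(c(
    lapply(a_profiles, `[[`, "gene_id"),
    lapply(b_profiles, `[[`, "gene_id"))))
  get <- function(df) {
    s <- stats::setNames(rep(0, length(genes)), genes)
    s[df$gene_id] <- df$psi_strength
    s
  }
  a_mat <- vapply(a_profiles, get, numeric(length(genes)))
  b_mat <- vapply(b_profiles, get, numeric(length(genes)))
  if (length(genes) == 1L) {
    a_mat <- matrix(a_mat, nrow = 1, dimnames = list(genes))
    b_mat <- matrix(b_mat, nrow = 1, dimnames = list(genes))
  }
  list(genes = genes, a = a_mat, b = b_mat, delta = a_mat - b_mat)
}

#' Assign genes to a pseudouridine synthase from a knockout contrast
#'
#' A gene is considered pseudouridylated by a given PUS when the difference
#' in gene-level Psi-strength between wild type and the PUS deletion mutant
#' is at least `min_delta` in every biological replicate pair (replicates
#' paired by index). Comparisons are restricted by the caller to samples
#' grown at the same condition (37 degrees C in the original design). A
#' gene may be assigned to several PUS enzymes across contrasts.
#'
#' @param wt_profiles,mutant_profiles Lists (one element per replicate) of
#'   gene-profile `data.frame`s from [transcript_psi_profiles()] (only
#'   `gene_id` and `psi_strength` are used). A gene absent from one side
#'   contributes strength 0.
#' @param min_delta Minimum per-replicate strength difference (default
#'   0.05).
#' @param pus_name Label of the knocked-out enzyme.
#' @return A `data.frame` per gene with per-replicate deltas and logical
#'   `assigned`.
#' @export
assign_pus <- function(wt_profiles, mutant_profiles, min_delta = 0.05,
                       pus_name = "PUS") {
  sd_ <- strength_delta(wt_profiles, mutant_profiles)
  delta <- sd_$delta
  assigned <- apply(delta >= min_delta, 1L, all)
  out <- data.frame(gene_id = sd_$genes, pus = pus_name,
                    stringsAsFactors = FALSE)
  for (r in seq_len(ncol(delta))) out[[paste0("delta_rep", r)]] <- delta[, r]
  out$assigned <- as.logical(assigned)
  rownames(out) <- NULL
  out
}

#' Detect stress-increased pseudouridylation
#'
#' A gene harbors increased Psi under a stress condition when the
#' stress-minus-control gene-level Psi-strength difference is at least
#' `min_delta` in every replicate pair. Candidates whose control strength
#' comes within `min_delta / 2` of the cutoff are flagged for review rather
#' than removed — these are the near-miss control signals most likely to be
#' false positives.
#'
#' @param stress_profiles,control_profiles Per-replicate lists of gene
#'   profiles, as in [assign_pus()].
#' @param min_delta Minimum per-replicate strength difference (default
#'   0.05).
#' @return A `data.frame` per gene with per-replicate deltas, logical
#'   `increased`, and logical `review_flag`.
#' @export
differential_stress <- function(stress_profiles, control_profiles,
                                min_delta = 0.05) {
  sd_ <- strength_delta(stress_profiles, control_profiles)
  increased <- apply(sd_$delta >= min_delta, 1L, all)
  near_cutoff <- apply(sd_$b >= min_delta / 2, 1L, any)
  out <- data.frame(gene_id = sd_$genes, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(sd_$delta))) {
    out[[paste0("delta_rep", r)]] <- sd_$delta[, r]
  }
  out$increased <- as.logical(increased)
  out$review_flag <- as.logical(increased & near_cutoff)
  rownames(out) <- NULL
  out
}

#' Classify a position as paired or unpaired from dot-bracket structure
#'
#' @param dot_bracket Secondary-structure string over `(`, `)`, `.`.
#' @param position 1-based position within the string.
#' @return `"paired"` or `"unpaired"` (vectorised over `position`).
#' @export
pairing_class <- function(dot_bracket, position) {
  stopifnot(length(dot_bracket) == 1L)
  chars <- strsplit(dot_bracket, "")[[1L]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop_data("dot-bracket string may contain only '(', ')' and '.'")
  }
  if (sum(chars == "(") != sum(chars == ")")) {
    warning("unbalanced brackets in dot-bracket string")
  }
  if (any(position < 1L | position > length(chars))) {
    stop_data("position outside structure string (length ", length(chars), ")")
  }
  ifelse(chars[position] == ".", "unpaired", "paired")
}

#' Rank correlation of Psi site density and level with mRNA abundance
#'
#' Spearman correlation (tie-corrected ranks) of (i) Psi sites per kb and
#' (ii) mean per-site Psi proportion (delta deletion fraction) against TPM,
#' across transcripts. Used in microbiome mode to ask whether the number of
#' modification sites, rather than their stoichiometry, tracks transcript
#' abundance.
#'
#' @param profiles Output of [transcript_psi_profiles()] with `tpm` filled;
#'   at least 3 rows.
#' @return A `data.frame` with rows `sites_per_kb` and `psi_level`: `rho`,
#'   `p_value`, `n`. Constant inputs yield `NA` with a message.
#' @export
sites_vs_abundance <- function(profiles) {
  if (nrow(profiles) < 3L) stop_data("need >= 3 transcript profiles")
  cor_one <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
      return(c(rho = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  a <- cor_one(profiles$sites_per_kb, profiles$tpm)
  b <- cor_one(profiles$mean_site_proportion, profiles$tpm)
  data.frame(metric = c("sites_per_kb", "psi_level"),
             rho = c(a["rho"], b["rho"]),
             p_value = c(a["p"], b["p"]),
             n = as.integer(c(a["n"], b["n"])),
             row.names = NULL)
}
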