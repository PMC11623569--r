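#' Read reference sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write reference sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Construct a gene annotation set
#'
#' Internal coordinates are 1-based inclusive throughout the package; BED
#' input/output converts at the boundary.
#'
#' @param gene_id Unique gene identifiers.
#' @param ref Reference sequence name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` or `"-"`.
#' @param feature_class Feature type label (default `"gene"`).
#' @return A `data.frame` of class `annotation_set`.
#' @export
annotation_set <- function(gene_id, ref, start, end, strand,
                           feature_class = "gene") {
  df <- data.frame(gene_id = as.character(gene_id), ref = as.character(ref),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   feature_class = as.character(feature_class),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop_data("annotation start > end")
  if (!all(df$strand %in% c("+", "-"))) {
    stop_data("unknown strand symbol: ",
              df$strand[!df$strand %in% c("+", "-")][1L])
  }
  if (anyDuplicated(df$gene_id)) {
    stop_data("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Read gene annotations from GFF3 or BED
#'
#' Parsing is delegated to [rtracklayer::import()]; GFF3 rows are restricted
#' to `gene` features when any are present, and the gene identifier is taken
#' from the first populated attribute among `ID`, `locus_tag`, `gene`, `Name`.
#'
#' @param path Annotation file path.
#' @param format `"GFF3"` or `"BED"` (default guessed from extension).
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop_data("annotation file not found: ", path)
  format <- toupper(format %||%
    if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3")
  if (!format %in% c("GFF3", "BED")) stop_data("unsupported format: ", format)
  gr <- if (format == "BED") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  meta <- S4Vectors::mcols(gr)
  if (format == "GFF3" && "type" %in% names(meta) &&
      any(as.character(meta$type) == "gene")) {
    gr <- gr[as.character(meta$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
  }
  ids <- rep(NA_character_, length(gr))
  for (field in c("ID", "locus_tag", "gene", "Name", "name")) {
    if (field %in% names(meta)) {
      v <- as.character(meta[[field]])
      ids <- ifelse(is.na(ids) & !is.na(v) & nzchar(v), v, ids)
    }
  }
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop_data("unknown strand symbol: *")
  annotation_set(
    gene_id = ids,
    ref = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = strand,
    feature_class = if ("type" %in% names(meta))
      as.character(meta$type) else "gene")
}

#' Write an annotation set as GFF3
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$ref,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- ann$feature_class
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write and read called sites as TSV
#'
#' The TSV is the package's native call format: one row per site, 1-based
#' inclusive coordinates, a `#`-prefixed header documenting the convention.
#'
#' @param calls A call `data.frame` as produced by [call_sites_isolate()],
#'   [call_sites_microbiome()] or [aggregate_high_confidence()].
#' @param path Output path.
#' @return `path` ([write_calls()]) or the call `data.frame` ([read_calls()]).
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# psiscan calls; coordinates 1-based inclusive", con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop_data("calls file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = lines, header = TRUE,
                          stringsAsFactors = FALSE)
  if ("strand" %in% names(df)) df$strand <- as.character(df$strand)
  df
}

#' Export called sites as BED
#'
#' BED uses 0-based half-open coordinates: a single site at internal 1-based
#' position p becomes the interval `[p-1, p)`. The score column carries the
#' Psi proportion scaled to 0-1000.
#'
#' @param calls A call `data.frame` with `ref`, `pos`, `strand`,
#'   `psi_proportion`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(
    chrom = calls$ref,
    start = calls$pos - 1L,
    end = calls$pos,
    name = sprintf("psi_%s_%d%s", calls$ref, calls$pos, calls$strand),
    score = as.integer(round(pmin(1, pmax(0, calls$psi_proportion)) * 1000)),
    strand = calls$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# psiscan calls; BED 0-based half-open", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an external predictor score table
#'
#' Promoter / terminator / target predictors are third-party tools; their
#' per-window probability scores are ingested from a headered TSV with
#' columns `ref`, `window_start`, `window_end`, `score`, `predictor`.
#'
#' @param path TSV path.
#' @return A validated `data.frame` of scores.
#' @export
read_predictor_scores <- function(path) {
  if (!file.exists(path)) stop_data("score table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("ref", "window_start", "window_end", "score", "predictor")
  if (!all(need %in% names(df))) {
    stop_data("predictor table must have columns ", paste(need, collapse = ", "))
  }
  assert_fraction(df$score, "predictor score")
  df
}
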