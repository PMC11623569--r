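#' Construct a per-base pileup count table
#'
#' The atomic input of the pipeline: one row per reference position carrying
#' the spanning-read depth and the number of reads with a deletion at that
#' position. Depth counts every read spanning the position, including reads
#' carrying the deletion, so `del_count / depth` is the deletion fraction.
#'
#' @param ref Character, reference sequence name per row.
#' @param pos Integer, 1-based position.
#' @param base Reference base at the position (`A`, `C`, `G`, `T` or `N`).
#' @param depth Integer spanning-read depth (>= 0).
#' @param del_count Integer deletion count (0 <= del_count <= depth).
#' @param sample_id Sample identifier stored as an attribute.
#' @return A `data.frame` of class `pileup_table` with columns
#'   `ref`, `pos`, `base`, `depth`, `del_count`.
#' @export
pileup_table <- function(ref, pos, base, depth, del_count,
                         sample_id = "sample") {
  df <- data.frame(ref = as.character(ref), pos = as.integer(pos),
                   base = toupper(as.character(base)),
                   depth = as.integer(depth),
                   del_count = as.integer(del_count),
                   stringsAsFactors = FALSE)
  if (any(df$depth < 0) || any(df$del_count < 0)) {
    stop_data("pileup counts must be non-negative")
  }
  if (any(df$del_count > df$depth)) {
    stop_data("del_count exceeds depth at ",
              sum(df$del_count > df$depth), " position(s)")
  }
  if (nrow(df) && any(df$pos < 1L)) stop_data("positions are 1-based (>= 1)")
  key <- paste(df$ref, df$pos)
  if (anyDuplicated(key)) {
    stop_data("duplicated (reference, position) in pileup: ",
              key[duplicated(key)][1L])
  }
  df <- df[order(df$ref, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("pileup_table", "data.frame")
  df
}

#' Read a per-base pileup count table
#'
#' Two dialects are accepted. `"bam-readcount"` is the whitespace-separated
#' text emitted by bam-readcount (reference, 1-based position, reference base,
#' depth, then one `allele:count:...` field per allele; deletion alleles are
#' prefixed `-`, insertions `+`). `"simple-tsv"` is a 6-column headered TSV
#' (`ref`, `pos`, `base`, `depth`, `del_count`, `nondel_count`) written by
#' [write_pileup()] and by the simulator, so tests need no external tooling.
#'
#' @param path Path to the pileup file.
#' @param dialect `"bam-readcount"` or `"simple-tsv"`.
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @return A [pileup_table()].
#' @export
read_pileup <- function(path, dialect = c("bam-readcount", "simple-tsv"),
                        sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("pileup file not found: ", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "simple-tsv") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    if (!length(lines) || (length(lines) == 1L && !nzchar(lines))) {
      warning("empty pileup file: ", path)
      return(pileup_table(character(), integer(), character(), integer(),
                          integer(), sample_id))
    }
    df <- utils::read.delim(text = lines, header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("ref", "pos", "base", "depth", "del_count")
    if (!all(need %in% names(df))) {
      stop_data("simple-tsv pileup must have columns ",
                paste(need, collapse = ", "))
    }
    return(pileup_table(df$ref, df$pos, df$base, df$depth, df$del_count,
                        sample_id))
  }
  ## bam-readcount text
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    warning("empty pileup file: ", path)
    return(pileup_table(character(), integer(), character(), integer(),
                        integer(), sample_id))
  }
  fields <- strsplit(lines, "[\t ]+")
  n_f <- lengths(fields)
  bad <- which(n_f < 4L)
  if (length(bad)) {
    stop_data(sprintf("unparseable bam-readcount row at line %d: '%s'",
                      bad[1L], lines[bad[1L]]))
  }
  ref <- vapply(fields, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(pos)) {
    stop_data("non-integer position at line ", which(is.na(pos))[1L])
  }
  base <- toupper(vapply(fields, `[[`, character(1), 3L))
  depth <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(depth)) {
    stop_data("non-integer depth at line ", which(is.na(depth))[1L])
  }
  del <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 5L) return(0L)
    alleles <- strsplit(f[5:length(f)], ":", fixed = TRUE)
    d <- 0L
    for (a in alleles) {
      if (length(a) < 2L) {
        stop_data(sprintf("unparseable allele field at line %d: '%s'",
                          i, paste(a, collapse = ":")))
      }
      if (startsWith(a[[1L]], "-")) {
        cnt <- suppressWarnings(as.integer(a[[2L]]))
        if (is.na(cnt)) {
          stop_data(sprintf("non-integer allele count at line %d", i))
        }
        d <- d + cnt
      }
    }
    d
  }, integer(1))
  pileup_table(ref, pos, base, depth, pmin(del, depth), sample_id)
}

#' Write a pileup table in the simple-tsv dialect
#'
#' @param x A [pileup_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(x, path) {
  stopifnot(inherits(x, "pileup_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# psiscan pileup, simple-tsv dialect; positions 1-based",
               sprintf("# sample_id=%s", attr(x, "sample_id"))), con)
  out <- data.frame(ref = x$ref, pos = x$pos, base = x$base, depth = x$depth,
                    del_count = x$del_count,
                    nondel_count = x$depth - x$del_count)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
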