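#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] returning plain
#' character, used when reading minus-strand sequence context.
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## extract the base at 1-based positions of named reference sequences
ref_base_at <- function(reference, ref_id, pos) {
  stopifnot(all(ref_id %in% names(reference)))
  vapply(seq_along(pos), function(i) {
    substr(reference[[ref_id[i]]], pos[i], pos[i])
  }, character(1))
}

stop_data <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop_data(sprintf("%s must lie in [0,1]; offending value: %g",
                      what, x[which(bad)[1L]]))
  }
  invisible(x)
}
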