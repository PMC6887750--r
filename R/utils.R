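#' @useDynLib mitewave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal coordinate convention: every interval in this package is 0-based,
# half-open [start, end), BED-style. Minus-strand hits keep start < end plus a
# strand flag. Conversions to/from 1-based formats happen only in io_formats.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Handles upper/lower case and the ambiguity code N; other characters
#' (e.g. gaps) are preserved as-is after reversal.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a DNA string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# length of the union of 0-based half-open intervals given as a 2-col matrix
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(r))
}

# overlap length of [s1,e1) with [s2,e2)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
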