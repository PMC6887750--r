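# Per-position query coverage and deletion-drop detection.
#
# A family's hits, stacked on the consensus ("query") coordinate system,
# give a per-position count of aligned nucleotides. An internal-deletion
# derivative segregating in the genome shows up as a window of depressed
# coverage; in genomes carrying only the derivative the window drops to
# zero.

#' Per-position query coverage from hit records
#'
#' `counts[i]` is the number of hits whose query interval contains
#' position `i` (0-based). Coverage is computed from coordinates: gapped
#' columns inside a hit count as covered, a deliberate difference from
#' alignment-column counting (tabular input carries no per-column gap
#' structure).
#'
#' @param hits a `mite_hits` data frame; all rows must share one
#'   `query_id`.
#' @param query_length length of the query consensus.
#' @return object of class `coverage_profile`: list with `query_id`,
#'   `query_length`, `counts` (integer vector of length `query_length`).
#' @export
coverage_profile <- function(hits, query_length) {
  query_length <- as.integer(query_length)
  qid <- if (nrow(hits)) unique(hits$query_id) else "query"
  if (length(qid) > 1L) stopf("hits span multiple query ids: %s",
                              paste(qid, collapse = ", "))
  if (nrow(hits)) {
    bad <- which(hits$query_end > query_length | hits$query_start < 0L)
    if (length(bad)) {
      stopf("hit %d (%s %d..%d) exceeds query_length %d", bad[1], qid,
            hits$query_start[bad[1]], hits$query_end[bad[1]], query_length)
    }
  }
  delta <- integer(query_length + 1L)
  if (nrow(hits)) {
    tab_s <- tabulate(hits$query_start + 1L, nbins = query_length + 1L)
    tab_e <- tabulate(hits$query_end + 1L, nbins = query_length + 1L)
    delta <- tab_s - tab_e
  }
  counts <- cumsum(delta)[seq_len(query_length)]
  structure(list(query_id = qid, query_length = query_length,
                 counts = as.integer(counts)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s, %d bp, depth %d-%d (median %s)\n",
              x$query_id, x$query_length, min(x$counts), max(x$counts),
              format(stats::median(x$counts))))
  invisible(x)
}

#' Detect low-coverage drop windows in a coverage profile
#'
#' A drop is a maximal run of positions with
#' `counts < rel_threshold * median(nonzero counts)`, at least
#' `min_width` wide. `mean_fraction` is the run's mean count divided by
#' the nonzero-median. With `rel_threshold = 0` only exact-zero runs
#' qualify.
#'
#' @param profile a `coverage_profile`.
#' @param rel_threshold fraction of the nonzero-median below which a
#'   position counts as dropped (default 0.1).
#' @param min_width minimum drop width in bp (default 30).
#' @return data frame with columns `start`, `end` (0-based half-open) and
#'   `mean_fraction`, sorted, maximal, non-overlapping. Empty (with a
#'   message) when the profile is all zeros.
#' @export
find_drops <- function(profile, rel_threshold = 0.1, min_width = 30L) {
  stopifnot(rel_threshold >= 0, rel_threshold <= 1, min_width >= 1L)
  counts <- profile$counts
  nz <- counts[counts > 0L]
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_fraction = numeric(0))
  if (!length(nz)) {
    message("coverage profile is all zeros; no drops reported")
    return(empty)
  }
  med <- stats::median(nz)
  low <- if (rel_threshold == 0) counts == 0L else counts < rel_threshold * med
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_width
  if (!any(keep)) return(empty)
  data.frame(
    start = starts[keep], end = ends[keep],
    mean_fraction = vapply(which(keep), function(i) {
      mean(counts[(starts[i] + 1L):ends[i]]) / med
    }, numeric(1))
  )
}

#' Write a coverage profile and its drops as TSV
#'
#' @param profile a `coverage_profile`.
#' @param path output TSV (position, count); drops go to
#'   `<path>.drops.tsv`.
#' @param ... passed to [find_drops()].
#' @export
write_coverage <- function(profile, path, ...) {
  utils::write.table(
    data.frame(position = seq_len(profile$query_length) - 1L,
               count = profile$counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(find_drops(profile, ...), paste0(path, ".drops.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
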