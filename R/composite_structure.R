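# Dissection of a composite MITE: which stretches of the element are
# homologous to which candidate parental sequences (a Mariner-family
# autonomous transposon at the termini, a SINE body in the middle, ...),
# and where its terminal inverted repeats lie.

#' Best local alignment of two DNA sequences (Smith-Waterman)
#'
#' Affine-gap Smith-Waterman; a gap of length `k` costs
#' `gap_open + k * gap_extend`. The traceback is deterministic (ties:
#' diagonal > up > left; best cell: first maximum in row-major order) and
#' a single best-scoring alignment is returned. The default scores
#' approximate megablast's.
#'
#' @param query,subject non-empty DNA strings (uppercased internally).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score`, `query_interval` and `subject_interval`
#'   (0-based half-open), `query_aln`/`subject_aln` (aligned strings with
#'   `-` gaps), `p_distance` and `jc_distance` over aligned non-gap
#'   columns.
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  r <- sw_align_cpp(toupper(query), toupper(subject), match, mismatch,
                    gap_open, gap_extend)
  p <- if (nchar(r$query_aln) > 0) p_distance(r$query_aln, r$subject_aln)
       else NA_real_
  list(score = r$score,
       query_interval = c(r$query_start, r$query_end),
       subject_interval = c(r$subject_start, r$subject_end),
       query_aln = r$query_aln, subject_aln = r$subject_aln,
       p_distance = p, jc_distance = jc_distance(p))
}

#' Tile a MITE with homology segments from candidate parental sequences
#'
#' For each subject, the best local alignment is extracted, its query
#' interval masked (the query is split there and the remaining unmasked
#' stretches are searched again), and the process repeats while the best
#' alignment scores at least `min_score` and spans at least `min_length`
#' query bases. Segments therefore never overlap on the query.
#'
#' @param mite MITE consensus sequence (string).
#' @param subjects named character vector of candidate parental sequences.
#' @param min_score minimum alignment score to keep a segment.
#' @param min_length minimum query-interval length to keep a segment.
#' @param ... scoring parameters passed to [local_align()].
#' @return data frame of class `homology_segments`, sorted by query
#'   position: `subject_id`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `score`, `p_distance`, `jc_distance`.
#' @export
segment_map <- function(mite, subjects, min_score = 40, min_length = 30L,
                        ...) {
  if (!length(subjects)) stopf("subjects must be non-empty")
  if (is.null(names(subjects))) names(subjects) <- paste0("subject", seq_along(subjects))
  mite <- toupper(mite)
  segs <- list()
  for (sid in names(subjects)) {
    # unmasked query windows, 0-based half-open
    windows <- list(c(0L, nchar(mite)))
    repeat {
      best <- NULL
      best_win <- NULL
      for (w in windows) {
        if (w[2] - w[1] < min_length) next
        aln <- local_align(substr(mite, w[1] + 1L, w[2]), subjects[[sid]], ...)
        if (is.null(best) || aln$score > best$score) {
          best <- aln
          best_win <- w
        }
      }
      if (is.null(best) || best$score < min_score ||
          diff(best$query_interval) < min_length) break
      qs <- best_win[1] + best$query_interval[1]
      qe <- best_win[1] + best$query_interval[2]
      segs[[length(segs) + 1L]] <- data.frame(
        subject_id = sid, query_start = qs, query_end = qe,
        subject_start = best$subject_interval[1],
        subject_end = best$subject_interval[2],
        strand = "+", score = best$score,
        p_distance = best$p_distance, jc_distance = best$jc_distance,
        stringsAsFactors = FALSE)
      # split the window that produced the hit
      new_windows <- list()
      for (w in windows) {
        if (!identical(w, best_win)) { new_windows <- c(new_windows, list(w)); next }
        if (qs - w[1] > 0L) new_windows <- c(new_windows, list(c(w[1], qs)))
        if (w[2] - qe > 0L) new_windows <- c(new_windows, list(c(qe, w[2])))
      }
      windows <- new_windows
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  out <- out[order(out$query_start, out$query_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_segments", "data.frame")
  out
}

empty_segments <- function() {
  data.frame(subject_id = character(0), query_start = integer(0),
             query_end = integer(0), subject_start = integer(0),
             subject_end = integer(0), strand = character(0),
             score = numeric(0), p_distance = numeric(0),
             jc_distance = numeric(0), stringsAsFactors = FALSE)
}

#' Detect terminal inverted repeats
#'
#' Aligns the 5' terminus against the reverse complement of the 3'
#' terminus, extending from position 0 for as long as the cumulative
#' mismatch fraction stays at or below `max_mismatch_fraction`. Within
#' that scan the reported arm ends at the prefix maximising
#' `matches - 2 * mismatches` (ties go to the longer prefix), so the call
#' does not absorb random flanking sequence beyond a genuine repeat; it
#' must reach at least `min_tir_length`.
#'
#' @param sequence DNA string, length at least `2 * min_tir_length`.
#' @param min_tir_length minimum reportable TIR length (default 10).
#' @param max_mismatch_fraction tolerated mismatch fraction (default 0.2).
#' @return `NULL` when no TIR qualifies, otherwise a list of class
#'   `tir_call`: `length`, `mismatches`, `arm5_interval`, `arm3_interval`
#'   (0-based half-open at the two termini).
#' @export
detect_tir <- function(sequence, min_tir_length = 10L,
                       max_mismatch_fraction = 0.2) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L * min_tir_length) {
    stopf("sequence shorter than 2 * min_tir_length")
  }
  fwd <- seq_chars(sequence)
  rc3 <- seq_chars(revcomp(sequence))   # rc3[k] pairs with position L-k+1
  half <- L %/% 2L
  mism <- cumsum(fwd[seq_len(half)] != rc3[seq_len(half)])
  frac_ok <- mism / seq_len(half) <= max_mismatch_fraction
  # extension stops at the first violation
  stop_at <- which(!frac_ok)[1]
  reach <- if (is.na(stop_at)) half else stop_at - 1L
  if (reach < min_tir_length) return(NULL)
  lens <- seq_len(reach)
  score <- (lens - mism[lens]) - 2L * mism[lens]
  len <- max(which(score == max(score)))
  if (len < min_tir_length) return(NULL)
  structure(list(length = len, mismatches = unname(mism[len]),
                 arm5_interval = c(0L, len),
                 arm3_interval = c(L - len, L)),
            class = "tir_call")
}

#' @export
print.tir_call <- function(x, ...) {
  cat(sprintf("<tir_call> %d bp terminal inverted repeat, %d mismatch(es)\n",
              x$length, x$mismatches))
  invisible(x)
}

#' Render a structure string from segments and a TIR call
#'
#' Produces a compact anatomy such as
#' `"TIR5|mariner:0-57|Ac1:60-240|mariner:761-865|TIR3"`.
#'
#' @param segments a `homology_segments` data frame.
#' @param tir a `tir_call` or `NULL`.
#' @param length total element length.
#' @return single character string.
#' @export
structure_string <- function(segments, tir, length) {
  parts <- character(0)
  if (!is.null(tir)) parts <- c(parts, "TIR5")
  if (nrow(segments)) {
    parts <- c(parts, sprintf("%s:%d-%d", segments$subject_id,
                              segments$query_start, segments$query_end))
  }
  if (!is.null(tir)) parts <- c(parts, "TIR3")
  paste(parts, collapse = "|")
}
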