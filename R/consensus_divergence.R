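# Majority-rule consensus from an MSA of copies and Jukes-Cantor
# divergence of each copy from that consensus. The within-family
# distribution of these distances ("divergence landscape") is the proxy
# for the family's activity through time: tight, low-divergence
# landscapes mean recent activity, broad high ones an old, finished wave.

#' Majority-rule consensus of a multiple sequence alignment
#'
#' Per column, the most frequent symbol among `{A, C, G, T, -}` wins
#' (`N` does not vote). Ties are broken by the fixed order
#' `A < C < G < T`, and a gap loses every tie. Columns whose majority is a
#' gap are flagged and dropped from the consensus string.
#'
#' @param msa named character vector of equal-width aligned sequences over
#'   `{A,C,G,T,N,-}` (case-insensitive).
#' @return object of class `consensus_profile`: `columns` (5 x width count
#'   matrix, rows A,C,G,T,gap), `consensus` (gap-free string),
#'   `column_kept` (logical per column), `width`.
#' @export
build_consensus <- function(msa) {
  if (length(msa) == 0L) stopf("empty MSA")
  w <- unique(nchar(msa))
  if (length(w) != 1L) stopf("MSA rows differ in width")
  m <- matrix(unlist(strsplit(toupper(msa), "", fixed = TRUE), use.names = FALSE),
              nrow = length(msa), byrow = TRUE)
  syms <- c(DNA_BASES, "-")
  counts <- do.call(rbind, lapply(syms, function(s) colSums(m == s)))
  rownames(counts) <- syms
  # which.max over rows ordered A,C,G,T,gap implements the tie rule
  winner <- syms[apply(counts, 2, which.max)]
  kept <- winner != "-"
  structure(list(columns = counts,
                 consensus = paste(winner[kept], collapse = ""),
                 column_kept = kept, width = ncol(m),
                 column_symbols = winner),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %d columns, consensus %d bp\n",
              x$width, sum(x$column_kept)))
  invisible(x)
}

# consensus expanded back over all MSA columns (gap at dropped columns)
consensus_row_view <- function(profile) {
  paste(profile$column_symbols, collapse = "")
}

#' Observed proportion of differing sites (p-distance)
#'
#' Pairwise deletion: columns where either sequence has a gap or `N` are
#' excluded from both numerator and denominator.
#'
#' @param a,b equal-length aligned strings.
#' @return fraction of mismatches among comparable columns; `NA` when no
#'   column is comparable (undefined, deliberately not 0).
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stopf("sequences differ in length")
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  comparable <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(comparable)) return(NA_real_)
  sum(ca[comparable] != cb[comparable]) / sum(comparable)
}

#' Jukes-Cantor distance from a p-distance
#'
#' `d = -(3/4) ln(1 - (4/3) p)`, the expected substitutions per site after
#' correcting the observed difference `p` for multiple hits. Saturated
#' inputs (`p >= 0.75`) return `NA` and are excluded from aggregates.
#'
#' @param p observed proportion of differing sites, vectorised.
#' @return substitutions/site (`NA` where saturated or `p` is `NA`).
#' @export
jc_distance <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stopf("negative p-distance")
  out <- ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  out
}

#' Divergence landscape of copies against a consensus
#'
#' Computes each copy's p- and Jukes-Cantor distance to the consensus
#' (pairwise deletion over MSA columns) and summarises the family:
#' arithmetic mean, minimum (the "youngest copy" statistic used for
#' dating the end of the wave), maximum, and a histogram with 1% bins.
#' Saturated copies (`p >= 0.75`) are counted but excluded from the
#' aggregates.
#'
#' @param msa named character vector of aligned copies.
#' @param consensus optional `consensus_profile` built from this MSA (or
#'   an externally supplied one of identical width); built from `msa` when
#'   missing.
#' @return object of class `divergence_summary`: `per_copy` data frame
#'   (`copy_id`, `p_distance`, `jc_distance`), `mean`, `min`, `max`,
#'   `n`, `n_saturated`, `histogram` (percent bins).
#' @export
divergence_landscape <- function(msa, consensus = NULL) {
  if (is.null(consensus)) consensus <- build_consensus(msa)
  if (consensus$width != unique(nchar(msa))[1]) {
    stopf("consensus width does not match MSA width")
  }
  cons_row <- consensus_row_view(consensus)
  p <- vapply(msa, p_distance, numeric(1), b = cons_row)
  jc <- jc_distance(p)
  ok <- !is.na(jc)
  hist_df <- if (any(ok)) {
    pct <- jc[ok] * 100
    breaks <- seq(0, ceiling(max(pct)) + 1, by = 1)
    cnt <- table(cut(pct, breaks, right = FALSE))
    data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
               count = as.integer(cnt))
  } else {
    data.frame(bin_low = numeric(0), bin_high = numeric(0),
               count = integer(0))
  }
  structure(list(
    per_copy = data.frame(copy_id = names(msa) %||% seq_along(msa),
                          p_distance = unname(p), jc_distance = unname(jc),
                          stringsAsFactors = FALSE),
    mean = if (any(ok)) mean(jc[ok]) else NA_real_,
    min = if (any(ok)) min(jc[ok]) else NA_real_,
    max = if (any(ok)) max(jc[ok]) else NA_real_,
    n = length(jc), n_saturated = sum(!ok),
    histogram = hist_df
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(paste0("<divergence_summary> %d copies (%d saturated); JC ",
                     "mean %.1f%%, min %.1f%%, max %.1f%%\n"),
              x$n, x$n_saturated, 100 * x$mean, 100 * x$min, 100 * x$max))
  invisible(x)
}
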