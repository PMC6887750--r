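# Activity dating through the molecular-clock identity T = D / s:
# a divergence D (substitutions/site) and a rate s (substitutions/site/
# year) date an event at T years; conversely a divergence anchored to a
# known cladogenetic split time calibrates the family-specific rate.

#' Complete a (T, D, s) dating model from any two components
#'
#' @param T_years event time in years.
#' @param D divergence, substitutions/site.
#' @param s substitution rate, substitutions/site/year.
#' @return object of class `dating_model` with all three fields filled via
#'   `T = D / s`.
#' @export
dating_model <- function(T_years = NULL, D = NULL, s = NULL) {
  given <- !vapply(list(T_years, D, s), is.null, logical(1))
  if (sum(given) != 2L) stopf("exactly two of T_years, D, s must be given")
  if (is.null(T_years)) T_years <- D / s
  if (is.null(D)) D <- T_years * s
  if (is.null(s)) s <- D / T_years
  if (any(c(T_years, D, s) < 0)) stopf("dating model components must be >= 0")
  structure(list(T_years = T_years, D = D, s = s), class = "dating_model")
}

#' @export
print.dating_model <- function(x, ...) {
  cat(sprintf("<dating_model> T = %.1f Mya, D = %.4f subs/site, s = %.3g subs/site/yr\n",
              x$T_years / 1e6, x$D, x$s))
  invisible(x)
}

#' Calibrate a substitution rate from divergence and a split time
#'
#' Anchors a family's mean copy-to-consensus divergence to the age of the
#' cladogenetic event that separated the lineages sharing the family:
#' `s = D / T`.
#'
#' @param D_mean mean divergence, substitutions/site (an unweighted mean
#'   across per-genome values).
#' @param T_split split time in years (> 0).
#' @return substitution rate, substitutions/site/year.
#' @export
calibrate_rate <- function(D_mean, T_split) {
  if (any(T_split <= 0)) stopf("T_split must be > 0")
  D_mean / T_split
}

#' Date an event from divergence and a substitution rate
#'
#' `T = D / s`.
#'
#' @param D divergence, substitutions/site.
#' @param s substitution rate, substitutions/site/year (> 0).
#' @return time in years.
#' @export
date_event <- function(D, s) {
  if (any(s <= 0)) stopf("substitution rate must be > 0")
  D / s
}

#' Date a family's activity wave from its divergence landscape
#'
#' The minimum copy-to-consensus divergence dates the *end* of the
#' amplification wave (the youngest surviving copy); the mean dates its
#' midpoint. The `active_recently` flag marks families whose youngest
#' copy is below `recent_threshold` (default 2% JC) — a reporting
#' convenience, not an inference.
#'
#' @param landscape a `divergence_summary`.
#' @param s substitution rate, substitutions/site/year.
#' @param recent_threshold JC divergence below which the youngest copy
#'   counts as recent.
#' @return object of class `wave_report`: `wave_end_mya`,
#'   `wave_mid_mya`, `active_recently`, `min_jc`, `mean_jc`, `rate_used`.
#' @export
wave_report <- function(landscape, s, recent_threshold = 0.02) {
  if (is.na(landscape$mean)) stopf("empty or fully saturated landscape")
  if (s <= 0) stopf("substitution rate must be > 0")
  structure(list(
    wave_end_mya = date_event(landscape$min, s) / 1e6,
    wave_mid_mya = date_event(landscape$mean, s) / 1e6,
    active_recently = landscape$min < recent_threshold,
    min_jc = landscape$min, mean_jc = landscape$mean, rate_used = s
  ), class = "wave_report")
}

#' @export
print.wave_report <- function(x, ...) {
  cat(sprintf(paste0("<wave_report> wave end %.1f Mya (min JC %.1f%%), ",
                     "midpoint %.1f Mya (mean JC %.1f%%), rate %.3g; ",
                     "recently active: %s\n"),
              x$wave_end_mya, 100 * x$min_jc, x$wave_mid_mya,
              100 * x$mean_jc, x$rate_used, x$active_recently))
  invisible(x)
}

#' Propagate a split-time confidence interval to a rate interval
#'
#' @param D_mean mean divergence, substitutions/site.
#' @param T_split numeric triple `c(low, point, high)` in years.
#' @return named numeric triple of rates `c(high, point, low)` — note the
#'   inversion: an older split gives a slower rate.
#' @export
calibrate_rate_interval <- function(D_mean, T_split) {
  stopifnot(length(T_split) == 3L, all(diff(T_split) >= 0))
  stats::setNames(calibrate_rate(D_mean, rev(T_split)),
                  c("low", "point", "high"))
}
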