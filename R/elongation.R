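#' Relative root elongation rates from a trace series
#'
#' A trace series records the cumulative length of all roots visible in a
#' traced image on successive days. For each interval between consecutive
#' tracings the absolute elongation rate is the length increase divided by the
#' number of days, and the relative elongation rate normalizes the absolute
#' rate by the traced total length at the end of the interval, times 10 to
#' express it in mm of new root per cm of existing root per day
#' (mm cm^-1 day^-1). The normalization makes the rate invariant to the
#' constant fraction of the root system that happens to be visible against
#' the observation window.
#'
#' `literal = TRUE` instead evaluates the alternative form "length increase
#' divided by the absolute rate, times 10"; it is retained for auditability
#' only, as its units do not reduce to mm cm^-1 day^-1.
#'
#' @param series Data frame with columns `day` (strictly increasing) and
#'   `traced_length_cm` (non-negative, non-decreasing), at least 2 rows.
#' @param literal Use the literal alternative form (see Details).
#' @return Data frame with one row per interval: `day` (interval end),
#'   `abs_rate_cm_day`, `rel_rate_mm_cm_day`. Intervals ending on zero traced
#'   length yield `NA` relative rates with a warning.
#' @examples
#' tr <- data.frame(day = c(0, 1), traced_length_cm = c(18, 20))
#' relative_elongation_rate(tr)   # 2 cm over 1 day on 20 cm traced -> 1.0
#' @export
relative_elongation_rate <- function(series, literal = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("day", "traced_length_cm") %in% names(series)))
  if (nrow(series) < 2L)
    stop("a trace series needs at least 2 records")
  d <- series$day
  l <- series$traced_length_cm
  if (any(diff(d) <= 0)) stop("trace days must be strictly increasing")
  if (any(l < 0)) stop("traced lengths must be non-negative")
  if (any(diff(l) < -1e-9)) stop("traced lengths must be non-decreasing")
  n <- nrow(series)
  dl <- diff(l)
  dt <- diff(d)
  abs_rate <- dl / dt
  l_end <- l[-1L]
  if (literal) {
    rel <- ifelse(abs_rate > 0, dl / abs_rate * 10, 0)
  } else {
    rel <- rep(NA_real_, n - 1L)
    pos <- l_end > 0
    rel[pos] <- abs_rate[pos] / l_end[pos] * 10
    if (any(!pos))
      warning("relative elongation rate undefined on intervals with zero traced length",
              call. = FALSE)
  }
  data.frame(day = d[-1L], abs_rate_cm_day = abs_rate,
             rel_rate_mm_cm_day = rel)
}

#' Trimmed mean
#'
#' Drops the `floor(fraction * n)` smallest and largest values and averages
#' the rest; with the default `fraction = 0.2` this is the 20% trim used to
#' guard elongation-rate summaries against the inflated values that short
#' trace intervals can produce.
#'
#' @param values Numeric vector (`NA`s are dropped first).
#' @param fraction Fraction trimmed from *each* tail, in \[0, 0.5).
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:10)   # mean of 3..8 = 5.5
#' @export
trimmed_mean <- function(values, fraction = 0.2) {
  stopifnot(is.numeric(values), fraction >= 0, fraction < 0.5)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values left to average after trimming")
  mean(values, trim = fraction)
}
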