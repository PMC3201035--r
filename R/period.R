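#' Detect a sustained oscillation period in a uniformly sampled series
#'
#' Discards the leading `transient_frac` of the series, locates interior
#' local maxima (with quadratic sub-grid refinement of each peak time), and
#' reports the mean inter-peak interval — provided the signal passes three
#' sustained-oscillation checks: at least `min_peaks` peaks, peak-to-trough
#' amplitude above `amp_floor`, and a coefficient of variation of the
#' inter-peak intervals below `cv_tol`. Damped, drifting or flat dynamics
#' return `NA` (non-oscillating).
#'
#' @param x Numeric series on a uniform time grid.
#' @param t Time grid (same length as `x`); alternatively supply `dt`.
#' @param dt Grid spacing if `t` is not given.
#' @param transient_frac Fraction of the series discarded as transient
#'   (default half).
#' @param min_peaks Minimum number of interior maxima required.
#' @param amp_floor Minimum absolute peak-to-trough amplitude.
#' @param cv_tol Maximum coefficient of variation of inter-peak intervals.
#' @return The period (mean inter-peak interval), or `NA_real_` if the
#'   series does not oscillate in a sustained way.
#' @export
detect_period <- function(x, t = NULL, dt = NULL, transient_frac = 0.5,
                          min_peaks = 4, amp_floor = 1e-4, cv_tol = 0.01) {
  n <- length(x)
  if (is.null(t)) {
    if (is.null(dt)) stop("supply either t or dt")
    t <- seq(0, by = dt, length.out = n)
  }
  if (length(t) != n) stop("x and t lengths differ")
  from <- max(1L, floor(n * transient_frac) + 1L)
  x <- x[from:n]
  t <- t[from:n]
  n <- length(x)
  if (n < 5L) return(NA_real_)
  if (!all(is.finite(x))) return(NA_real_)
  if (max(x) - min(x) <= amp_floor) return(NA_real_)

  xm <- x[2:(n - 1)]
  is_peak <- xm > x[1:(n - 2)] & xm >= x[3:n]
  idx <- which(is_peak) + 1L
  # collapse runs of equal-height plateau points to their first index
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  if (length(idx) < min_peaks) return(NA_real_)

  # quadratic refinement of each peak time
  h <- t[2] - t[1]
  xl <- x[idx - 1L]
  xc <- x[idx]
  xr <- x[idx + 1L]
  denom <- xl - 2 * xc + xr
  shift <- ifelse(abs(denom) > 0, 0.5 * (xl - xr) / denom, 0)
  shift[abs(shift) > 1] <- 0
  tp <- t[idx] + shift * h

  gaps <- diff(tp)
  if (any(gaps <= 0)) return(NA_real_)
  cv <- stats::sd(gaps) / mean(gaps)
  if (!is.finite(cv) || cv >= cv_tol) return(NA_real_)
  mean(gaps)
}

#' Period-mismatch cost
#'
#' Squared deviation of the oscillation period from the unit target, in
#' units of the 10% viability half-width: `((T - 1) / 0.1)^2`. A period of
#' exactly 1 costs 0 and periods of 0.9 or 1.1 sit on the viability
#' boundary (cost 1).
#'
#' @param period Detected period, or `NA` for a non-oscillating point.
#' @return The cost; `+Inf` when `period` is `NA`.
#' @export
period_cost <- function(period) {
  ifelse(is.na(period), Inf, ((period - 1) / 0.1)^2)
}
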