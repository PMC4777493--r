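#' Approximate entropy ApEn(m, r, N)
#'
#' Pincus approximate entropy: the negative average natural logarithm of the
#' conditional probability that epochs similar for `m` points (within
#' tolerance `r`, Chebyshev distance, self-matches included) remain similar
#' at the next point. Low values indicate regularity. The tolerance is
#' `r_factor` times the sample standard deviation of the whole series, which
#' makes the statistic invariant under affine transforms of the signal.
#'
#' Besides the whole-series value, the series is cut into non-overlapping
#' sub-windows (default 5 minutes) and ApEn is computed per sub-window with
#' the same global tolerance; `apen_high` and `apen_low` are the maximum and
#' minimum of the first differences of that sub-window sequence. They
#' capture the largest upward and downward swing in signal regularity across
#' the night (near-symmetric about zero: `apen_high` is typically positive,
#' `apen_low` negative).
#'
#' A constant series is perfectly regular and returns `apen = 0` exactly
#' (every epoch matches every other at zero tolerance).
#'
#' @param s An `osa_series` (at least 50 samples).
#' @param m Pattern length (default 2).
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @param subwindow_seconds Sub-window length for the high/low swing
#'   statistics, in seconds (default 300); `NA` values are returned when
#'   fewer than three sub-windows fit.
#' @return An object of class `osa_apen`: `apen`, `apen_high`, `apen_low`,
#'   `m`, `r`, `n_samples`, and `subwindow_apen` (the per-window sequence).
#' @examples
#' s <- generate_reference_series("white_noise", n = 300, seed = 1)
#' apen(s)$apen
#' @export
apen <- function(s, m = 2, r_factor = 0.2, subwindow_seconds = 300) {
  stopifnot(inherits(s, "osa_series"))
  x <- s$values
  N <- length(x)
  if (N < 50) {
    stop(sprintf("series too short for ApEn: %d samples, need >= 50", N),
         call. = FALSE)
  }
  sdev <- stats::sd(x)
  if (sdev == 0) {
    # perfectly regular: every epoch matches every other
    return(structure(list(apen = 0, apen_high = NA_real_,
                          apen_low = NA_real_, m = m, r = 0, n_samples = N,
                          subwindow_apen = NULL),
                     class = "osa_apen"))
  }
  r <- r_factor * sdev
  a <- apen_core(x, as.integer(m), r)

  sw <- round(subwindow_seconds * s$rate)
  sub <- NULL
  hi <- lo <- NA_real_
  n_win <- N %/% sw
  if (n_win >= 3 && sw >= 50) {
    sub <- vapply(seq_len(n_win), function(w) {
      apen_core(x[((w - 1) * sw + 1):(w * sw)], as.integer(m), r)
    }, 0)
    d <- diff(sub)
    hi <- max(d)
    lo <- min(d)
  }
  structure(list(apen = a, apen_high = hi, apen_low = lo, m = m, r = r,
                 n_samples = N, subwindow_apen = sub),
            class = "osa_apen")
}

#' @export
print.osa_apen <- function(x, ...) {
  cat(sprintf("<osa_apen> ApEn(%d, r=%.4g, N=%d) = %.4f  [swing low %.3f / high %.3f]\n",
              x$m, x$r, x$n_samples, x$apen, x$apen_low, x$apen_high))
  invisible(x)
}
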