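#' Detrended fluctuation analysis
#'
#' Computes the DFA fluctuation function and the two scaling exponents used
#' throughout the pipeline. The series is integrated (cumulative sum of the
#' mean-subtracted samples), partitioned into non-overlapping boxes of `n`
#' samples, a least-squares line is removed within each box, and
#' `F(n) = sqrt(mean(residual^2))` over all retained samples; the trailing
#' partial box is discarded. A straight log F(n) -- log n relationship
#' indicates power-law (fractal) scaling, and its slope is the scaling
#' exponent alpha: ~0.5 for uncorrelated noise, ~1 for strongly long-range
#' correlated signals.
#'
#' Two exponents are reported, matching the breathing time scales of
#' interest: `alpha_fast` is the slope over box durations in
#' `fast_band` (default 8-30 s, roughly 2-6 breaths) and `alpha_slow` over
#' `slow_band` (default 30-100 s, 6-24 breaths). Each band holds at least
#' `boxes_per_band` log-spaced box sizes so the slope is a genuine
#' regression, not a two-point ratio.
#'
#' @param s An `osa_series`.
#' @param box_sizes_seconds Optional explicit box durations (seconds);
#'   `NULL` builds `boxes_per_band` log-spaced sizes per band.
#' @param fast_band,slow_band Box-duration bands (seconds) for the two
#'   slopes.
#' @param boxes_per_band Number of log-spaced box sizes per band (>= 3).
#' @return An object of class `osa_dfa`: `box_sizes` (samples),
#'   `box_seconds`, `fluctuations`, `alpha_fast`, `alpha_slow`, and
#'   `degenerate` (`TRUE` when the series has no variance so slopes are
#'   undefined).
#' @examples
#' s <- generate_reference_series("white_noise", n = 4096, seed = 1)
#' dfa(s)$alpha_fast  # near 0.5 for uncorrelated noise
#' @export
dfa <- function(s, box_sizes_seconds = NULL, fast_band = c(8, 30),
                slow_band = c(30, 100), boxes_per_band = 7) {
  stopifnot(inherits(s, "osa_series"), boxes_per_band >= 3)
  if (is.null(box_sizes_seconds)) {
    box_sizes_seconds <- sort(unique(c(
      exp(seq(log(fast_band[1]), log(fast_band[2]), length.out = boxes_per_band)),
      exp(seq(log(slow_band[1]), log(slow_band[2]), length.out = boxes_per_band))
    )))
  }
  x <- s$values
  N <- length(x)
  box_samples <- unique(pmax(4L, as.integer(round(box_sizes_seconds * s$rate))))
  box_seconds <- box_samples / s$rate
  if (N < 4 * max(box_samples)) {
    stop(sprintf(
      "series too short for DFA: %d samples, need >= %d (4 x largest box)",
      N, 4 * max(box_samples)), call. = FALSE)
  }

  y <- cumsum(x - mean(x))                 # integrated profile
  tiny <- 1e-300
  Fn <- vapply(box_samples, function(n) {
    m <- N %/% n                           # complete boxes; tail discarded
    Y <- matrix(y[seq_len(m * n)], nrow = n)
    t <- seq_len(n)
    tc <- t - mean(t)
    denom <- sum(tc^2)
    b <- colSums(Y * tc) / denom           # per-box linear trend
    a <- colMeans(Y)
    resid <- Y - outer(tc, b) - rep(a, each = n)
    sqrt(mean(resid^2))
  }, 0)

  degenerate <- all(Fn < 1e-12)
  band_slope <- function(band) {
    if (degenerate) return(NA_real_)
    sel <- box_seconds >= band[1] - 1e-9 & box_seconds <= band[2] + 1e-9 &
      Fn > 0
    if (sum(sel) < 3) return(NA_real_)
    stats::coef(stats::lm(log(Fn[sel] + tiny) ~ log(box_samples[sel])))[[2]]
  }

  structure(
    list(box_sizes = box_samples, box_seconds = box_seconds,
         fluctuations = Fn,
         alpha_fast = band_slope(fast_band),
         alpha_slow = band_slope(slow_band),
         degenerate = degenerate),
    class = "osa_dfa"
  )
}

#' @export
print.osa_dfa <- function(x, ...) {
  cat(sprintf("<osa_dfa> alpha_fast = %.3f, alpha_slow = %.3f (%d box sizes)%s\n",
              x$alpha_fast, x$alpha_slow, length(x$box_sizes),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
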