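# delay embedding: rows are points (x_i, x_{i+delay}, ..., x_{i+(d-1)delay})
delay_embed <- function(x, dim, delay) {
  M <- length(x) - (dim - 1) * delay
  if (M < 2) stop("series too short for this embedding", call. = FALSE)
  vapply(seq_len(dim), function(k) x[(seq_len(M)) + (k - 1) * delay],
         numeric(M))
}

# first non-positive lag of the sample autocorrelation; a standard heuristic
# for the embedding delay
acf_zero_crossing <- function(x, max_lag = min(length(x) %/% 4, 2000)) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  i <- which(a <= 0)[1]
  if (is.na(i)) max_lag else i
}

#' Largest Lyapunov exponent by the Rosenstein method
#'
#' Estimates the mean exponential rate of divergence of initially close
#' trajectories in reconstructed phase space. The series is delay-embedded;
#' for each embedded point the nearest neighbour with temporal separation
#' greater than `theiler_window` is found; the mean log separation of those
#' pairs is tracked as both evolve (the divergence curve), and the exponent
#' is the least-squares slope of the curve over its initial, approximately
#' linear region. Positive exponents indicate chaos-like sensitivity to
#' initial conditions; periodic orbits give exponents near zero. The
#' estimate is invariant to amplitude scaling of the signal (scaling shifts
#' the whole divergence curve by a constant) and may legitimately be
#' negative for strongly contracting dynamics.
#'
#' @param s An `osa_series`.
#' @param embed_dim Embedding dimension; default 5, appropriate for
#'   respiratory signals (use 2 for one-dimensional maps).
#' @param delay Embedding lag in samples; `NULL` uses the first
#'   zero-crossing of the autocorrelation function.
#' @param theiler_window Minimum temporal separation (samples) between a
#'   point and its neighbour; `NULL` uses one mean cycle, approximated as
#'   four delays.
#' @param fit_steps Number of initial divergence-curve steps used for the
#'   slope fit; `NULL` uses the first third of the horizon.
#' @param max_steps Divergence horizon in steps; `NULL` picks
#'   `min(500, M / 10)` for the `M` embedded points.
#' @param analysis_rate Optional working rate (Hz): the series is block-mean
#'   resampled before embedding. The divergence statistics only need a few
#'   samples per breath, so respiratory channels are analysed well below
#'   their native rates.
#' @return An object of class `osa_lle`: `lambda` (per second),
#'   `lambda_per_step`, `divergence_curve`, `embed_dim`, `delay`,
#'   `theiler_window`, `fit_range` (steps), `rate`.
#' @examples
#' s <- generate_reference_series("logistic_map", n = 2000, r = 4, seed = 1)
#' lle_rosenstein(s, embed_dim = 2, delay = 1, theiler_window = 1)$lambda
#' @export
lle_rosenstein <- function(s, embed_dim = 5, delay = NULL,
                           theiler_window = NULL, fit_steps = NULL,
                           max_steps = NULL, analysis_rate = NULL) {
  stopifnot(inherits(s, "osa_series"))
  if (!is.null(analysis_rate) && analysis_rate < s$rate) {
    s <- resample_mean(s, analysis_rate)
  }
  x <- s$values
  if (stats::sd(x) == 0) {
    stop("degenerate (constant) input: no phase-space structure to embed",
         call. = FALSE)
  }
  if (is.null(delay)) delay <- acf_zero_crossing(x)
  delay <- max(1L, as.integer(delay))
  if (is.null(theiler_window)) theiler_window <- 4L * delay
  emb <- delay_embed(x, embed_dim, delay)
  M <- nrow(emb)
  if (M < 100) {
    stop(sprintf("only %d embedded points; need >= 100", M), call. = FALSE)
  }
  if (is.null(max_steps)) max_steps <- max(10L, min(500L, M %/% 10L))
  max_steps <- as.integer(min(max_steps, M - 2L))
  curve <- lle_divergence(emb, as.integer(theiler_window), max_steps)
  if (all(!is.finite(curve))) {
    stop("no admissible neighbour pairs (theiler_window too large?)",
         call. = FALSE)
  }
  if (is.null(fit_steps)) fit_steps <- max(3L, max_steps %/% 3L)
  fit_steps <- as.integer(min(fit_steps, max_steps))
  k <- 0:fit_steps
  ok <- is.finite(curve[k + 1])
  slope <- stats::coef(stats::lm(curve[k + 1][ok] ~ k[ok]))[[2]]
  structure(
    list(lambda = slope * s$rate, lambda_per_step = slope,
         divergence_curve = curve, embed_dim = embed_dim, delay = delay,
         theiler_window = theiler_window, fit_range = c(0L, fit_steps),
         rate = s$rate),
    class = "osa_lle"
  )
}

#' @export
print.osa_lle <- function(x, ...) {
  cat(sprintf(
    "<osa_lle> lambda = %.4f /s (%.4f /step); dim %d, delay %d, theiler %d, fit 0..%d\n",
    x$lambda, x$lambda_per_step, x$embed_dim, x$delay, x$theiler_window,
    x$fit_range[2]))
  invisible(x)
}
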