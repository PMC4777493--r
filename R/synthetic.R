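# Synthetic overnight recordings with known ground truth.
#
# The generator emulates what the nonlinear estimators sense in real
# respiratory polysomnography channels: quasi-periodic breathing (~4 s
# breaths) in the flow and thoracic channels, apnea/hypopnea events at a
# controlled hourly rate (flow amplitude collapses during apneas, is reduced
# during hypopneas, while paradoxical thoracic excursion persists), SpO2
# desaturation ramps that trail each event, measurement noise, and a slow
# amplitude modulation that grows with event load so that severe-OSA nights
# carry more long-range correlation structure than quiet ones.

# evaluate expr under a temporary RNG state so generators are pure
# functions of (spec, seed) and never disturb the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic overnight recording
#'
#' Holds every knob of the synthetic-night generator. Defaults describe a
#' typical six-hour study: 4-s breaths, events averaging 25 s, ~8% SpO2
#' desaturations, and 5% relative measurement noise.
#'
#' @param duration Recording length in seconds.
#' @param true_ahi Target apnea-hypopnea index in events per hour.
#' @param apnea_fraction Proportion of events that are apneas (the rest are
#'   hypopneas); the cohort default 0.67 mirrors an apnea-dominated case mix.
#' @param breath_period Breath duration in seconds.
#' @param event_duration_mean,event_duration_sd Event length distribution in
#'   seconds (truncated to [10, 90]).
#' @param desat_depth_mean Mean SpO2 drop per event, in percentage points.
#' @param noise_sd Measurement noise standard deviation relative to the
#'   breathing amplitude.
#' @param flow_rate,thoracic_rate,spo2_rate Channel sampling rates in Hz.
#' @param seed Integer seed; every generator output is a pure function of
#'   (spec, seed).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration = 6 * 3600, true_ahi = 15,
                           apnea_fraction = 0.67, breath_period = 4,
                           event_duration_mean = 25, event_duration_sd = 8,
                           desat_depth_mean = 8, noise_sd = 0.05,
                           flow_rate = 200, thoracic_rate = 10, spo2_rate = 1,
                           seed = 1) {
  stopifnot(duration > 0, true_ahi >= 0, apnea_fraction >= 0,
            apnea_fraction <= 1, breath_period > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# place n events of the given durations in [margin, duration - margin]
# without overlap and with a minimum gap; exponential gaps rescaled to the
# free time give a renewal-like arrangement with an exact event count
place_events <- function(n, durations, total, gap_min, margin = 60) {
  usable <- total - 2 * margin
  free <- usable - sum(durations) - (n + 1) * gap_min
  if (free < 0) {
    stop(sprintf(
      "event load infeasible: %d events totalling %.0f s cannot fit in %.0f s",
      n, sum(durations), usable), call. = FALSE)
  }
  gaps <- stats::rexp(n + 1)
  gaps <- gaps / sum(gaps) * free
  starts <- margin + gap_min + cumsum(gaps[seq_len(n)]) +
    c(0, cumsum(durations[-n] + gap_min))
  starts
}

# slow multiplicative amplitude modulation; strength grows with event load
slow_modulation <- function(t, true_ahi, knot_spacing = 60) {
  depth <- 0.3 * min(1, true_ahi / 30)
  if (depth == 0 || length(t) == 0) return(rep(1, length(t)))
  knots <- seq(0, max(t) + knot_spacing, by = knot_spacing)
  z <- stats::rnorm(length(knots))
  # smooth by cumulative averaging so the modulation drifts on minute scales
  z <- stats::filter(z, rep(1 / 5, 5), sides = 2, circular = TRUE)
  pmax(0.2, 1 + depth * stats::approx(knots, as.numeric(z), xout = t)$y)
}

#' Generate a synthetic overnight recording with ground-truth events
#'
#' Produces the three channels of a [sleep_recording()] plus the event list
#' that defines the true AHI. The realized event count is exactly
#' `round(true_ahi * duration / 3600)`; events never overlap and keep at
#' least one breath period between them.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `recording` ([sleep_recording()]) and
#'   `events` (data frame with columns `start`, `duration`, `kind`).
#' @examples
#' out <- generate_recording(synthetic_spec(duration = 3600, true_ahi = 20,
#'                                          flow_rate = 8, thoracic_rate = 4,
#'                                          seed = 42))
#' nrow(out$events)
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_ev <- round(spec$true_ahi * spec$duration / 3600)
    if (n_ev > 0) {
      durs <- pmin(90, pmax(10, stats::rnorm(n_ev, spec$event_duration_mean,
                                             spec$event_duration_sd)))
      starts <- place_events(n_ev, durs, spec$duration, spec$breath_period)
      kinds <- ifelse(stats::runif(n_ev) < spec$apnea_fraction,
                      "apnea", "hypopnea")
      # residual breathing amplitude during the event
      residual <- ifelse(kinds == "apnea", 0.05, stats::runif(n_ev, 0.3, 0.7))
      depths <- pmax(2, stats::rnorm(n_ev, spec$desat_depth_mean, 2))
      events <- data.frame(start = starts, duration = durs, kind = kinds,
                           stringsAsFactors = FALSE)
    } else {
      events <- data.frame(start = numeric(0), duration = numeric(0),
                           kind = character(0), stringsAsFactors = FALSE)
      residual <- numeric(0); depths <- numeric(0)
    }

    envelope_at <- function(t, event_residual) {
      env <- rep(1, length(t))
      for (i in seq_len(n_ev)) {
        in_ev <- t >= events$start[i] & t < events$start[i] + events$duration[i]
        env[in_ev] <- env[in_ev] * event_residual[i]
      }
      env
    }

    breathing_channel <- function(rate, amp, event_residual, phase = 0) {
      n <- round(spec$duration * rate)
      t <- (seq_len(n) - 1) / rate
      base <- amp * sin(2 * pi * t / spec$breath_period + phase)
      env <- envelope_at(t, event_residual)
      if (n_ev > 0) env <- env * slow_modulation(t, spec$true_ahi)
      x <- base * env
      if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd * amp)
      x
    }

    flow <- breathing_channel(spec$flow_rate, 1, residual)
    # thoracic excursion persists (paradoxical effort) during obstruction
    thor <- breathing_channel(spec$thoracic_rate, 0.8,
                              rep(0.6, n_ev), phase = pi / 6)

    n_sp <- round(spec$duration * spec$spo2_rate)
    t_sp <- (seq_len(n_sp) - 1) / spec$spo2_rate
    deficit <- rep(0, n_sp)
    for (i in seq_len(n_ev)) {
      t0 <- events$start[i] + 10            # desaturation lags the event
      t1 <- t0 + events$duration[i]
      ramp <- t_sp >= t0 & t_sp < t1
      deficit[ramp] <- deficit[ramp] + depths[i] * (t_sp[ramp] - t0) /
        events$duration[i]
      rec <- t_sp >= t1
      deficit[rec] <- deficit[rec] + depths[i] * exp(-(t_sp[rec] - t1) / 15)
    }
    spo2 <- pmin(100, pmax(40, 96 - deficit))

    rec <- sleep_recording(
      flow = series(flow, spec$flow_rate, "Flow"),
      thoracic = series(thor, spec$thoracic_rate, "Thorax"),
      spo2 = series(spo2, spec$spo2_rate, "SpO2")
    )
    list(recording = rec, events = events)
  })
}

#' Generate an SpO2 series with a prescribed T90
#'
#' Builds a saturation trace whose fraction of samples below 90% matches
#' `target_t90` to well within one percentage point. Time below 90% is spent
#' in contiguous desaturation episodes (nadir 85%) separated by stretches at
#' the 96% baseline.
#'
#' @param spec A [synthetic_spec()] (only `duration`, `spo2_rate` and `seed`
#'   are used).
#' @param target_t90 Target percentage of time below 90% SpO2, in [0, 100].
#' @return An `osa_series` of saturations.
#' @export
spo2_with_target_t90 <- function(spec, target_t90) {
  stopifnot(inherits(spec, "synthetic_spec"),
            target_t90 >= 0, target_t90 <= 100)
  n <- round(spec$duration * spec$spo2_rate)
  need <- round(target_t90 / 100 * n)
  x <- rep(96, n)
  if (need > 0) {
    n_ep <- max(1L, min(round(need / 120), 50L))
    sizes <- rep(need %/% n_ep, n_ep)
    sizes[seq_len(need %% n_ep)] <- sizes[seq_len(need %% n_ep)] + 1L
    # episodes evenly spread over the night
    gap <- (n - need) %/% (n_ep + 1L)
    pos <- gap
    for (i in seq_len(n_ep)) {
      len <- sizes[i]
      idx <- pos + seq_len(len)
      ep <- rep(85, len)
      edge <- min(4L, len %/% 2L)
      if (edge > 0) {                       # ramps stay below the 90% line
        ep[seq_len(edge)] <- seq(89.5, 85, length.out = edge + 1)[-1]
        ep[len + 1 - seq_len(edge)] <- seq(89.5, 85, length.out = edge + 1)[-1]
      }
      x[idx] <- ep
      pos <- pos + len + gap
    }
  }
  series(x[seq_len(n)], rate = spec$spo2_rate, label = "SpO2")
}

#' Reference series with known nonlinear properties
#'
#' Deterministic (seeded) test signals for validating the estimators:
#' `constant` and `sine` as degenerate/periodic references, `white_noise`
#' for the DFA alpha = 0.5 benchmark, fractional Gaussian noise `fgn` with
#' exact Davies-Harte (circulant embedding) synthesis for alpha = H, the
#' `logistic_map` whose largest Lyapunov exponent at r = 4 is ln 2, and the
#' x-coordinate of the `lorenz_x` attractor.
#'
#' @param kind One of `"constant"`, `"sine"`, `"white_noise"`, `"fgn"`,
#'   `"logistic_map"`, `"lorenz_x"`.
#' @param n Number of samples (>= 64).
#' @param seed Integer seed.
#' @param H Hurst exponent for `fgn`, in (0, 1).
#' @param r Logistic-map parameter, in (3.57, 4].
#' @param period_samples Samples per cycle for `sine`.
#' @param lorenz_dt Integration/sampling step for `lorenz_x`, seconds.
#' @return An `osa_series`; map-type series carry rate 1 (per iteration).
#' @export
generate_reference_series <- function(kind, n, seed = 1, H = 0.7, r = 4,
                                      period_samples = 100, lorenz_dt = 0.01) {
  if (n < 64) stop("`n` must be at least 64", call. = FALSE)
  kind <- match.arg(kind, c("constant", "sine", "white_noise", "fgn",
                            "logistic_map", "lorenz_x"))
  vals <- with_seed(seed, switch(
    kind,
    constant = rep(1, n),
    sine = sin(2 * pi * (seq_len(n) - 1) / period_samples),
    white_noise = stats::rnorm(n),
    fgn = {
      if (H <= 0 || H >= 1) stop("`H` must lie in (0, 1)", call. = FALSE)
      fgn_davies_harte(n, H)
    },
    logistic_map = {
      if (r <= 3.57 || r > 4) {
        stop("logistic `r` must lie in (3.57, 4]", call. = FALSE)
      }
      x <- stats::runif(1, 0.1, 0.9)
      out <- numeric(n + 100)
      for (i in seq_len(n + 100)) {
        x <- r * x * (1 - x)
        out[i] <- x
      }
      out[-seq_len(100)]                  # drop transient
    },
    lorenz_x = {
      lorenz <- function(t, y, p) {
        list(c(p$sigma * (y[2] - y[1]),
               y[1] * (p$rho - y[3]) - y[2],
               y[1] * y[2] - p$beta * y[3]))
      }
      y0 <- c(1 + stats::runif(1, -0.1, 0.1), 1, 20)
      times <- seq(0, (n + 500) * lorenz_dt, by = lorenz_dt)
      sol <- deSolve::ode(y0, times, lorenz,
                          list(sigma = 10, rho = 28, beta = 8 / 3))
      as.numeric(sol[-seq_len(501), 2])[seq_len(n)]
    }
  ))
  rate <- if (kind == "lorenz_x") 1 / lorenz_dt else 1
  series(vals, rate = rate, label = kind)
}

# Exact synthesis of fractional Gaussian noise by circulant embedding of the
# fGn autocovariance gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2
# (Davies & Harte). The circulant eigenvalues are non-negative for all
# H in (0,1), so the synthesis is exact in distribution.
fgn_davies_harte <- function(n, H) {
  m <- 2^ceiling(log2(n))
  k <- 0:m
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(gamma, gamma[m:2])             # circulant first row, length 2m
  ev <- Re(stats::fft(row))
  ev[ev < 0] <- 0                          # guard tiny negative round-off
  z <- complex(real = stats::rnorm(2 * m), imaginary = stats::rnorm(2 * m))
  w <- stats::fft(sqrt(ev / (4 * m)) * z)
  Re(w)[seq_len(n)]
}

#' Generate a synthetic study cohort
#'
#' Draws per-subject demographics and true AHI, and (optionally) a full
#' synthetic overnight recording per subject. AHI follows a mixture of a
#' normal-range component and a log-normal patient component; BMI and
#' Epworth score are coupled to AHI through a Gaussian copula with
#' configurable target correlations (defaults 0.58 and 0.47, the strength of
#' association reported in clinic populations).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param ahi_sampler Optional function `(n)` returning true AHI draws from a
#'   vector of standard-normal latents; `NULL` uses the built-in mixture.
#' @param normal_fraction Mixture weight of the normal-range (AHI < 5)
#'   component.
#' @param bmi_r,epworth_r Target correlations of BMI and Epworth with AHI.
#' @param signals If `TRUE`, generate a recording and event list per subject.
#' @param spec Template [synthetic_spec()] for the per-subject recordings
#'   (its `true_ahi` and `seed` are overridden per subject).
#' @return A list with `subjects` (data frame: `id`, `age`, `sex`, `bmi`,
#'   `epworth`, `ahi_true`, `ai`, `hi`, `severity`) and, when `signals` is
#'   `TRUE`, parallel lists `recordings` and `events`.
#' @export
generate_cohort <- function(n_subjects, seed = 1, ahi_sampler = NULL,
                            normal_fraction = 0.24, bmi_r = 0.58,
                            epworth_r = 0.47, signals = TRUE,
                            spec = synthetic_spec()) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (normal_fraction < 0 || normal_fraction >= 1 ||
      abs(bmi_r) >= 1 || abs(epworth_r) >= 1) {
    stop("degenerate distribution parameters", call. = FALSE)
  }
  out <- with_seed(seed, {
    z <- stats::rnorm(n_subjects)          # shared severity latent
    ahi <- if (is.null(ahi_sampler)) {
      u <- stats::pnorm(z)
      a <- numeric(n_subjects)
      lo <- u < normal_fraction
      a[lo] <- u[lo] / normal_fraction * 5  # normal range, AHI in [0, 5)
      a[!lo] <- pmin(110, stats::qlnorm((u[!lo] - normal_fraction) /
                                          (1 - normal_fraction),
                                        meanlog = 3.58, sdlog = 0.64))
      a
    } else {
      ahi_sampler(z)
    }
    mix <- function(rho) rho * z + sqrt(1 - rho^2) * stats::rnorm(n_subjects)
    bmi <- pmin(53, pmax(17, 31.9 + 6.9 * mix(bmi_r)))
    epworth <- pmin(24, pmax(0, round(7.8 + 5.1 * mix(epworth_r))))
    age <- pmin(83, pmax(16, round(stats::rnorm(n_subjects, 48.4, 13.6))))
    sex <- ifelse(stats::runif(n_subjects) < 0.74, "male", "female")
    sub_seeds <- sample.int(2^31 - 2, n_subjects)
    list(ahi = ahi, bmi = bmi, epworth = epworth, age = age, sex = sex,
         sub_seeds = sub_seeds)
  })

  recordings <- events <- vector("list", n_subjects)
  ai <- hi <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    if (signals) {
      sp <- spec
      sp$true_ahi <- out$ahi[i]
      sp$seed <- out$sub_seeds[i]
      g <- generate_recording(sp)
      recordings[[i]] <- g$recording
      events[[i]] <- g$events
      hours <- sp$duration / 3600
      ai[i] <- sum(g$events$kind == "apnea") / hours
      hi[i] <- sum(g$events$kind == "hypopnea") / hours
    } else {
      frac <- spec$apnea_fraction
      ai[i] <- out$ahi[i] * frac
      hi[i] <- out$ahi[i] * (1 - frac)
    }
  }
  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n_subjects)),
    age = out$age, sex = out$sex, bmi = out$bmi, epworth = out$epworth,
    ahi_true = out$ahi, ai = ai, hi = hi,
    severity = vapply(out$ahi, classify_severity, ""),
    stringsAsFactors = FALSE
  )
  res <- list(subjects = subjects)
  if (signals) {
    res$recordings <- recordings
    res$events <- events
  }
  res
}
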