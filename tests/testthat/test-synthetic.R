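test_that("event-free noiseless flow is exactly periodic", {
  out <- generate_recording(synthetic_spec(duration = 600, true_ahi = 0,
                                           noise_sd = 0, flow_rate = 8,
                                           thoracic_rate = 4, seed = 1))
  expect_identical(nrow(out$events), 0L)
  v <- out$recording$flow$values
  period <- 4 * 8                          # one breath in samples
  expect_equal(v[seq_len(length(v) - period)],
               v[(period + 1):length(v)], tolerance = 1e-12)
  expect_true(all(out$recording$spo2$values == 96))
})

test_that("realized event count reproduces the requested AHI exactly", {
  spec <- synthetic_spec(duration = 3600, true_ahi = 30, flow_rate = 8,
                         thoracic_rate = 4, seed = 7)
  out <- generate_recording(spec)
  expect_identical(nrow(out$events), 30L)
  expect_equal(nrow(out$events) / (spec$duration / 3600), 30)
  # events sorted, non-overlapping, with a breath of separation
  ends <- out$events$start + out$events$duration
  expect_true(all(diff(out$events$start) > 0))
  expect_true(all(out$events$start[-1] - ends[-30] >= spec$breath_period - 1e-9))
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- synthetic_spec(duration = 1800, true_ahi = 20, flow_rate = 8,
                         thoracic_rate = 4, seed = 7)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$flow$values, b$recording$flow$values)
  expect_identical(a$events, b$events)
  spec$seed <- 8
  c <- generate_recording(spec)
  expect_false(identical(a$events$start, c$events$start))
})

test_that("flow collapses during apneas while thoracic excursion persists", {
  spec <- synthetic_spec(duration = 3600, true_ahi = 20, apnea_fraction = 1,
                         noise_sd = 0, flow_rate = 8, thoracic_rate = 8,
                         seed = 3)
  out <- generate_recording(spec)
  ev <- out$events[1, ]
  t_f <- (seq_along(out$recording$flow$values) - 1) / 8
  inside <- t_f >= ev$start + 2 & t_f < ev$start + ev$duration - 2
  # clear of any event (plus recovery margin)
  outside <- rep(TRUE, length(t_f))
  for (i in seq_len(nrow(out$events))) {
    outside <- outside & (t_f < out$events$start[i] - 2 |
                            t_f > out$events$start[i] + out$events$duration[i] + 2)
  }
  amp_in_flow <- max(abs(out$recording$flow$values[inside]))
  amp_out_flow <- max(abs(out$recording$flow$values[outside]))
  expect_lt(amp_in_flow, 0.1 * amp_out_flow)
  amp_in_thor <- max(abs(out$recording$thoracic$values[inside]))
  amp_out_thor <- max(abs(out$recording$thoracic$values[outside]))
  expect_gt(amp_in_thor, 0.3 * amp_out_thor)
})

test_that("desaturations trail events and recover afterwards", {
  spec <- synthetic_spec(duration = 3600, true_ahi = 6, noise_sd = 0,
                         flow_rate = 8, thoracic_rate = 4, seed = 9)
  out <- generate_recording(spec)
  sp <- out$recording$spo2$values
  ev <- out$events[1, ]
  before <- sp[floor(ev$start) - 5]
  nadir_window <- sp[floor(ev$start + 10):ceiling(ev$start + 10 + ev$duration + 5)]
  expect_lt(min(nadir_window), before - 2)
  late <- sp[min(length(sp), ceiling(ev$start + ev$duration + 120))]
  expect_gt(late, min(nadir_window))
})

test_that("spo2_with_target_t90 hits its target within one point", {
  spec <- synthetic_spec(duration = 3600, spo2_rate = 1)
  for (target in c(0, 5, 25, 50, 90, 100)) {
    s <- spo2_with_target_t90(spec, target)
    expect_lt(abs(t90(s) - target), 1)
  }
  expect_true(all(spo2_with_target_t90(spec, 0)$values >= 90))
  expect_true(all(spo2_with_target_t90(spec, 100)$values < 90))
  # 50% of 3600 samples: between 1764 and 1836 below 90
  n_below <- sum(spo2_with_target_t90(spec, 50)$values < 90)
  expect_gte(n_below, 1764)
  expect_lte(n_below, 1836)
})

test_that("reference series have their defining structure", {
  expect_true(all(generate_reference_series("constant", 1000)$values == 1))
  # logistic orbit obeys the recurrence x -> r x (1 - x)
  s <- generate_reference_series("logistic_map", 5000, seed = 2, r = 4)
  x <- s$values
  expect_equal(x[-1], 4 * x[-5000] * (1 - x[-5000]), tolerance = 1e-12)
  expect_true(all(x > 0 & x < 1))
  expect_error(generate_reference_series("logistic_map", 100, r = 2),
               "3.57")
  expect_error(generate_reference_series("fgn", 100, H = 1.2), "0, 1")
  expect_error(generate_reference_series("white_noise", 10), "64")
})

test_that("fGn synthesis matches the closed-form lag-1 autocorrelation", {
  # rho(1) = 2^(2H-1) - 1 = 0.741 for H = 0.9. Time averages of a single
  # long-range-dependent realization converge slowly, so the check pools
  # lag-1 products over an ensemble of independent replicates (the process
  # mean is 0 by construction).
  pooled_rho1 <- function(H, n = 256, reps = 100) {
    num <- den <- 0
    for (i in seq_len(reps)) {
      x <- generate_reference_series("fgn", n, seed = 7000 + i, H = H)$values
      num <- num + sum(x[-1] * x[-n])
      den <- den + sum(x^2)
    }
    num / den
  }
  expect_lt(abs(pooled_rho1(0.9) - (2^(2 * 0.9 - 1) - 1)), 0.05)
  # H = 0.5 reduces to white noise: near-zero lag-1 correlation
  expect_lt(abs(pooled_rho1(0.5)), 0.05)
})

test_that("cohort generation is reproducible and couples BMI to AHI", {
  a <- generate_cohort(100, seed = 5, signals = FALSE)
  b <- generate_cohort(100, seed = 5, signals = FALSE)
  expect_identical(a$subjects, b$subjects)
  big <- generate_cohort(200, seed = 11, signals = FALSE)$subjects
  r_bmi <- stats::cor(big$bmi, big$ahi_true)
  expect_gt(r_bmi, 0.45)
  expect_lt(r_bmi, 0.70)
  expect_true(all(big$ahi_true >= 0 & big$ahi_true <= 140))
  # all-normal cohort: every severity label is "normal"
  norm <- generate_cohort(10, seed = 2, signals = FALSE,
                          ahi_sampler = function(z) stats::pnorm(z) * 4.9)
  expect_true(all(norm$subjects$severity == "normal"))
})
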