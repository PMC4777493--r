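test_that("the published equation evaluates exactly", {
  m <- published_ahi_model()
  zero <- list(bmi = 0, T90 = 0, dDFA_f2 = 0, dLLE = 0, mmDFA_t2 = 0)
  expect_identical(predict_ahi(m, zero), -27)
  # cohort-typical predictor values, checked by hand arithmetic:
  # 1.2*31.94 + 0.4*23.9 - 18.6*0.02 + 7.8*(-0.47) + 60.5*0.44 - 27 = 43.47
  typical <- list(bmi = 31.94, T90 = 23.9, dDFA_f2 = 0.02, dLLE = -0.47,
                  mmDFA_t2 = 0.44)
  expect_equal(predict_ahi(m, typical), 43.47, tolerance = 1e-10)
  # affinity: doubling all predictors doubles (prediction + 27)
  doubled <- lapply(typical, function(v) 2 * v)
  expect_equal(predict_ahi(m, doubled) + 27,
               2 * (predict_ahi(m, typical) + 27), tolerance = 1e-10)
  expect_error(predict_ahi(m, typical[-1]), "bmi")
  expect_identical(predict_ahi(m, zero, clamp_zero = TRUE), 0)
})

test_that("severity bands use the printed boundaries", {
  expect_identical(classify_severity(0), "normal")
  expect_identical(classify_severity(5), "normal")
  expect_identical(classify_severity(5.0001), "mild")
  expect_identical(classify_severity(15), "mild")
  expect_identical(classify_severity(15.0001), "moderate")
  expect_identical(classify_severity(30), "moderate")
  expect_identical(classify_severity(30.0001), "severe")
  expect_error(classify_severity(-1), "non-negative")
})

test_that("the CPAP dichotomy maps labels and the AHI boundary as documented", {
  expect_identical(binarize_for_cpap("mild"), "normal/mild")
  expect_identical(binarize_for_cpap("moderate"), "moderate/severe")
  expect_identical(binarize_for_cpap("severe"), "moderate/severe")
  # label route: AHI = 15 is mild, hence conservative group
  expect_identical(binarize_for_cpap(classify_severity(15)), "normal/mild")
  # direct-AHI route follows the >= 15 treatment-group convention
  expect_identical(binarize_for_cpap(15, by_ahi = TRUE), "moderate/severe")
  expect_identical(binarize_for_cpap(16, by_ahi = TRUE), "moderate/severe")
  expect_identical(binarize_for_cpap(14.9, by_ahi = TRUE), "normal/mild")
  expect_error(binarize_for_cpap("extreme"), "invalid severity")
  # agreement of the two routes everywhere except the boundary point
  ahis <- c(0, 3, 7, 14.99, 15.01, 22, 31, 80)
  expect_identical(binarize_for_cpap(classify_severity(ahis)),
                   binarize_for_cpap(ahis, by_ahi = TRUE))
})

test_that("models round-trip through their JSON file format", {
  m <- published_ahi_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_ahi_model(m, path)
  back <- read_ahi_model(path)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  expect_true(back$published)
  fv <- list(bmi = 30, T90 = 10, dDFA_f2 = 0.1, dLLE = -0.2, mmDFA_t2 = 0.5)
  expect_identical(predict_ahi(back, fv), predict_ahi(m, fv))
})

test_that("OLS refit recovers the generating coefficients", {
  truth <- published_ahi_model()
  set.seed(41)
  n <- 200
  tab <- data.frame(bmi = stats::rnorm(n, 32, 7),
                    T90 = stats::runif(n, 0, 80),
                    dDFA_f2 = stats::rnorm(n, 0.02, 0.25),
                    dLLE = stats::rnorm(n, -0.47, 0.7),
                    mmDFA_t2 = stats::rnorm(n, 0.44, 0.13))
  clean <- predict_ahi(truth, tab)
  # noise-free targets: exact interpolation
  tab$ahi_true <- clean
  # an exact interpolation legitimately trips lm's perfect-fit warning
  m0 <- suppressWarnings(fit_linear(tab))
  expect_equal(unname(m0$coefficients),
               unname(truth$coefficients), tolerance = 1e-8)
  expect_equal(m0$intercept, -27, tolerance = 1e-8)
  # Gaussian noise sd = 5: every coefficient within 3 standard errors
  tab$ahi_true <- clean + stats::rnorm(n, 0, 5)
  m1 <- fit_linear(tab)
  se <- summary(attr(m1, "fit"))$coefficients[, "Std. Error"]
  est <- c(m1$intercept, m1$coefficients)
  ref <- c(-27, truth$coefficients)
  expect_true(all(abs(est - ref) <= 3 * se))
  expect_true(m1$r > 0.9)
})

test_that("refitting is permutation-invariant and guards rank deficiency", {
  set.seed(43)
  n <- 60
  tab <- data.frame(bmi = stats::rnorm(n, 32, 7),
                    T90 = stats::runif(n, 0, 80),
                    dDFA_f2 = stats::rnorm(n),
                    dLLE = stats::rnorm(n),
                    mmDFA_t2 = stats::rnorm(n))
  tab$ahi_true <- predict_ahi(published_ahi_model(), tab) +
    stats::rnorm(n, 0, 3)
  m1 <- fit_linear(tab)
  m2 <- fit_linear(tab[sample(n), ])
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  tab$dup <- tab$bmi
  expect_error(fit_linear(tab, predictors = c("bmi", "dup", "T90")),
               "rank deficient")
  expect_error(fit_linear(tab[1:5, ]), "more subjects")
})
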