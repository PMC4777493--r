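#' Linear AHI prediction model
#'
#' An affine model of the apnea-hypopnea index on five predictors: BMI, T90,
#' `dDFA_f2`, `dLLE` and `mmDFA_t2`. [published_ahi_model()] returns the
#' fixed published instance
#' `AHI = 1.2*BMI + 0.4*T90 - 18.6*dDFA_f2 + 7.8*dLLE + 60.5*mmDFA_t2 - 27`.
#'
#' @param coefficients Named numeric vector of slopes.
#' @param intercept Intercept.
#' @param r Optional multiple correlation coefficient of the fit.
#' @param residual_sd Optional residual standard deviation.
#' @param published Logical flag: a published instance refuses coefficient
#'   modification on prediction paths.
#' @return An object of class `linear_ahi_model`.
#' @export
linear_ahi_model <- function(coefficients, intercept, r = NA_real_,
                             residual_sd = NA_real_, published = FALSE) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))), is.numeric(intercept))
  structure(
    list(coefficients = coefficients, intercept = as.numeric(intercept),
         r = r, residual_sd = residual_sd, published = published),
    class = "linear_ahi_model"
  )
}

#' @rdname linear_ahi_model
#' @export
published_ahi_model <- function() {
  linear_ahi_model(
    coefficients = c(bmi = 1.2, T90 = 0.4, dDFA_f2 = -18.6, dLLE = 7.8,
                     mmDFA_t2 = 60.5),
    intercept = -27, published = TRUE
  )
}

#' @export
print.linear_ahi_model <- function(x, ...) {
  terms <- paste(sprintf("%+g*%s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("<linear_ahi_model>%s AHI = %s %+g\n",
              if (x$published) " [published]" else "", terms, x$intercept))
  if (is.finite(x$r)) cat(sprintf("  R = %.3f, residual SD = %.2f\n",
                                  x$r, x$residual_sd))
  invisible(x)
}

#' Predict AHI from a feature vector
#'
#' Exact affine evaluation of a [linear_ahi_model()]. The output may be
#' negative: downstream screening thresholds (5, 8) are applied to the raw
#' affine value, so no clamping happens unless requested.
#'
#' @param model A [linear_ahi_model()].
#' @param fv Named list, one-row data frame or [extract_features()] output
#'   supplying every predictor named in the model (case-sensitive; `bmi`
#'   comes from demographics).
#' @param clamp_zero If `TRUE`, negative predictions are truncated at 0.
#' @return Predicted AHI in events/hour (vectorized over data-frame rows).
#' @examples
#' m <- published_ahi_model()
#' predict_ahi(m, list(bmi = 0, T90 = 0, dDFA_f2 = 0, dLLE = 0, mmDFA_t2 = 0))
#' @export
predict_ahi <- function(model, fv, clamp_zero = FALSE) {
  stopifnot(inherits(model, "linear_ahi_model"))
  vals <- lapply(names(model$coefficients), function(nm) {
    v <- fv[[nm]]
    if (is.null(v) || any(!is.finite(v))) {
      stop(sprintf("predictor '%s' missing or non-finite", nm), call. = FALSE)
    }
    as.numeric(v)
  })
  pred <- Reduce(`+`, Map(`*`, model$coefficients, vals)) + model$intercept
  if (clamp_zero) pred <- pmax(0, pred)
  pred
}

#' Classify OSA severity from AHI
#'
#' Band edges as used clinically: AHI <= 5 is normal, (5, 15] mild,
#' (15, 30] moderate, above 30 severe.
#'
#' @param ahi AHI in events/hour (>= 0); vectorized.
#' @return Character vector with levels `normal`, `mild`, `moderate`,
#'   `severe`.
#' @export
classify_severity <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be non-negative", call. = FALSE)
  ifelse(ahi <= 5, "normal",
         ifelse(ahi <= 15, "mild",
                ifelse(ahi <= 30, "moderate", "severe")))
}

#' Collapse severity into the CPAP-treatment dichotomy
#'
#' Moderate and severe OSA constitute the group in which CPAP therapy is
#' normally considered; normal and mild form the conservative-management
#' group. With `by_ahi`, an AHI value is dichotomized directly at 15
#' (AHI >= 15 goes to the treatment group), which places the boundary value
#' 15 itself in the treatment group; the severity-label route puts AHI = 15
#' (mild) in the conservative group. Both conventions are exposed because
#' the boundary is genuinely ambiguous in clinical use.
#'
#' @param severity Character vector of severity labels, or AHI values when
#'   `by_ahi = TRUE`.
#' @param by_ahi Dichotomize numeric AHI at 15 instead of mapping labels.
#' @return Character vector with levels `normal/mild`, `moderate/severe`.
#' @export
binarize_for_cpap <- function(severity, by_ahi = FALSE) {
  if (by_ahi) {
    return(ifelse(severity >= 15, "moderate/severe", "normal/mild"))
  }
  ok <- severity %in% c("normal", "mild", "moderate", "severe")
  if (!all(ok)) {
    stop(sprintf("invalid severity label: %s",
                 paste(unique(severity[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  ifelse(severity %in% c("moderate", "severe"), "moderate/severe",
         "normal/mild")
}

#' Read or write a linear AHI model as JSON
#'
#' Serializes the coefficients, intercept and fit summary so models can be
#' exchanged between analyses; `read_ahi_model()` restores an equivalent
#' [linear_ahi_model()].
#'
#' @param model A [linear_ahi_model()].
#' @param path JSON file path.
#' @return `write_ahi_model()` returns `path` invisibly; `read_ahi_model()`
#'   returns the model.
#' @export
write_ahi_model <- function(model, path) {
  stopifnot(inherits(model, "linear_ahi_model"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         intercept = model$intercept, r = model$r,
         residual_sd = model$residual_sd, published = model$published),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ahi_model
#' @export
read_ahi_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_ahi_model(coefficients = unlist(j$coefficients),
                   intercept = j$intercept,
                   r = if (is.null(j$r)) NA_real_ else j$r,
                   residual_sd = if (is.null(j$residual_sd)) NA_real_
                   else j$residual_sd,
                   published = isTRUE(j$published))
}

#' Fit the linear AHI model by ordinary least squares
#'
#' Refits the affine AHI model on a subject table, returning a
#' [linear_ahi_model()] with the multiple correlation coefficient and
#' residual SD of the fit.
#'
#' @param table Data frame with one row per subject containing the
#'   predictors and the outcome.
#' @param predictors Character vector of predictor column names.
#' @param outcome Outcome column name (default `"ahi_true"`).
#' @return A [linear_ahi_model()] with attribute `"fit"` carrying the
#'   underlying `lm` object.
#' @export
fit_linear <- function(table, predictors = c("bmi", "T90", "dDFA_f2",
                                             "dLLE", "mmDFA_t2"),
                       outcome = "ahi_true") {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(predictors, outcome), names(table))
  if (length(missing_cols)) {
    stop(sprintf("columns not in table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(table) < length(predictors) + 2) {
    stop("need at least 2 more subjects than predictors", call. = FALSE)
  }
  X <- as.matrix(table[predictors])
  if (qr(cbind(1, X))$rank < length(predictors) + 1) {
    stop("design matrix is rank deficient (collinear predictors)",
         call. = FALSE)
  }
  df <- data.frame(.y = table[[outcome]], X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  m <- linear_ahi_model(
    coefficients = co[-1], intercept = co[[1]],
    r = sqrt(summary(fit)$r.squared),
    residual_sd = summary(fit)$sigma
  )
  attr(m, "fit") <- fit
  m
}
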