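# Statistical toolkit applied around the pipeline: normality-gated group
# comparison, correlation, ROC/AUC, screening sensitivity/specificity,
# Bland-Altman agreement, Cohen's kappa and the two-sample design power.

#' Normality-gated two-group comparison
#'
#' Tests each group for normality (Lilliefors-corrected Kolmogorov-Smirnov
#' by default, since group means and SDs are estimated from the data; plain
#' KS available for compatibility with software that defaults to it) and
#' compares the groups with a t-test when both pass at `alpha`, otherwise
#' with the Mann-Whitney U test. The t branch reports the 95% confidence
#' interval of the mean difference.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @param normality `"lilliefors"` (default) or `"ks"`.
#' @param var_equal Pooled-variance t-test when `TRUE` (default, the classic
#'   equality-of-means form); Welch when `FALSE`.
#' @return An object of class `osa_group_comparison`: `test_used` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `mean_difference`, `ci95`,
#'   and the two normality p-values.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           normality = c("lilliefors", "ks"),
                           var_equal = TRUE) {
  normality <- match.arg(normality)
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  norm_p <- function(x) {
    if (stats::sd(x) == 0) return(0)          # degenerate: not normal
    if (normality == "lilliefors" && length(x) >= 4) {
      nortest::lillie.test(x)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
  }
  pa <- norm_p(a); pb <- norm_p(b)
  both_normal <- pa > alpha && pb > alpha
  if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(test_used = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, mean_difference = mean(a) - mean(b),
                ci95 = unname(tt$conf.int))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                mean_difference = mean(a) - mean(b),
                ci95 = c(NA_real_, NA_real_))
  }
  res$normality_p <- c(a = pa, b = pb)
  structure(res, class = "osa_group_comparison")
}

#' @export
print.osa_group_comparison <- function(x, ...) {
  cat(sprintf("<osa_group_comparison> %s: statistic %.3f, p = %.4g, mean diff %.3f\n",
              x$test_used, x$statistic, x$p_value, x$mean_difference))
  invisible(x)
}

#' Screening sensitivity and specificity at an AHI cutoff
#'
#' Disease status is defined on the true AHI (OSA when `true_ahi >=
#' disease_threshold`, default 5); the screening decision is
#' `pred_ahi >= cutoff`. When one of the two groups is absent the
#' corresponding rate is undefined and is returned as `NA` with its name in
#' the `undefined` field rather than silently propagating NaN.
#'
#' @param pred_ahi Predicted AHI values.
#' @param true_ahi Reference AHI values (same length).
#' @param cutoff Screening threshold applied to the prediction.
#' @param disease_threshold True-AHI threshold defining disease (default 5).
#' @return List with `sensitivity` and `specificity` (percent), the
#'   2x2 counts `tp`, `fn`, `fp`, `tn`, and `undefined`.
#' @export
sens_spec <- function(pred_ahi, true_ahi, cutoff, disease_threshold = 5) {
  if (length(pred_ahi) != length(true_ahi)) {
    stop("pred_ahi and true_ahi must be paired", call. = FALSE)
  }
  disease <- true_ahi >= disease_threshold
  positive <- pred_ahi >= cutoff
  tp <- sum(disease & positive); fn <- sum(disease & !positive)
  fp <- sum(!disease & positive); tn <- sum(!disease & !positive)
  undefined <- character(0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  list(sensitivity = sens, specificity = spec, tp = tp, fn = fn, fp = fp,
       tn = tn, undefined = undefined)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all score thresholds with tie groups handled by
#' single trapezoids (equivalent to the normalized Mann-Whitney U
#' statistic).
#'
#' @param scores Numeric ranking scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1 or two-level factor); the
#'   larger/`TRUE` level is the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) == 2L
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must be paired", call. = FALSE)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  # sweep thresholds from high to low; ties advance TPR and FPR jointly
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tpr <- c(0, cumsum(tp_g) / n1)
  fpr <- c(0, cumsum(n_g - tp_g) / n0)
  sum((fpr[-1] - fpr[-length(fpr)]) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference) and 95% limits of agreement
#' (bias +/- 1.96 SD of the differences) between two measurement methods.
#'
#' @param a,b Paired numeric vectors (n >= 2).
#' @return An object of class `osa_agreement`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `pairs`, `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors required", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s, pairs = length(d), differences = d,
         means = (a + b) / 2),
    class = "osa_agreement"
  )
}

#' @export
print.osa_agreement <- function(x, ...) {
  cat(sprintf("<osa_agreement> bias %.3f, limits of agreement [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$pairs))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (n >= 3, non-zero variances).
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("paired vectors with n >= 3 required", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Power of a two-sided two-sample comparison of means
#'
#' Normal-approximation power for detecting a mean difference `delta` with
#' common standard deviation `sd` at sizes `n1`, `n2`:
#' `power = Phi(delta/se - z) + Phi(-delta/se - z)` with
#' `se = sd * sqrt(1/n1 + 1/n2)` and `z` the two-sided critical value. This
#' is the closed-form design arithmetic used for sample-size planning; a
#' noncentral-t version is available for exactness at small n.
#'
#' @param delta True mean difference.
#' @param sd Common standard deviation (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param method `"normal"` (default) or `"t"` (noncentral t).
#' @return Power in (0, 1).
#' @examples
#' power_two_sample(0.15, 0.2, 25, 75)  # the classic 100-subject design
#' @export
power_two_sample <- function(delta, sd, n1, n2, alpha = 0.05,
                             method = c("normal", "t")) {
  method <- match.arg(method)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha", call. = FALSE)
  se <- sd * sqrt(1 / n1 + 1 / n2)
  ncp <- delta / se
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  } else {
    df <- n1 + n2 - 2
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products. Works for k x k matrices with rows
#' as one rater/truth and columns as the other/prediction.
#'
#' @param confusion Square matrix of non-negative counts, total > 0.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || any(m < 0) || sum(m) == 0) {
    stop("confusion must be a square non-negative matrix with total > 0",
         call. = FALSE)
  }
  N <- sum(m)
  po <- sum(diag(m)) / N
  pe <- sum(rowSums(m) * colSums(m)) / N^2
  if (abs(1 - pe) < 1e-12) {
    stop("expected agreement is 1 (all mass on one marginal pair); kappa undefined",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve plot
#'
#' Cosmetic helper; the numeric contract is [roc_auc()].
#'
#' @param scores,labels As in [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (is.factor(labels)) labels <- as.integer(labels) == 2L
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  df <- data.frame(fpr = c(0, cumsum(!y) / sum(!labels)),
                   tpr = c(0, cumsum(y) / sum(labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)",
                                  roc_auc(scores, labels)))
}

#' Bland-Altman plot
#'
#' Cosmetic helper; the numeric contract is [bland_altman()].
#'
#' @param a,b Paired measurements.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(a, b) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ba <- bland_altman(a, b)
  df <- data.frame(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c(1, 2, 2)) +
    ggplot2::labs(x = "Mean of methods", y = "Difference",
                  title = sprintf("Bland-Altman: bias %.2f [%.2f, %.2f]",
                                  ba$bias, ba$loa_low, ba$loa_high))
}
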