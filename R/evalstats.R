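# ROC/AUC with DeLong variance, paired DeLong tests, Youden operating
# points, Lilliefors normality screening, univariate logistic AUC, and
# two-way random-effects ICC.

roc_object <- function(scores, labels) {
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  pROC::roc(response = y, predictor = as.numeric(scores),
            levels = c("benign", "malignant"), direction = "<",
            quiet = TRUE)
}

#' AUC with DeLong confidence interval
#'
#' AUC as the Mann-Whitney statistic of the scores, with a 95% confidence
#' interval from the DeLong structural-component variance
#' (`AUC +/- 1.96 SE`, clipped to `[0, 1]`). Scores are oriented
#' malignant-high; no automatic direction flipping is applied, so an
#' anti-informative score yields AUC < 0.5.
#'
#' @param scores Numeric scores, higher = more malignant.
#' @param labels Class labels (`benign`/`malignant`, or a factor whose
#'   second level is the positive class).
#' @return List with `auc`, `ci` (length 2), `se`.
#' @export
auc_delong <- function(scores, labels) {
  r <- roc_object(scores, labels)
  a <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(max(v, 0))
  ci <- pmin(pmax(a + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = a, ci = ci, se = se)
}

#' Paired DeLong test between two score vectors
#'
#' Two-sided z-test on the AUC difference of two models scored on the same
#' patients, using the DeLong covariance of the paired structural
#' components. Identical score vectors (or a zero-variance difference with
#' zero AUC difference) return p = 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Class labels shared by both.
#' @return Two-sided p-value.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have identical length")
  }
  ra <- roc_object(scores_a, labels)
  rb <- roc_object(scores_b, labels)
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) return(1)
  res <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  )
  p <- res$p.value
  if (!is.finite(p)) {
    p <- if (abs(as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))) < 1e-12) 1 else 0
  }
  p
}

#' Operating point by the Youden index
#'
#' Scans candidate thresholds (below the minimum score and the midpoints
#' between consecutive distinct scores); a pixel scores positive when its
#' score exceeds the threshold. The threshold maximizing
#' sensitivity + specificity - 1 is chosen, ties resolving to the lowest
#' threshold. Supplying `threshold` skips the search (used to carry a
#' training-derived operating point to a validation cohort).
#'
#' @param scores Numeric scores, higher = more malignant.
#' @param labels Class labels.
#' @param threshold Optional fixed threshold.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `threshold`.
#' @export
youden_metrics <- function(scores, labels, threshold = NULL) {
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pos <- y == "malignant"
  eval_at <- function(thr) {
    pred <- scores > thr
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    acc <- mean(pred == pos)
    c(sens, spec, acc)
  }
  if (is.null(threshold)) {
    su <- sort(unique(scores))
    cand <- if (length(su) > 1) {
      c(su[1] - 1, (su[-1] + su[-length(su)]) / 2)
    } else su - 1
    j <- vapply(cand, function(thr) sum(eval_at(thr)[1:2]) - 1, numeric(1))
    threshold <- cand[which.max(j)]  # which.max ties -> first = lowest
  }
  m <- eval_at(threshold)
  list(sensitivity = m[1], specificity = m[2], accuracy = m[3],
       threshold = threshold)
}

#' Lilliefors-corrected normality screen
#'
#' Kolmogorov-Smirnov test against a normal with estimated mean and SD
#' (Lilliefors correction). Decides how a variable should be summarized:
#' p >= 0.05 reports "mean±SD", otherwise "median±IQR". A zero-variance
#' sample is non-normal by convention.
#'
#' @param values Numeric sample, n >= 4.
#' @return List with `p` and `mode` (`"mean±SD"` or `"median±IQR"`).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("ks_normality needs at least 4 values")
  if (stats::sd(values) == 0) {
    return(list(p = 0, mode = "median±IQR"))
  }
  p <- nortest::lillie.test(values)$p.value
  list(p = p, mode = if (p >= 0.05) "mean±SD" else "median±IQR")
}

#' Univariate logistic AUC of one feature
#'
#' Single-covariate logistic fit; the AUC of the fitted probabilities (the
#' sign of the association is absorbed by the fit) and the Wald p-value of
#' the slope. Near-separable fits flag the Wald p as unreliable.
#'
#' @param x Feature values.
#' @param labels Class labels.
#' @return List with `auc`, `p` (Wald), `slope`, `wald_unreliable`.
#' @export
univariate_auc <- function(x, labels) {
  y <- as_label_factor(labels)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial())
  )
  sm <- summary(fit)$coefficients
  probs <- stats::fitted(fit)
  a <- auc_delong(probs, y)$auc
  se <- sm["x", "Std. Error"]
  unreliable <- !is.finite(se) || se > 100 || !fit$converged
  list(auc = a, p = sm["x", "Pr(>|z|)"], slope = sm["x", "Estimate"],
       wald_unreliable = unreliable)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, from the
#' two-way ANOVA decomposition over n subjects and two readers:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + MS_E + \frac{2}{n}(MS_C - MS_E)}}
#'
#' @param a,b Paired readings from the two readers, n >= 3.
#' @return ICC estimate.
#' @export
icc_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("readings must be paired")
  n <- length(a)
  if (n < 3L) stop("ICC needs at least 3 paired readings")
  x <- cbind(a, b)
  k <- 2
  grand <- mean(x)
  subj_means <- rowMeans(x)
  rater_means <- colMeans(x)
  ssr <- k * sum((subj_means - grand)^2)
  ssc <- n * sum((rater_means - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
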