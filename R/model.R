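# Feature prefiltering, LASSO selection and DT/SVM classifiers with 10-fold
# cross-validation. Labels are factors with levels c("benign", "malignant");
# scores are oriented so that higher means more malignant.

as_label_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (anyNA(f)) stop("labels must be 'benign' or 'malignant'")
  f
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k; every fold contains both
#'   classes when counts allow.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  y <- as_label_factor(labels)
  fold <- integer(length(y))
  local_seed_eval(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(tapply(seq_along(y), fold, function(i) length(unique(y[i]))) < 2L)) {
    stop("stratification error: a fold is missing a class")
  }
  fold
}

#' Pearson correlation prefilter
#'
#' Greedy scan in canonical feature order: zero-variance features are removed
#' first (correlation undefined), then for every pair with `|r|` above the
#' threshold the later feature in canonical order is removed. Deterministic
#' and independent of patient row order.
#'
#' @param X Numeric matrix or data frame, columns in canonical order.
#' @param threshold Absolute correlation cut (default 0.95).
#' @return List with `kept` (column names), `removed_correlated`,
#'   `removed_constant`.
#' @export
prefilter_correlated <- function(X, threshold = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("prefilter needs at least 2 patients")
  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[!is.finite(sds) | sds == 0]
  Xv <- X[, setdiff(colnames(X), constant), drop = FALSE]
  if (ncol(Xv) == 0L) stop("all features removed: every column is constant")
  cm <- abs(stats::cor(Xv))
  keep <- rep(TRUE, ncol(Xv))
  for (i in seq_len(ncol(Xv) - 1L)) {
    if (!keep[i]) next
    j <- which(keep & seq_len(ncol(Xv)) > i & cm[i, ] > threshold)
    keep[j] <- FALSE
  }
  kept <- colnames(Xv)[keep]
  if (!length(kept)) stop("all features removed by the correlation filter")
  list(
    kept = kept,
    removed_correlated = colnames(Xv)[!keep],
    removed_constant = constant
  )
}

#' LASSO feature selection
#'
#' L1-penalized logistic path on z-scored features; the penalty is chosen by
#' 10-fold cross-validated deviance at its minimum (`lambda.min`), and the
#' selected set is the features with nonzero coefficients there. An empty
#' selection (all coefficients shrunk away) is returned flagged rather than
#' raised.
#'
#' @param X Numeric feature matrix (patients x features).
#' @param labels Class labels.
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling fold assignment.
#' @return A `selection_result`: list with `selected`, `coefficients`
#'   (named, nonzero only), `lambda`, `empty` flag, and the scaling
#'   (`center`, `scale`) used.
#' @export
lasso_select <- function(X, labels, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  foldid <- make_folds(y, folds, seed)
  cvfit <- local_seed_eval(derive_seed(seed, 101L), {
    withCallingHandlers(
      glmnet::cv.glmnet(Xs, y, family = "binomial", foldid = foldid,
                        standardize = FALSE),
      warning = function(w) {
        # glmnet advisories about small folds/classes; expected on small
        # cohorts and not actionable here
        if (grepl("dangerous ground|grouped=FALSE", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  nz <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  structure(list(
    selected = nz,
    coefficients = stats::setNames(cf[nz, 1], nz),
    lambda = cvfit$lambda.min,
    cv_deviance = min(cvfit$cvm),
    empty = length(nz) == 0L,
    center = ctr, scale = scl
  ), class = "selection_result")
}

# Rank (Mann-Whitney) AUC; cheap, used inside hyperparameter searches.
auc_rank <- function(scores, y) {
  pos <- y == "malignant"
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

svm_grid <- function(p) {
  expand.grid(C = c(0.1, 1, 10, 100),
              gamma = c(1 / p, 0.01, 0.1, 1),
              KEEP.OUT.ATTRS = FALSE)
}

# Decision scores oriented so higher = malignant.
svm_scores <- function(fit, Xs) {
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  # e1071 orients the decision value toward the first factor level seen in
  # training; flip when that level is 'malignant'
  if (grepl("^malignant", colnames(dv)[1])) s else -s
}

fit_svm_once <- function(Xs, y, C, gamma) {
  e1071::svm(Xs, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

fit_dt_once <- function(Xs, y, cp) {
  df <- data.frame(y = y, Xs, check.names = FALSE)
  rpart::rpart(y ~ ., data = df, method = "class",
               control = rpart::rpart.control(cp = cp, xval = 0))
}

dt_scores <- function(fit, Xs) {
  stats::predict(fit, data.frame(Xs, check.names = FALSE),
                 type = "prob")[, "malignant"]
}

#' Fit a decision-tree or SVM classifier with cross-validation
#'
#' Decision tree: CART with the Gini index, cost-complexity pruning at the
#' complexity parameter minimizing inner 10-fold CV error. SVM: RBF kernel
#' with `(C, gamma)` chosen on an inner 10-fold CV grid
#' (`C` in 0.1/1/10/100, `gamma` in 1/p, 0.01, 0.1, 1) by CV AUC. Folds are
#' stratified and seeded. The returned model is refit on all training rows;
#' pooled out-of-fold scores from a final 10-fold pass are stored for
#' leakage-free training-cohort ROC analysis.
#'
#' @param kind `"dt"` or `"svm"`.
#' @param X Numeric matrix restricted to the selected features.
#' @param labels Class labels.
#' @param folds Number of CV folds.
#' @param seed Integer seed.
#' @return A `fitted_model`: list with `kind`, `model`, `hyper`, scaling,
#'   `cv_scores` (out-of-fold, aligned to rows), `fold_id`, `features`.
#' @export
fit_classifier <- function(kind = c("dt", "svm"), X, labels,
                           folds = 10L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("fit_classifier: empty feature selection")
  y <- as_label_factor(labels)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fold_id <- make_folds(y, folds, seed)

  if (kind == "svm") {
    grid <- svm_grid(ncol(X))
    cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
      sc <- rep(NA_real_, length(y))
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- fit_svm_once(Xs[tr, , drop = FALSE], y[tr],
                            grid$C[g], grid$gamma[g])
        sc[!tr] <- svm_scores(fit, Xs[!tr, , drop = FALSE])
      }
      auc_rank(sc, y)
    }, numeric(1))
    best <- which.max(cv_auc)  # ties -> first grid entry
    hyper <- list(C = grid$C[best], gamma = grid$gamma[best],
                  cv_auc = cv_auc[best])
    model <- fit_svm_once(Xs, y, hyper$C, hyper$gamma)
    cv_scores <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_svm_once(Xs[tr, , drop = FALSE], y[tr], hyper$C, hyper$gamma)
      cv_scores[!tr] <- svm_scores(fit, Xs[!tr, , drop = FALSE])
    }
  } else {
    # grow a full tree once to obtain the pruning path, then pick cp by
    # rpart's internal 10-fold cross-validated error
    df <- data.frame(y = y, Xs, check.names = FALSE)
    full <- local_seed_eval(derive_seed(seed, 202L), {
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = 0, xval = folds))
    })
    ct <- full$cptable
    cp_best <- ct[which.min(ct[, "xerror"]), "CP"]
    hyper <- list(cp = cp_best)
    model <- rpart::prune(full, cp = cp_best)
    cv_scores <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_dt_once(Xs[tr, , drop = FALSE], y[tr], cp_best)
      cv_scores[!tr] <- dt_scores(fit, Xs[!tr, , drop = FALSE])
    }
  }
  structure(list(
    kind = kind, model = model, hyper = hyper,
    center = ctr, scale = scl, features = colnames(X),
    cv_scores = cv_scores, fold_id = fold_id, labels = y
  ), class = "fitted_model")
}

#' Continuous malignancy scores from a fitted model
#'
#' Decision tree: probability of the malignant class at the reached leaf.
#' SVM: signed decision value. Higher always means more malignant.
#'
#' @param model A [fit_classifier()] result.
#' @param X Feature matrix containing the model's selected features.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  X <- as.matrix(X)
  missing_cols <- setdiff(model$features, colnames(X))
  if (length(missing_cols)) {
    stop("schema error: missing feature columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "))
  }
  Xs <- scale(X[, model$features, drop = FALSE],
              center = model$center, scale = model$scale)
  if (model$kind == "svm") svm_scores(model$model, Xs)
  else dt_scores(model$model, Xs)
}
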