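# Orchestration: simulate -> segment -> partition -> extract -> train ->
# evaluate, with reproducible seeding throughout.

.regions <- c("whole", "early", "moderate", "late")

#' Pipeline configuration
#'
#' @param seed Master seed; every stage derives its own substream.
#' @param scenario Synthetic scenario preset, see [scenario_preset()].
#' @param n_train,n_val Named counts `c(benign = ..., malignant = ...)`.
#' @param grid Image grid.
#' @param levels Gray levels for texture matrices.
#' @param folds CV folds for selection and model fitting.
#' @param fcm Named list of [spatial_fcm()] overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 17L, scenario = "default",
                            n_train = c(benign = 84L, malignant = 125L),
                            n_val = c(benign = 40L, malignant = 50L),
                            grid = c(128L, 128L), levels = 256L,
                            folds = 10L, fcm = list()) {
  structure(list(
    seed = as.integer(seed), scenario = scenario,
    n_train = n_train, n_val = n_val, grid = grid,
    levels = as.integer(levels), folds = as.integer(folds), fcm = fcm
  ), class = "pipeline_config")
}

#' Validate a list of studies
#'
#' Structural checks mirroring exclusion bookkeeping: phase count (1 pre +
#' 8 post), shape agreement, metadata completeness. Problems are reported,
#' not thrown; unusable studies are listed with reasons.
#'
#' @param studies List of `dce_study` objects (or malformed entries).
#' @return List with `manifest` (data frame of usable studies) and
#'   `problems` (data frame of index + reason).
#' @export
validate_studies <- function(studies) {
  probs <- list()
  rows <- list()
  for (k in seq_along(studies)) {
    s <- studies[[k]]
    reason <- NULL
    if (!is.list(s) || is.null(s$pre) || is.null(s$post)) {
      reason <- "missing pre/post images"
    } else if (!is.matrix(s$pre) || length(dim(s$post)) != 3) {
      reason <- "images have wrong dimensionality"
    } else if (dim(s$post)[3] != 8L) {
      reason <- sprintf("expected 8 post phases, found %d", dim(s$post)[3])
    } else if (!identical(dim(s$pre), dim(s$post)[1:2])) {
      reason <- "pre/post shape mismatch"
    } else if (is.null(s$label) || !s$label %in% c("benign", "malignant")) {
      reason <- "missing or unknown class label"
    } else if (is.null(s$cohort)) {
      reason <- "missing cohort tag"
    }
    if (is.null(reason)) {
      rows[[length(rows) + 1L]] <- data.frame(
        index = k,
        patient_id = if (is.null(s$patient_id)) NA_character_ else s$patient_id,
        label = s$label, cohort = s$cohort,
        rows = nrow(s$pre), cols = ncol(s$pre)
      )
    } else {
      probs[[length(probs) + 1L]] <- data.frame(index = k, reason = reason)
    }
  }
  list(
    manifest = if (length(rows)) do.call(rbind, rows) else
      data.frame(index = integer(0)),
    problems = if (length(probs)) do.call(rbind, probs) else
      data.frame(index = integer(0), reason = character(0))
  )
}

#' Segment, partition and extract features for a cohort
#'
#' Runs the per-patient pipeline: phase-4 subtraction segmentation
#' (spatial FCM + refinement), relative enhancement, TTP mapping, subregion
#' partition, and 467-feature extraction for the whole lesion and each
#' kinetic zone.
#'
#' @param studies List of `dce_study` objects.
#' @param levels Gray levels for texture matrices.
#' @param fcm Named list of [spatial_fcm()] overrides.
#' @return List with `features` (data frame: patient_id, cohort, label,
#'   region, missing flag, then the 467 canonical columns) and `qc`
#'   (per-patient Dice against the truth mask, TTP recovery fraction, zone
#'   pixel counts).
#' @export
build_feature_table <- function(studies, levels = 256L, fcm = list()) {
  schema <- feature_schema()
  feat_rows <- vector("list", length(studies) * 4L)
  qc_rows <- vector("list", length(studies))
  for (k in seq_along(studies)) {
    s <- studies[[k]]
    seg <- do.call(segment_study, c(list(study = s), fcm))
    H <- relative_enhancement(s)
    ttp <- time_to_peak(H, seg$mask)
    sm <- partition_subregions(ttp, seg$mask)
    box <- seg$qroi$box
    crop <- function(m) m[box$rows, box$cols, drop = FALSE]
    region_masks <- c(list(whole = crop(seg$mask)),
                      lapply(sm$zone_masks, crop))
    for (ri in seq_along(.regions)) {
      fv <- extract_features(seg$qroi$patch, region_masks[[.regions[ri]]],
                             levels)
      feat_rows[[(k - 1L) * 4L + ri]] <- data.frame(
        patient_id = s$patient_id, cohort = s$cohort, label = s$label,
        region = .regions[ri],
        missing = isTRUE(attr(fv, "missing")),
        as.list(fv), check.names = FALSE
      )
    }
    truth <- s$truth
    dice <- if (!is.null(truth$mask)) {
      dice_coefficient(seg$mask, truth$mask)
    } else NA_real_
    ttp_match <- if (!is.null(truth$ttp)) {
      common <- seg$mask & truth$mask
      if (any(common)) mean(ttp[common] == truth$ttp[common]) else NA_real_
    } else NA_real_
    qc_rows[[k]] <- data.frame(
      patient_id = s$patient_id, cohort = s$cohort, label = s$label,
      dice = dice, ttp_match = ttp_match,
      n_early = sm$counts[["early"]], n_moderate = sm$counts[["moderate"]],
      n_late = sm$counts[["late"]]
    )
  }
  list(features = do.call(rbind, feat_rows),
       qc = do.call(rbind, qc_rows))
}

# Rows of one region with complete feature vectors. Patients whose zone is
# empty, or too small for some co-occurrence offset (NA sentinel features),
# are excluded from that zone's model only.
region_matrix <- function(features, region) {
  rows <- features[features$region == region & !features$missing, ]
  X <- as.matrix(rows[, feature_schema(), drop = FALSE])
  complete <- rowSums(!is.finite(X)) == 0L
  rows <- rows[complete, ]
  X <- X[complete, , drop = FALSE]
  rownames(X) <- rows$patient_id
  list(X = X, labels = rows$label, patient_id = rows$patient_id,
       n_excluded = sum(!complete))
}

#' Train per-region models on a training feature table
#'
#' For every region (whole/early/moderate/late): Pearson prefilter, LASSO
#' selection, then one decision tree and one SVM on the selected features.
#' Patients whose zone is empty are excluded from that zone's models only.
#'
#' @param features Training feature table from [build_feature_table()].
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return Nested list `models[[region]][[kind]]` plus
#'   `selections[[region]]`.
#' @export
train_models <- function(features, folds = 10L, seed = 17L) {
  models <- list()
  selections <- list()
  for (region in .regions) {
    rm_ <- region_matrix(features, region)
    counts <- table(factor(rm_$labels, c("benign", "malignant")))
    if (min(counts) < folds) {
      # too few complete patients in this zone to stratify the CV; the
      # region is reported with chance-level constant scores downstream
      selections[[region]] <- list(insufficient = TRUE,
                                   n = length(rm_$labels))
      models[[region]] <- list(dt = NULL, svm = NULL)
      next
    }
    pf <- prefilter_correlated(rm_$X)
    Xp <- rm_$X[, pf$kept, drop = FALSE]
    sel <- lasso_select(Xp, rm_$labels, folds = folds,
                        seed = derive_seed(seed, match(region, .regions)))
    selections[[region]] <- list(prefilter = pf, lasso = sel)
    models[[region]] <- list()
    for (kind in c("dt", "svm")) {
      if (sel$empty) {
        models[[region]][[kind]] <- NULL
      } else {
        models[[region]][[kind]] <- fit_classifier(
          kind, Xp[, sel$selected, drop = FALSE], rm_$labels,
          folds = folds,
          seed = derive_seed(seed, 10L + match(region, .regions))
        )
      }
    }
  }
  list(models = models, selections = selections)
}

model_label <- function(kind, region) {
  paste0(toupper(kind), "_", tools::toTitleCase(region))
}

score_cohort <- function(model, features, region) {
  rm_ <- region_matrix(features, region)
  if (is.null(model)) {
    list(scores = rep(0, length(rm_$labels)), labels = rm_$labels,
         patient_id = rm_$patient_id)
  } else {
    list(scores = predict_scores(model, rm_$X), labels = rm_$labels,
         patient_id = rm_$patient_id)
  }
}

roc_row <- function(scores, labels, threshold = NULL) {
  if (length(unique(as_label_factor(labels))) < 2L) {
    # degenerate cohort for this region (all complete rows share a class)
    return(data.frame(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      accuracy = NA_real_, threshold = NA_real_))
  }
  res <- auc_delong(scores, labels)
  ym <- youden_metrics(scores, labels, threshold)
  data.frame(auc = res$auc, ci_lo = res$ci[1], ci_hi = res$ci[2],
             sensitivity = ym$sensitivity, specificity = ym$specificity,
             accuracy = ym$accuracy, threshold = ym$threshold)
}

#' Evaluate trained models on training (cross-validated) and validation data
#'
#' Training-cohort metrics use pooled out-of-fold CV scores (leakage-free);
#' resubstitution metrics of the refit model are also reported, labeled.
#' Validation metrics apply each refit model with the training-derived
#' Youden threshold. Pairwise DeLong p-value matrices are computed per
#' cohort over all models, restricted to patients scored by both.
#'
#' @param trained [train_models()] output.
#' @param feat_train,feat_val Feature tables.
#' @return An `evaluation_report`: list with `performance` (data frame),
#'   `delong` (list of matrices per cohort), `multiple_testing_correction`
#'   (caveat flag; raw p-values are reported).
#' @export
evaluate_models <- function(trained, feat_train, feat_val) {
  perf <- list()
  score_store <- list()
  for (region in .regions) {
    for (kind in c("dt", "svm")) {
      mdl <- trained$models[[region]][[kind]]
      lab <- model_label(kind, region)
      tr_rm <- region_matrix(feat_train, region)
      cv_scores <- if (is.null(mdl)) rep(0, length(tr_rm$labels)) else
        mdl$cv_scores
      tr_fit <- score_cohort(mdl, feat_train, region)
      va <- score_cohort(mdl, feat_val, region)
      row_cv <- roc_row(cv_scores, tr_rm$labels)
      row_rs <- roc_row(tr_fit$scores, tr_fit$labels)
      row_va <- roc_row(va$scores, va$labels, threshold = row_cv$threshold)
      perf[[length(perf) + 1L]] <- cbind(
        data.frame(model = lab, kind = kind, region = region,
                   cohort = c("training_cv", "training_resub", "validation"),
                   n = c(length(cv_scores), length(tr_fit$scores),
                         length(va$scores))),
        rbind(row_cv, row_rs, row_va)
      )
      score_store[[lab]] <- list(
        training = list(scores = cv_scores, labels = tr_rm$labels,
                        patient_id = tr_rm$patient_id),
        validation = va
      )
    }
  }
  delong <- list()
  for (cohort in c("training", "validation")) {
    labs <- names(score_store)
    P <- matrix(1, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (j <= i) next
      si <- score_store[[labs[i]]][[cohort]]
      sj <- score_store[[labs[j]]][[cohort]]
      common <- intersect(si$patient_id, sj$patient_id)
      ii <- match(common, si$patient_id)
      jj <- match(common, sj$patient_id)
      p <- tryCatch(
        delong_test(si$scores[ii], sj$scores[jj], si$labels[ii]),
        error = function(e) NA_real_
      )
      P[i, j] <- p; P[j, i] <- p
    }
    delong[[cohort]] <- P
  }
  structure(list(
    performance = do.call(rbind, perf),
    delong = delong,
    scores = score_store,
    multiple_testing_correction = "none (raw p-values)"
  ), class = "evaluation_report")
}

#' Run the full pipeline
#'
#' Simulates training and validation cohorts, segments and partitions every
#' lesion, extracts the 467-feature vectors for the whole lesion and each
#' kinetic subregion, trains per-region DT and SVM models on the training
#' cohort, and evaluates everything.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `qc.csv`, `report.json` and `feature_schema.json`.
#' @return List with `report` ([evaluate_models()] output), `qc`
#'   (per-patient Dice/TTP recovery for both cohorts), `selections`,
#'   `models`, `features` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  train_st <- generate_cohort(config$n_train[["benign"]],
                              config$n_train[["malignant"]],
                              config$scenario, derive_seed(config$seed, 1L),
                              "training", config$grid)
  val_st <- generate_cohort(config$n_val[["benign"]],
                            config$n_val[["malignant"]],
                            config$scenario, derive_seed(config$seed, 2L),
                            "validation", config$grid)
  ft_train <- build_feature_table(train_st, config$levels, config$fcm)
  ft_val <- build_feature_table(val_st, config$levels, config$fcm)
  trained <- train_models(ft_train$features, config$folds, config$seed)
  report <- evaluate_models(trained, ft_train$features, ft_val$features)
  qc <- rbind(ft_train$qc, ft_val$qc)
  out <- list(report = report, qc = qc,
              selections = trained$selections, models = trained$models,
              features = rbind(ft_train$features, ft_val$features),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    jsonlite::write_json(feature_schema(),
                         file.path(out_dir, "feature_schema.json"))
    jsonlite::write_json(
      list(performance = report$performance,
           delong = lapply(report$delong, as.data.frame)),
      file.path(out_dir, "report.json"), dataframe = "rows", digits = NA
    )
  }
  out
}
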