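# Leave-one-subject-out gradient-boosting classification protocol.

#' Hyperparameter grid for the gradient-boosted classifier
#'
#' The default spans tree depths 2-10, 60-220 boosting rounds and learning
#' rates 0.001/0.01/0.1. [hyper_grid_reduced()] is a coarse subset of the
#' same ranges for desk-scale runs.
#'
#' @param depths integer tree depths.
#' @param n_estimators integer numbers of boosting rounds.
#' @param learning_rates learning rates (eta).
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(depths = c(2, 4, 6, 8, 10),
                       n_estimators = c(60, 100, 140, 180, 220),
                       learning_rates = c(0.001, 0.01, 0.1)) {
  stopifnot(length(depths) > 0, length(n_estimators) > 0,
            length(learning_rates) > 0)
  structure(list(depths = as.integer(depths),
                 n_estimators = as.integer(n_estimators),
                 learning_rates = as.numeric(learning_rates)),
            class = "hyper_grid")
}

#' @rdname hyper_grid
#' @export
hyper_grid_reduced <- function() {
  hyper_grid(depths = c(2, 6), n_estimators = c(60, 140),
             learning_rates = c(0.01, 0.1))
}

#' Balance classes by undersampling the majority class
#'
#' Keeps the whole minority class and draws a uniform subsample (without
#' replacement) of the majority class of matching size.
#'
#' @param labels binary vector (0/1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Integer indices (sorted) of the retained, class-balanced rows.
#' @export
undersample_majority <- function(labels, seed = NULL) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present to undersample", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(c("0", "1"), minority)
  idx_min <- which(labels == as.numeric(minority))
  idx_maj <- which(labels == as.numeric(majority))
  draw <- function() sample(idx_maj, length(idx_min))
  picked <- if (length(idx_maj) == length(idx_min)) idx_maj
            else if (is.null(seed)) draw() else with_seed(seed, draw())
  sort(c(idx_min, picked))
}

#' Classification performance metrics
#'
#' Accuracy at the given probability threshold, sensitivity (recall of the
#' instability class, label 1), and the rank-based (Mann-Whitney) area under
#' the ROC curve with tie correction.
#'
#' @param y_true binary labels.
#' @param y_score predicted probabilities in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return A list with `accuracy`, `sensitivity`, `auc` (the latter `NA`
#'   when only one class is present).
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score),
            all(y_true %in% c(0, 1)), all(y_score >= 0 & y_score <= 1))
  pred <- as.integer(y_score >= threshold)
  acc <- mean(pred == y_true)
  n_pos <- sum(y_true == 1)
  sens <- if (n_pos == 0) NA_real_ else sum(pred == 1 & y_true == 1) / n_pos
  n_neg <- length(y_true) - n_pos
  auc <- if (n_pos == 0 || n_neg == 0) {
    NA_real_
  } else {
    r <- rank(y_score)  # average ranks handle ties
    (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(accuracy = acc, sensitivity = sens, auc = auc)
}

# Fit the gradient-boosted tree ensemble (binary logistic objective).
fit_gbm <- function(X, y, depth, nrounds, eta) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

# Stratified fold assignment: within each class, shuffle and deal into k
# folds as evenly as possible.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.feature_set_cols <- list(
  copv = "med_abs_copv", sh = "med_abs_sh", ha = "med_abs_ha",
  ttb = "med_abs_ttb",
  all4 = c("med_abs_copv", "med_abs_sh", "med_abs_ha", "med_abs_ttb")
)

#' Leave-one-subject-out evaluation with inner grid search
#'
#' The full prediction protocol, per left-out subject and repeat: build a
#' class-balanced test set from the left-out subject (undersampling its
#' majority class), pool the remaining subjects and undersample to balance,
#' select hyperparameters by mean accuracy over an inner stratified 5-fold
#' cross-validation of the training pool (ties prefer shallower trees, then
#' fewer rounds, then smaller learning rate), refit on the full balanced
#' pool, and evaluate on the held-out test set. All randomness derives
#' deterministically from `(seed, subject, repeat, feature_set)`, so
#' different feature sets see identical test subsets.
#'
#' @param features feature table from [feature_table()] (columns
#'   `subject_id`, `label`, and the four feature columns).
#' @param feature_set one of `"copv"`, `"sh"`, `"ha"`, `"ttb"`, `"all4"`.
#' @param grid a [hyper_grid()]; defaults to [hyper_grid_reduced()].
#' @param repeats repeats per left-out subject (default 10).
#' @param seed master seed.
#' @param permute_labels when `TRUE`, class labels are randomly permuted
#'   (with a per-run seed) before each run — the chance-level control.
#' @param inner_folds inner CV folds (default 5).
#' @param importance compute per-run mean |Shapley value| per feature on the
#'   test set (default: only for multi-feature sets).
#' @param threshold classification threshold for accuracy/sensitivity.
#' @param keep_indices attach the per-run test/train row indices as
#'   list-columns (`test_rows`, `train_rows`) — useful for auditing the
#'   no-leakage and balance guarantees.
#' @return A data frame with one row per (subject, repeat): chosen
#'   hyperparameters, `accuracy`, `sensitivity`, `auc`, `n_test`, and (when
#'   `importance`) one `shap_*` column per feature.
#' @export
loso_evaluate <- function(features, feature_set = "all4",
                          grid = hyper_grid_reduced(), repeats = 10, seed = 1,
                          permute_labels = FALSE, inner_folds = 5,
                          importance = NULL, threshold = 0.5,
                          keep_indices = FALSE) {
  stopifnot(inherits(grid, "hyper_grid"))
  feature_set <- match.arg(feature_set, names(.feature_set_cols))
  cols <- .feature_set_cols[[feature_set]]
  if (is.null(importance)) importance <- length(cols) > 1
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO", call. = FALSE)
  if (repeats < 1) stop("`repeats` must be >= 1", call. = FALSE)
  combos <- expand.grid(depth = grid$depths, nrounds = grid$n_estimators,
                        eta = grid$learning_rates)
  res <- list()
  # body of one (subject, repeat) run; called under the run's RNG seed
  run_once <- function(si) {
    labels <- features$label
    if (permute_labels) labels <- sample(labels)
    is_test <- features$subject_id == subjects[si]
    if (length(unique(labels[is_test])) < 2) {
      warning(sprintf("subject %s has a single class; run skipped", subjects[si]))
      return(NULL)
    }
    test_rows <- which(is_test)[undersample_majority(labels[is_test])]
    pool_rows <- which(!is_test)
    if (length(unique(labels[pool_rows])) < 2) {
      warning("training pool has a single class; run skipped")
      return(NULL)
    }
    train_rows <- pool_rows[undersample_majority(labels[pool_rows])]
    X_tr <- as.matrix(features[train_rows, cols, drop = FALSE])
    y_tr <- labels[train_rows]
    X_te <- as.matrix(features[test_rows, cols, drop = FALSE])
    y_te <- labels[test_rows]
    fold <- stratified_folds(y_tr, inner_folds)
    cv_acc <- vapply(seq_len(nrow(combos)), function(ci) {
      accs <- vapply(seq_len(inner_folds), function(k) {
        tr <- fold != k
        m <- fit_gbm(X_tr[tr, , drop = FALSE], y_tr[tr],
                     combos$depth[ci], combos$nrounds[ci], combos$eta[ci])
        p <- predict(m, X_tr[!tr, , drop = FALSE])
        mean((p >= threshold) == y_tr[!tr])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- order(-cv_acc, combos$depth, combos$nrounds, combos$eta)[1]
    model <- fit_gbm(X_tr, y_tr, combos$depth[best], combos$nrounds[best],
                     combos$eta[best])
    p_te <- predict(model, X_te)
    met <- compute_metrics(y_te, p_te, threshold)
    out <- data.frame(
      subject = subjects[si], repeat_index = rep_i,
      feature_set = feature_set,
      max_depth = combos$depth[best], n_estimators = combos$nrounds[best],
      learning_rate = combos$eta[best],
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      auc = met$auc, n_test = length(test_rows)
    )
    if (importance) {
      contrib <- predict(model, X_te, predcontrib = TRUE)
      imp <- colMeans(abs(contrib[, cols, drop = FALSE]))
      out[paste0("shap_", cols)] <- as.list(imp)
    }
    if (keep_indices) {
      out$test_rows <- I(list(test_rows))
      out$train_rows <- I(list(train_rows))
    }
    out
  }
  for (si in seq_along(subjects)) {
    for (rep_i in seq_len(repeats)) {
      run_seed <- hash_seed(seed, si, rep_i, feature_set)
      row <- with_seed(run_seed, run_once(si))
      if (!is.null(row)) res[[length(res) + 1L]] <- row
    }
  }
  if (length(res) == 0L) stop("no valid LOSO runs", call. = FALSE)
  do.call(rbind, res)
}

#' Shapley-value feature importance of a fitted model
#'
#' Mean absolute Shapley value per feature over the supplied samples, with a
#' direction summary: the sign of the correlation between feature values and
#' their Shapley contributions (+1 when larger feature values push the model
#' towards the instability class).
#'
#' @param model a fitted `xgb.Booster` (tree ensemble).
#' @param X numeric matrix of samples (named columns, training order).
#' @param method `"tree"` (xgboost's exact TreeSHAP, float32) or `"exact"`
#'   (the package's double-precision subset enumeration,
#'   [shap_values_exact()]).
#' @return A data frame sorted by decreasing importance: `feature`,
#'   `mean_abs_shap`, `direction`.
#' @export
shap_importance <- function(model, X, method = c("tree", "exact")) {
  method <- match.arg(method)
  if (!inherits(model, "xgb.Booster")) {
    stop("`model` must be a fitted xgb.Booster tree ensemble", call. = FALSE)
  }
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("`X` must be non-empty", call. = FALSE)
  phi <- if (method == "tree") {
    contrib <- predict(model, X, predcontrib = TRUE)
    contrib[, colnames(X), drop = FALSE]
  } else {
    shap_values_exact(model, X)$phi
  }
  direction <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(phi[, j]) == 0) 0
    else sign(stats::cor(X[, j], phi[, j]))
  }, numeric(1))
  out <- data.frame(feature = colnames(X),
                    mean_abs_shap = colMeans(abs(phi)),
                    direction = direction)
  out[order(-out$mean_abs_shap), , drop = FALSE]
}

#' Compare feature-set models across LOSO runs
#'
#' For each performance metric: mean and standard error per feature set over
#' all (subject x repeat) runs, plus all pairwise independent two-sample
#' t-tests between feature sets with significance flagged at `alpha`
#' (default 0.005, Bonferroni-minded for the ten comparisons among five
#' models).
#'
#' @param results row-bound output of [loso_evaluate()] over >= 2 feature
#'   sets.
#' @param alpha significance level for flagging.
#' @return A list: `summary` (data frame feature_set x metric mean/SE),
#'   `p_matrices` (named list of symmetric p-value matrices per metric),
#'   `alpha`.
#' @export
compare_models <- function(results, alpha = 0.005) {
  sets <- unique(results$feature_set)
  if (length(sets) < 2) stop("need results from at least 2 feature sets", call. = FALSE)
  metrics <- c("accuracy", "sensitivity", "auc")
  counts <- table(results$feature_set)
  if (any(counts < 2)) stop("each feature set needs at least 2 runs", call. = FALSE)
  summary <- do.call(rbind, lapply(sets, function(s) {
    sub <- results[results$feature_set == s, ]
    do.call(rbind, lapply(metrics, function(m) {
      x <- sub[[m]][is.finite(sub[[m]])]
      data.frame(feature_set = s, metric = m, mean = mean(x),
                 se = stats::sd(x) / sqrt(length(x)), n_runs = length(x))
    }))
  }))
  p_matrices <- lapply(stats::setNames(metrics, metrics), function(m) {
    pm <- matrix(NA_real_, length(sets), length(sets),
                 dimnames = list(sets, sets))
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j) {
        a <- results[[m]][results$feature_set == sets[i]]
        b <- results[[m]][results$feature_set == sets[j]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) {
          # degenerate (constant) samples: equal means are indistinguishable
          if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
        })
        pm[i, j] <- pm[j, i] <- p
      }
    }
    pm
  })
  list(summary = summary, p_matrices = p_matrices, alpha = alpha)
}
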