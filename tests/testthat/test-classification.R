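test_that("undersampling balances classes and is seed-deterministic", {
  labels <- c(rep(0, 726), rep(1, 338))
  idx <- undersample_majority(labels, seed = 1)
  expect_length(idx, 2 * 338)
  expect_equal(sum(labels[idx] == 0), 338)
  expect_equal(sum(labels[idx] == 1), 338)
  expect_identical(idx, undersample_majority(labels, seed = 1))
  expect_false(identical(idx, undersample_majority(labels, seed = 2)))
  # already balanced: identity
  bal <- rep(c(0, 1), 10)
  expect_identical(undersample_majority(bal, seed = 3), seq_along(bal))
  expect_error(undersample_majority(rep(1, 10)), "both classes")
})

test_that("metrics match their definitions and the all-pairs AUC oracle", {
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$auc, 1)
  zeros <- compute_metrics(c(0, 1, 0, 1), rep(0, 4))
  expect_equal(zeros$accuracy, 0.5)
  expect_equal(zeros$sensitivity, 0)
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))$auc, 0.75)
  # brute force over all positive-negative pairs, with ties, n = 50
  set.seed(14)
  y <- rbinom(50, 1, 0.4)
  s <- round(runif(50), 1)  # coarse scores force ties
  pos <- which(y == 1); neg <- which(y == 0)
  brute <- mean(outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(compute_metrics(y, s)$auc, brute)
  expect_true(is.na(compute_metrics(rep(1, 4), runif(4))$auc))
})

test_that("LOSO runs are deterministic, balanced, and leak-free", {
  f <- toy_features()
  r1 <- loso_evaluate(f, "all4", grid = hyper_grid(2, 60, 0.1), repeats = 2,
                      seed = 9, keep_indices = TRUE)
  r2 <- loso_evaluate(f, "all4", grid = hyper_grid(2, 60, 0.1), repeats = 2,
                      seed = 9, keep_indices = TRUE)
  expect_identical(r1[, setdiff(names(r1), c("test_rows", "train_rows"))],
                   r2[, setdiff(names(r2), c("test_rows", "train_rows"))])
  for (i in seq_len(nrow(r1))) {
    te <- r1$test_rows[[i]]; tr <- r1$train_rows[[i]]
    # balanced test set from the left-out subject only
    expect_equal(sum(f$label[te] == 0), sum(f$label[te] == 1))
    expect_true(all(f$subject_id[te] == r1$subject[i]))
    # the left-out subject's rows never reach the training pool
    expect_length(intersect(te, tr), 0)
    expect_false(any(f$subject_id[tr] == r1$subject[i]))
    expect_equal(sum(f$label[tr] == 0), sum(f$label[tr] == 1))
  }
  expect_true(all(r1$n_test %% 2 == 0))
})

test_that("an information-bearing feature yields near-perfect accuracy", {
  f <- toy_features(signal = 25)           # label written into the feature
  r <- loso_evaluate(f, "copv", grid = hyper_grid(2, 60, 0.1), repeats = 1,
                     seed = 4)
  expect_gt(mean(r$accuracy), 0.97)
})

test_that("exact Shapley values satisfy local accuracy and match TreeSHAP", {
  set.seed(15)
  n <- 200
  X <- cbind(med_abs_copv = rnorm(n), med_abs_sh = rnorm(n),
             med_abs_ha = rnorm(n), med_abs_ttb = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X[, 4] - X[, 1]))
  m <- balanceN1:::fit_gbm(X, y, 4, 80, 0.1)
  sv <- shap_values_exact(m, X[1:20, ])
  # additivity in double precision
  expect_lt(max(abs(sv$base + rowSums(sv$phi) - sv$value)), 1e-6)
  # the enumerated model output agrees with the booster's margin
  marg <- predict(m, X[1:20, ], outputmargin = TRUE)
  expect_lt(max(abs(sv$value - marg)), 1e-4)
  # per-feature agreement with xgboost's TreeSHAP (float32)
  contrib <- predict(m, X[1:20, ], predcontrib = TRUE)
  expect_lt(max(abs(sv$phi - contrib[, 1:4])), 1e-4)
})

test_that("shap_importance ranks informative features and flags directions", {
  set.seed(16)
  n <- 400
  X <- cbind(med_abs_copv = rnorm(n), med_abs_sh = rnorm(n),
             med_abs_ha = rep(1, n), med_abs_ttb = rnorm(n))
  y <- as.integer(X[, "med_abs_ttb"] < 0)   # single informative feature
  m <- balanceN1:::fit_gbm(X, y, 3, 60, 0.3)
  imp <- shap_importance(m, X)
  expect_equal(imp$feature[1], "med_abs_ttb")
  expect_equal(imp$mean_abs_shap[imp$feature == "med_abs_ha"], 0)
  expect_equal(imp$direction[imp$feature == "med_abs_ttb"], -1)
  imp_exact <- shap_importance(m, X[1:30, ], method = "exact")
  expect_equal(imp_exact$feature[1], "med_abs_ttb")
  expect_error(shap_importance(lm(y ~ X), X), "xgb.Booster")
})

test_that("model comparison flags real differences and not identical sets", {
  base <- data.frame(subject = "S01", repeat_index = 1,
                     sensitivity = 0.8, auc = 0.8, n_test = 10)
  set.seed(17)
  mk <- function(fs, mu) {
    d <- base[rep(1, 100), ]
    d$feature_set <- fs
    d$accuracy <- rnorm(100, mu, 0.01)
    d
  }
  same <- rbind(mk("a", 0.7), mk("b", 0.7))
  same$accuracy[101:200] <- same$accuracy[1:100]  # identical values
  cm_same <- compare_models(same)
  expect_gt(cm_same$p_matrices$accuracy["a", "b"], 0.99)
  diff <- rbind(mk("a", 0.70), mk("b", 0.58))
  cm <- compare_models(diff)
  expect_lt(cm$p_matrices$accuracy["a", "b"], 0.005)
  expect_equal(nrow(cm$summary), 2 * 3)  # feature sets x metrics
  expect_error(compare_models(mk("a", 0.7)), "at least 2 feature sets")
})
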