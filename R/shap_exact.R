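# Exact Shapley values for small gradient-boosted tree ensembles.
#
# With only four biomechanical features the 2^p subset enumeration is cheap,
# so the conditional-expectation Shapley attribution can be computed exactly
# in double precision. This is the package's reference implementation; the
# fast float32 TreeSHAP path in xgboost is cross-checked against it.

# Round doubles to the nearest float32 value (xgboost stores features and
# split thresholds in single precision; split comparisons must replicate
# that to land in the same leaves).
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), what = "numeric",
          size = 4L, n = length(x))
}

# Parse an xgboost booster into a list of per-tree node tables.
parse_booster_trees <- function(model, feature_names) {
  td <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  lapply(split(td, td$Tree), function(tt) {
    id2row <- stats::setNames(seq_len(nrow(tt)), tt$ID)
    list(
      is_leaf = tt$Feature == "Leaf",
      feat = match(tt$Feature, feature_names),
      # thresholds are single-precision in the model; the text dump does not
      # always round-trip exactly, so snap back to float32
      split = ifelse(is.na(tt$Split), NA_real_, as_float32(tt$Split)),
      yes = ifelse(tt$Feature == "Leaf", NA_integer_, id2row[tt$Yes]),
      no = ifelse(tt$Feature == "Leaf", NA_integer_, id2row[tt$No]),
      value = tt$Gain,      # leaf output for leaf rows
      cover = tt$Cover
    )
  })
}

# Expected tree output for one sample when only the features in `in_s`
# (logical vector over features) are known; unknown splits are averaged with
# cover weights.
tree_exp_value <- function(tree, x, in_s, node = 1L) {
  if (tree$is_leaf[node]) return(tree$value[node])
  f <- tree$feat[node]
  if (!is.na(f) && in_s[f]) {
    nxt <- if (x[f] < tree$split[node]) tree$yes[node] else tree$no[node]
    return(tree_exp_value(tree, x, in_s, nxt))
  }
  yes <- tree$yes[node]; no <- tree$no[node]
  (tree$cover[yes] * tree_exp_value(tree, x, in_s, yes) +
     tree$cover[no] * tree_exp_value(tree, x, in_s, no)) / tree$cover[node]
}

#' Exact Shapley values of a gradient-boosted tree model
#'
#' Enumerates all feature subsets (feasible for the handful of features used
#' here) and computes the Shapley attribution of the model's margin output
#' for each sample, using cover-weighted conditional expectations within
#' each tree. Computed entirely in double precision, so the additivity
#' identity `rowSums(phi) = f(x) - f0` holds to machine accuracy.
#'
#' @param model a fitted `xgb.Booster`.
#' @param X numeric matrix with named columns (the training feature order).
#' @return A list: `phi` (n x p matrix of Shapley values, margin scale),
#'   `base` (expected margin over the training distribution, tree part),
#'   `value` (per-sample tree-sum margin, i.e. `base + rowSums(phi)`).
#' @export
shap_values_exact <- function(model, X) {
  if (!inherits(model, "xgb.Booster")) stop("`model` must be an xgb.Booster", call. = FALSE)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 10) stop("exact enumeration supported for at most 10 features", call. = FALSE)
  X_cmp <- X
  X_cmp[] <- as_float32(X)   # replicate xgboost's single-precision comparisons
  trees <- parse_booster_trees(model, colnames(X))
  # intercept: xgboost boosts from an estimated base_score (probability scale)
  cfg <- xgboost::xgb.config(model)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  b0 <- stats::qlogis(as.numeric(cfg$learner$learner_model_param$base_score))
  if (!is.finite(b0)) b0 <- 0
  n_sub <- 2^p
  subsets <- lapply(0:(n_sub - 1), function(m) as.logical(bitwAnd(m, 2^(0:(p - 1)))))
  sizes <- vapply(subsets, sum, integer(1))
  w <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  value <- numeric(nrow(X))
  base <- 0
  for (i in seq_len(nrow(X))) {
    x <- X_cmp[i, ]
    v <- vapply(subsets, function(s) {
      sum(vapply(trees, tree_exp_value, numeric(1), x = x, in_s = s))
    }, numeric(1))
    for (j in seq_len(p)) {
      bit <- 2^(j - 1)
      # positions (1-based) of subsets not containing feature j; the matching
      # subset with j added sits `bit` positions later
      without <- which(bitwAnd(0:(n_sub - 1), bit) == 0L)
      phi[i, j] <- sum(w[sizes[without] + 1] * (v[without + bit] - v[without]))
    }
    value[i] <- v[n_sub] + b0
    if (i == 1L) base <- v[1] + b0
  }
  list(phi = phi, base = base, value = value)
}
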