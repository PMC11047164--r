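# Epoch-level biomechanical features and descriptive statistics.

#' Reduce one epoch to the four-parameter feature vector
#'
#' Per channel (COPv, shear, head acceleration, TTB), the median — or,
#' optionally, the mean — of the absolute sample values whose timestamps lie
#' in the closed window relative to the epoch center (default -300..-50 ms;
#' the window ends before the center because vestibular afference needs
#' ~50 ms to reach cortex). 100 Hz channels contribute ~26 samples, 10 Hz
#' channels 2-3.
#'
#' @param epoch a `labeled_epoch` from [extract_epochs()].
#' @param window_ms closed feature window relative to the center, in ms.
#' @param stat `"median"` (default) or `"mean"`.
#' @return A one-row data frame: `subject_id`, `label`, `center_time_s`,
#'   `med_abs_copv`, `med_abs_sh`, `med_abs_ha`, `med_abs_ttb`.
#' @export
compute_features <- function(epoch, window_ms = c(-300, -50), stat = "median") {
  stopifnot(inherits(epoch, "labeled_epoch"))
  stat_fun <- switch(stat, median = stats::median, mean = mean,
                     stop("`stat` must be \"median\" or \"mean\"", call. = FALSE))
  lo <- epoch$center_time_s + window_ms[1] / 1000
  hi <- epoch$center_time_s + window_ms[2] / 1000
  vals <- vapply(c("copv", "sh", "ha", "ttb"), function(ch) {
    tr <- epoch$traces[[ch]]
    idx <- ts_window_idx(tr, lo, hi)
    if (length(idx) == 0L) {
      stop(sprintf("channel \"%s\" has no samples in the feature window", ch),
           call. = FALSE)
    }
    stat_fun(abs(tr$values[idx]))
  }, numeric(1))
  data.frame(subject_id = epoch$subject_id, label = epoch$label,
             center_time_s = epoch$center_time_s,
             med_abs_copv = vals[["copv"]], med_abs_sh = vals[["sh"]],
             med_abs_ha = vals[["ha"]], med_abs_ttb = vals[["ttb"]])
}

#' Feature table for a list of epochs
#'
#' @param epochs list of `labeled_epoch`.
#' @inheritParams compute_features
#' @return A data frame, one row per epoch (see [compute_features()]).
#' @export
feature_table <- function(epochs, window_ms = c(-300, -50), stat = "median") {
  if (length(epochs) == 0L) {
    return(data.frame(subject_id = character(0), label = integer(0),
                      center_time_s = numeric(0), med_abs_copv = numeric(0),
                      med_abs_sh = numeric(0), med_abs_ha = numeric(0),
                      med_abs_ttb = numeric(0)))
  }
  do.call(rbind, lapply(epochs, compute_features, window_ms = window_ms, stat = stat))
}

.feature_cols <- c("med_abs_copv", "med_abs_sh", "med_abs_ha", "med_abs_ttb")
.feature_names <- c(med_abs_copv = "COPv", med_abs_sh = "SH",
                    med_abs_ha = "HA", med_abs_ttb = "TTB")

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_p` where `s_p` pools the two group variances with
#' `(n_a - 1, n_b - 1)` weights.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return The effect size (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("pooled SD is zero; Cohen's d undefined", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Normality and collinearity screen of the feature set
#'
#' Shapiro-Wilk p-value per feature and Pearson correlation (with p-value)
#' for all six feature pairs, pooled over both classes. Pairs with
#' `|r| >= 0.7` are flagged as strong — a collinearity warning for the
#' combined classification model. Constant features yield `NA` correlations,
#' reported as such.
#'
#' @param features feature table from [feature_table()].
#' @return A list with `shapiro` (data frame: feature, p) and `pearson`
#'   (data frame: feature_1, feature_2, r, p, strong).
#' @export
correlation_screen <- function(features) {
  if (nrow(features) < 3) stop("need at least 3 epochs", call. = FALSE)
  shapiro <- do.call(rbind, lapply(.feature_cols, function(cn) {
    x <- features[[cn]]
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    p <- if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
    data.frame(feature = .feature_names[[cn]], p = p)
  }))
  pairs <- utils::combn(.feature_cols, 2)
  pearson <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- features[[pairs[1, k]]]; b <- features[[pairs[2, k]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(a, b)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(feature_1 = .feature_names[[pairs[1, k]]],
               feature_2 = .feature_names[[pairs[2, k]]],
               r = r, p = p, strong = is.finite(r) && abs(r) >= 0.7)
  }))
  list(shapiro = shapiro, pearson = pearson)
}

#' Class contrast of the four features
#'
#' Per parameter: class means with standard errors, Cohen's d
#' (instability minus control) and the Welch two-sample t-test p-value.
#'
#' @param features feature table from [feature_table()] containing both
#'   classes.
#' @return A data frame with one row per parameter: `feature`,
#'   `mean_instability`, `se_instability`, `mean_control`, `se_control`,
#'   `cohens_d`, `p_value`.
#' @export
class_contrast <- function(features) {
  if (length(unique(features$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  do.call(rbind, lapply(.feature_cols, function(cn) {
    a <- features[[cn]][features$label == 1]
    b <- features[[cn]][features$label == 0]
    data.frame(
      feature = .feature_names[[cn]],
      mean_instability = mean(a), se_instability = stats::sd(a) / sqrt(length(a)),
      mean_control = mean(b), se_control = stats::sd(b) / sqrt(length(b)),
      cohens_d = cohens_d(a, b),
      p_value = stats::t.test(a, b)$p.value
    )
  }))
}
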