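# End-to-end pipeline: simulate -> detect -> epoch -> features -> classify
# -> report.

#' Pipeline configuration
#'
#' Gathers every analysis constant in one place so deviations from the
#' standard protocol are visible in a single object: detection windows,
#' SD multipliers, TTB guards, the hyperparameter grid and the master seed.
#'
#' @param cohort a [cohort_params()]; its `seed` is overridden by
#'   `master_seed`.
#' @param n1_search_window_ms N1 search window relative to the zero-crossing
#'   (default `c(-250, -100)`).
#' @param epoch_window_ms epoch window around each center (default
#'   `c(-300, 100)`).
#' @param feature_window_ms feature window (default `c(-300, -50)`); must be
#'   nested in the epoch window.
#' @param copv_k_sd COPv threshold multiplier (default 3).
#' @param n1_k_sd trough depth multiplier (default 2).
#' @param ttb_cap_s,ttb_eps_cm_s TTB cap and velocity floor.
#' @param refractory_s event refractory period (s).
#' @param control_exclusion_ms,control_min_sep_ms control-trough policy (see
#'   [detect_control_troughs()]).
#' @param feature_stat `"median"` (default) or `"mean"`.
#' @param grid a [hyper_grid()].
#' @param feature_sets feature sets to evaluate.
#' @param repeats LOSO repeats per subject.
#' @param master_seed master seed for cohort generation and every
#'   classification run.
#' @param output_dir optional directory for artifacts (`NULL`: in-memory
#'   only).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_params(),
                            n1_search_window_ms = c(-250, -100),
                            epoch_window_ms = c(-300, 100),
                            feature_window_ms = c(-300, -50),
                            copv_k_sd = 3, n1_k_sd = 2,
                            ttb_cap_s = 10, ttb_eps_cm_s = 0.1,
                            refractory_s = 1.0,
                            control_exclusion_ms = 300,
                            control_min_sep_ms = 400,
                            feature_stat = "median",
                            grid = hyper_grid_reduced(),
                            feature_sets = c("copv", "sh", "ha", "ttb", "all4"),
                            repeats = 10,
                            master_seed = 42,
                            output_dir = NULL) {
  if (copv_k_sd <= 0 || n1_k_sd <= 0) stop("SD multipliers must be positive", call. = FALSE)
  if (feature_window_ms[1] < epoch_window_ms[1] ||
      feature_window_ms[2] > epoch_window_ms[2]) {
    stop("feature window must be nested inside the epoch window", call. = FALSE)
  }
  cohort$seed <- master_seed
  structure(
    list(cohort = cohort, n1_search_window_ms = n1_search_window_ms,
         epoch_window_ms = epoch_window_ms,
         feature_window_ms = feature_window_ms,
         copv_k_sd = copv_k_sd, n1_k_sd = n1_k_sd, ttb_cap_s = ttb_cap_s,
         ttb_eps_cm_s = ttb_eps_cm_s, refractory_s = refractory_s,
         control_exclusion_ms = control_exclusion_ms,
         control_min_sep_ms = control_min_sep_ms,
         feature_stat = feature_stat, grid = grid,
         feature_sets = feature_sets, repeats = repeats,
         master_seed = master_seed, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Detect events, troughs and epochs for one subject
#'
#' Runs the detection chain on one recording: biomechanical derivations and
#' instability events, IC baseline correction, N1 and control troughs, and
#' labeled epoch extraction.
#'
#' @param recording a `subject_recording`.
#' @param config a [pipeline_config()].
#' @return A list: `derived` (`biomech_derived`), `baseline`
#'   (`baseline_stats`), `n1` and `controls` (data frames), `epochs` (list
#'   of `labeled_epoch`), `features` (data frame).
#' @export
process_subject <- function(recording, config = pipeline_config()) {
  derived <- derive_biomech(recording, k_sd = config$copv_k_sd,
                            cap_s = config$ttb_cap_s,
                            eps_cm_s = config$ttb_eps_cm_s,
                            refractory_s = config$refractory_s)
  bc <- baseline_correct(recording$ic_trace)
  n1 <- detect_n1(bc$ic, bc$stats, derived$events,
                  search_window_ms = config$n1_search_window_ms,
                  k_sd = config$n1_k_sd)
  task_bounds <- c(recording$cop_ap$t0, ts_end(recording$cop_ap))
  controls <- detect_control_troughs(
    bc$ic, bc$stats, n1$time_s, k_sd = config$n1_k_sd,
    exclusion_ms = config$control_exclusion_ms,
    min_sep_ms = config$control_min_sep_ms,
    search_bounds = task_bounds,
    epoch_window_ms = config$epoch_window_ms,
    epoch_bounds = task_bounds
  )
  centers <- rbind(
    if (nrow(n1)) data.frame(time_s = n1$time_s, label = 1L),
    if (nrow(controls)) data.frame(time_s = controls$time_s, label = 0L)
  )
  epochs <- if (is.null(centers)) list() else {
    extract_epochs(recording, derived, centers, bc$ic,
                   epoch_window_ms = config$epoch_window_ms)
  }
  features <- feature_table(epochs, window_ms = config$feature_window_ms,
                            stat = config$feature_stat)
  list(derived = derived, baseline = bc$stats, n1 = n1, controls = controls,
       epochs = epochs, features = features)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage \"%s\" failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, detects instability events and N1/control troughs,
#' extracts epochs and features, runs the leave-one-subject-out evaluation
#' for every configured feature set, and assembles descriptive statistics,
#' model comparisons and Shapley importances. Fully deterministic given
#' `config$master_seed`. When `config$output_dir` is set, artifacts
#' (`features.csv`, `runs.csv`, `events/*.json`, `comparison.json`,
#' `importance.json`, `manifest.json`, `report.md`, `report.json`) are
#' written there.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `manifest`,
#'   `features`, `per_subject`, `contrast`, `screen`, `runs`, `comparison`,
#'   `importance`, `latency_summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_start <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- run_stage(stage, expr)
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }

  cohort <- clock("simulate", generate_cohort(config$cohort))
  per_subject <- clock("detect", lapply(cohort$subjects, process_subject,
                                        config = config))
  names(per_subject) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")

  features <- clock("features", do.call(rbind, lapply(per_subject, `[[`, "features")))
  rownames(features) <- NULL

  n1_all <- do.call(rbind, lapply(per_subject, `[[`, "n1"))
  latency_summary <- if (is.null(n1_all) || nrow(n1_all) == 0) NULL else {
    list(mean_ms = mean(n1_all$latency_ms),
         se_ms = stats::sd(n1_all$latency_ms) / sqrt(nrow(n1_all)),
         n = nrow(n1_all))
  }

  class_counts <- table(factor(features$label, levels = c(0, 1)))
  both_classes <- min(class_counts) >= 2
  contrast <- NULL
  screen <- NULL
  if (both_classes) {
    contrast <- clock("descriptives", class_contrast(features))
    screen <- run_stage("descriptives", correlation_screen(features))
  } else {
    warning("single-class feature table; descriptive contrasts skipped")
  }

  runs <- clock("classify", {
    per_set <- lapply(config$feature_sets, function(fs) {
      loso_evaluate(features, feature_set = fs, grid = config$grid,
                    repeats = config$repeats, seed = config$master_seed)
    })
    all_cols <- unique(unlist(lapply(per_set, names)))
    do.call(rbind, lapply(per_set, function(d) {
      d[setdiff(all_cols, names(d))] <- NA_real_
      d[all_cols]
    }))
  })
  comparison <- if (length(config$feature_sets) >= 2) {
    run_stage("compare", compare_models(runs))
  }

  importance <- NULL
  if ("all4" %in% config$feature_sets) {
    shap_cols <- paste0("shap_", .feature_set_cols$all4)
    all4_runs <- runs[runs$feature_set == "all4", , drop = FALSE]
    if (all(shap_cols %in% names(all4_runs)) && nrow(all4_runs) > 0) {
      mean_abs <- colMeans(all4_runs[, shap_cols, drop = FALSE])
      # direction from one pooled, balanced, seeded refit
      direction <- run_stage("importance", with_seed(config$master_seed, {
        bal <- undersample_majority(features$label)
        X <- as.matrix(features[bal, .feature_set_cols$all4, drop = FALSE])
        m <- fit_gbm(X, features$label[bal], depth = 4, nrounds = 100, eta = 0.1)
        imp <- shap_importance(m, X)
        stats::setNames(imp$direction, imp$feature)
      }))
      importance <- data.frame(
        feature = .feature_set_cols$all4,
        mean_abs_shap = unname(mean_abs),
        direction = unname(direction[.feature_set_cols$all4])
      )
      importance <- importance[order(-importance$mean_abs_shap), ]
      rownames(importance) <- NULL
    }
  }

  manifest <- list(
    config_hash = sprintf("%08x", hash_seed(paste(utils::capture.output(
      utils::str(config, give.attr = FALSE)), collapse = "\n"))),
    master_seed = config$master_seed,
    n_subjects = length(cohort$subjects),
    counts = list(
      events = sum(vapply(per_subject, function(s) nrow(s$derived$events), integer(1))),
      n1 = sum(vapply(per_subject, function(s) nrow(s$n1), integer(1))),
      controls = sum(vapply(per_subject, function(s) nrow(s$controls), integer(1))),
      epochs = nrow(features),
      runs = nrow(runs)
    ),
    timings_s = timings,
    total_s = as.numeric(Sys.time() - t_start, units = "secs")
  )

  result <- structure(
    list(manifest = manifest, features = features, per_subject = per_subject,
         contrast = contrast, screen = screen, runs = runs,
         comparison = comparison, importance = importance,
         latency_summary = latency_summary, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_report(result, config$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d: %d epochs (%d N1, %d control), %d LOSO runs\n",
              x$config$master_seed, x$manifest$counts$epochs,
              x$manifest$counts$n1, x$manifest$counts$controls,
              x$manifest$counts$runs))
  invisible(x)
}

fmt_pct <- function(m, s) sprintf("%.1f ± %.1f", 100 * m, 100 * s)

#' Write pipeline artifacts and the human-readable report
#'
#' Emits machine-readable JSON/CSV artifacts plus `report.md` with the three
#' standard tables: performance metrics per feature-set model (mean ± SE
#' over runs), per-parameter class contrast with effect sizes, and the
#' Shapley importance ranking, together with the per-cohort N1 latency
#' summary. Sections without content (e.g. no importance for single-feature
#' configurations) are omitted.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(result$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  ev_dir <- file.path(dir, "events")
  dir.create(ev_dir, showWarnings = FALSE)
  for (sid in names(result$per_subject)) {
    s <- result$per_subject[[sid]]
    jsonlite::write_json(
      list(threshold_cm_s = s$derived$threshold, events = s$derived$events,
           n1 = s$n1, controls = s$controls),
      file.path(ev_dir, paste0(sid, ".json")), dataframe = "rows", digits = NA
    )
  }
  if (!is.null(result$comparison)) {
    jsonlite::write_json(
      list(summary = result$comparison$summary,
           p_matrices = lapply(result$comparison$p_matrices, function(m) {
             list(sets = rownames(m), p = m)
           }),
           alpha = result$comparison$alpha),
      file.path(dir, "comparison.json"), dataframe = "rows", digits = NA,
      auto_unbox = TRUE, na = "null"
    )
  }
  if (!is.null(result$importance)) {
    jsonlite::write_json(result$importance, file.path(dir, "importance.json"),
                         dataframe = "rows", digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  md <- c(sprintf("# Balance-N1 pipeline report (seed %d, config %s)",
                  result$config$master_seed, result$manifest$config_hash), "")
  cnt <- result$manifest$counts
  md <- c(md, sprintf("Epochs: %d instability, %d control (%.1f%% instability).",
                      cnt$n1, cnt$controls, 100 * cnt$n1 / max(cnt$epochs, 1)), "")
  if (!is.null(result$latency_summary)) {
    md <- c(md, sprintf("N1 latency before the corrective zero-crossing: %.1f ± %.1f ms (mean ± SE, n = %d).",
                        result$latency_summary$mean_ms, result$latency_summary$se_ms,
                        result$latency_summary$n), "")
  }
  if (!is.null(result$comparison)) {
    md <- c(md, "## Model performance (mean ± SE over runs, %)", "",
            "| Model | Accuracy | Sensitivity | AUC |", "|---|---|---|---|")
    for (fs in unique(result$comparison$summary$feature_set)) {
      s <- result$comparison$summary
      g <- function(m) {
        r <- s[s$feature_set == fs & s$metric == m, ]
        fmt_pct(r$mean, r$se)
      }
      md <- c(md, sprintf("| %s | %s | %s | %s |", fs,
                          g("accuracy"), g("sensitivity"), g("auc")))
    }
    md <- c(md, "")
  }
  if (!is.null(result$contrast)) {
    md <- c(md, "## Class contrast (instability vs control)", "",
            "| Parameter | Instability (mean ± SE) | Control (mean ± SE) | Cohen's d | p |",
            "|---|---|---|---|---|")
    for (i in seq_len(nrow(result$contrast))) {
      r <- result$contrast[i, ]
      md <- c(md, sprintf("| %s | %.3f ± %.3f | %.3f ± %.3f | %.2f | %.2g |",
                          r$feature, r$mean_instability, r$se_instability,
                          r$mean_control, r$se_control, r$cohens_d, r$p_value))
    }
    md <- c(md, "")
  }
  if (!is.null(result$importance) && nrow(result$importance) > 0) {
    md <- c(md, "## Feature importance (mean |Shapley value| over runs)", "",
            "| Rank | Feature | Mean |SHAP| | Direction |", "|---|---|---|---|")
    for (i in seq_len(nrow(result$importance))) {
      r <- result$importance[i, ]
      md <- c(md, sprintf("| %d | %s | %.4f | %+d |", i,
                          sub("med_abs_", "", r$feature), r$mean_abs_shap,
                          as.integer(r$direction)))
    }
    md <- c(md, "")
  }
  writeLines(md, file.path(dir, "report.md"))
  jsonlite::write_json(
    list(manifest = result$manifest,
         latency_summary = result$latency_summary,
         contrast = result$contrast,
         importance = result$importance),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA, na = "null"
  )
  invisible(dir)
}
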