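# Shared fixtures. Heavy objects (the default synthetic cohort and its
# processed per-subject outputs) are built once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# The default study-conditions cohort (10 subjects, master seed 42) with the
# full detection chain applied per subject.
default_processed <- function() {
  memo("default_processed", function() {
    config <- pipeline_config(master_seed = 42)
    cohort <- generate_cohort(config$cohort)
    per_subject <- lapply(cohort$subjects, process_subject, config = config)
    names(per_subject) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
    features <- do.call(rbind, lapply(per_subject, `[[`, "features"))
    rownames(features) <- NULL
    list(cohort = cohort, per_subject = per_subject, features = features,
         config = config)
  })
}

# A small three-subject cohort for cheaper structural tests.
small_processed <- function() {
  memo("small_processed", function() {
    config <- pipeline_config(cohort = cohort_params(n_subjects = 3),
                              master_seed = 11,
                              grid = hyper_grid(2, 60, 0.1),
                              repeats = 1,
                              feature_sets = c("ttb", "all4"))
    cohort <- generate_cohort(config$cohort)
    per_subject <- lapply(cohort$subjects, process_subject, config = config)
    features <- do.call(rbind, lapply(per_subject, `[[`, "features"))
    rownames(features) <- NULL
    list(cohort = cohort, per_subject = per_subject, features = features,
         config = config)
  })
}

# A deterministic toy feature table with a controllable signal feature.
toy_features <- function(n_subjects = 4, n_per = 40, signal = 2, seed = 5) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    force(code)
  }
  with_seed(seed, {
    subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_per)
    label <- rep_len(c(0L, 1L), length(subj))
    base <- function() abs(rnorm(length(subj)))
    data.frame(
      subject_id = subj, label = label, center_time_s = seq_along(subj),
      med_abs_copv = base() + signal * label,
      med_abs_sh = base(),
      med_abs_ha = base(),
      med_abs_ttb = base()
    )
  })
}
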