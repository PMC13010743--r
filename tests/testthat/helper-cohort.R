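# Shared, lazily built heavy fixtures (default study cohort, its feature
# tables per gaze stream, and the primary nested-LOSO report). Built once per
# test session and reused across test files.

gs_test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, gs_test_cache)) assign(name, builder(), gs_test_cache)
  get(name, gs_test_cache)
}

default_cohort <- function() {
  cached("cohort", function() simulate_cohort(cohort_spec(n_per_group = 35, seed = 1)))
}

default_features <- function(stream = "cyclopean") {
  cached(paste0("features_", stream), function() {
    extract_features(default_cohort(), stream_kind = stream)
  })
}

default_loso <- function() {
  cached("loso", function() {
    nested_loso(default_features(), model_config(), seed = 1)
  })
}

# small synthesized trial-level feature table (no simulator) for fast model
# tests: n subjects per group, k trials each, group-shifted gaussian features
toy_feature_table <- function(n_per_group = 6, k_trials = 10, p = 6,
                              shift = 1.5, seed = 1, miss_frac = 0) {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(2 * n_per_group))
  grp <- rep(c("control", "amblyopia"), each = n_per_group)
  rows <- list()
  for (i in seq_along(subj)) {
    mu <- stats::rnorm(p, mean = if (grp[i] == "amblyopia") shift else 0, sd = 0.5)
    X <- matrix(stats::rnorm(k_trials * p, mean = rep(mu, each = k_trials)),
                k_trials, p)
    if (miss_frac > 0) X[stats::runif(length(X)) < miss_frac] <- NA
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(p))
    df$subject_id <- subj[i]; df$group <- grp[i]
    df$task_id <- 1L; df$trial_id <- seq_len(k_trials); df$retained <- TRUE
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}
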