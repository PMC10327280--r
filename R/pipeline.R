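# End-to-end pipeline: simulate -> cohort stats -> GFK/MMD -> core
# selection -> classification experiments, with a JSON manifest for
# reproducible re-runs.

#' Build a pipeline configuration
#'
#' Accepts a nested list (or a YAML file path) with an `out_dir`, a global
#' `seed`, and optional per-stage blocks `simulate`, `stats`, `select`,
#' `experiments` overriding stage defaults. Per-stage seeds are derived
#' deterministically from the global seed (`seed * 101 + stage index`,
#' modulo 2^31 - 1), so each stage is reproducible in isolation.
#'
#' @param config A list or YAML file path.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    out_dir = "healthycore_run",
    seed = 1,
    input = NULL,  # optional pre-existing feature table CSV (skips simulate)
    simulate = list(),
    stats = list(q = 0.05, k = 21, reps = 100),
    select = list(target_size = "auto", method = "greedy_backward"),
    experiments = list(positive = "CM", repeats = 5)
  )
  cfg <- modifyList(defaults, config)
  known <- names(defaults)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop_hc(paste0("unknown pipeline config field(s): ",
                   paste(unknown, collapse = ", ")),
            "healthycore_validation_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop_hc("config field 'seed' must be a single integer",
            "healthycore_validation_error")
  }
  if (!(identical(cfg$select$target_size, "auto") ||
        is.numeric(cfg$select$target_size))) {
    stop_hc("select stage needs 'target_size' (a count or \"auto\")",
            "healthycore_validation_error")
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop_hc(paste0("input file does not exist: ", cfg$input),
            "healthycore_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(seed, index) {
  as.integer((seed * 101 + index) %% (2^31 - 1))
}

#' Run the full healthy-core pipeline
#'
#' Executes the stages in dependency order -- simulate (or load), cohort
#' statistics, GFK + MMD between the HC cohorts, healthy-core selection,
#' and the three classification experiments -- writing each stage's
#' artifacts under `out_dir` and a `manifest.json` recording stage, inputs,
#' outputs, seed and content hashes. Re-running with the same configuration
#' reproduces identical artifact hashes.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to one).
#' @param dry_run Validate the configuration and report the stage plan
#'   without reading or writing any data.
#' @return A tibble manifest (stage, output, md5, seed), invisibly unless
#'   `dry_run`.
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- c("simulate", "stats", "gfk_mmd", "select", "experiments")
  if (dry_run) {
    return(tibble(stage = stages,
                  seed = stage_seed(config$seed, seq_along(stages))))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_stage <- function(stage, outputs, seed, t0) {
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] seed=%d wrote %s (%.1fs)", stage, seed,
                    paste(basename(outputs), collapse = ", "), elapsed))
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, output = outputs,
      md5 = unname(tools::md5sum(outputs)), seed = seed
    )
  }

  # Stage 1: simulate (or load).
  t0 <- Sys.time()
  s1 <- stage_seed(config$seed, 1)
  if (is.null(config$input)) {
    cfg <- do.call(synthetic_config, config$simulate)
    sim <- generate_multisite_cohorts(cfg, seed = s1)
    tab <- sim$table
    truth_path <- file.path(config$out_dir, "ground_truth.csv")
    readr::write_csv(sim$truth$core, truth_path)
    data_path <- file.path(config$out_dir, "features.csv")
    write_feature_table(tab, data_path)
    log_stage("simulate", c(data_path, truth_path), s1, t0)
  } else {
    tab <- read_feature_table(config$input)
    data_path <- config$input
    log_stage("simulate", data_path, s1, t0)
  }
  cohorts <- sort(unique(tab$cohort))
  if (length(cohorts) != 2) {
    stop_hc("pipeline expects exactly two cohorts", "healthycore_validation_error")
  }
  hc_a <- subset_rows(tab, cohort = cohorts[1], diagnosis = "HC")
  hc_b <- subset_rows(tab, cohort = cohorts[2], diagnosis = "HC")

  # Stage 2: cohort statistics.
  t0 <- Sys.time()
  s2 <- stage_seed(config$seed, 2)
  q <- config$stats$q
  means <- univariate_mean_tests(hc_a, hc_b, q = q)
  vars <- univariate_variance_tests(hc_a, hc_b, q = q)
  prot <- subset_mean_difference_protocol(hc_a, hc_b, k = config$stats$k,
                                          reps = config$stats$reps, seed = s2)
  stats_path <- file.path(config$out_dir, "cohort_tests.csv")
  readr::write_csv(bind_rows(means, vars), stats_path)
  prot_path <- file.path(config$out_dir, "subset_protocol.csv")
  readr::write_csv(prot, prot_path)
  summary_path <- file.path(config$out_dir, "stats_summary.json")
  jsonlite::write_json(list(
    q = q,
    mean_tests = count_rejections(means),
    variance_tests = count_rejections(vars)
  ), summary_path, auto_unbox = TRUE, pretty = TRUE)
  log_stage("stats", c(stats_path, prot_path, summary_path), s2, t0)

  # Stage 3: GFK + MMD between the HC cohorts.
  t0 <- Sys.time()
  s3 <- stage_seed(config$seed, 3)
  gfk <- fit_gfk(hc_a, hc_b)
  spec <- kernel_spec("rbf", "median-heuristic", space = "gfk", gfk = gfk)
  test <- mmd_permutation_test(hc_a, hc_b, spec, n_perm = 499, seed = s3)
  mmd_path <- file.path(config$out_dir, "mmd.json")
  jsonlite::write_json(as.list(tidy(test)), mmd_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("gfk_mmd", mmd_path, s3, t0)

  # Stage 4: healthy-core selection.
  t0 <- Sys.time()
  s4 <- stage_seed(config$seed, 4)
  core <- select_healthy_core(
    hc_a, hc_b,
    target_size = config$select$target_size,
    method = config$select$method %||% "greedy_backward",
    seed = s4
  )
  core_path <- file.path(config$out_dir, "core.json")
  jsonlite::write_json(list(
    ids_a = core$ids_a, ids_b = core$ids_b, mmd2 = core$mmd2,
    config = core$config[setdiff(names(core$config), "bandwidth")],
    bandwidth = unname(core$config$bandwidth)
  ), core_path, auto_unbox = TRUE, pretty = TRUE)
  traj_path <- file.path(config$out_dir, "core_trajectory.csv")
  readr::write_csv(core$trajectory, traj_path)
  log_stage("select", c(core_path, traj_path), s4, t0)

  # Stage 5: experiments.
  t0 <- Sys.time()
  s5 <- stage_seed(config$seed, 5)
  positive <- config$experiments$positive
  repeats <- config$experiments$repeats
  single <- run_single_dataset_experiment(tab, positive, repeats = repeats,
                                          seed = s5, cohort = cohorts[1])
  cross <- run_cross_dataset_experiment(
    subset_rows(tab, cohort = cohorts[1]),
    subset_rows(tab, cohort = cohorts[2]),
    positive, repeats = repeats, seed = s5
  )
  corex <- run_healthy_core_experiment(
    core, subset_rows(tab, cohort = cohorts[1]),
    subset_rows(tab, cohort = cohorts[2]),
    positive, repeats = repeats, seed = s5
  )
  exp_path <- file.path(config$out_dir, "experiments.json")
  jsonlite::write_json(list(
    single = aggregate_repeats(single),
    cross = aggregate_repeats(cross),
    healthy_core = aggregate_repeats(corex)
  ), exp_path, pretty = TRUE, digits = NA)
  log_stage("experiments", exp_path, s5, t0)

  manifest <- bind_rows(manifest)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, pretty = TRUE)
  invisible(manifest)
}

count_rejections <- function(res) {
  res %>%
    group_by(.data$test) %>%
    summarise(before_fdr = sum(.data$p_value <= attr(res, "q")),
              after_fdr = sum(.data$rejected), .groups = "drop") %>%
    (function(d) setNames(
      lapply(seq_len(nrow(d)),
             function(i) list(before_fdr = d$before_fdr[i],
                              after_fdr = d$after_fdr[i])),
      d$test))()
}
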