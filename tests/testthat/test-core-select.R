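# Toy instance: a shared tight cluster in both cohorts plus
# cohort-specific distant clusters; the optimum core is the shared cluster.
two_cluster_toy <- function(n_shared = 4, n_off = 2, D = 4, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(center, n, cohort, prefix) {
      m <- matrix(rnorm(n * D, sd = 0.2), n, D) +
        matrix(center, n, D, byrow = TRUE)
      colnames(m) <- paste0("lh_r", seq_len(D), "_area")
      feature_table(dplyr::bind_cols(
        tibble::tibble(subject_id = sprintf("%s%02d", prefix, seq_len(n)),
                       cohort = cohort, diagnosis = "HC",
                       sex = "F", age = 30),
        tibble::as_tibble(m)
      ))
    }
    a <- feature_table(dplyr::bind_rows(
      as.data.frame(mk(rep(0, D), n_shared, "A", "a_sh")),
      as.data.frame(mk(rep(8, D), n_off, "A", "a_off"))
    ))
    b <- feature_table(dplyr::bind_rows(
      as.data.frame(mk(rep(0, D), n_shared, "B", "b_sh")),
      as.data.frame(mk(rep(-8, D), n_off, "B", "b_off"))
    ))
    list(a = a, b = b)
  })
}

test_that("identical cohorts give a zero-MMD full core", {
  a <- make_ft(n = 6, d = 4, cohort = "A", prefix = "A")
  bdf <- as.data.frame(a)
  bdf$cohort <- "B"
  bdf$subject_id <- sub("^A", "B", bdf$subject_id)
  b <- feature_table(bdf)
  core <- select_healthy_core(a, b, target_size = 12,
                              spec = kernel_spec("linear", space = "raw"),
                              estimator = "biased")
  expect_equal(length(core$ids_a) + length(core$ids_b), 12)
  expect_equal(core$mmd2, 0, tolerance = 1e-10)
})

test_that("exhaustive search finds the shared cluster and dominates greedy", {
  toy <- two_cluster_toy()
  spec <- kernel_spec("rbf", space = "raw")
  ex <- exhaustive_core_search(toy$a, toy$b, target_size = 8, spec = spec)
  expect_setequal(c(ex$ids_a, ex$ids_b),
                  c(paste0("a_sh0", 1:4), paste0("b_sh0", 1:4)))

  gr <- select_healthy_core(toy$a, toy$b, target_size = 8, spec = spec)
  expect_gte(gr$mmd2, ex$mmd2 - 1e-12)
  expect_setequal(c(gr$ids_a, gr$ids_b), c(ex$ids_a, ex$ids_b))

  # target = total returns everyone
  all_core <- exhaustive_core_search(toy$a, toy$b, target_size = 12,
                                     spec = spec)
  expect_equal(length(all_core$ids_a) + length(all_core$ids_b), 12)

  expect_error(
    exhaustive_core_search(toy$a, toy$b, target_size = 8, spec = spec,
                           max_combinations = 10),
    class = "healthycore_size_guard_error"
  )
})

test_that("greedy objective is near-optimal on random tiny instances", {
  n_ok <- 0
  for (s in 1:10) {
    a <- make_ft(n = 6, d = 6, cohort = "A", prefix = "A", seed = 300 + s)
    b <- make_ft(n = 6, d = 6, cohort = "B", prefix = "B", seed = 600 + s)
    ex <- exhaustive_core_search(a, b, target_size = 8)
    gr <- select_healthy_core(a, b, target_size = 8)
    expect_gte(gr$mmd2, ex$mmd2 - 1e-12)
    # balance forces the 4 + 4 composition
    expect_equal(length(ex$ids_a), 4)
    expect_equal(length(gr$ids_a), 4)
    if (gr$mmd2 <= ex$mmd2 * 1.1 + 1e-12) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 8)
})

test_that("selection is reproducible and invariant to row order", {
  toy <- two_cluster_toy(seed = 5)
  spec <- kernel_spec("rbf", space = "raw")
  c1 <- select_healthy_core(toy$a, toy$b, target_size = 8, spec = spec,
                            seed = 3)
  c2 <- select_healthy_core(toy$a, toy$b, target_size = 8, spec = spec,
                            seed = 3)
  expect_identical(c1$ids_a, c2$ids_a)
  expect_identical(c1$trajectory, c2$trajectory)

  shuffled <- toy$a[withr::with_seed(9, sample(nrow(toy$a))), ]
  shuffled <- healthycore:::restore_feature_table(shuffled, toy$a)
  c3 <- select_healthy_core(shuffled, toy$b, target_size = 8, spec = spec,
                            seed = 3)
  expect_identical(c1$ids_a, c3$ids_a)
  expect_identical(c1$ids_b, c3$ids_b)
})

test_that("greedy trajectory decreases while unmatched mass remains", {
  toy <- two_cluster_toy(n_shared = 5, n_off = 3, seed = 7)
  core <- select_healthy_core(toy$a, toy$b, target_size = 10,
                              spec = kernel_spec("rbf", space = "raw"))
  expect_true(all(diff(core$trajectory$mmd2) <= 1e-12))
  # removed subjects are exactly the off-cluster members
  removed <- core$trajectory$id[-1]
  expect_true(all(grepl("off", removed)))
})

test_that("contract violations are rejected", {
  toy <- two_cluster_toy()
  patients <- as.data.frame(toy$a)
  patients$diagnosis[1] <- "CM"
  expect_error(
    select_healthy_core(feature_table(patients), toy$b, target_size = 8),
    class = "healthycore_contract_error"
  )
  expect_error(
    select_healthy_core(toy$a, toy$b, target_size = 2),
    class = "healthycore_parameter_error"
  )
})

test_that("auto stopping yields a core that passes the permutation test", {
  toy <- two_cluster_toy(n_shared = 6, n_off = 3, seed = 11)
  core <- select_healthy_core(toy$a, toy$b, target_size = "auto",
                              spec = kernel_spec("rbf", space = "raw"),
                              seed = 5, n_perm = 99)
  n_sel <- length(core$ids_a) + length(core$ids_b)
  expect_gte(n_sel, 4)
  expect_lte(n_sel, 18)
  # the selected groups should no longer differ detectably
  sel_a <- subset_rows(toy$a, ids = core$ids_a)
  sel_b <- subset_rows(toy$b, ids = core$ids_b)
  p <- mmd_permutation_test(feature_matrix(sel_a), feature_matrix(sel_b),
                            kernel_spec("rbf", space = "raw"),
                            n_perm = 199, seed = 21)$p_value
  expect_gt(p, 0.05)
})

test_that("quality report quantifies optimization gain and planted recovery", {
  sim <- generate_multisite_cohorts(synthetic_config(), seed = 31)
  a <- subset_rows(sim$table, cohort = "DS1", diagnosis = "HC")
  b <- subset_rows(sim$table, cohort = "DS2", diagnosis = "HC")
  planted <- sim$truth$core$subject_id[sim$truth$core$core_member]
  core <- select_healthy_core(a, b, target_size = length(planted), seed = 31)
  rep <- core_quality_report(core, a, b, truth = sim$truth, n_random = 100,
                             seed = 1)
  expect_lte(rep$percentile, 0.05)
  expect_gte(rep$recall, 0.7)
  expect_gte(rep$precision, 0.7)

  # a random same-shape "core" is unexceptional
  ids_a <- withr::with_seed(2, sample(a$subject_id, length(core$ids_a)))
  ids_b <- withr::with_seed(3, sample(b$subject_id, length(core$ids_b)))
  rand_core <- core
  rand_core$ids_a <- sort(ids_a)
  rand_core$ids_b <- sort(ids_b)
  rand_core$mmd2 <- healthycore:::subset_objective(
    core$space$K,
    which(core$space$ids %in% ids_a),
    which(core$space$ids %in% ids_b),
    "biased"
  )
  rep2 <- core_quality_report(rand_core, a, b, n_random = 100, seed = 4)
  expect_gte(rep2$percentile, 0.05)
})
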