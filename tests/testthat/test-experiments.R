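test_that("rank-based AUC matches enumeration and pROC", {
  expect_equal(auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), class = "healthycore_metric_error")

  withr::local_seed(1)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  expect_equal(auc(scores, labels),
               as.numeric(suppressMessages(
                 pROC::auc(labels, scores, direction = "<"))))
})

test_that("repeat aggregation reproduces a results-table average row", {
  rows <- tibble::tibble(
    model = c("regularized_logistic", "svm", "random_forest",
              "gradient_boosted_trees"),
    rep = 1L,
    train = c(0.9600, 0.8720, 0.9320, 0.9480),
    validation = rep(0.9, 4),
    test = c(0.7360, 0.6700, 0.7700, 0.8370),
    params = ""
  )
  res <- healthycore:::new_experiment_result(rows, "single", "CM", "auc",
                                             list(), 1)
  agg <- aggregate_repeats(res)
  # the reference table prints its average to four decimals (0.7533)
  expect_equal(agg$test_mean[agg$model == "Average"], 0.7533,
               tolerance = 1e-4)
  expect_equal(agg$test_sd[agg$model == "svm"], 0)

  # permutation invariance of the summary
  res2 <- healthycore:::new_experiment_result(rows[c(3, 1, 4, 2), ], "single",
                                              "CM", "auc", list(), 1)
  agg2 <- aggregate_repeats(res2)
  expect_equal(dplyr::arrange(agg, model), dplyr::arrange(agg2, model))
})

test_that("two-way split rule reproduces the study's 80/20 cells", {
  printed <- list(`54` = c(43, 11), `42` = c(33, 9), `15` = c(12, 3),
                  `26` = c(21, 5), `51` = c(41, 10), `8` = c(6, 2))
  for (n in names(printed)) {
    expect_equal(unname(healthycore:::split_counts_two_way(as.integer(n))),
                 printed[[n]])
  }
})

test_that("stratified splits are disjoint and exhaustive per class", {
  withr::local_seed(2)
  for (i in 1:20) {
    sizes <- sample(5:40, 2)
    ids <- list(HC = paste0("h", seq_len(sizes[1])),
                CM = paste0("c", seq_len(sizes[2])))
    counts <- healthycore:::default_counts(ids, three_way = TRUE)
    split <- healthycore:::draw_split(ids, counts)
    all_ids <- unlist(split)
    expect_equal(anyDuplicated(all_ids), 0)
    expect_equal(sum(lengths(split)), sum(lengths(ids)))
  }
})

test_that("single-dataset experiment honors the printed study design", {
  sim <- paper_sim()
  ds1 <- subset_rows(sim$table, cohort = "DS1")
  counts <- healthycore:::study_counts("single", "CM", "DS1")
  res <- run_single_dataset_experiment(ds1, "CM", repeats = 1, seed = 1,
                                       counts = counts,
                                       models = default_model_specs()["regularized_logistic"])
  used <- attr(res, "counts")
  expect_equal(unname(used$HC), c(34, 9, 11))
  expect_equal(unname(used$CM), c(9, 3, 3))
  expect_true(all(res$test >= 0 & res$test <= 1))

  # reproducibility of the full result
  res2 <- run_single_dataset_experiment(ds1, "CM", repeats = 1, seed = 1,
                                        counts = counts,
                                        models = default_model_specs()["regularized_logistic"])
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("cross-dataset experiment tests on every eligible target row", {
  sim <- paper_sim()
  ds1 <- subset_rows(sim$table, cohort = "DS1")
  ds2 <- subset_rows(sim$table, cohort = "DS2")
  counts <- healthycore:::study_counts("cross", "CM", "DS1")
  res <- run_cross_dataset_experiment(
    ds1, ds2, "CM", repeats = 1, seed = 2, counts = counts,
    models = default_model_specs()["gradient_boosted_trees"]
  )
  used <- attr(res, "counts")
  expect_equal(unname(used$HC), c(43, 11))
  expect_equal(unname(used$CM), c(12, 3))
  expect_s3_class(res, "experiment_result")
})

test_that("healthy-core experiment guards leakage and scores patients only", {
  sim <- paper_sim()
  ds1 <- subset_rows(sim$table, cohort = "DS1")
  ds2 <- subset_rows(sim$table, cohort = "DS2")
  hc_ids <- c(subset_rows(ds1, diagnosis = "HC")$subject_id[1:15],
              subset_rows(ds2, diagnosis = "HC")$subject_id[1:13])
  res <- run_healthy_core_experiment(
    hc_ids, ds1, ds2, "CM", repeats = 1, seed = 3,
    models = default_model_specs()["regularized_logistic"]
  )
  expect_setequal(unique(res$arm), c("with_core", "without_core"))
  expect_true(all(res$test >= 0 & res$test <= 1))
  expect_true(all(is.finite(res$target_auc)))

  # a zero threshold makes every target patient a positive call
  res0 <- run_healthy_core_experiment(
    hc_ids, ds1, ds2, "CM", repeats = 1, seed = 3, threshold = 0,
    models = default_model_specs()["regularized_logistic"],
    include_without_core = FALSE
  )
  expect_true(all(res0$test == 1))

  # core ids overlapping the target patients are a contamination error
  bad <- c(hc_ids[-1], subset_rows(ds2, diagnosis = "CM")$subject_id[1])
  expect_error(
    run_healthy_core_experiment(bad, ds1, ds2, "CM", repeats = 1),
    class = "healthycore_lookup_error"
  )
})

test_that("null data give chance-level AUC", {
  cfg <- synthetic_config(effect_cm = 0, effect_em = 0,
                          site_shift_scale = 0, site_shift_align = 0,
                          hetero_scale = 0,
                          cohort_sizes = list(DS1 = c(HC = 30, EM = 0, CM = 15),
                                              DS2 = c(HC = 20, EM = 0, CM = 10)))
  sim <- generate_multisite_cohorts(cfg, seed = 17)
  ds1 <- subset_rows(sim$table, cohort = "DS1")
  res <- run_single_dataset_experiment(
    ds1, "CM", repeats = 4, seed = 5,
    models = default_model_specs()["regularized_logistic"]
  )
  expect_lt(abs(mean(res$test) - 0.5), 0.2)
})

test_that("t-SNE embedding is deterministic and separates clear clusters", {
  withr::local_seed(6)
  x <- rbind(matrix(rnorm(150), 30, 5),
             matrix(rnorm(150, mean = 8), 30, 5))
  e1 <- tsne_embedding(x, seed = 4, perplexity = 8)
  e2 <- tsne_embedding(x, seed = 4, perplexity = 8)
  expect_equal(dim(e1), c(60, 2))
  expect_identical(e1, e2)

  labels <- rep(1:2, each = 30)
  sil <- cluster::silhouette(labels, dist(as.matrix(e1)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(tsne_embedding(x[1:10, ], perplexity = 8),
               class = "healthycore_parameter_error")

  # feature-table input carries metadata through
  ft <- make_ft(n = 40, d = 5, seed = 8)
  emb <- tsne_embedding(ft, seed = 1, perplexity = 5)
  expect_true(all(c("subject_id", "diagnosis", "tsne1", "tsne2") %in%
                    names(emb)))
})
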