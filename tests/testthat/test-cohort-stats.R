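test_that("BH step-up matches hand evaluation and controls structure", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_equal(out$adjusted, rep(0.05, 5))
  expect_true(all(out$rejected))

  expect_equal(bh_fdr(rep(1, 4))$adjusted, rep(1, 4))
  expect_equal(sum(bh_fdr(rep(1, 4))$rejected), 0)
  expect_equal(bh_fdr(0.031)$adjusted, 0.031)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "healthycore_domain_error")

  # property: adjusted values of sorted p are non-decreasing and rejections
  # form a prefix of the sorted list
  for (s in 1:5) {
    p <- sort(withr::with_seed(s, runif(30)^2))
    out <- bh_fdr(p, q = 0.1)
    expect_true(all(diff(out$adjusted) >= -1e-15))
    rej <- which(out$rejected)
    if (length(rej) > 0) expect_equal(rej, seq_len(max(rej)))
    expect_true(all(out$adjusted >= p))
  }
})

test_that("mean tests find planted shifts and behave at the identity", {
  a <- make_ft(n = 40, d = 10, seed = 3)
  ident <- univariate_mean_tests(a, a)
  tstats <- ident$statistic[ident$test == "t"]
  expect_true(all(abs(tstats) < 1e-12))
  expect_equal(sum(ident$rejected), 0)

  # shift 3 of 10 features by 2 pooled SDs
  b <- a
  shifted <- feature_names(a)[c(2, 5, 9)]
  bdf <- as.data.frame(b)
  for (f in shifted) bdf[[f]] <- bdf[[f]] + 2
  b <- feature_table(bdf)
  res <- univariate_mean_tests(a, b, q = 0.05)
  for (tn in c("t", "ks")) {
    sub <- res[res$test == tn, ]
    expect_true(all(shifted %in% sub$feature[sub$rejected]))
    expect_lte(sum(sub$rejected), sum(sub$p_value <= 0.05))
  }
})

test_that("null mean-test rejection rate is near nominal", {
  hits <- 0
  n_tests <- 0
  for (s in 1:40) {
    a <- make_ft(n = 15, d = 8, seed = 100 + s)
    b <- make_ft(n = 15, d = 8, seed = 500 + s, prefix = "B")
    res <- univariate_mean_tests(a, b)
    sub <- res[res$test == "t", ]
    hits <- hits + sum(sub$p_value <= 0.05)
    n_tests <- n_tests + nrow(sub)
  }
  # 99.9% binomial band around 5%
  expect_lte(hits, qbinom(0.9995, n_tests, 0.05))
  expect_gte(hits, qbinom(0.0005, n_tests, 0.05))
})

test_that("variance tests detect scale changes and pass the identity", {
  a <- make_ft(n = 40, d = 6, seed = 4)
  ident <- univariate_variance_tests(a, a)
  expect_true(all(abs(ident$statistic[ident$test == "f"] - 1) < 1e-12))
  expect_equal(sum(ident$rejected), 0)

  bdf <- as.data.frame(a)
  f1 <- feature_names(a)[1]
  bdf[[f1]] <- bdf[[f1]] * 3
  bdf$subject_id <- paste0("B", bdf$subject_id)
  b <- feature_table(bdf)
  res <- univariate_variance_tests(a, b, q = 0.05)
  for (tn in c("f", "ansari")) {
    sub <- res[res$test == tn, ]
    expect_true(sub$rejected[sub$feature == f1])
  }
})

test_that("Hotelling T2 reduces to t^2 and matches a direct formula", {
  a <- make_ft(n = 12, d = 1, seed = 7, modalities = "area")
  b <- make_ft(n = 9, d = 1, seed = 8, prefix = "B", modalities = "area")
  ht <- hotelling_t2(a, b)
  tt <- t.test(feature_matrix(a)[, 1], feature_matrix(b)[, 1],
               var.equal = TRUE)
  expect_equal(ht$statistic, unname(tt$statistic)^2, tolerance = 1e-10)

  # identical group means -> zero statistic, p = 1
  same <- hotelling_t2(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)

  # 2-feature case against the explicit pooled-covariance formula
  a2 <- make_ft(n = 10, d = 2, seed = 9)
  b2 <- make_ft(n = 8, d = 2, seed = 10, prefix = "B")
  xa <- feature_matrix(a2)
  xb <- feature_matrix(b2)
  n1 <- nrow(xa); n2 <- nrow(xb)
  dd <- colMeans(xa) - colMeans(xb)
  sp <- ((n1 - 1) * cov(xa) + (n2 - 1) * cov(xb)) / (n1 + n2 - 2)
  t2_direct <- (n1 * n2 / (n1 + n2)) *
    as.numeric(t(dd) %*% solve(sp) %*% dd)
  ht2 <- hotelling_t2(a2, b2)
  expect_equal(ht2$statistic, t2_direct, tolerance = 1e-10)
  expect_false(ht2$reduced)

  # high-dimensional case falls back to PCA scores
  a3 <- make_ft(n = 8, d = 20, seed = 11)
  b3 <- make_ft(n = 7, d = 20, seed = 12, prefix = "B")
  ht3 <- hotelling_t2(a3, b3)
  expect_true(ht3$reduced)
  expect_lte(ht3$p_dim, 12)
  expect_error(hotelling_t2(a3, b3, reduce = "none"),
               class = "healthycore_singular_error")
})

test_that("within-cohort standardization is exact, idempotent and reusable", {
  both <- feature_table(dplyr::bind_rows(
    as.data.frame(make_ft(n = 10, d = 4, cohort = "A", seed = 1)),
    as.data.frame(make_ft(n = 8, d = 4, cohort = "B", prefix = "B", seed = 2))
  ))
  out <- standardize_within_cohort(both)
  for (co in c("A", "B")) {
    m <- feature_matrix(subset_rows(out$table, cohort = co))
    expect_true(all(abs(colMeans(m)) < 1e-10))
    expect_true(all(abs(apply(m, 2, var) - 1) < 1e-10))
  }
  twice <- standardize_within_cohort(out$table)
  expect_equal(feature_matrix(twice$table), feature_matrix(out$table),
               tolerance = 1e-10)

  reapplied <- apply_adjustment(out$model, both)
  expect_equal(feature_matrix(reapplied), feature_matrix(out$table))

  const <- as.data.frame(both)
  const[[feature_names(both)[2]]][const$cohort == "B"] <- 5
  err <- tryCatch(standardize_within_cohort(feature_table(const)),
                  error = function(e) conditionMessage(e))
  expect_match(err, feature_names(both)[2])
  expect_match(err, "B")
})

test_that("mean-shift-only cohorts are compatible after adjustment", {
  a <- make_ft(n = 30, d = 8, cohort = "A", seed = 21)
  bdf <- as.data.frame(make_ft(n = 30, d = 8, cohort = "B", prefix = "B",
                               seed = 22))
  for (f in feature_names(a)[1:4]) bdf[[f]] <- bdf[[f]] + 1.5
  b <- feature_table(bdf)
  before <- univariate_mean_tests(a, b)
  expect_gt(sum(before$rejected), 0)
  adj <- standardize_within_cohort(feature_table(dplyr::bind_rows(
    as.data.frame(a), as.data.frame(b))))$table
  after <- univariate_mean_tests(subset_rows(adj, cohort = "A"),
                                 subset_rows(adj, cohort = "B"))
  expect_equal(sum(after$rejected), 0)
})

test_that("subset protocol computes exact values in degenerate cases", {
  # constant features: within-cohort differences 0, between = the constant gap
  n <- 8
  mk <- function(cohort, val, prefix) {
    df <- data.frame(
      subject_id = sprintf("%s%02d", prefix, 1:n), cohort = cohort,
      diagnosis = "HC", sex = "F", age = 30,
      lh_r1_area = val, lh_r2_thickness = val * 2
    )
    feature_table(df)
  }
  a <- mk("A", 1, "a")
  b <- mk("B", 4, "b")
  prot <- subset_mean_difference_protocol(a, b, k = 3, reps = 2, seed = 1)
  expect_equal(prot$value[prot$scenario == "within_a"], c(0, 0))
  area_ab <- prot$value[prot$scenario == "a_vs_b" & prot$modality == "area"]
  expect_equal(area_ab, 3)

  # determinism and symmetry of the between-cohort scenario
  a2 <- make_ft(n = 12, d = 4, cohort = "A", seed = 31)
  b2 <- make_ft(n = 12, d = 4, cohort = "B", prefix = "B", seed = 32)
  p1 <- subset_mean_difference_protocol(a2, b2, k = 4, reps = 5, seed = 9)
  p2 <- subset_mean_difference_protocol(a2, b2, k = 4, reps = 5, seed = 9)
  expect_identical(p1$value, p2$value)

  expect_error(subset_mean_difference_protocol(a2, b2, k = 10),
               class = "healthycore_parameter_error")
})

test_that("between-cohort differences exceed within-cohort under site shift", {
  sim <- generate_multisite_cohorts(
    synthetic_config(site_shift_scale = 0.4), seed = 11)
  a <- subset_rows(sim$table, cohort = "DS1", diagnosis = "HC")
  b <- subset_rows(sim$table, cohort = "DS2", diagnosis = "HC")
  prot <- subset_mean_difference_protocol(a, b, k = 21, reps = 40, seed = 2)
  for (mod in c("area", "thickness", "volume")) {
    w <- prot[prot$modality == mod, ]
    ab <- w$value[w$scenario == "a_vs_b"]
    expect_gt(ab, max(w$value[w$scenario != "a_vs_b"]))
  }
})

test_that("balanced resampling keeps genuine shifts and is reproducible", {
  a <- make_ft(n = 30, d = 3, cohort = "A", seed = 41)
  bdf <- as.data.frame(make_ft(n = 30, d = 3, cohort = "B", prefix = "B",
                               seed = 42))
  # heavy sex imbalance in B, plus a sex-independent mean shift
  bdf$sex <- rep(c("F", "M"), c(24, 6))
  for (f in feature_names(a)) bdf[[f]] <- bdf[[f]] + 2
  b <- feature_table(bdf)
  res <- balanced_resampling_test(a, b, reps = 15, seed = 3)
  expect_gt(res$rejection_rate[res$test == "t"], 0.8)

  r1 <- balanced_resampling_test(a, b, reps = 2, seed = 5)
  r2 <- balanced_resampling_test(a, b, reps = 2, seed = 5)
  expect_identical(r1$rejection_rate, r2$rejection_rate)

  # null: same distribution, rejection rates stay low after FDR (the rates
  # are conditional on the realized cohorts, so the bound is generous)
  a2 <- make_ft(n = 40, d = 3, cohort = "A", seed = 43)
  b2 <- make_ft(n = 40, d = 3, cohort = "B", prefix = "B", seed = 44)
  res0 <- balanced_resampling_test(a2, b2, reps = 15, seed = 4)
  expect_lt(max(res0$rejection_rate), 0.5)

  cdf <- as.data.frame(b2)
  cdf$sex <- "F"
  expect_error(balanced_resampling_test(a2, feature_table(cdf), reps = 2),
               class = "healthycore_balance_error")
})
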