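# Cohort-difference evaluation protocol: univariate mean/variance tests with
# FDR control, Hotelling's T2, within-cohort standardization, the random
# subset mean-difference protocol, and the balanced resampling test.

check_same_features <- function(a, b) {
  fa <- feature_names(a)
  fb <- feature_names(b)
  if (!identical(fa, fb)) {
    stop_hc("the two tables must share identical feature columns",
            "healthycore_schema_error")
  }
  fa
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) plus the rejection set at
#' level `q`.
#'
#' @param p P-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list with `adjusted` (monotone, capped at 1) and `rejected`
#'   (logical, `adjusted <= q`).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_hc("p-values must lie in [0, 1]", "healthycore_domain_error")
  }
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

run_univariate <- function(a, b, q, tests, fdr_scope) {
  feats <- check_same_features(a, b)
  if (nrow(a) < 3 || nrow(b) < 3) {
    stop_hc("each cohort needs at least 3 rows", "healthycore_parameter_error")
  }
  ma <- feature_matrix(a)
  mb <- feature_matrix(b)
  res <- purrr::map_dfr(feats, function(f) {
    x <- ma[, f]
    y <- mb[, f]
    purrr::map_dfr(names(tests), function(tn) {
      out <- tests[[tn]](x, y)
      tibble(feature = f, modality = feature_modality(f), test = tn,
             statistic = out$statistic, p_value = out$p_value,
             degenerate = out$degenerate)
    })
  })
  res <- if (fdr_scope == "modality") {
    group_by(res, .data$test, .data$modality)
  } else {
    group_by(res, .data$test)
  }
  res <- res %>%
    mutate(p_adjusted = bh_fdr(.data$p_value, q)$adjusted,
           rejected = .data$p_adjusted <= q) %>%
    ungroup()
  attr(res, "q") <- q
  res
}

#' Per-feature mean-difference tests (t and Kolmogorov-Smirnov)
#'
#' Runs a two-sample t-test (Welch by default) and a two-sample KS test on
#' every feature, with Benjamini-Hochberg adjustment applied separately per
#' test family across the features.
#'
#' @param a,b Feature tables with identical feature columns and >= 3 rows
#'   each.
#' @param q FDR level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param fdr_scope Adjust across all features (`"global"`, default) or
#'   within each modality (`"modality"`).
#' @return A tibble with one row per feature x test: `statistic`, `p_value`,
#'   `p_adjusted`, `rejected`, and a `degenerate` flag for zero-variance
#'   features where the t statistic is undefined.
#' @export
univariate_mean_tests <- function(a, b, q = 0.05, var_equal = FALSE,
                                  fdr_scope = c("global", "modality")) {
  fdr_scope <- match.arg(fdr_scope)
  tests <- list(
    t = function(x, y) {
      if (sd(x) == 0 && sd(y) == 0) {
        # no variability: statistic defined as 0 when means agree
        return(list(statistic = if (mean(x) == mean(y)) 0 else NA_real_,
                    p_value = 1, degenerate = TRUE))
      }
      tt <- t.test(x, y, var.equal = var_equal)
      list(statistic = unname(tt$statistic), p_value = tt$p.value,
           degenerate = FALSE)
    },
    ks = function(x, y) {
      kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
      list(statistic = unname(kt$statistic), p_value = kt$p.value,
           degenerate = FALSE)
    }
  )
  run_univariate(a, b, q, tests, fdr_scope)
}

#' Per-feature variance-difference tests (F and Ansari-Bradley)
#'
#' @inheritParams univariate_mean_tests
#' @return A tibble shaped like [univariate_mean_tests()], with tests `f`
#'   and `ansari`.
#' @export
univariate_variance_tests <- function(a, b, q = 0.05,
                                      fdr_scope = c("global", "modality")) {
  fdr_scope <- match.arg(fdr_scope)
  tests <- list(
    f = function(x, y) {
      if (sd(x) == 0 || sd(y) == 0) {
        return(list(statistic = NA_real_, p_value = 1, degenerate = TRUE))
      }
      ft <- var.test(x, y)
      list(statistic = unname(ft$statistic), p_value = ft$p.value,
           degenerate = FALSE)
    },
    ansari = function(x, y) {
      at <- suppressWarnings(ansari.test(x, y, exact = FALSE))
      list(statistic = unname(at$statistic), p_value = at$p.value,
           degenerate = FALSE)
    }
  )
  run_univariate(a, b, q, tests, fdr_scope)
}

#' Two-sample Hotelling's T2 test
#'
#' The multivariate extension of the two-group t-test, using the pooled
#' covariance. When the feature count approaches the combined sample size the
#' pooled covariance is singular; with `reduce = "auto"` the test is then run
#' on PCA scores of the pooled centered data retaining `var_explained` of the
#' variance (capped so the covariance stays invertible), and the reduction is
#' recorded in the result.
#'
#' @param a,b Feature tables with identical feature columns.
#' @param features Optional subset of feature names to test.
#' @param reduce `"auto"` (PCA fallback in high dimension) or `"none"`
#'   (error when the covariance is singular).
#' @param var_explained Variance fraction retained by the PCA fallback.
#' @param covariates Optional metadata column names (e.g. `c("age", "sex")`)
#'   regressed out of every feature before testing (covariance-adjusted
#'   variant).
#' @return A list of class `hotelling_test`: `statistic` (T2),
#'   `f_statistic`, `df1`, `df2`, `p_value`, `p_dim` (dimension actually
#'   tested) and `reduced`.
#' @export
hotelling_t2 <- function(a, b, features = NULL, reduce = c("auto", "none"),
                         var_explained = 0.95, covariates = NULL) {
  reduce <- match.arg(reduce)
  feats <- check_same_features(a, b)
  features <- features %||% feats
  xa <- feature_matrix(a)[, features, drop = FALSE]
  xb <- feature_matrix(b)[, features, drop = FALSE]
  if (!is.null(covariates)) {
    xa <- residualize(xa, a, covariates)
    xb <- residualize(xb, b, covariates)
  }
  n1 <- nrow(xa)
  n2 <- nrow(xb)
  p <- ncol(xa)
  reduced <- FALSE
  if (p > n1 + n2 - 2 || qr(rbind(scale(xa, scale = FALSE),
                                  scale(xb, scale = FALSE)))$rank < p) {
    if (reduce == "none") {
      stop_hc(paste0("pooled covariance is singular (p = ", p, ", n = ",
                     n1 + n2, "); reduce the dimension or use reduce = 'auto'"),
              "healthycore_singular_error")
    }
    pooled <- rbind(xa, xb)
    pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    keep <- min(which(cum >= var_explained)[1], n1 + n2 - 3)
    keep <- max(keep, 1)
    scores <- pc$x[, seq_len(keep), drop = FALSE]
    xa <- scores[seq_len(n1), , drop = FALSE]
    xb <- scores[n1 + seq_len(n2), , drop = FALSE]
    p <- keep
    reduced <- TRUE
  }
  d <- colMeans(xa) - colMeans(xb)
  s_pooled <- ((n1 - 1) * stats::cov(xa) + (n2 - 1) * stats::cov(xb)) / (n1 + n2 - 2)
  t2 <- as.numeric((n1 * n2 / (n1 + n2)) * crossprod(d, solve(s_pooled, d)))
  f_stat <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  p_value <- stats::pf(f_stat, p, n1 + n2 - p - 1, lower.tail = FALSE)
  structure(
    list(statistic = t2, f_statistic = f_stat, df1 = p,
         df2 = n1 + n2 - p - 1, p_value = p_value, p_dim = p,
         reduced = reduced, n1 = n1, n2 = n2),
    class = "hotelling_test"
  )
}

residualize <- function(x, tab, covariates) {
  df <- as.data.frame(tab[, covariates, drop = FALSE])
  keep <- complete.cases(df)
  mm <- stats::model.matrix(~ ., df[keep, , drop = FALSE])
  res <- stats::lm.fit(mm, x[keep, , drop = FALSE])$residuals
  res
}

#' Standardize features within each cohort
#'
#' Centers and scales every feature to zero mean and unit variance per
#' cohort, removing cohort-level mean and variance differences (the
#' adjustment applied before asking whether two cohorts remain different).
#'
#' @param x A feature table with >= 2 rows per cohort.
#' @return A list with `table` (the adjusted feature table) and `model`, a
#'   tibble of class `adjustment_model` (cohort, feature, mean, sd) that can
#'   be reapplied with [apply_adjustment()].
#' @export
standardize_within_cohort <- function(x) {
  feats <- feature_names(x)
  model <- x %>%
    as_tibble() %>%
    tidyr::pivot_longer(all_of(feats), names_to = "feature",
                        values_to = "value") %>%
    group_by(.data$cohort, .data$feature) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  bad <- model[model$sd <= 0 | !is.finite(model$sd), ]
  if (nrow(bad) > 0) {
    stop_hc(sprintf("zero-variance feature '%s' in cohort '%s'",
                    bad$feature[1], bad$cohort[1]),
            "healthycore_degenerate_error")
  }
  model <- structure(model, class = c("adjustment_model", class(model)))
  list(table = apply_adjustment(model, x), model = model)
}

#' Apply a stored within-cohort adjustment
#'
#' @param model An `adjustment_model` from [standardize_within_cohort()].
#' @param x A feature table whose cohorts appear in the model.
#' @return The standardized feature table.
#' @export
apply_adjustment <- function(model, x) {
  feats <- feature_names(x)
  out <- as_tibble(as.data.frame(x))
  for (co in unique(out$cohort)) {
    m <- model[model$cohort == co, ]
    if (nrow(m) == 0) {
      stop_hc(paste0("cohort '", co, "' not present in adjustment model"),
              "healthycore_lookup_error")
    }
    idx <- out$cohort == co
    mu <- setNames(m$mean, m$feature)[feats]
    sdv <- setNames(m$sd, m$feature)[feats]
    out[idx, feats] <- sweep(sweep(as.matrix(out[idx, feats]), 2, mu, "-"),
                             2, sdv, "/")
  }
  restore_feature_table(out, x)
}

#' Random-subset mean-difference protocol
#'
#' For each scenario -- two disjoint subsets within cohort A, within cohort
#' B, from the pooled A+B sample ("random splits"), and one subset from each
#' cohort ("a_vs_b") -- draws two disjoint subsets of size `k`, computes the
#' per-feature absolute difference of subset means, averages within each
#' modality, and repeats. The between-cohort scenario exceeding the three
#' within/random scenarios is the signature of a site effect.
#'
#' @param a,b Feature tables with identical features.
#' @param k Subset size (21 in the reference protocol).
#' @param reps Number of repeats averaged.
#' @param seed Integer seed (draws are deterministic given the seed).
#' @return A tibble of class `subset_protocol`: scenario x modality rows with
#'   the averaged absolute mean difference, plus `k`/`reps` attributes.
#' @export
subset_mean_difference_protocol <- function(a, b, k = 21, reps = 100, seed = 1) {
  feats <- check_same_features(a, b)
  mod <- feature_modality(feats)
  ma <- feature_matrix(a)
  mb <- feature_matrix(b)
  pools <- list(
    within_a = list(ma, NULL),
    within_b = list(mb, NULL),
    random_splits = list(rbind(ma, mb), NULL),
    a_vs_b = list(ma, mb)
  )
  if (nrow(ma) < 2 * k || nrow(mb) < 2 * k) {
    stop_hc(sprintf("each within-cohort pool needs >= 2k = %d rows", 2 * k),
            "healthycore_parameter_error")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  acc <- matrix(0, length(pools), length(unique(stats::na.omit(mod))))
  mods <- sort(unique(stats::na.omit(mod)))
  colnames(acc) <- mods
  rownames(acc) <- names(pools)
  for (r in seq_len(reps)) {
    for (sc in names(pools)) {
      p1 <- pools[[sc]][[1]]
      p2 <- pools[[sc]][[2]]
      if (is.null(p2)) {
        idx <- sample.int(nrow(p1), 2 * k)
        g1 <- p1[idx[seq_len(k)], , drop = FALSE]
        g2 <- p1[idx[k + seq_len(k)], , drop = FALSE]
      } else {
        g1 <- p1[sample.int(nrow(p1), k), , drop = FALSE]
        g2 <- p2[sample.int(nrow(p2), k), , drop = FALSE]
      }
      diffs <- abs(colMeans(g1) - colMeans(g2))
      for (m in mods) acc[sc, m] <- acc[sc, m] + mean(diffs[which(mod == m)])
    }
  }
  acc <- acc / reps
  out <- tidyr::pivot_longer(
    bind_cols(tibble(scenario = rownames(acc)), as_tibble(acc)),
    all_of(mods), names_to = "modality", values_to = "value"
  )
  attr(out, "k") <- k
  attr(out, "reps") <- reps
  structure(out, class = c("subset_protocol", class(out)))
}

#' Balanced resampling test of cohort differences
#'
#' Repeatedly draws subsamples from both cohorts with matched composition of
#' a balancing variable (sex by default), runs the mean (t, KS) and variance
#' (F, Ansari-Bradley) tests per feature with BH adjustment within each
#' repeat, and reports the fraction of repeats in which each family rejects.
#' A cohort difference that survives balancing is not explained by the
#' balanced variable.
#'
#' @param a,b Feature tables; both must contain every category of
#'   `balance_var`.
#' @param balance_var Metadata column to balance on.
#' @param reps Number of resampling repeats (the reference protocol uses
#'   10,000; scale down for exploration).
#' @param q FDR level within each repeat.
#' @param seed Integer seed.
#' @param features Optional subset of features to test (all by default).
#' @return A tibble: test family x mean per-feature rejection rate across
#'   repeats (`rejection_rate`), with the per-feature rates in the
#'   `per_feature` attribute.
#' @export
balanced_resampling_test <- function(a, b, balance_var = "sex", reps = 100,
                                     q = 0.05, seed = 1, features = NULL) {
  feats <- features %||% check_same_features(a, b)
  cats <- sort(unique(c(a[[balance_var]], b[[balance_var]])))
  counts <- vapply(cats, function(cc) {
    min(sum(a[[balance_var]] == cc), sum(b[[balance_var]] == cc))
  }, numeric(1))
  if (any(counts == 0)) {
    stop_hc(sprintf("category '%s' of %s absent from one cohort",
                    cats[which(counts == 0)[1]], balance_var),
            "healthycore_balance_error")
  }
  ma <- feature_matrix(a)[, feats, drop = FALSE]
  mb <- feature_matrix(b)[, feats, drop = FALSE]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fams <- c("t", "ks", "f", "ansari")
  rej <- matrix(0, length(feats), length(fams), dimnames = list(feats, fams))
  for (r in seq_len(reps)) {
    ia <- unlist(lapply(cats, function(cc) {
      idx <- which(a[[balance_var]] == cc)
      idx[sample.int(length(idx), counts[[cc]])]
    }))
    ib <- unlist(lapply(cats, function(cc) {
      idx <- which(b[[balance_var]] == cc)
      idx[sample.int(length(idx), counts[[cc]])]
    }))
    xa <- ma[ia, , drop = FALSE]
    xb <- mb[ib, , drop = FALSE]
    p <- sapply(seq_along(feats), function(j) {
      x <- xa[, j]
      y <- xb[, j]
      c(t = t.test(x, y)$p.value,
        ks = suppressWarnings(ks.test(x, y, exact = FALSE)$p.value),
        f = var.test(x, y)$p.value,
        ansari = suppressWarnings(ansari.test(x, y, exact = FALSE)$p.value))
    })
    for (fam in fams) {
      rej[, fam] <- rej[, fam] + bh_fdr(p[fam, ], q)$rejected
    }
  }
  rates <- rej / reps
  out <- tibble(test = fams,
                rejection_rate = colMeans(rates),
                n_reps = reps, n_per_group = sum(counts))
  attr(out, "per_feature") <- as_tibble(rates) %>% mutate(feature = feats)
  out
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Two-sample Hotelling's T2\n  T2 = %.4f, F(%d, %d) = %.4f, p = %.4g%s\n",
    x$statistic, x$df1, x$df2, x$f_statistic, x$p_value,
    if (x$reduced) sprintf("  [PCA-reduced to %d dims]", x$p_dim) else ""
  ))
  invisible(x)
}

#' @export
tidy.hotelling_test <- function(x, ...) {
  tibble(statistic = x$statistic, f_statistic = x$f_statistic,
         df1 = x$df1, df2 = x$df2, p.value = x$p_value,
         reduced = x$reduced)
}

#' @export
glance.hotelling_test <- function(x, ...) tidy(x)
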