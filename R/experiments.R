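# The three validation experiment designs: within a single dataset,
# across datasets, and across datasets with a healthy core as the shared
# reference class.

# Split-size rules. Two-way (train/validation): validation gets
# floor(0.2 n + 0.6) -- nearest integer with halves-and-above-0.4 rounding
# up -- which reproduces the reference study's printed 80/20 cells for every
# class size. Three-way additionally carves a test fold first
# (floor(0.2 n + 0.5)), then the validation share from the remainder.
split_counts_two_way <- function(n) {
  val <- max(1L, as.integer(floor(0.2 * n + 0.6)))
  if (n - val < 1) val <- n - 1L
  c(train = n - val, val = val)
}

split_counts_three_way <- function(n) {
  test <- max(1L, as.integer(floor(0.2 * n + 0.5)))
  rem <- n - test
  val <- max(1L, as.integer(floor(0.2 * rem + 0.6)))
  train <- rem - val
  if (train < 1) {
    stop_hc(sprintf("class of size %d cannot be split three ways", n),
            "healthycore_parameter_error")
  }
  c(train = train, val = val, test = test)
}

#' Printed split designs of the reference study
#'
#' The per-class train/validation/test cell counts of the reference study's
#' single-dataset, cross-dataset, and healthy-core experiment tables. These
#' printed designs are one random realization of approximate 60/20/20 (or
#' 80/20) splits and are not all reproducible from a rounding rule, so they
#' ship as data; pass the relevant subset as the `counts` argument of an
#' experiment function to reproduce the printed cells exactly.
#'
#' @return A tibble: `design` (`single`/`cross`), `positive`, `dataset`
#'   (source cohort), `class`, `train`, `validation`, `test` (NA where the
#'   design has no within-source test fold).
#' @export
study_design <- function() {
  tibble::tribble(
    ~design, ~positive, ~dataset, ~class, ~train, ~validation, ~test,
    "single", "CM", "DS1", "HC", 34L, 9L, 11L,
    "single", "CM", "DS1", "CM", 9L, 3L, 3L,
    "single", "CM", "DS2", "HC", 27L, 7L, 8L,
    "single", "CM", "DS2", "CM", 17L, 4L, 5L,
    "single", "EM", "DS1", "HC", 34L, 9L, 11L,
    "single", "EM", "DS1", "EM", 31L, 10L, 10L,
    "single", "EM", "DS2", "HC", 27L, 7L, 8L,
    "single", "EM", "DS2", "EM", 4L, 2L, 2L,
    "cross", "CM", "DS1", "HC", 43L, 11L, NA_integer_,
    "cross", "CM", "DS1", "CM", 12L, 3L, NA_integer_,
    "cross", "CM", "DS2", "HC", 33L, 9L, NA_integer_,
    "cross", "CM", "DS2", "CM", 21L, 5L, NA_integer_,
    "cross", "EM", "DS1", "HC", 43L, 11L, NA_integer_,
    "cross", "EM", "DS1", "EM", 41L, 10L, NA_integer_,
    "cross", "EM", "DS2", "HC", 33L, 9L, NA_integer_,
    "cross", "EM", "DS2", "EM", 6L, 2L, NA_integer_
  )
}

study_counts <- function(design, positive, dataset) {
  rows <- dplyr::filter(study_design(), .data$design == !!design,
                        .data$positive == !!positive,
                        .data$dataset == !!dataset)
  if (nrow(rows) == 0) return(NULL)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    v <- c(train = rows$train[i], val = rows$validation[i],
           test = rows$test[i])
    v[!is.na(v)]
  })
  setNames(out, rows$class)
}

# Draw a stratified split. counts: named list class -> named count vector
# (train/val[/test]). Returns list of id vectors per part.
draw_split <- function(ids_by_class, counts) {
  parts <- unique(unlist(lapply(counts, names)))
  out <- setNames(vector("list", length(parts)), parts)
  for (cl in names(ids_by_class)) {
    ids <- sample(ids_by_class[[cl]])
    cnt <- counts[[cl]]
    if (sum(cnt) > length(ids)) {
      stop_hc(sprintf("split counts for class '%s' exceed its %d rows",
                      cl, length(ids)), "healthycore_parameter_error")
    }
    at <- 0
    for (p in names(cnt)) {
      out[[p]] <- c(out[[p]], ids[at + seq_len(cnt[[p]])])
      at <- at + cnt[[p]]
    }
  }
  stopifnot(!anyDuplicated(unlist(out)))
  out
}

default_counts <- function(ids_by_class, three_way) {
  lapply(ids_by_class, function(ids) {
    if (three_way) split_counts_three_way(length(ids))
    else split_counts_two_way(length(ids))
  })
}

standardize_train <- function(x_train, others) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, sd)
  sdv[sdv <= 0] <- 1
  tf <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  c(list(train = tf(x_train)), lapply(others, tf))
}

pick_one_cohort <- function(tab, cohort, what) {
  if (!is.null(cohort)) tab <- subset_rows(tab, cohort = cohort)
  if (length(unique(tab$cohort)) > 1) {
    stop_hc(paste0(what, " spans multiple cohorts; pass `cohort` to pick one"),
            "healthycore_parameter_error")
  }
  tab
}

new_experiment_result <- function(rows, design, positive, metric, counts,
                                  seed) {
  structure(rows, design = design, positive = positive, metric = metric,
            counts = counts, seed = seed,
            class = c("experiment_result", class(rows)))
}

repeat_seed <- function(seed, r) as.integer((seed * 1009 + r * 7919) %% .Machine$integer.max)

# Tune one family on the validation fold, return metrics for all folds.
tune_and_score <- function(ms, folds_x, y_train, y_val, y_test, metric_fun,
                           seed) {
  best <- NULL
  for (gi in seq_len(nrow(ms$grid))) {
    params <- ms$grid[gi, , drop = FALSE]
    preds <- fit_predict_model(ms$family, params, folds_x$train, y_train,
                               folds_x[c("val", "test")], seed = seed)
    val_metric <- metric_fun(preds$val, y_val)
    if (is.null(best) || val_metric > best$val + 1e-12) {
      train_pred <- fit_predict_model(ms$family, params, folds_x$train,
                                      y_train, list(tr = folds_x$train),
                                      seed = seed)$tr
      best <- list(val = val_metric,
                   train = metric_fun(train_pred, y_train),
                   test = metric_fun(preds$test, y_test),
                   params = params)
    }
  }
  best
}

#' Single-dataset classification experiment
#'
#' Within one cohort, repeatedly splits HC vs. the positive class into
#' stratified training (~60%), validation (~20%) and test (~20%) folds,
#' tunes each model family on validation AUC, and reports train/validation/
#' test AUC per repeat.
#'
#' @param data A feature table containing HC and the positive class.
#' @param positive Positive class, `"CM"` or `"EM"`.
#' @param models Named list of [model_spec()]s.
#' @param repeats Number of random repeats averaged.
#' @param seed Integer seed.
#' @param counts Optional explicit per-class split counts (named list:
#'   class -> c(train, val, test)), e.g. built from [study_design()];
#'   `NULL` uses the rounding rule.
#' @param cohort Cohort to use when `data` holds several.
#' @return A tibble of class `experiment_result`: one row per model x
#'   repeat with `train`, `validation`, `test` metrics; summarize with
#'   [aggregate_repeats()] or `glance()`.
#' @export
run_single_dataset_experiment <- function(data, positive = c("CM", "EM"),
                                          models = default_model_specs(),
                                          repeats = 5, seed = 1,
                                          counts = NULL, cohort = NULL) {
  positive <- match.arg(positive)
  data <- pick_one_cohort(data, cohort, "data")
  neg <- subset_rows(data, diagnosis = "HC")
  pos <- subset_rows(data, diagnosis = positive)
  if (nrow(neg) < 3 || nrow(pos) < 3) {
    stop_hc("need >= 3 HC and >= 3 positive-class rows",
            "healthycore_parameter_error")
  }
  ids_by_class <- list(HC = neg$subject_id, POS = pos$subject_id)
  names(ids_by_class)[2] <- positive
  counts <- counts %||% default_counts(ids_by_class, three_way = TRUE)
  x_all <- feature_matrix(data)
  y_of <- setNames(as.integer(data$diagnosis == positive), data$subject_id)
  rows <- list()
  for (r in seq_len(repeats)) {
    rs <- repeat_seed(seed, r)
    set.seed(rs)
    split <- draw_split(ids_by_class, counts)
    stopifnot(length(intersect(split$train, split$test)) == 0,
              length(intersect(split$train, split$val)) == 0,
              length(intersect(split$val, split$test)) == 0)
    folds_x <- standardize_train(
      x_all[split$train, , drop = FALSE],
      list(val = x_all[split$val, , drop = FALSE],
           test = x_all[split$test, , drop = FALSE])
    )
    for (ms in models) {
      res <- tune_and_score(ms, folds_x, y_of[split$train], y_of[split$val],
                            y_of[split$test], auc, seed = rs)
      rows[[length(rows) + 1]] <- tibble(
        model = ms$family, rep = r, train = res$train,
        validation = res$val, test = res$test,
        params = paste(names(res$params), unlist(res$params),
                       sep = "=", collapse = ",")
      )
    }
  }
  new_experiment_result(bind_rows(rows), "single", positive, "auc", counts,
                        seed)
}

#' Cross-dataset classification experiment
#'
#' Trains on one cohort (stratified ~80/20 train/validation), tunes on
#' validation AUC, and tests on every eligible row (HC + positive class) of
#' the second cohort.
#'
#' @param source,target Feature tables for the training and test cohorts.
#' @inheritParams run_single_dataset_experiment
#' @param source_cohort,target_cohort Cohort pickers when a table holds
#'   several.
#' @return An `experiment_result` tibble (metric = AUC).
#' @export
run_cross_dataset_experiment <- function(source, target,
                                         positive = c("CM", "EM"),
                                         models = default_model_specs(),
                                         repeats = 5, seed = 1, counts = NULL,
                                         source_cohort = NULL,
                                         target_cohort = NULL) {
  positive <- match.arg(positive)
  source <- pick_one_cohort(source, source_cohort, "source")
  target <- pick_one_cohort(target, target_cohort, "target")
  check_same_features(source, target)
  neg <- subset_rows(source, diagnosis = "HC")
  pos <- subset_rows(source, diagnosis = positive)
  ids_by_class <- setNames(list(neg$subject_id, pos$subject_id),
                           c("HC", positive))
  counts <- counts %||% default_counts(ids_by_class, three_way = FALSE)
  x_src <- feature_matrix(source)
  y_src <- setNames(as.integer(source$diagnosis == positive),
                    source$subject_id)
  tgt <- subset_rows(target, diagnosis = c("HC", positive))
  x_tgt <- feature_matrix(tgt)
  y_tgt <- as.integer(tgt$diagnosis == positive)
  if (length(intersect(source$subject_id, tgt$subject_id)) > 0) {
    stop_hc("source and target share subject ids", "healthycore_contract_error")
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    rs <- repeat_seed(seed, r)
    set.seed(rs)
    split <- draw_split(ids_by_class, counts)
    stopifnot(length(intersect(split$train, split$val)) == 0)
    folds_x <- standardize_train(
      x_src[split$train, , drop = FALSE],
      list(val = x_src[split$val, , drop = FALSE], test = x_tgt)
    )
    for (ms in models) {
      res <- tune_and_score(ms, folds_x, y_src[split$train], y_src[split$val],
                            y_tgt, auc, seed = rs)
      rows[[length(rows) + 1]] <- tibble(
        model = ms$family, rep = r, train = res$train,
        validation = res$val, test = res$test,
        params = paste(names(res$params), unlist(res$params),
                       sep = "=", collapse = ",")
      )
    }
  }
  new_experiment_result(bind_rows(rows), "cross", positive, "auc", counts,
                        seed)
}

#' Cross-dataset experiment with (and without) a healthy core
#'
#' Trains classifiers that separate a shared healthy-core reference class
#' from one cohort's migraine patients and tests on the other cohort's
#' patients only; the test metric is the fraction of target patients
#' classified as migraine (probability above `threshold`). Model selection
#' uses validation accuracy. A matched `without_core` arm replaces the core
#' with all source-cohort HCs for paired comparison. As in the reference
#' design, the full core serves in both the training and validation folds
#' (`core_val = "shared"`); `core_val = "split"` divides it 80/20 instead.
#'
#' @param core A `healthy_core` object or character vector of HC subject
#'   ids.
#' @param source,target Feature tables for the training cohort (patients
#'   used in training) and the test cohort; HC rows for the core may come
#'   from both.
#' @inheritParams run_cross_dataset_experiment
#' @param threshold Probability threshold for calling migraine.
#' @param core_val `"shared"` (printed design) or `"split"`.
#' @param include_without_core Also run the matched all-HC arm.
#' @return An `experiment_result` tibble with an `arm` column
#'   (`with_core` / `without_core`); metric = migraine-classification
#'   accuracy.
#' @export
run_healthy_core_experiment <- function(core, source, target,
                                        positive = c("CM", "EM"),
                                        models = default_model_specs(),
                                        repeats = 5, seed = 1, counts = NULL,
                                        source_cohort = NULL,
                                        target_cohort = NULL,
                                        threshold = 0.5,
                                        core_val = c("shared", "split"),
                                        include_without_core = TRUE) {
  positive <- match.arg(positive)
  core_val <- match.arg(core_val)
  source <- pick_one_cohort(source, source_cohort, "source")
  target <- pick_one_cohort(target, target_cohort, "target")
  check_same_features(source, target)
  core_ids <- if (inherits(core, "healthy_core")) c(core$ids_a, core$ids_b)
              else as.character(core)
  hc_pool <- bind_rows(
    as_tibble(as.data.frame(subset_rows(source, diagnosis = "HC"))),
    as_tibble(as.data.frame(subset_rows(target, diagnosis = "HC")))
  )
  missing <- setdiff(core_ids, hc_pool$subject_id)
  if (length(missing) > 0) {
    stop_hc(paste0("core ids not found among HCs: ",
                   paste(head(missing, 5), collapse = ", ")),
            "healthycore_lookup_error")
  }
  pos_src <- subset_rows(source, diagnosis = positive)
  pos_tgt <- subset_rows(target, diagnosis = positive)
  if (length(intersect(core_ids, pos_tgt$subject_id)) > 0) {
    stop_hc("core overlaps the test set", "healthycore_contamination_error")
  }
  feats <- feature_names(source)
  x_hc <- as.matrix(hc_pool[, feats])
  rownames(x_hc) <- hc_pool$subject_id
  x_pos_src <- feature_matrix(pos_src)
  x_test <- feature_matrix(pos_tgt)
  pos_counts <- (counts %||% list())[[positive]] %||%
    split_counts_two_way(nrow(pos_src))
  accuracy <- function(pred, y) mean((pred > threshold) == (y == 1))
  # Auxiliary discrimination check: target-cohort HCs outside the core
  # (never trained on) vs target patients.
  aux_hc <- subset_rows(target, diagnosis = "HC")
  aux_hc <- aux_hc[!aux_hc$subject_id %in% core_ids, ]
  x_aux <- if (nrow(aux_hc) > 1) {
    rbind(feature_matrix(aux_hc), x_test)
  } else NULL
  y_aux <- c(rep(0L, nrow(aux_hc)), rep(1L, nrow(x_test)))
  arms <- list(with_core = core_ids)
  if (include_without_core) {
    arms$without_core <- subset_rows(source, diagnosis = "HC")$subject_id
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    rs <- repeat_seed(seed, r)
    set.seed(rs)
    pos_split <- draw_split(list(P = pos_src$subject_id),
                            list(P = pos_counts))
    for (arm in names(arms)) {
      hc_ids <- arms[[arm]]
      if (core_val == "split" ) {
        hc_cnt <- split_counts_two_way(length(hc_ids))
        hc_split <- draw_split(list(H = hc_ids), list(H = hc_cnt))
        hc_train <- hc_split$train
        hc_val <- hc_split$val
      } else {
        hc_train <- hc_ids
        hc_val <- hc_ids
      }
      stopifnot(length(intersect(hc_ids, pos_tgt$subject_id)) == 0,
                length(intersect(pos_split$train, pos_split$val)) == 0)
      x_train <- rbind(x_hc[hc_train, , drop = FALSE],
                       x_pos_src[pos_split$train, , drop = FALSE])
      y_train <- c(rep(0L, length(hc_train)), rep(1L, length(pos_split$train)))
      x_val <- rbind(x_hc[hc_val, , drop = FALSE],
                     x_pos_src[pos_split$val, , drop = FALSE])
      y_val <- c(rep(0L, length(hc_val)), rep(1L, length(pos_split$val)))
      extra <- if (is.null(x_aux)) list() else list(aux = x_aux)
      folds_x <- standardize_train(x_train, c(list(val = x_val,
                                                   test = x_test), extra))
      y_test <- rep(1L, nrow(x_test))
      for (ms in models) {
        res <- tune_and_score(ms, folds_x, y_train, y_val, y_test, accuracy,
                              seed = rs)
        aux_auc <- NA_real_
        if (!is.null(x_aux)) {
          pred_aux <- fit_predict_model(ms$family, res$params, folds_x$train,
                                        y_train, folds_x["aux"],
                                        seed = rs)$aux
          aux_auc <- auc(pred_aux, y_aux)
        }
        rows[[length(rows) + 1]] <- tibble(
          model = ms$family, arm = arm, rep = r, train = res$train,
          validation = res$val, test = res$test, target_auc = aux_auc,
          params = paste(names(res$params), unlist(res$params),
                         sep = "=", collapse = ",")
        )
      }
    }
  }
  new_experiment_result(bind_rows(rows), "healthy_core", positive,
                        "accuracy", list(pos = pos_counts), seed)
}

#' Aggregate an experiment over its repeats
#'
#' Per-model means and SDs across repeats, plus an `Average` row taking the
#' arithmetic mean over the model families (per arm where applicable), as in
#' a results table's average row.
#'
#' @param result An `experiment_result`.
#' @return A tibble: model (or `Average`) x mean/sd of each metric column.
#' @export
aggregate_repeats <- function(result) {
  if (nrow(result) == 0) stop_hc("empty result", "healthycore_parameter_error")
  grp <- intersect(c("model", "arm"), names(result))
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  agg <- result %>%
    group_by(across(all_of(grp))) %>%
    summarise(across(c("train", "validation", "test"),
                     list(mean = mean, sd = sd0)), .groups = "drop")
  avg_grp <- setdiff(grp, "model")
  avg <- agg %>%
    group_by(across(all_of(avg_grp))) %>%
    summarise(across(dplyr::ends_with("_mean"), mean), .groups = "drop") %>%
    mutate(model = "Average")
  bind_rows(agg, avg)
}

#' @export
tidy.experiment_result <- function(x, ...) as_tibble(as.data.frame(x))

#' @export
glance.experiment_result <- function(x, ...) {
  agg <- aggregate_repeats(x)
  avg <- agg[agg$model == "Average", , drop = FALSE]
  out <- tibble(design = attr(x, "design"), positive = attr(x, "positive"),
                metric = attr(x, "metric"))
  if ("arm" %in% names(avg)) {
    for (i in seq_len(nrow(avg))) {
      out[[paste0("test_", avg$arm[i])]] <- avg$test_mean[i]
    }
  } else {
    out$train <- avg$train_mean
    out$test <- avg$test_mean
  }
  out
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  aes <- if ("arm" %in% names(df)) {
    ggplot2::aes(x = .data$model, y = .data$test, colour = .data$arm)
  } else {
    ggplot2::aes(x = .data$model, y = .data$test)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.75), size = 1) +
    ggplot2::labs(y = paste("test", attr(object, "metric")),
                  x = NULL,
                  title = sprintf("%s experiment, HC vs %s",
                                  attr(object, "design"),
                                  attr(object, "positive"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
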