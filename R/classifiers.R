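# Four-family binary classifier harness used by the experiment designs.
# Hyperparameters are tuned on the validation fold; features are
# standardized with training-fold statistics only.

#' Model specification for the experiment harness
#'
#' @param family One of `"regularized_logistic"`, `"svm"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`.
#' @param grid Data frame of hyperparameter combinations (one per row);
#'   `NULL` uses the family default.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("regularized_logistic", "svm",
                                  "random_forest", "gradient_boosted_trees"),
                       grid = NULL) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (nrow(grid) == 0) {
    stop_hc("hyperparameter grid must be non-empty", "healthycore_parameter_error")
  }
  structure(list(family = family, grid = grid), class = "model_spec")
}

default_grid <- function(family) {
  switch(family,
    regularized_logistic = expand.grid(C = c(0.01, 0.1, 1, 10)),
    svm = expand.grid(cost = c(0.1, 1, 10), sigma_mult = c(0.5, 1, 2)),
    random_forest = expand.grid(max_depth = c(3, 6, 0)),
    gradient_boosted_trees = expand.grid(nrounds = c(100, 300),
                                         max_depth = c(2, 4), eta = 0.1)
  )
}

#' Default model set: the four families with their standard grids
#'
#' L2-regularized logistic regression, RBF-kernel SVM, random forest
#' (500 trees) and gradient-boosted trees.
#'
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function() {
  fams <- c("regularized_logistic", "svm", "random_forest",
            "gradient_boosted_trees")
  setNames(lapply(fams, model_spec), fams)
}

# Fit one family with one hyperparameter row; return predicted P(positive)
# for each matrix in newx (a named list). y is a 0/1 vector.
fit_predict_model <- function(family, params, x, y, newx, seed = 1) {
  set.seed(seed)
  if (length(unique(y)) < 2) {
    stop_hc("training fold has a single class", "healthycore_parameter_error")
  }
  switch(family,
    regularized_logistic = {
      lambda <- 1 / (params$C * length(y))
      fit <- suppressWarnings(
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = FALSE)
      )
      lapply(newx, function(m) {
        as.numeric(predict(fit, m, type = "response"))
      })
    },
    svm = {
      med <- tryCatch(median_heuristic_bandwidth(x),
                      error = function(e) sqrt(ncol(x)))
      gamma <- 1 / (2 * (params$sigma_mult * med)^2)
      fit <- suppressWarnings(
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = params$cost, gamma = gamma, probability = TRUE)
      )
      lapply(newx, function(m) {
        pr <- attr(predict(fit, m, probability = TRUE), "probabilities")
        as.numeric(pr[, "1"])
      })
    },
    random_forest = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df, num.trees = 500,
        max.depth = params$max_depth, probability = TRUE,
        num.threads = 1, seed = seed
      )
      lapply(newx, function(m) {
        as.numeric(predict(fit, as.data.frame(m),
                           num.threads = 1)$predictions[, "1"])
      })
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
      lapply(newx, function(m) {
        as.numeric(predict(fit, xgboost::xgb.DMatrix(m)))
      })
    },
    stop_hc(paste0("unknown model family: ", family),
            "healthycore_parameter_error")
  )
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' The probability that a random positive scores above a random negative,
#' counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical, 0/1, or a factor whose second level
#'   is positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_hc("AUC needs both classes present", "healthycore_metric_error")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  stop_hc("labels must be logical, 0/1, or a two-level factor",
          "healthycore_metric_error")
}
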