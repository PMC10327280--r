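# Maximum Mean Discrepancy estimators and the permutation two-sample test,
# on raw features or in GFK space.

#' Kernel specification for MMD computations
#'
#' @param kind `"rbf"` (Gaussian) or `"linear"`.
#' @param bandwidth Positive bandwidth sigma of the RBF kernel
#'   `exp(-||x - y||^2 / (2 sigma^2))`, or `"median-heuristic"` to set it
#'   from the pooled pairwise distances at evaluation time.
#' @param space `"raw"` or `"gfk"`; the latter evaluates the kernel on
#'   GFK-embedded rows and requires `gfk`.
#' @param gfk A `gfk_kernel` (required when `space = "gfk"`).
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"),
                        bandwidth = "median-heuristic",
                        space = c("raw", "gfk"), gfk = NULL) {
  kind <- match.arg(kind)
  space <- match.arg(space)
  if (is.numeric(bandwidth) && bandwidth <= 0) {
    stop_hc("bandwidth must be positive", "healthycore_parameter_error")
  }
  if (space == "gfk" && is.null(gfk)) {
    stop_hc("space = 'gfk' requires a gfk_kernel", "healthycore_parameter_error")
  }
  structure(list(kind = kind, bandwidth = bandwidth, space = space, gfk = gfk),
            class = "kernel_spec")
}

# Map rows into the evaluation space and pin down a numeric bandwidth.
resolve_kernel <- function(x, y, spec) {
  if (spec$space == "gfk") {
    x <- gfk_embed(x, spec$gfk)
    y <- gfk_embed(y, spec$gfk)
  } else {
    x <- if (is.matrix(x)) x else feature_matrix(x)
    y <- if (is.matrix(y)) y else feature_matrix(y)
  }
  if (ncol(x) != ncol(y)) {
    stop_hc("row dimensions differ between the two samples",
            "healthycore_contract_error")
  }
  bw <- spec$bandwidth
  if (spec$kind == "rbf" && identical(bw, "median-heuristic")) {
    bw <- median_heuristic_bandwidth(x, y)
  }
  list(x = x, y = y, bandwidth = bw)
}

#' Median-heuristic RBF bandwidth
#'
#' The median of the pairwise Euclidean distances over the pooled sample
#' (each unordered pair once; self-distances excluded).
#'
#' @param x,y Numeric matrices (rows = observations); `y` optional.
#' @return A positive scalar.
#' @export
median_heuristic_bandwidth <- function(x, y = NULL) {
  pooled <- rbind(if (is.matrix(x)) x else feature_matrix(x),
                  if (is.null(y)) NULL else if (is.matrix(y)) y else feature_matrix(y))
  if (nrow(pooled) < 2) {
    stop_hc("need at least 2 pooled rows", "healthycore_parameter_error")
  }
  d <- as.numeric(dist(pooled))
  m <- median(d)
  if (!is.finite(m) || m <= 0) {
    stop_hc("degenerate bandwidth: pooled points are (almost) all identical",
            "healthycore_degenerate_error")
  }
  m
}

cross_sqdist <- function(x, y) {
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' Kernel matrix between two samples
#'
#' @param x,y Numeric matrices (or feature tables).
#' @param spec A [kernel_spec()].
#' @return The `nrow(x)` x `nrow(y)` matrix of `k(x_i, y_j)`.
#' @export
kernel_matrix <- function(x, y, spec = kernel_spec()) {
  r <- resolve_kernel(x, y, spec)
  kernel_matrix_resolved(r$x, r$y, spec$kind, r$bandwidth)
}

kernel_matrix_resolved <- function(x, y, kind, bandwidth) {
  if (kind == "linear") {
    tcrossprod(x, y)
  } else {
    exp(-cross_sqdist(x, y) / (2 * bandwidth^2))
  }
}

mmd2_from_blocks <- function(kxx, kyy, kxy, estimator) {
  m <- nrow(kxx)
  n <- nrow(kyy)
  if (estimator == "biased") {
    mean(kxx) + mean(kyy) - 2 * mean(kxy)
  } else {
    if (m < 2 || n < 2) {
      stop_hc("the unbiased estimator needs >= 2 rows per sample",
              "healthycore_parameter_error")
    }
    (sum(kxx) - sum(diag(kxx))) / (m * (m - 1)) +
      (sum(kyy) - sum(diag(kyy))) / (n * (n - 1)) -
      2 * mean(kxy)
  }
}

#' Squared Maximum Mean Discrepancy between two samples
#'
#' The biased (V-statistic) estimator is
#' `mean(Kxx) + mean(Kyy) - 2 mean(Kxy)` and is always non-negative; the
#' unbiased (U-statistic) estimator drops the within-sample diagonals and
#' can be slightly negative under the null.
#'
#' @param x,y Numeric matrices or feature tables with >= 2 rows each.
#' @param spec A [kernel_spec()].
#' @param estimator `"unbiased"` (default) or `"biased"`.
#' @return A list of class `mmd_result`: `mmd2`, `estimator`, `kernel`
#'   (spec with the bandwidth resolved to a number), `m`, `n`.
#' @export
mmd2 <- function(x, y, spec = kernel_spec(),
                 estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  r <- resolve_kernel(x, y, spec)
  if (nrow(r$x) < 2 || nrow(r$y) < 2) {
    stop_hc("each sample needs >= 2 rows", "healthycore_parameter_error")
  }
  kxx <- kernel_matrix_resolved(r$x, r$x, spec$kind, r$bandwidth)
  kyy <- kernel_matrix_resolved(r$y, r$y, spec$kind, r$bandwidth)
  kxy <- kernel_matrix_resolved(r$x, r$y, spec$kind, r$bandwidth)
  out_spec <- spec
  out_spec$bandwidth <- r$bandwidth
  structure(
    list(mmd2 = mmd2_from_blocks(kxx, kyy, kxy, estimator),
         estimator = estimator, kernel = out_spec,
         m = nrow(r$x), n = nrow(r$y), p_value = NULL, n_perm = NULL,
         seed = NULL),
    class = "mmd_result"
  )
}

#' Permutation two-sample test on the MMD statistic
#'
#' Permutes the pooled group labels `n_perm` times and reports
#' `p = (1 + #(permuted >= observed)) / (n_perm + 1)`. The biased statistic
#' is used by default (standard practice for the permutation null). The
#' kernel (bandwidth, GFK embedding) is resolved once on the pooled observed
#' sample and held fixed across permutations.
#'
#' @inheritParams mmd2
#' @param n_perm Number of permutations (>= 99 recommended).
#' @param seed Integer seed; the test is deterministic given it.
#' @return An `mmd_result` with `p_value`, `n_perm` and `seed` filled in.
#' @export
mmd_permutation_test <- function(x, y, spec = kernel_spec(), n_perm = 999,
                                 seed = 1, estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  if (n_perm < 1) {
    stop_hc("n_perm must be >= 1", "healthycore_parameter_error")
  }
  r <- resolve_kernel(x, y, spec)
  m <- nrow(r$x)
  n <- nrow(r$y)
  if (m < 2 || n < 2) {
    stop_hc("each sample needs >= 2 rows", "healthycore_parameter_error")
  }
  pooled <- rbind(r$x, r$y)
  k <- kernel_matrix_resolved(pooled, pooled, spec$kind, r$bandwidth)
  stat_for <- function(ix) {
    iy <- setdiff(seq_len(m + n), ix)
    mmd2_from_blocks(k[ix, ix, drop = FALSE], k[iy, iy, drop = FALSE],
                     k[ix, iy, drop = FALSE], estimator)
  }
  observed <- stat_for(seq_len(m))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    stat_for(sample.int(m + n, m))
  }, numeric(1))
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  out_spec <- spec
  out_spec$bandwidth <- r$bandwidth
  structure(
    list(mmd2 = observed, estimator = estimator, kernel = out_spec,
         m = m, n = n, p_value = p, n_perm = n_perm, seed = seed),
    class = "mmd_result"
  )
}

#' @export
print.mmd_result <- function(x, ...) {
  cat(sprintf("MMD^2 (%s, %s kernel%s): %.6g", x$estimator, x$kernel$kind,
              if (x$kernel$space == "gfk") ", GFK space" else "", x$mmd2))
  if (!is.null(x$p_value)) {
    cat(sprintf("  [permutation p = %.4g, %d permutations]", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.mmd_result <- function(x, ...) {
  tibble(mmd2 = x$mmd2, estimator = x$estimator, kernel = x$kernel$kind,
         space = x$kernel$space,
         bandwidth = if (is.numeric(x$kernel$bandwidth)) x$kernel$bandwidth else NA_real_,
         m = x$m, n = x$n,
         p.value = x$p_value %||% NA_real_,
         n_perm = x$n_perm %||% NA_integer_)
}

#' @export
glance.mmd_result <- function(x, ...) tidy(x)
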