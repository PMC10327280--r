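# t-SNE visualization export for cohort/core illustrations.

#' Two-dimensional t-SNE embedding
#'
#' Wraps Rtsne with a deterministic PCA initialization (first two principal
#' component scores, scaled to SD 1e-4), so the embedding is reproducible
#' given the seed.
#'
#' @param x Numeric matrix or feature table (rows = subjects).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; requires `nrow(x) > 3 * perplexity`.
#' @param max_iter Gradient-descent iterations.
#' @return For a matrix: a tibble with `tsne1`, `tsne2` (and `subject_id`
#'   when rownames exist). For a feature table: the metadata columns plus
#'   `tsne1`, `tsne2`.
#' @export
tsne_embedding <- function(x, seed = 1, perplexity = 10, max_iter = 500) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  n <- nrow(m)
  if (n <= 3 * perplexity) {
    stop_hc(sprintf("perplexity %g infeasible for n = %d (need n > 3*perplexity)",
                    perplexity, n), "healthycore_parameter_error")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  init <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(init) < 2) init <- cbind(init, 0)
  init <- scale(init, center = TRUE, scale = FALSE)
  init <- init / max(stats::sd(init), 1e-12) * 1e-4
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                      max_iter = max_iter, Y_init = init, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE,
                      num_threads = 1)
  coords <- tibble(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  if (!is.matrix(x)) {
    bind_cols(as_tibble(as.data.frame(x))[, intersect(FT_META, names(x))],
              coords)
  } else {
    if (!is.null(rownames(m))) coords <- bind_cols(
      tibble(subject_id = rownames(m)), coords)
    coords
  }
}

#' Scatter plot of a t-SNE embedding
#'
#' @param coords Output of [tsne_embedding()].
#' @param colour Column name used for point colour (e.g. `"diagnosis"` or a
#'   core-membership flag added by the caller).
#' @return A ggplot object.
#' @export
plot_tsne <- function(coords, colour = "diagnosis") {
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}
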