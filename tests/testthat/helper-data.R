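# Small fixtures built in code.

# A minimal feature table with arbitrary numbers, independent of the
# synthetic generator.
make_ft <- function(n = 6, d = 4, cohort = "DS1", diagnosis = "HC",
                    prefix = cohort, seed = 1,
                    modalities = c("thickness", "area")) {
  withr::with_seed(seed, {
    feats <- paste0("lh_region", seq_len(d), "_",
                    rep_len(modalities, d))
    m <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, feats))
    feature_table(dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("%s_%02d", prefix, seq_len(n)),
        cohort = cohort,
        diagnosis = rep_len(diagnosis, n),
        sex = rep_len(c("F", "M"), n),
        age = 30 + seq_len(n)
      ),
      tibble::as_tibble(m)
    ))
  })
}

# Random column-orthonormal basis.
rand_basis <- function(D, d) qr.Q(qr(matrix(rnorm(D * d), D, d)))

# A paper-shaped synthetic dataset cached per test run.
paper_sim <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) {
      cache <<- generate_multisite_cohorts(synthetic_config(), seed = seed)
    }
    cache
  }
})

# Trapezoid-rule quadrature of the geodesic projector integral; the
# independent oracle for the closed-form GFK matrix.
gfk_quadrature <- function(pair, nodes = 10000) {
  comp <- healthycore:::gfk_components(pair)
  d <- length(comp$theta)
  ts <- seq(0, 1, length.out = nodes)
  w <- rep(1, nodes)
  w[c(1, nodes)] <- 0.5
  w <- w / (nodes - 1)
  G <- matrix(0, nrow(pair$ps), nrow(pair$ps))
  for (i in seq_along(ts)) {
    phi <- comp$omega1 %*% diag(cos(ts[i] * comp$theta), d) -
      comp$omega2 %*% diag(sin(ts[i] * comp$theta), d)
    G <- G + w[i] * tcrossprod(phi)
  }
  G
}
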