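# Geodesic Flow Kernel between two cohorts' principal subspaces.
#
# The two cohorts' feature matrices are summarized by d-dimensional principal
# subspaces span(Ps), span(Pt) of R^D. The geodesic Phi(t) on the Grassmann
# manifold connects them (Phi(0) spans Ps, Phi(1) spans Pt), parameterized by
# the principal angles theta between the subspaces. The GFK matrix
#   G = integral_0^1 Phi(t) Phi(t)' dt
# has a closed form in terms of theta and induces the inner product
# <x, y>_G = x' G y that averages projections along the whole geodesic
# rather than using either cohort's snapshot subspace alone.

#' Fit a principal subspace to a data matrix
#'
#' Returns a column-orthonormal basis of the top-`d` principal directions of
#' the column-centered data. Column signs are fixed (largest-magnitude entry
#' positive) so the basis is deterministic.
#'
#' @param x Numeric matrix, observations in rows (>= 2 rows).
#' @param d Subspace dimension, `1 <= d <= min(nrow(x) - 1, ncol(x))`.
#' @return A `ncol(x)` x `d` matrix with orthonormal columns; the column
#'   means used for centering are stored in the `"center"` attribute.
#' @export
fit_subspace <- function(x, d) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- ncol(x)
  if (n < 2) stop_hc("need >= 2 rows", "healthycore_parameter_error")
  if (d < 1 || d > min(n - 1, D)) {
    stop_hc(sprintf("d must be in [1, %d]", min(n - 1, D)),
            "healthycore_parameter_error")
  }
  ctr <- colMeans(x)
  sv <- svd(sweep(x, 2, ctr), nu = 0, nv = d)
  basis <- fix_signs(sv$v)
  attr(basis, "center") <- ctr
  basis
}

fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

check_orthonormal <- function(p, tol = 1e-8, what = "basis") {
  if (max(abs(crossprod(p) - diag(ncol(p)))) > tol) {
    stop_hc(paste0(what, " must have orthonormal columns"),
            "healthycore_contract_error")
  }
  invisible(p)
}

#' Principal angles between two subspaces
#'
#' `theta_i = acos(sigma_i)` for the singular values `sigma` of `Ps' Pt`
#' (clamped to `[0, 1]`), returned in ascending order within `[0, pi/2]`.
#'
#' @param ps,pt Column-orthonormal bases of equal dimensions.
#' @return Numeric vector of `d` angles in radians.
#' @export
principal_angles <- function(ps, pt) {
  if (!all(dim(ps) == dim(pt))) {
    stop_hc("bases must have equal dimensions", "healthycore_contract_error")
  }
  check_orthonormal(ps)
  check_orthonormal(pt)
  s <- svd(crossprod(ps, pt), nu = 0, nv = 0)$d
  acos(pmin(1, pmax(0, s)))
}

#' Pair of subspaces with the machinery needed by the GFK closed form
#'
#' Builds the orthogonal complement `Rs` of the source basis and the
#' principal angles; requires `d <= D - d` so the complement construction is
#' well defined.
#'
#' @param ps,pt Column-orthonormal `D x d` bases (source, target).
#' @return A list of class `subspace_pair`: `ps`, `pt`, `rs`, `theta`.
#' @export
subspace_pair <- function(ps, pt) {
  if (!all(dim(ps) == dim(pt))) {
    stop_hc("bases must have equal dimensions", "healthycore_contract_error")
  }
  check_orthonormal(ps, what = "source basis")
  check_orthonormal(pt, what = "target basis")
  D <- nrow(ps)
  d <- ncol(ps)
  if (d > D - d) {
    stop_hc(sprintf("need d <= D - d (got d = %d, D = %d)", d, D),
            "healthycore_parameter_error")
  }
  qs <- qr(ps)
  rs <- qr.Q(qs, complete = TRUE)[, (d + 1):D, drop = FALSE]
  structure(
    list(ps = ps, pt = pt, rs = rs, theta = principal_angles(ps, pt)),
    class = "subspace_pair"
  )
}

# Rotated bases and angle-wise integral coefficients of the GFK closed form.
gfk_components <- function(pair) {
  ps <- pair$ps
  pt <- pair$pt
  rs <- pair$rs
  sv <- svd(crossprod(ps, pt))
  cos_th <- pmin(1, pmax(0, sv$d))
  theta <- acos(cos_th)
  sin_th <- sin(theta)
  b <- crossprod(rs, pt) %*% sv$v
  u2 <- matrix(0, nrow(b), ncol(b))
  ok <- sin_th > 1e-12
  if (any(ok)) {
    u2[, ok] <- -sweep(b[, ok, drop = FALSE], 2, sin_th[ok], "/")
  }
  list(omega1 = ps %*% sv$u, omega2 = rs %*% u2, theta = theta)
}

gfk_lambdas <- function(theta, eps = 1e-4) {
  l1 <- ifelse(theta < eps, 1 - theta^2 / 3, 0.5 + sin(2 * theta) / (4 * theta))
  l2 <- ifelse(theta < eps, -theta / 2, (cos(2 * theta) - 1) / (4 * theta))
  l3 <- ifelse(theta < eps, theta^2 / 3, 0.5 - sin(2 * theta) / (4 * theta))
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Closed-form GFK matrix of a subspace pair
#'
#' Evaluates `G = integral_0^1 Phi(t) Phi(t)' dt` analytically, where
#' `Phi(t)` is the Grassmann geodesic from the source to the target
#' subspace. `G` is symmetric, positive semi-definite, has eigenvalues in
#' `[0, 1]` and trace equal to `d`; small principal angles are handled by
#' series expansions so that identical subspaces give exactly `Ps Ps'`.
#'
#' @param pair A [subspace_pair()].
#' @return A list of class `gfk_kernel`: `G` (D x D), `sqrt` (symmetric PSD
#'   square root of `G`), `d`, `theta`, `pair`, plus identity `center` and
#'   `scale` (overridden by [fit_gfk()]).
#' @export
gfk_matrix <- function(pair) {
  comp <- gfk_components(pair)
  lam <- gfk_lambdas(comp$theta)
  o1 <- comp$omega1
  o2 <- comp$omega2
  g <- o1 %*% (lam$l1 * t(o1)) + o1 %*% (lam$l2 * t(o2)) +
    o2 %*% (lam$l2 * t(o1)) + o2 %*% (lam$l3 * t(o2))
  g <- (g + t(g)) / 2
  new_gfk_kernel(g, d = ncol(pair$ps), theta = comp$theta, pair = pair,
                 center = rep(0, nrow(g)), scale = rep(1, nrow(g)))
}

new_gfk_kernel <- function(g, d, theta, pair, center, scale) {
  eg <- eigen(g, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  s <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  structure(
    list(G = g, sqrt = (s + t(s)) / 2, d = d, theta = theta, pair = pair,
         center = center, scale = scale),
    class = "gfk_kernel"
  )
}

#' Fit a GFK between two cohorts' feature tables
#'
#' Standardizes features with pooled statistics, fits each cohort's principal
#' subspace, and evaluates the closed-form GFK matrix. The subspace dimension
#' (the method's scale parameter) defaults to the smallest `d` explaining
#' `var_explained` of the variance in both cohorts, capped so the complement
#' construction (`d <= D - d`) and the sample sizes allow it.
#'
#' @param a,b Feature tables (or numeric matrices) with identical feature
#'   columns; conventionally the healthy controls of each cohort.
#' @param d Subspace dimension, or `"auto"`.
#' @param var_explained Variance fraction targeted by `d = "auto"`.
#' @param standardize Center and scale features with pooled statistics before
#'   fitting (the centering/scaling is stored and re-applied by
#'   [gfk_embed()]).
#' @return A `gfk_kernel` whose `center`/`scale` reproduce the
#'   preprocessing.
#' @export
fit_gfk <- function(a, b, d = "auto", var_explained = 0.95,
                    standardize = TRUE) {
  xa <- if (is.matrix(a)) a else feature_matrix(a)
  xb <- if (is.matrix(b)) b else feature_matrix(b)
  if (ncol(xa) != ncol(xb)) {
    stop_hc("cohorts must share feature columns", "healthycore_contract_error")
  }
  pooled <- rbind(xa, xb)
  if (standardize) {
    ctr <- colMeans(pooled)
    scl <- apply(pooled, 2, sd)
    if (any(scl <= 0)) {
      stop_hc("zero-variance feature; cannot standardize", "healthycore_degenerate_error")
    }
  } else {
    ctr <- colMeans(pooled)
    scl <- rep(1, ncol(pooled))
  }
  za <- sweep(sweep(xa, 2, ctr), 2, scl, "/")
  zb <- sweep(sweep(xb, 2, ctr), 2, scl, "/")
  D <- ncol(za)
  d_max <- min(nrow(za) - 1, nrow(zb) - 1, floor(D / 2))
  if (identical(d, "auto")) {
    d <- max(1, min(d_for_variance(za, var_explained),
                    d_for_variance(zb, var_explained), d_max))
  }
  if (d > d_max) {
    stop_hc(sprintf("d = %d exceeds the feasible maximum %d", d, d_max),
            "healthycore_parameter_error")
  }
  ps <- fit_subspace(za, d)
  pt <- fit_subspace(zb, d)
  pair <- subspace_pair(ps, pt)
  k <- gfk_matrix(pair)
  k$center <- ctr
  k$scale <- scl
  k
}

d_for_variance <- function(x, var_explained) {
  sv <- svd(scale(x, scale = FALSE), nu = 0, nv = 0)$d
  cum <- cumsum(sv^2) / sum(sv^2)
  which(cum >= var_explained)[1]
}

#' Embed data in GFK space
#'
#' Applies the kernel's stored centering/scaling and maps rows through the
#' symmetric square root `S` of `G`, so that inner products (and distances)
#' of embedded rows equal the G-inner products of the preprocessed rows:
#' `embed(x) . embed(y) = x' G y`.
#'
#' @param x Numeric matrix (or feature table) with the kernel's feature
#'   dimension.
#' @param kernel A `gfk_kernel`.
#' @return Numeric matrix of embedded rows.
#' @export
gfk_embed <- function(x, kernel) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  if (ncol(m) != nrow(kernel$G)) {
    stop_hc(sprintf("x has %d columns but the kernel dimension is %d",
                    ncol(m), nrow(kernel$G)),
            "healthycore_contract_error")
  }
  z <- sweep(sweep(m, 2, kernel$center), 2, kernel$scale, "/")
  out <- z %*% kernel$sqrt
  rownames(out) <- rownames(m)
  out
}

#' @export
print.gfk_kernel <- function(x, ...) {
  cat(sprintf("GFK kernel: D = %d, d = %d, principal angles [%.3g, %.3g] rad\n",
              nrow(x$G), x$d, min(x$theta), max(x$theta)))
  invisible(x)
}

#' @export
tidy.gfk_kernel <- function(x, ...) {
  tibble(component = seq_along(x$theta), theta = x$theta,
         cos_theta = cos(x$theta))
}

#' @export
glance.gfk_kernel <- function(x, ...) {
  ev <- eigen(x$G, symmetric = TRUE, only.values = TRUE)$values
  tibble(D = nrow(x$G), d = x$d, trace = sum(diag(x$G)),
         min_eigenvalue = min(ev), max_eigenvalue = max(ev),
         max_theta = max(x$theta))
}
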