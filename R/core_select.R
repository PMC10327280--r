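# Healthy-core selection: find subsets of each cohort's healthy controls
# that are mutually homogeneous, by minimizing MMD^2 between the two
# selections in GFK space. Greedy backward elimination is the workhorse;
# an exhaustive search over tiny instances serves as the optimality oracle.

# Shared construction of the selection space: per-cohort standardization
# (optional), GFK fitted once on the full cohorts and frozen, kernel matrix
# over the pooled HCs with the bandwidth resolved once.
build_core_space <- function(h_a, h_b, spec = NULL, standardize = FALSE,
                             d = "auto", var_explained = 0.95) {
  check_same_features(h_a, h_b)
  if (any(h_a$diagnosis != "HC") || any(h_b$diagnosis != "HC")) {
    stop_hc("healthy-core selection expects HC rows only",
            "healthycore_contract_error")
  }
  if (length(intersect(h_a$subject_id, h_b$subject_id)) > 0) {
    stop_hc("cohorts share subject ids", "healthycore_contract_error")
  }
  if (standardize) {
    h_a <- standardize_cohort_matrixwise(h_a)
    h_b <- standardize_cohort_matrixwise(h_b)
  }
  xa <- feature_matrix(h_a)
  xb <- feature_matrix(h_b)
  if (is.null(spec)) {
    gfk <- fit_gfk(xa, xb, d = d, var_explained = var_explained,
                   standardize = TRUE)
    spec <- kernel_spec("rbf", "median-heuristic", space = "gfk", gfk = gfk)
  } else if (spec$space == "gfk" && is.null(spec$gfk)) {
    spec$gfk <- fit_gfk(xa, xb, d = d, var_explained = var_explained,
                        standardize = TRUE)
  }
  r <- resolve_kernel(xa, xb, spec)
  pooled <- rbind(r$x, r$y)
  k <- kernel_matrix_resolved(pooled, pooled, spec$kind, r$bandwidth)
  spec$bandwidth <- r$bandwidth
  list(
    ids = c(h_a$subject_id, h_b$subject_id),
    cohort = c(rep("A", nrow(xa)), rep("B", nrow(xb))),
    K = k, spec = spec
  )
}

standardize_cohort_matrixwise <- function(tab) {
  m <- feature_matrix(tab)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv <= 0)) {
    stop_hc("zero-variance feature within a cohort", "healthycore_degenerate_error")
  }
  out <- as_tibble(as.data.frame(tab))
  out[, feature_names(tab)] <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  restore_feature_table(out, tab)
}

subset_objective <- function(k, ia, ib, estimator) {
  mmd2_from_blocks(k[ia, ia, drop = FALSE], k[ib, ib, drop = FALSE],
                   k[ia, ib, drop = FALSE], estimator)
}

balance_bounds <- function(total, p_a, tol, min_per_cohort) {
  lo <- max(min_per_cohort, ceiling((1 - tol) * p_a * total - 1e-9))
  hi <- min(total - min_per_cohort, floor((1 + tol) * p_a * total + 1e-9))
  c(lo, hi)
}

#' Select a healthy core from two cohorts of healthy controls
#'
#' Greedy backward elimination (default) starts from all HCs and repeatedly
#' removes the subject whose removal most decreases the MMD^2 between the
#' two cohort selections, evaluated with the chosen kernel (by default: RBF
#' with median-heuristic bandwidth on GFK-embedded, within-cohort
#' standardized features; the GFK is fitted once on the full cohorts and
#' frozen). Selection stops at `target_size`, or -- with
#' `target_size = "auto"` -- at the first step where the MMD permutation test
#' between the selections no longer rejects at level `alpha`. A balance
#' constraint keeps each cohort's share of the core within `balance_tol` of
#' proportionality to the cohort sizes. Ties are broken by lexicographic
#' subject id, so membership is invariant to input row order.
#'
#' @param h_a,h_b Feature tables holding only HC rows, identical features.
#' @param target_size Total core size, or `"auto"` (permutation-test
#'   stopping).
#' @param method `"greedy_backward"` or `"greedy_forward"`.
#' @param spec Optional [kernel_spec()]; `NULL` builds the default GFK/RBF
#'   spec from the data.
#' @param seed Integer seed (used by the permutation stopping rule).
#' @param estimator MMD estimator used as the objective. The biased
#'   (V-statistic) estimator is the default: it is bounded below by zero,
#'   whereas minimizing the unbiased estimator over subsets chases negative
#'   finite-sample fluctuations and rewards degenerate anti-matched
#'   selections.
#' @param standardize Standardize features within each cohort (mean 0,
#'   variance 1 per cohort) before building the selection space. Off by
#'   default: when heterogeneous subjects inflate each cohort's variances
#'   along cohort-specific directions, per-cohort scaling distorts the
#'   shared core differently in each cohort; the GFK's pooled
#'   standardization is applied either way.
#' @param d,var_explained Passed to [fit_gfk()] when the GFK is built here.
#' @param balance_tol Allowed relative deviation of each cohort's core share
#'   from proportionality.
#' @param min_per_cohort Minimum core members per cohort.
#' @param alpha,n_perm Stopping rule parameters for `target_size = "auto"`.
#' @return A list of class `healthy_core`: `ids_a`, `ids_b`, `trajectory`
#'   (tibble: step, removed/added id, cohort, mmd2, size), `mmd2` (final
#'   objective), `config`, and the frozen selection `space`.
#' @export
select_healthy_core <- function(h_a, h_b, target_size = "auto",
                                method = c("greedy_backward", "greedy_forward"),
                                spec = NULL, seed = 1,
                                estimator = c("biased", "unbiased"),
                                standardize = FALSE, d = "auto",
                                var_explained = 0.95, balance_tol = 0.2,
                                min_per_cohort = 2, alpha = 0.05,
                                n_perm = 199) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  space <- build_core_space(h_a, h_b, spec, standardize, d, var_explained)
  n_a <- sum(space$cohort == "A")
  n_b <- sum(space$cohort == "B")
  n <- n_a + n_b
  p_a <- n_a / n
  auto <- identical(target_size, "auto")
  if (!auto) {
    target_size <- as.integer(target_size)
    if (target_size > n || target_size < 2 * min_per_cohort) {
      stop_hc(sprintf("target_size must lie in [%d, %d]", 2 * min_per_cohort, n),
              "healthycore_parameter_error")
    }
    bb <- balance_bounds(target_size, p_a, balance_tol, min_per_cohort)
    if (bb[1] > bb[2]) {
      stop_hc("no per-cohort composition satisfies the balance constraint at target_size",
              "healthycore_constraint_error")
    }
  }
  config <- list(method = method, target_size = if (auto) "auto" else target_size,
                 estimator = estimator, standardize = standardize,
                 balance_tol = balance_tol, min_per_cohort = min_per_cohort,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 kernel = space$spec$kind, kernel_space = space$spec$space,
                 bandwidth = space$spec$bandwidth)
  core <- if (method == "greedy_backward") {
    greedy_backward_select(space, target_size, auto, estimator, p_a,
                           balance_tol, min_per_cohort, alpha, n_perm, seed,
                           config)
  } else {
    greedy_forward_select(space, target_size, auto, estimator, p_a,
                          balance_tol, min_per_cohort, alpha, n_perm, seed,
                          config)
  }
  # Polish the greedy selection with best-improvement swaps.
  is_a <- space$cohort == "A"
  sel <- space$ids %in% c(core$ids_a, core$ids_b)
  ref <- local_swap_refine(space$K, sel, is_a, space$ids, estimator)
  if (ref$n_swaps > 0) {
    core$ids_a <- sort(space$ids[ref$sel & is_a])
    core$ids_b <- sort(space$ids[ref$sel & !is_a])
    core$mmd2 <- ref$obj
  }
  core$config$n_refine_swaps <- ref$n_swaps
  core
}

greedy_backward_select <- function(space, target_size, auto, estimator, p_a,
                                   balance_tol, min_per_cohort, alpha, n_perm,
                                   seed, config) {
  k <- space$K
  ids <- space$ids
  is_a <- space$cohort == "A"
  sel <- rep(TRUE, length(ids))
  # Running sums: row sums of K against current A- and B-selections.
  rows_a <- rowSums(k[, is_a, drop = FALSE])
  rows_b <- rowSums(k[, !is_a, drop = FALSE])
  s_aa <- sum(rows_a[is_a])
  s_bb <- sum(rows_b[!is_a])
  s_ab <- sum(rows_b[is_a])
  d_aa <- sum(diag(k)[is_a])
  d_bb <- sum(diag(k)[!is_a])
  m_a <- sum(is_a)
  m_b <- sum(!is_a)
  obj_current <- objective_from_sums(s_aa, s_bb, s_ab, d_aa, d_bb, m_a, m_b,
                                     estimator)
  traj <- list(tibble(step = 0L, id = NA_character_, cohort = NA_character_,
                      mmd2 = obj_current, size = m_a + m_b))
  if (auto) {
    p0 <- perm_p_from_kernel(k, which(sel & is_a), which(sel & !is_a),
                             n_perm, seed)
    if (p0 > alpha) {
      return(finish_core(space, sel, is_a, traj, obj_current, config))
    }
  }
  step <- 0L
  while (TRUE) {
    total <- m_a + m_b
    if (!auto && total <= target_size) break
    if (auto && total <= 2 * min_per_cohort) break
    cand <- which(sel)
    cand_a <- cand[is_a[cand]]
    cand_b <- cand[!is_a[cand]]
    # Feasibility of removing one member at the new total: both cohorts must
    # stay inside their balance bounds (falling back to lower bounds only if
    # rounding makes the two-sided constraint momentarily unsatisfiable).
    t_new <- total - 1
    bb_a <- balance_bounds(t_new, p_a, balance_tol, min_per_cohort)
    bb_b <- balance_bounds(t_new, 1 - p_a, balance_tol, min_per_cohort)
    ok_a <- (m_a - 1) >= bb_a[1] && (m_a - 1) <= bb_a[2] &&
      m_b >= bb_b[1] && m_b <= bb_b[2]
    ok_b <- (m_b - 1) >= bb_b[1] && (m_b - 1) <= bb_b[2] &&
      m_a >= bb_a[1] && m_a <= bb_a[2]
    if (!ok_a && !ok_b) {
      ok_a <- (m_a - 1) >= bb_a[1] && m_b >= bb_b[1]
      ok_b <- (m_b - 1) >= bb_b[1] && m_a >= bb_a[1]
    }
    objs <- rep(Inf, length(ids))
    if (ok_a && length(cand_a) > 0) {
      s_aa_new <- s_aa - 2 * rows_a[cand_a] + diag(k)[cand_a]
      d_aa_new <- d_aa - diag(k)[cand_a]
      s_ab_new <- s_ab - rows_b[cand_a]
      objs[cand_a] <- objective_from_sums(s_aa_new, s_bb, s_ab_new, d_aa_new,
                                          d_bb, m_a - 1, m_b, estimator)
    }
    if (ok_b && length(cand_b) > 0) {
      s_bb_new <- s_bb - 2 * rows_b[cand_b] + diag(k)[cand_b]
      d_bb_new <- d_bb - diag(k)[cand_b]
      s_ab_new <- s_ab - rows_a[cand_b]
      objs[cand_b] <- objective_from_sums(s_aa, s_bb_new, s_ab_new, d_aa,
                                          d_bb_new, m_a, m_b - 1, estimator)
    }
    if (!any(is.finite(objs))) {
      if (auto) break
      stop_hc("no feasible removal satisfies the balance constraint",
              "healthycore_constraint_error")
    }
    best <- min(objs)
    best_ix <- which(objs <= best + 1e-15)
    rm_ix <- best_ix[order(ids[best_ix])][1]
    # Commit the removal.
    sel[rm_ix] <- FALSE
    if (is_a[rm_ix]) {
      s_aa <- s_aa - 2 * rows_a[rm_ix] + k[rm_ix, rm_ix]
      d_aa <- d_aa - k[rm_ix, rm_ix]
      s_ab <- s_ab - rows_b[rm_ix]
      rows_a <- rows_a - k[, rm_ix]
      m_a <- m_a - 1
    } else {
      s_bb <- s_bb - 2 * rows_b[rm_ix] + k[rm_ix, rm_ix]
      d_bb <- d_bb - k[rm_ix, rm_ix]
      s_ab <- s_ab - rows_a[rm_ix]
      rows_b <- rows_b - k[, rm_ix]
      m_b <- m_b - 1
    }
    obj_current <- objective_from_sums(s_aa, s_bb, s_ab, d_aa, d_bb, m_a, m_b,
                                       estimator)
    step <- step + 1L
    traj[[length(traj) + 1]] <- tibble(
      step = step, id = ids[rm_ix],
      cohort = if (is_a[rm_ix]) "A" else "B",
      mmd2 = obj_current, size = m_a + m_b
    )
    if (auto) {
      p <- perm_p_from_kernel(k, which(sel & is_a), which(sel & !is_a),
                              n_perm, seed + step)
      if (p > alpha) break
    }
  }
  finish_core(space, sel, is_a, traj, obj_current, config)
}

objective_from_sums <- function(s_aa, s_bb, s_ab, d_aa, d_bb, m_a, m_b,
                                estimator) {
  if (estimator == "biased") {
    s_aa / m_a^2 + s_bb / m_b^2 - 2 * s_ab / (m_a * m_b)
  } else {
    (s_aa - d_aa) / (m_a * (m_a - 1)) + (s_bb - d_bb) / (m_b * (m_b - 1)) -
      2 * s_ab / (m_a * m_b)
  }
}

perm_p_from_kernel <- function(k, ia, ib, n_perm, seed) {
  sub <- c(ia, ib)
  ksub <- k[sub, sub, drop = FALSE]
  m <- length(ia)
  n <- length(ib)
  stat_for <- function(ix) {
    iy <- setdiff(seq_len(m + n), ix)
    mmd2_from_blocks(ksub[ix, ix, drop = FALSE], ksub[iy, iy, drop = FALSE],
                     ksub[ix, iy, drop = FALSE], "biased")
  }
  observed <- stat_for(seq_len(m))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat_for(sample.int(m + n, m)),
                 numeric(1))
  (1 + sum(perm >= observed)) / (n_perm + 1)
}

greedy_forward_select <- function(space, target_size, auto, estimator, p_a,
                                  balance_tol, min_per_cohort, alpha, n_perm,
                                  seed, config) {
  k <- space$K
  ids <- space$ids
  is_a <- space$cohort == "A"
  n <- length(ids)
  target <- if (auto) n else target_size
  bb <- balance_bounds(target, p_a, balance_tol, min_per_cohort)
  max_a <- bb[2]
  max_b <- target - bb[1]
  # Seed with the best-matched cross-cohort pair (ties by id).
  cross <- k
  cross[outer(is_a, is_a, "==")] <- -Inf
  best <- which(cross == max(cross), arr.ind = TRUE)
  best <- best[order(pmin(ids[best[, 1]], ids[best[, 2]])), , drop = FALSE]
  sel <- rep(FALSE, n)
  sel[best[1, ]] <- TRUE
  traj <- list()
  step <- 0L
  while (sum(sel) < target) {
    m_a <- sum(sel & is_a)
    m_b <- sum(sel & !is_a)
    cand <- which(!sel)
    ok <- (is_a[cand] & m_a + 1 <= max_a) | (!is_a[cand] & m_b + 1 <= max_b)
    cand <- cand[ok]
    if (length(cand) == 0) break
    est <- if (m_a < 2 || m_b < 2) "biased" else estimator
    objs <- vapply(cand, function(i) {
      s <- sel
      s[i] <- TRUE
      est_i <- if (sum(s & is_a) < 2 || sum(s & !is_a) < 2) "biased" else est
      subset_objective(k, which(s & is_a), which(s & !is_a), est_i)
    }, numeric(1))
    best_obj <- min(objs)
    pick <- cand[objs <= best_obj + 1e-15]
    add_ix <- pick[order(ids[pick])][1]
    sel[add_ix] <- TRUE
    step <- step + 1L
    obj_now <- subset_objective(k, which(sel & is_a), which(sel & !is_a),
                                if (sum(sel & is_a) < 2 || sum(sel & !is_a) < 2)
                                  "biased" else estimator)
    traj[[length(traj) + 1]] <- tibble(
      step = step, id = ids[add_ix],
      cohort = if (is_a[add_ix]) "A" else "B",
      mmd2 = obj_now, size = sum(sel)
    )
    if (auto && sum(sel & is_a) >= min_per_cohort &&
        sum(sel & !is_a) >= min_per_cohort && sum(sel) >= 2 * min_per_cohort) {
      p <- perm_p_from_kernel(k, which(sel & is_a), which(sel & !is_a),
                              n_perm, seed + step)
      if (p <= alpha) {
        # Adding more members re-introduced a detectable difference; keep
        # growing only while the selections stay indistinguishable.
        next
      }
    }
  }
  obj_final <- subset_objective(k, which(sel & is_a), which(sel & !is_a),
                                if (sum(sel & is_a) < 2 || sum(sel & !is_a) < 2)
                                  "biased" else estimator)
  finish_core(space, sel, is_a, traj, obj_final, config)
}

# Deterministic 1-swap local refinement: repeatedly apply the best
# same-cohort swap (one member out, one non-member in) that lowers the
# objective, until no swap improves. Keeps the per-cohort composition, so
# the balance constraint is preserved.
local_swap_refine <- function(k, sel, is_a, ids, estimator, max_passes = 100) {
  diag_k <- diag(k)
  rows_a <- rowSums(k[, sel & is_a, drop = FALSE])
  rows_b <- rowSums(k[, sel & !is_a, drop = FALSE])
  s_aa <- sum(rows_a[sel & is_a])
  s_bb <- sum(rows_b[sel & !is_a])
  s_ab <- sum(rows_b[sel & is_a])
  d_aa <- sum(diag_k[sel & is_a])
  d_bb <- sum(diag_k[sel & !is_a])
  m_a <- sum(sel & is_a)
  m_b <- sum(sel & !is_a)
  n_swaps <- 0L
  current <- objective_from_sums(s_aa, s_bb, s_ab, d_aa, d_bb, m_a, m_b,
                                 estimator)
  for (pass in seq_len(max_passes)) {
    best <- list(obj = current, i = NA, j = NA)
    for (co in c(TRUE, FALSE)) {
      outs <- which(sel & (is_a == co))
      ins <- which(!sel & (is_a == co))
      if (length(outs) == 0 || length(ins) == 0) next
      if (co) {
        base_s <- s_aa - 2 * rows_a[outs] + diag_k[outs]
        add_s <- 2 * rows_a[ins] + diag_k[ins]
        s_new <- outer(base_s, add_s, "+") - 2 * t(k[ins, outs, drop = FALSE])
        d_new <- outer(d_aa - diag_k[outs], diag_k[ins], "+")
        ab_new <- outer(s_ab - rows_b[outs], rows_b[ins], "+")
        objs <- objective_from_sums(s_new, s_bb, ab_new, d_new, d_bb,
                                    m_a, m_b, estimator)
      } else {
        base_s <- s_bb - 2 * rows_b[outs] + diag_k[outs]
        add_s <- 2 * rows_b[ins] + diag_k[ins]
        s_new <- outer(base_s, add_s, "+") - 2 * t(k[ins, outs, drop = FALSE])
        d_new <- outer(d_bb - diag_k[outs], diag_k[ins], "+")
        ab_new <- outer(s_ab - rows_a[outs], rows_a[ins], "+")
        objs <- objective_from_sums(s_aa, s_new, ab_new, d_aa, d_new,
                                    m_a, m_b, estimator)
      }
      hit <- which(objs < best$obj - 1e-14, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        vals <- objs[hit]
        pick <- hit[order(vals, ids[outs[hit[, 1]]], ids[ins[hit[, 2]]])[1], ]
        if (objs[pick[1], pick[2]] < best$obj - 1e-14) {
          best <- list(obj = objs[pick[1], pick[2]],
                       i = outs[pick[1]], j = ins[pick[2]])
        }
      }
    }
    if (is.na(best$i)) {
      # Single swaps converged. On small instances, escape remaining local
      # optima with a joint neighborhood: one swap in each cohort applied
      # simultaneously (the natural move when a matched pair should be
      # exchanged together).
      outs_a <- which(sel & is_a)
      ins_a <- which(!sel & is_a)
      outs_b <- which(sel & !is_a)
      ins_b <- which(!sel & !is_a)
      combos <- length(outs_a) * length(ins_a) *
        length(outs_b) * length(ins_b)
      if (combos == 0 || combos > 20000) break
      jb <- list(obj = current, sel = NULL)
      for (oa in outs_a) for (ja in ins_a) for (ob in outs_b) for (nb in ins_b) {
        s <- sel
        s[c(oa, ob)] <- FALSE
        s[c(ja, nb)] <- TRUE
        o <- subset_objective(k, which(s & is_a), which(s & !is_a), estimator)
        if (o < jb$obj - 1e-14) jb <- list(obj = o, sel = s)
      }
      if (is.null(jb$sel)) break
      sel <- jb$sel
      current <- jb$obj
      n_swaps <- n_swaps + 2L
      # refresh the running sums after the joint move
      rows_a <- rowSums(k[, sel & is_a, drop = FALSE])
      rows_b <- rowSums(k[, sel & !is_a, drop = FALSE])
      s_aa <- sum(rows_a[sel & is_a])
      s_bb <- sum(rows_b[sel & !is_a])
      s_ab <- sum(rows_b[sel & is_a])
      d_aa <- sum(diag_k[sel & is_a])
      d_bb <- sum(diag_k[sel & !is_a])
      next
    }
    i <- best$i
    j <- best$j
    sel[i] <- FALSE
    sel[j] <- TRUE
    if (is_a[i]) {
      s_aa <- s_aa - 2 * rows_a[i] + diag_k[i] + 2 * rows_a[j] -
        2 * k[i, j] + diag_k[j]
      d_aa <- d_aa - diag_k[i] + diag_k[j]
      s_ab <- s_ab - rows_b[i] + rows_b[j]
      rows_a <- rows_a - k[, i] + k[, j]
    } else {
      s_bb <- s_bb - 2 * rows_b[i] + diag_k[i] + 2 * rows_b[j] -
        2 * k[i, j] + diag_k[j]
      d_bb <- d_bb - diag_k[i] + diag_k[j]
      s_ab <- s_ab - rows_a[i] + rows_a[j]
      rows_b <- rows_b - k[, i] + k[, j]
    }
    current <- best$obj
    n_swaps <- n_swaps + 1L
  }
  list(sel = sel, obj = current, n_swaps = n_swaps)
}

finish_core <- function(space, sel, is_a, traj, obj, config) {
  structure(
    list(
      ids_a = sort(space$ids[sel & is_a]),
      ids_b = sort(space$ids[sel & !is_a]),
      trajectory = bind_rows(traj),
      mmd2 = obj,
      config = config,
      space = space
    ),
    class = "healthy_core"
  )
}

#' Exhaustive minimum-MMD core search (testing oracle)
#'
#' Enumerates every per-cohort composition satisfying the balance constraint
#' and every subset of each size, and returns the global minimum-MMD^2 core.
#' Guarded to at most `max_combinations` evaluations; intended for tiny
#' instances and oracle tests.
#'
#' @inheritParams select_healthy_core
#' @param target_size Total core size (must be numeric here).
#' @param max_combinations Enumeration guard.
#' @return A `healthy_core` (empty trajectory, method `"exhaustive"`).
#' @export
exhaustive_core_search <- function(h_a, h_b, target_size, spec = NULL,
                                   estimator = c("biased", "unbiased"),
                                   standardize = FALSE, d = "auto",
                                   var_explained = 0.95, balance_tol = 0.2,
                                   min_per_cohort = 2,
                                   max_combinations = 1e6) {
  estimator <- match.arg(estimator)
  space <- build_core_space(h_a, h_b, spec, standardize, d, var_explained)
  k <- space$K
  is_a <- space$cohort == "A"
  n_a <- sum(is_a)
  n_b <- sum(!is_a)
  p_a <- n_a / (n_a + n_b)
  target_size <- as.integer(target_size)
  bb_a <- balance_bounds(target_size, p_a, balance_tol, min_per_cohort)
  bb_b <- balance_bounds(target_size, 1 - p_a, balance_tol, min_per_cohort)
  ka_lo <- max(bb_a[1], target_size - n_b, target_size - bb_b[2])
  ka_hi <- min(bb_a[2], n_a, target_size - bb_b[1])
  k_as <- if (ka_lo > ka_hi) integer(0) else seq(ka_lo, ka_hi)
  k_as <- k_as[k_as >= 2 & target_size - k_as >= 2 & target_size - k_as <= n_b]
  if (length(k_as) == 0) {
    stop_hc("no feasible composition at target_size", "healthycore_constraint_error")
  }
  total <- sum(vapply(k_as, function(ka) {
    choose(n_a, ka) * choose(n_b, target_size - ka)
  }, numeric(1)))
  if (total > max_combinations) {
    stop_hc(sprintf("instance too large for exhaustive search (%.3g combinations)",
                    total), "healthycore_size_guard_error")
  }
  idx_a <- which(is_a)
  idx_b <- which(!is_a)
  best_obj <- Inf
  best_sel <- NULL
  for (ka in k_as) {
    kb <- target_size - ka
    combs_a <- combn(idx_a, ka)
    combs_b <- combn(idx_b, kb)
    for (i in seq_len(ncol(combs_a))) {
      ia <- combs_a[, i]
      for (j in seq_len(ncol(combs_b))) {
        ib <- combs_b[, j]
        obj <- subset_objective(k, ia, ib, estimator)
        if (obj < best_obj - 1e-15) {
          best_obj <- obj
          best_sel <- c(ia, ib)
        } else if (obj <= best_obj + 1e-15 && !is.null(best_sel)) {
          cand_ids <- sort(space$ids[c(ia, ib)])
          if (paste(cand_ids, collapse = "|") <
              paste(sort(space$ids[best_sel]), collapse = "|")) {
            best_sel <- c(ia, ib)
          }
        }
      }
    }
  }
  sel <- rep(FALSE, length(space$ids))
  sel[best_sel] <- TRUE
  config <- list(method = "exhaustive", target_size = target_size,
                 estimator = estimator, standardize = standardize,
                 balance_tol = balance_tol, min_per_cohort = min_per_cohort,
                 kernel = space$spec$kind, kernel_space = space$spec$space,
                 bandwidth = space$spec$bandwidth)
  finish_core(space, sel, is_a, list(), best_obj, config)
}

#' Quality report for a selected healthy core
#'
#' Compares the core's final MMD^2 against the empirical distribution over
#' random subsets of the same size and per-cohort composition, and -- when
#' the planted ground truth is available -- reports precision/recall of core
#' membership.
#'
#' @param core A `healthy_core`.
#' @param h_a,h_b The HC tables the core was selected from.
#' @param truth Optional `ground_truth` from
#'   [generate_multisite_cohorts()].
#' @param n_random Random same-shape subsets drawn for the percentile.
#' @param seed Integer seed.
#' @return A one-row tibble: `mmd2`, `percentile` (fraction of random
#'   subsets with objective <= the core's), `n_random`, and
#'   `precision`/`recall` when truth is given.
#' @export
core_quality_report <- function(core, h_a, h_b, truth = NULL, n_random = 500,
                                seed = 1) {
  space <- core$space
  k <- space$K
  is_a <- space$cohort == "A"
  idx_a <- which(is_a)
  idx_b <- which(!is_a)
  ka <- length(core$ids_a)
  kb <- length(core$ids_b)
  estimator <- core$config$estimator %||% "biased"
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rand <- vapply(seq_len(n_random), function(i) {
    subset_objective(k, sample(idx_a, ka), sample(idx_b, kb), estimator)
  }, numeric(1))
  out <- tibble(
    mmd2 = core$mmd2,
    percentile = mean(rand <= core$mmd2),
    n_random = n_random,
    size_a = ka, size_b = kb
  )
  if (!is.null(truth)) {
    selected <- c(core$ids_a, core$ids_b)
    planted <- truth$core$subject_id[truth$core$core_member]
    planted <- intersect(planted, space$ids)
    out$precision <- length(intersect(selected, planted)) / length(selected)
    out$recall <- length(intersect(selected, planted)) / length(planted)
  }
  out
}

#' @export
print.healthy_core <- function(x, ...) {
  cat(sprintf(
    "Healthy core: %d members (A: %d, B: %d), MMD^2 = %.6g [%s, %s]\n",
    length(x$ids_a) + length(x$ids_b), length(x$ids_a), length(x$ids_b),
    x$mmd2, x$config$method, x$config$estimator
  ))
  invisible(x)
}

#' @export
tidy.healthy_core <- function(x, ...) x$trajectory

#' @export
glance.healthy_core <- function(x, ...) {
  tibble(n_core = length(x$ids_a) + length(x$ids_b),
         n_a = length(x$ids_a), n_b = length(x$ids_b),
         mmd2 = x$mmd2, method = x$config$method,
         estimator = x$config$estimator)
}

#' @export
autoplot.healthy_core <- function(object, ...) {
  traj <- object$trajectory
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$size, y = .data$mmd2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "subjects retained", y = expression(MMD^2),
                  title = "Healthy-core selection trajectory") +
    ggplot2::theme_minimal()
}
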