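# Full-information maximum likelihood estimation.
#
# Each family contributes the multivariate-normal log density of its
# observed sub-vector under the model-implied mean/covariance restricted
# to the observed slots.  Families sharing a missingness pattern are
# collapsed to sufficient statistics (count, mean, centered scatter), so
# one likelihood evaluation costs one Cholesky per pattern regardless of
# the number of families.

LOG2PI <- log(2 * pi)
.INFEASIBLE <- 1e10

# group families by missingness pattern and precompute sufficient stats
pattern_stats <- function(obs, mask) {
  key <- as.vector(mask %*% 2^(0:15))
  groups <- split(seq_len(nrow(obs)), key)
  lapply(groups, function(rows) {
    idx <- which(mask[rows[1], ])
    X <- obs[rows, idx, drop = FALSE]
    n <- nrow(X)
    xbar <- colMeans(X)
    Sc <- crossprod(sweep(X, 2, xbar, check.margin = FALSE))
    list(idx = idx, n = n, xbar = xbar, Sc = Sc)
  })
}

# Negative log-likelihood and analytic score closures.
#
# All slot bookkeeping is done once: the implied mean/covariance is
# assembled only over the slots the dataset ever observes, and pattern
# indices are pre-mapped into that reduced ordering.  The score uses the
# standard FIML gradient accumulators
#   d ll / d mu    = sum_g n_g Sigma_o^{-1} d_g
#   d ll / d Sigma = sum_g -1/2 (n_g Sigma_o^{-1}
#                     - Sigma_o^{-1} (Sc_g + n_g d_g d_g') Sigma_o^{-1})
# contracted through the structural map Sigma(theta), mu(theta) in closed
# form, so one gradient costs one pass over the patterns.  Infeasible
# iterates (non-PD joint covariance) return a large constant / zero score.
make_objective <- function(compiled, stats, mask) {
  active <- which(colSums(mask) > 0L)
  pa <- active[active <= 4L]
  ra <- active[active > 4L] - 4L
  k <- length(pa) + length(ra)
  nr <- length(ra)
  B_idx_a <- compiled$B_idx[ra, , drop = FALSE]
  rvar_idx_a <- compiled$rvar_idx[ra]
  RE_idx_a <- compiled$RE_idx[ra, ra, drop = FALSE]
  RE_off <- which(RE_idx_a > 0L)
  RE_cells <- RE_idx_a[RE_off]
  RE_ut <- which(RE_idx_a > 0L & upper.tri(RE_idx_a), arr.ind = TRUE)
  RP_idx <- compiled$pcorr_idx
  RP_off <- which(RP_idx > 0L)
  RP_cells <- RP_idx[RP_off]
  RP_ut <- which(RP_idx > 0L & upper.tri(RP_idx), arr.ind = TRUE)
  alpha_idx_a <- compiled$alpha_idx[ra]
  fixed_values <- compiled$fixed_values
  free_cells <- which(compiled$cell_to_free > 0L)
  free_map <- compiled$cell_to_free[free_cells]
  n_cells <- length(fixed_values)
  slot_map <- integer(16)
  slot_map[active] <- seq_len(k)
  stats_a <- lapply(stats, function(g) {
    g$idx <- slot_map[g$idx]
    g
  })
  sum_nk_log2pi <- sum(vapply(stats_a, function(g) g$n * length(g$idx),
                              numeric(1))) * LOG2PI
  p_rows <- seq_along(pa)
  o_rows <- length(pa) + seq_len(nr)

  assemble <- function(theta) {
    v <- fixed_values
    v[free_cells] <- theta[free_map]
    sdP <- sqrt(v[compiled$pvar_idx])
    RP <- diag(4)
    RP[RP_off] <- v[RP_cells]
    Sigma_P <- (sdP %o% sdP) * RP
    B_a <- matrix(v[B_idx_a], nr, 4L)
    sdE <- sqrt(v[rvar_idx_a])
    RE <- diag(nr)
    RE[RE_off] <- v[RE_cells]
    Sigma_E <- (sdE %o% sdE) * RE
    SPB <- Sigma_P %*% t(B_a)
    Sig <- matrix(0, k, k)
    if (length(pa)) {
      Sig[p_rows, p_rows] <- Sigma_P[pa, pa]
      Sig[p_rows, o_rows] <- SPB[pa, , drop = FALSE]
      Sig[o_rows, p_rows] <- t(SPB[pa, , drop = FALSE])
    }
    Sig[o_rows, o_rows] <- B_a %*% SPB + Sigma_E
    mu_P <- v[compiled$mu_idx]
    mu <- c(mu_P[pa], v[alpha_idx_a] + drop(B_a %*% mu_P))
    list(v = v, Sig = Sig, mu = mu, Sigma_P = Sigma_P, Sigma_E = Sigma_E,
         B_a = B_a, sdP = sdP, sdE = sdE, mu_P = mu_P)
  }

  negll <- function(theta) {
    a <- assemble(theta)
    # a PD joint covariance makes every observed submatrix PD, so one
    # upfront check covers all patterns; near-singular iterates can still
    # fail a submatrix factorization numerically, hence the outer guard
    ok <- tryCatch({ chol(a$Sig); TRUE }, error = function(e) FALSE)
    if (!ok) return(.INFEASIBLE)
    total <- tryCatch({
      acc <- -0.5 * sum_nk_log2pi
      for (g in stats_a) {
        L <- chol(a$Sig[g$idx, g$idx, drop = FALSE])
        Minv <- chol2inv(L)
        d <- g$xbar - a$mu[g$idx]
        acc <- acc - 0.5 * (g$n * 2 * sum(log(diag(L))) +
                            sum(Minv * g$Sc) + g$n * sum(d * (Minv %*% d)))
      }
      acc
    }, error = function(e) NA_real_)
    if (!is.finite(total)) return(.INFEASIBLE)
    -total
  }

  # gradient of negll w.r.t. the natural-scale free parameters
  grad <- function(theta) {
    a <- assemble(theta)
    ok <- tryCatch({ chol(a$Sig); TRUE }, error = function(e) FALSE)
    if (!ok) return(numeric(compiled$n_free))
    G <- matrix(0, k, k)   # d ll / d Sigma (full symmetric convention)
    gm <- numeric(k)       # d ll / d mu
    ok2 <- tryCatch({
      for (g in stats_a) {
        idx <- g$idx
        Minv <- chol2inv(chol(a$Sig[idx, idx, drop = FALSE]))
        d <- g$xbar - a$mu[idx]
        Md <- Minv %*% d
        A <- g$Sc + g$n * (d %o% d)
        G[idx, idx] <- G[idx, idx] - 0.5 * (g$n * Minv - Minv %*% A %*% Minv)
        gm[idx] <- gm[idx] + g$n * Md
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok2) return(numeric(compiled$n_free))
    # embed the parental partitions back into the full 4-slot frame
    G_pp <- matrix(0, 4, 4)
    G_po <- matrix(0, 4, nr)
    if (length(pa)) {
      G_pp[pa, pa] <- G[p_rows, p_rows]
      G_po[pa, ] <- G[p_rows, o_rows, drop = FALSE]
    }
    G_oo <- G[o_rows, o_rows, drop = FALSE]
    gm_p <- numeric(4)
    if (length(pa)) gm_p[pa] <- gm[p_rows]
    gm_o <- gm[o_rows]

    B_a <- a$B_a
    # transmission block: d ll / d B[r, c]
    GB <- 2 * t(G_po) %*% a$Sigma_P + 2 * G_oo %*% B_a %*% a$Sigma_P +
      gm_o %o% a$mu_P
    # parental covariance block: d ll / d Sigma_P (symmetrized)
    W <- G_pp + 2 * G_po %*% B_a + t(B_a) %*% G_oo %*% B_a
    W <- (W + t(W)) / 2
    # means
    wmu <- gm_p + drop(t(B_a) %*% gm_o)

    g_cell <- numeric(n_cells)
    # transmission cells (shared across birth order: accumulate)
    gb <- rowsum(as.vector(GB), as.vector(B_idx_a))
    g_cell[as.integer(rownames(gb))] <- g_cell[as.integer(rownames(gb))] + gb[, 1]
    # parental variances: sum_b W[i,b] Sigma_P[i,b] / v_i
    wv <- rowSums(W * a$Sigma_P)
    g_cell[compiled$pvar_idx] <- g_cell[compiled$pvar_idx] +
      wv / a$v[compiled$pvar_idx]
    # parental correlations
    g_cell[RP_idx[RP_ut]] <- g_cell[RP_idx[RP_ut]] +
      2 * W[RP_ut] * a$sdP[RP_ut[, 1]] * a$sdP[RP_ut[, 2]]
    # residual variances
    gr_rows <- rowSums(G_oo * a$Sigma_E)
    rv <- rowsum(gr_rows / a$v[rvar_idx_a], rvar_idx_a)
    g_cell[as.integer(rownames(rv))] <- g_cell[as.integer(rownames(rv))] + rv[, 1]
    # residual correlations (within-person and sibling classes alike)
    if (nrow(RE_ut)) {
      re_val <- 2 * G_oo[RE_ut] * a$sdE[RE_ut[, 1]] * a$sdE[RE_ut[, 2]]
      re <- rowsum(re_val, RE_idx_a[RE_ut])
      g_cell[as.integer(rownames(re))] <- g_cell[as.integer(rownames(re))] + re[, 1]
    }
    # means and intercepts
    g_cell[compiled$mu_idx] <- g_cell[compiled$mu_idx] + wmu
    al <- rowsum(gm_o, alpha_idx_a)
    g_cell[as.integer(rownames(al))] <- g_cell[as.integer(rownames(al))] + al[, 1]

    gfree <- rowsum(g_cell[free_cells], free_map)
    -as.numeric(gfree[order(as.integer(rownames(gfree))), 1])
  }

  list(negll = negll, grad = grad)
}

#' Log-likelihood contribution of one family
#'
#' The multivariate-normal log density of the family's observed slots
#' under the model-implied moments at `theta`, i.e. the family's FIML
#' contribution.
#'
#' @param model A `transmission_model`.
#' @param theta Named free-parameter vector (natural scale).
#' @param observation Length-16 numeric vector in canonical slot order
#'   (`NA` = missing, at least one slot observed), or a
#'   [family_dataset()] containing a single family.
#' @return The log-likelihood contribution (scalar).
#' @export
family_loglik <- function(model, theta, observation) {
  if (inherits(observation, "family_dataset")) {
    om <- family_observations(observation)
    if (nrow(om$observation) != 1L) {
      stop("observation dataset must contain exactly one family", call. = FALSE)
    }
    observation <- om$observation[1, ]
  }
  stopifnot(length(observation) == 16L)
  if (!any(is.finite(observation))) {
    stop("family has no observed slot", call. = FALSE)
  }
  mom <- implied_moments(model, theta, check = FALSE)
  idx <- which(is.finite(observation))
  x <- observation[idx]
  So <- mom$cov[idx, idx, drop = FALSE]
  L <- tryCatch(chol(So), error = function(e) NULL)
  if (is.null(L)) stop("implied covariance of the observed slots is singular",
                       call. = FALSE)
  d <- x - mom$mean[idx]
  z <- backsolve(L, d, transpose = TRUE)
  -0.5 * (length(idx) * LOG2PI + 2 * sum(log(diag(L))) + sum(z^2))
}

# ---- identification of free classes under the observed patterns --------

identified_classes <- function(compiled, mask) {
  J <- crossprod(mask)  # 16x16 joint observation counts
  cells <- compiled$cells
  slot_of <- function(role, trait, k = NA) slot_index(role, k, trait)
  off_slots <- function(os, ot) vapply(1:3, function(k) slot_of(os, ot, k), 1L)

  cell_ok <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    nm <- cells$cell[i]
    cell_ok[i] <- switch(
      cells$block[i],
      transmission = {
        p <- strsplit(nm, "_")[[1]]  # b ps pt os ot
        ps_slot <- slot_of(p[2], p[3])
        any(J[ps_slot, off_slots(p[4], p[5])] > 0)
      },
      parental_var = J[match(sub("^var_", "", nm), .slot_names),
                       match(sub("^var_", "", nm), .slot_names)] > 0,
      parental_corr = {
        p <- sub("^rho_p_", "", nm)
        a <- match(sub("_(father|mother)_(bmi|ea)$", "", p), .slot_names)
        b <- match(sub("^(father|mother)_(bmi|ea)_", "", p), .slot_names)
        J[a, b] > 0
      },
      resid_var = {
        p <- strsplit(sub("^rvar_", "", nm), "_")[[1]]
        any(diag(J)[off_slots(p[1], p[2])] > 0)
      },
      resid_wp_corr = {
        os <- sub("^rho_wp_", "", nm)
        any(vapply(1:3, function(k) {
          J[slot_of(os, "bmi", k), slot_of(os, "ea", k)] > 0
        }, logical(1)))
      },
      resid_sib_corr = {
        p <- sub("^rho_r_", "", nm)
        vars <- regmatches(p, regexec("^((son|daughter)[0-9]_(bmi|ea))_((son|daughter)[0-9]_(bmi|ea))$", p))[[1]]
        a <- match(vars[2], .slot_names)
        b <- match(vars[5], .slot_names)
        J[a, b] > 0
      },
      intercept = {
        v <- sub("^(mu|alpha)_", "", nm)
        if (v %in% .slot_names) {
          J[match(v, .slot_names), match(v, .slot_names)] > 0
        } else {
          p <- strsplit(v, "_")[[1]]
          any(diag(J)[off_slots(p[1], p[2])] > 0)
        }
      }
    )
  }
  ok_class <- tapply(cell_ok, cells$class, any)
  free <- is.na(cells$fixed)
  compiled$classes %in% names(ok_class)[ok_class]
}

# ---- moment-based start values -----------------------------------------

moment_start <- function(compiled, obs) {
  mu0 <- suppressWarnings(colMeans(obs, na.rm = TRUE))
  mu0[!is.finite(mu0)] <- 0
  S0 <- suppressWarnings(stats::cov(obs, use = "pairwise.complete.obs"))
  S0[!is.finite(S0)] <- 0
  dv <- diag(S0)
  dv[dv <= 0] <- 1
  diag(S0) <- dv
  # pairwise-complete covariances need not be PD under missingness; shrink
  # toward the diagonal for a robust feasible start (complete data already
  # give the exact ML moments, so no shrinkage is applied there)
  lambda <- if (anyNA(obs)) 0.1 else 0
  S0 <- (1 - lambda) * S0 + lambda * diag(dv)

  SP <- S0[1:4, 1:4]
  B0 <- tryCatch(S0[5:16, 1:4] %*% solve(SP), error = function(e) matrix(0, 12, 4))
  SE0 <- S0[5:16, 5:16] - B0 %*% SP %*% t(B0)
  ve <- diag(SE0)
  floor_e <- 0.05 * diag(S0)[5:16]
  ve <- pmax(ve, floor_e)
  RE0 <- SE0 / sqrt(outer(ve, ve))
  RE0[!is.finite(RE0)] <- 0
  damp <- if (anyNA(obs)) 0.6 else 0.95
  RE0 <- pmin(pmax(RE0, -damp), damp)
  # pairs never jointly observed carry no information; the subtraction
  # above would otherwise leak spurious correlations into them
  J <- crossprod(!is.na(obs))
  RE0[J[5:16, 5:16] == 0L] <- 0
  alpha0 <- mu0[5:16] - drop(B0 %*% mu0[1:4])

  # per-cell start values; cells shared across birth order average their
  # member slots, weighting slots with no data at zero
  v <- numeric(nrow(compiled$cells))
  w_slot <- as.numeric(diag(J)[5:16] > 0L)
  fill_weighted <- function(v, idx_vec, vals, w) {
    keys <- unique(idx_vec)
    for (key in keys) {
      ii <- which(idx_vec == key)
      ww <- w[ii]
      v[key] <- if (sum(ww) > 0) sum(vals[ii] * ww) / sum(ww) else mean(vals[ii])
    }
    v
  }
  v <- fill_weighted(v, as.vector(compiled$B_idx), as.vector(B0),
                     rep(w_slot, 4L))
  v[compiled$pvar_idx] <- diag(SP)
  cp <- compiled$pcorr_idx
  for (a in 1:3) for (b in (a + 1):4) {
    v[cp[a, b]] <- max(min(SP[a, b] / sqrt(SP[a, a] * SP[b, b]), 0.9), -0.9)
  }
  v <- fill_weighted(v, compiled$rvar_idx, ve, w_slot)
  re <- compiled$RE_idx
  ut <- which(upper.tri(re), arr.ind = TRUE)
  v <- fill_weighted(v, re[ut], RE0[ut],
                     as.numeric(J[5:16, 5:16][ut] > 0L))
  v[compiled$mu_idx] <- mu0[1:4]
  v <- fill_weighted(v, compiled$alpha_idx, alpha0, w_slot)

  free <- compiled$cell_to_free > 0L
  theta <- as.numeric(tapply(v[free], compiled$cell_to_free[free], mean))
  names(theta) <- compiled$classes
  theta
}

neutral_start <- function(compiled) {
  theta <- numeric(compiled$n_free)
  theta[compiled$class_transform == "log"] <- 1
  names(theta) <- compiled$classes
  theta
}

# ---- optimization -------------------------------------------------------

num_gradient <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  g
}

#' Fit a transmission model by FIML
#'
#' Maximizes the sum of per-family observed-data log-likelihoods over the
#' model's free parameters.  Variances are optimized on the log scale and
#' correlations through atanh; non-positive-definite iterates are rejected.
#' Optimization is quasi-Newton (BFGS with central-difference gradients,
#' polished by a final `nlminb` pass) from a moment-based start, with a
#' perturbed and a neutral restart if convergence fails.  Free-parameter
#' classes with no support in the observed missingness patterns (e.g.
#' sibling correlations of never-observed birth slots) are held at their
#' start values and reported as dropped.
#'
#' @param model A `transmission_model`.
#' @param ds A [family_dataset()].
#' @param start Optional named start vector (natural scale).
#' @param se Compute standard errors from the inverse observed information
#'   (numeric Hessian) and Wald 95% confidence intervals.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param polish Run a final `nlminb` pass after BFGS for extra precision
#'   (disable for speed in large replication loops).
#' @param max_restarts Additional starts tried on failure.
#' @param seed Integer seed controlling restart perturbations.
#' @return A `fiml_fit` object; see [tidy.fiml_fit()] and
#'   [glance.fiml_fit()].
#' @export
fit_fiml <- function(model, ds, start = NULL, se = TRUE,
                     reltol = 1e-13, polish = TRUE, max_restarts = 2L, seed = 1L) {
  stopifnot(inherits(model, "transmission_model"), inherits(ds, "family_dataset"))
  om <- family_observations(ds)
  if (nrow(om$observation) == 0L) stop("dataset has no observed families", call. = FALSE)
  stats <- pattern_stats(om$observation, om$mask)
  compiled <- compile_model(model)

  id <- identified_classes(compiled, om$mask)
  theta0 <- moment_start(compiled, om$observation)
  if (!is.null(start)) {
    known <- intersect(names(start), compiled$classes)
    theta0[known] <- start[known]
  }

  core <- make_objective(compiled, stats, om$mask)
  negll_nat <- core$negll
  grad_nat <- core$grad

  # optimize only the identified part, on the transformed scale
  fixed_part <- theta0
  tr_id <- compiled$class_transform[id]
  obj <- function(tt_id) {
    nat_id <- tt_id
    nat_id[tr_id == "log"] <- exp(tt_id[tr_id == "log"])
    nat_id[tr_id == "atanh"] <- tanh(tt_id[tr_id == "atanh"])
    th <- fixed_part
    th[id] <- nat_id
    negll_nat(th)
  }
  gr_obj <- function(tt_id) {
    nat_id <- tt_id
    nat_id[tr_id == "log"] <- exp(tt_id[tr_id == "log"])
    nat_id[tr_id == "atanh"] <- tanh(tt_id[tr_id == "atanh"])
    th <- fixed_part
    th[id] <- nat_id
    g <- grad_nat(th)[id]
    jac <- rep(1, length(nat_id))
    jac[tr_id == "log"] <- nat_id[tr_id == "log"]
    jac[tr_id == "atanh"] <- 1 - nat_id[tr_id == "atanh"]^2
    g * jac
  }
  to_opt_id <- function(nat) {
    tt <- nat
    tt[tr_id == "log"] <- log(nat[tr_id == "log"])
    tt[tr_id == "atanh"] <- atanh(nat[tr_id == "atanh"])
    tt
  }
  from_opt_id <- function(tt) {
    nat <- tt
    nat[tr_id == "log"] <- exp(tt[tr_id == "log"])
    nat[tr_id == "atanh"] <- tanh(tt[tr_id == "atanh"])
    nat
  }

  ensure_feasible <- function(tt0) {
    for (k in 0:20) {
      if (obj(tt0) < .INFEASIBLE) return(tt0)
      tt0[tr_id == "atanh"] <- tt0[tr_id == "atanh"] * 0.5
    }
    stop("could not find a feasible start (residual blocks not PSD)", call. = FALSE)
  }

  run_opt <- function(tt0) {
    tt0 <- ensure_feasible(tt0)
    o1 <- stats::optim(tt0, obj, gr = gr_obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = reltol))
    o2 <- if (!polish) NULL else tryCatch(
      stats::nlminb(o1$par, obj, gradient = gr_obj,
                    control = list(rel.tol = 1e-15, iter.max = 500)),
      error = function(e) NULL
    )
    if (!is.null(o2) && is.finite(o2$objective) && o2$objective <= o1$value) {
      list(par = o2$par, value = o2$objective, converged = TRUE,
           evals = o1$counts[["function"]] + o2$evaluations[["function"]])
    } else {
      list(par = o1$par, value = o1$value, converged = o1$convergence == 0,
           evals = o1$counts[["function"]])
    }
  }

  best <- run_opt(to_opt_id(theta0[id]))
  trace <- sprintf("start=moment negll=%.6f converged=%s", best$value, best$converged)
  if (!best$converged && max_restarts > 0) {
    starts <- list()
    withr::with_seed(seed, {
      starts[[1]] <- to_opt_id(theta0[id]) + stats::rnorm(sum(id), 0, 0.1)
    })
    starts[[2]] <- to_opt_id(neutral_start(compiled)[id])
    for (j in seq_len(min(max_restarts, length(starts)))) {
      alt <- tryCatch(run_opt(starts[[j]]), error = function(e) NULL)
      if (!is.null(alt) && alt$value < best$value) best <- alt
      trace <- c(trace, sprintf("restart %d negll=%.6f", j,
                                if (is.null(alt)) NA_real_ else alt$value))
      if (best$converged) break
    }
  }

  theta_hat <- fixed_part
  theta_hat[id] <- from_opt_id(best$par)
  loglik <- -negll_nat(theta_hat)

  se_vec <- rep(NA_real_, compiled$n_free)
  rank_deficient <- FALSE
  if (se) {
    # observed information: central-difference Jacobian of the analytic
    # score on the natural scale
    p <- sum(id)
    H <- matrix(0, p, p)
    base <- theta_hat
    for (j in seq_len(p)) {
      jj <- which(id)[j]
      h <- 1e-5 * (1 + abs(base[jj]))
      thp <- base; thp[jj] <- base[jj] + h
      thm <- base; thm[jj] <- base[jj] - h
      H[, j] <- (grad_nat(thp)[id] - grad_nat(thm)[id]) / (2 * h)
    }
    H <- (H + t(H)) / 2
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
      rank_deficient <- TRUE
      V <- pracma::pinv(H)
      warning("observed information is rank-deficient; standard errors use a ",
              "pseudo-inverse and some parameters may be unidentified",
              call. = FALSE)
    }
    se_vec[id] <- sqrt(pmax(diag(V), 0))
  }
  names(se_vec) <- compiled$classes
  names(theta_hat) <- compiled$classes

  structure(
    list(
      model = model,
      name = model$name,
      theta = theta_hat,
      se = se_vec,
      ci_lower = theta_hat - 1.96 * se_vec,
      ci_upper = theta_hat + 1.96 * se_vec,
      loglik = loglik,
      n_families = nrow(om$observation),
      n_free = compiled$n_free,
      n_free_identified = sum(id),
      identified = stats::setNames(id, compiled$classes),
      dropped = compiled$classes[!id],
      converged = best$converged,
      rank_deficient = rank_deficient,
      trace = trace,
      n_patterns = length(stats),
      slots_observed = .slot_names[colSums(om$mask) > 0],
      data_signature = data_signature(stats)
    ),
    class = "fiml_fit"
  )
}

data_signature <- function(stats) {
  sum(vapply(stats, function(g) g$n * (1 + sum(g$idx)) + sum(g$xbar) + sum(g$Sc),
             numeric(1)))
}

#' @export
print.fiml_fit <- function(x, ...) {
  cat("<fiml_fit> model '", x$name, "'\n", sep = "")
  cat(sprintf("  families: %d  patterns: %d  logLik: %.3f\n",
              x$n_families, x$n_patterns, x$loglik))
  cat(sprintf("  free parameters: %d (%d identified)  converged: %s\n",
              x$n_free, x$n_free_identified, x$converged))
  invisible(x)
}

#' @export
logLik.fiml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_identified,
            nobs = object$n_families, class = "logLik")
}

#' Extract a fitted parameter
#' @param fit A `fiml_fit`.
#' @param name Free-parameter class name (see [free_parameter_names()]).
#' @return The estimate (scalar).
#' @export
coef_fiml <- function(fit, name) {
  stopifnot(inherits(fit, "fiml_fit"))
  unname(fit$theta[name])
}
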