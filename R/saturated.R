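# Saturated-model FIML: unrestricted mean vector and covariance matrix of
# the slots the data ever observes, fitted by EM over missingness-pattern
# sufficient statistics.  Supplies the reference log-likelihood for the
# model chi-square.

#' Fit the saturated model by FIML
#'
#' Estimates an unrestricted mean vector and covariance matrix over every
#' canonical slot observed at least once, by expectation-maximization on
#' the per-pattern sufficient statistics.  With complete data this
#' reproduces the sample mean and the maximum-likelihood (1/n) sample
#' covariance in a single step.
#'
#' @param ds A [family_dataset()].
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A `saturated_fit` with elements `mean`, `cov` (named by slot),
#'   `loglik`, `n_free` (means + distinct covariances), `n_families`,
#'   `converged`, `slots`, `data_signature`.
#' @export
fit_saturated <- function(ds, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(ds, "family_dataset"))
  om <- family_observations(ds)
  if (nrow(om$observation) == 0L) stop("dataset has no observed families", call. = FALSE)
  keep <- colSums(om$mask) > 0L
  obs <- om$observation[, keep, drop = FALSE]
  mask <- om$mask[, keep, drop = FALSE]
  k <- ncol(obs)
  n <- nrow(obs)
  if (n < 2L) stop("too few families to identify the saturated covariance", call. = FALSE)

  key <- as.vector(mask %*% 2^(seq_len(k) - 1))
  groups <- split(seq_len(n), key)
  stats <- lapply(groups, function(rows) {
    idx <- which(mask[rows[1], ])
    X <- obs[rows, idx, drop = FALSE]
    xbar <- colMeans(X)
    list(idx = idx, n = nrow(X), xbar = xbar,
         Sc = crossprod(sweep(X, 2, xbar, check.margin = FALSE)))
  })

  # init: available-case means, pairwise covariances ridged to PD
  mu <- suppressWarnings(colMeans(obs, na.rm = TRUE))
  mu[!is.finite(mu)] <- 0
  S <- suppressWarnings(stats::cov(obs, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  dv <- diag(S); dv[dv <= 0] <- 1; diag(S) <- dv
  S <- 0.9 * S + 0.1 * diag(dv)
  S <- clip_to_pd(S)

  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    T1 <- numeric(k)
    T2 <- matrix(0, k, k)
    for (g in stats) {
      o <- g$idx
      m <- setdiff(seq_len(k), o)
      xbar <- g$xbar
      if (length(m) == 0L) {
        T1[o] <- T1[o] + g$n * xbar
        T2[o, o] <- T2[o, o] + g$Sc + g$n * tcrossprod(xbar)
      } else {
        Soo_inv <- chol2inv(chol_pd(S[o, o, drop = FALSE]))
        A <- S[m, o, drop = FALSE] %*% Soo_inv
        C <- S[m, m, drop = FALSE] - A %*% S[o, m, drop = FALSE]
        d <- xbar - mu[o]
        em <- mu[m] + drop(A %*% d)           # E[x_m] at the pattern mean
        T1[o] <- T1[o] + g$n * xbar
        T1[m] <- T1[m] + g$n * em
        Too <- g$Sc + g$n * tcrossprod(xbar)
        T2[o, o] <- T2[o, o] + Too
        Tom <- g$n * tcrossprod(xbar, mu[m]) +
          (Too - g$n * tcrossprod(xbar, mu[o])) %*% t(A)
        T2[o, m] <- T2[o, m] + Tom
        T2[m, o] <- T2[m, o] + t(Tom)
        Scd <- g$Sc + g$n * tcrossprod(d)
        T2[m, m] <- T2[m, m] + g$n * C + g$n * tcrossprod(mu[m]) +
          g$n * tcrossprod(mu[m], drop(A %*% d)) +
          g$n * tcrossprod(drop(A %*% d), mu[m]) +
          A %*% Scd %*% t(A)
      }
    }
    mu <- T1 / n
    S <- T2 / n - tcrossprod(mu)
    S <- clip_to_pd((S + t(S)) / 2)
    ll <- loglik_sat(stats, mu, S)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }

  names(mu) <- colnames(obs)
  dimnames(S) <- list(colnames(obs), colnames(obs))
  structure(
    list(
      name = "saturated",
      mean = mu, cov = S,
      loglik = ll_old,
      n_free = as.integer(k + k * (k + 1) / 2),
      n_families = n,
      converged = converged,
      slots = colnames(obs),
      data_signature = data_signature(lapply(stats, function(g) {
        g$idx <- which(keep)[g$idx]
        g
      }))
    ),
    class = "saturated_fit"
  )
}

# clip eigenvalues to keep a symmetric matrix safely positive definite
# (needed when pairwise-complete initial covariances are indefinite)
clip_to_pd <- function(S, rel_eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  floor_val <- rel_eps * max(abs(e$values), 1)
  if (min(e$values) >= floor_val) return(S)
  vals <- pmax(e$values, floor_val)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

chol_pd <- function(S) {
  tryCatch(chol(S), error = function(e) chol(clip_to_pd(S, 1e-6)))
}

loglik_sat <- function(stats, mu, S) {
  total <- 0
  for (g in stats) {
    So <- S[g$idx, g$idx, drop = FALSE]
    L <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
    kk <- length(g$idx)
    Minv <- chol2inv(L)
    d <- g$xbar - mu[g$idx]
    total <- total - 0.5 * (g$n * kk * LOG2PI + g$n * 2 * sum(log(diag(L))) +
                            sum(Minv * g$Sc) + g$n * drop(d %*% Minv %*% d))
  }
  total
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat("<saturated_fit> ", length(x$slots), " slots, ", x$n_free,
      " moments, logLik ", sprintf("%.3f", x$loglik), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.saturated_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n_families,
            class = "logLik")
}

#' Overall fit indices of a fitted model
#'
#' The model chi-square is twice the log-likelihood gap to the saturated
#' model fitted to the same data; degrees of freedom are the number of
#' distinct first and second moments of the slots the data observes minus
#' the number of identified free scalars; RMSEA is
#' `sqrt(max(chi2 - df, 0) / (df * (n - 1)))`.
#'
#' @param fit A `fiml_fit`.
#' @param saturated A `saturated_fit` on the same dataset.
#' @return A one-row tibble with `chi_square`, `df`, `rmsea`.
#' @export
fit_indices <- function(fit, saturated) {
  stopifnot(inherits(fit, "fiml_fit"), inherits(saturated, "saturated_fit"))
  if (!isTRUE(all.equal(fit$data_signature, saturated$data_signature,
                        tolerance = 1e-8))) {
    stop("fit and saturated reference are not based on the same dataset",
         call. = FALSE)
  }
  chi2 <- max(2 * (saturated$loglik - fit$loglik), 0)
  df <- saturated$n_free - fit$n_free_identified
  if (df <= 0) stop("model has non-positive degrees of freedom", call. = FALSE)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (fit$n_families - 1)))
  tibble::tibble(chi_square = chi2, df = as.integer(df), rmsea = rmsea)
}
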