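# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a FIML fit
#'
#' @param x A `fiml_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `block`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `identified`.
#' @export
tidy.fiml_fit <- function(x, ...) {
  cells <- x$model$cells
  block <- cells$block[match(names(x$theta), cells$class)]
  tibble::tibble(
    term = names(x$theta),
    block = block,
    estimate = unname(x$theta),
    std.error = unname(x$se),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper),
    identified = unname(x$identified)
  )
}

#' One-row summary of a FIML fit
#'
#' @param x A `fiml_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `n_free`, `n_identified`, `n_families`,
#'   `n_patterns`, `converged`.
#' @export
glance.fiml_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_free = x$n_free,
    n_identified = x$n_free_identified,
    n_families = x$n_families,
    n_patterns = x$n_patterns,
    converged = x$converged
  )
}

#' Tidy a saturated fit
#' @param x A `saturated_fit`.
#' @param ... Unused.
#' @return Tibble of estimated moments: `term`, `estimate`.
#' @export
tidy.saturated_fit <- function(x, ...) {
  k <- length(x$mean)
  iu <- which(upper.tri(x$cov, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    term = c(paste0("mean_", names(x$mean)),
             paste0("cov_", rownames(x$cov)[iu[, 1]], "_", colnames(x$cov)[iu[, 2]])),
    estimate = c(unname(x$mean), x$cov[iu])
  )
}

#' One-row summary of a saturated fit
#' @param x A `saturated_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `n_free`, `n_families`, `converged`.
#' @export
glance.saturated_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_free = x$n_free,
    n_families = x$n_families,
    converged = x$converged
  )
}

#' Tidy a gender-comparison report
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return The test table: `constraint`, `statistic`, `df`, `p.value`,
#'   `significant`.
#' @export
tidy.comparison_report <- function(x, ...) {
  x$tests
}

#' Serialize a FIML fit to JSON
#'
#' Full-precision dump of estimates, standard errors, Wald CIs and the
#' fit summary.
#'
#' @param fit A `fiml_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "fiml_fit") || inherits(fit, "saturated_fit"))
  payload <- if (inherits(fit, "fiml_fit")) {
    list(model = fit$name, estimates = tidy(fit), glance = glance(fit),
         dropped = fit$dropped, trace = fit$trace)
  } else {
    list(model = fit$name, estimates = tidy(fit), glance = glance(fit))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
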