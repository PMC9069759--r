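# Standardization and path-tracing effect decomposition.
#
# A direct effect is the standardized transmission coefficient itself; an
# indirect effect of parental variable j on offspring variable k is the
# sum of the three paths through j's correlations with the other parental
# variables; the total effect is their sum.  Standardization divides by
# the model-implied total standard deviation of the offspring variable,
# which keeps direct + indirect = total exact on the standardized scale.

#' Standardize a raw transmission coefficient
#'
#' @param raw_b Raw coefficient (offspring-trait units per parent-trait
#'   unit).
#' @param sd_parent Standard deviation of the parental variable.
#' @param sd_offspring Model-implied total standard deviation of the
#'   offspring variable.
#' @return `raw_b * sd_parent / sd_offspring`; vectorized.
#' @examples
#' standardize_coefficient(0.192, sqrt(10.492), sqrt(9.298))
#' @export
standardize_coefficient <- function(raw_b, sd_parent, sd_offspring) {
  if (any(sd_parent <= 0) || any(sd_offspring <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  raw_b * sd_parent / sd_offspring
}

#' Decompose standardized effects into direct, indirect and total
#'
#' @param std_b 4 x k matrix of standardized transmission coefficients;
#'   rows are the parental variables in canonical order (father BMI,
#'   father EA, mother BMI, mother EA), columns offspring variables.
#' @param parental_corr Symmetric 4 x 4 parental correlation matrix with
#'   unit diagonal, same row order.
#' @return A tibble with one row per (parental variable, offspring
#'   variable): `direct`, `indirect` (sum of the three cross-parental
#'   paths), `total = direct + indirect`.
#' @export
decompose_effects <- function(std_b, parental_corr) {
  std_b <- as.matrix(std_b)
  stopifnot(nrow(std_b) == 4L, nrow(parental_corr) == 4L,
            ncol(parental_corr) == 4L)
  if (max(abs(parental_corr - t(parental_corr))) > 1e-10 ||
      max(abs(diag(parental_corr) - 1)) > 1e-10) {
    stop("parental_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  total <- parental_corr %*% std_b
  out <- tidyr::expand_grid(
    offspring_var = colnames(std_b) %||% paste0("offspring_", seq_len(ncol(std_b))),
    parent_var = rownames(std_b) %||% .parent_vars
  )
  # expand_grid varies parent_var fastest; column-major matches that order
  out$direct <- as.vector(std_b)
  out$total <- as.vector(total)
  out$indirect <- out$total - out$direct
  out[, c("parent_var", "offspring_var", "direct", "indirect", "total")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cell-level estimates and ses of a fit (transmission block)
transmission_cells <- function(fit) {
  cells <- fit$model$cells
  tr <- cells[cells$block == "transmission", ]
  parts <- strsplit(tr$cell, "_")
  tibble::tibble(
    cell = tr$cell,
    parent_sex = vapply(parts, `[`, "", 2),
    parent_trait = vapply(parts, `[`, "", 3),
    offspring_sex = vapply(parts, `[`, "", 4),
    offspring_trait = vapply(parts, `[`, "", 5),
    class = tr$class,
    estimate = unname(fit$theta[tr$class]),
    se = unname(fit$se[tr$class])
  )
}

#' Direct, indirect and total effect table of a fitted model
#'
#' For each offspring sex and each (parental variable, offspring trait)
#' combination: the raw transmission estimate with Wald 95% CI, its
#' standardized value (raw times parent SD over model-implied offspring
#' SD) with CI scaled by the same factor, the indirect effect through the
#' parental correlations at the estimates, and the total effect.
#' Residual within-person EA-BMI rows are appended per offspring sex
#' (raw = residual covariance, standardized = residual correlation).
#'
#' @param fit A converged `fiml_fit`.
#' @return An `effect_table` tibble.
#' @seealso [decompose_effects()], [residual_ea_bmi_correlation()]
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "fiml_fit"))
  compiled <- compile_model(fit$model)
  par <- assemble_parameters(compiled, cell_values(compiled, align_theta(compiled, fit$theta)))
  mom <- moments_from_parameters(par)
  sd_parent <- sqrt(diag(par$Sigma_P))
  parental_corr <- par$Sigma_P / outer(sd_parent, sd_parent)
  # implied total offspring SD per (sex, trait), shared across birth order
  sd_off <- c(
    son_bmi = sqrt(mom$cov["son1_bmi", "son1_bmi"]),
    son_ea = sqrt(mom$cov["son1_ea", "son1_ea"]),
    daughter_bmi = sqrt(mom$cov["daughter1_bmi", "daughter1_bmi"]),
    daughter_ea = sqrt(mom$cov["daughter1_ea", "daughter1_ea"])
  )

  tc <- transmission_cells(fit)
  tc$parent_var <- paste(tc$parent_sex, tc$parent_trait, sep = "_")
  tc$scale <- unname(sd_parent[tc$parent_var] /
    sd_off[paste(tc$offspring_sex, tc$offspring_trait, sep = "_")])
  tc$conf.low <- tc$estimate - 1.96 * tc$se
  tc$conf.high <- tc$estimate + 1.96 * tc$se
  tc$std_estimate <- tc$estimate * tc$scale
  tc$std_conf.low <- tc$conf.low * tc$scale
  tc$std_conf.high <- tc$conf.high * tc$scale

  rows <- list()
  for (os in c("son", "daughter")) {
    sub <- tc[tc$offspring_sex == os, ]
    std_b <- matrix(0, 4, 2, dimnames = list(.parent_vars, c("bmi", "ea")))
    std_b[cbind(match(sub$parent_var, .parent_vars),
                match(sub$offspring_trait, c("bmi", "ea")))] <- sub$std_estimate
    dec <- decompose_effects(std_b, parental_corr)
    sub$indirect <- dec$indirect[match(
      paste(sub$parent_var, sub$offspring_trait),
      paste(dec$parent_var, dec$offspring_var)
    )]
    sub$total <- sub$std_estimate + sub$indirect
    rows[[os]] <- sub
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("offspring_sex", "offspring_trait", "parent_sex", "parent_trait",
                 "estimate", "conf.low", "conf.high",
                 "std_estimate", "std_conf.low", "std_conf.high",
                 "indirect", "total")]
  resid <- dplyr::bind_rows(
    residual_ea_bmi_correlation(fit, "son"),
    residual_ea_bmi_correlation(fit, "daughter")
  )
  structure(out, residual_correlations = resid,
            class = c("effect_table", class(out)))
}

#' Residual within-person EA-BMI association in the offspring generation
#'
#' The estimated EA-BMI residual correlation for one offspring sex (the
#' within-person association left after removing what parental
#' transmission explains) and the corresponding residual covariance under
#' the estimated residual variances.
#'
#' @param fit A converged `fiml_fit`.
#' @param offspring_sex `"son"` or `"daughter"`.
#' @return One-row tibble: `offspring_sex`, `covariance`, `correlation`,
#'   `corr_conf.low`, `corr_conf.high`.
#' @export
residual_ea_bmi_correlation <- function(fit, offspring_sex = c("son", "daughter")) {
  stopifnot(inherits(fit, "fiml_fit"))
  offspring_sex <- match.arg(offspring_sex)
  rho <- unname(fit$theta[paste0("rho_wp_", offspring_sex)])
  se <- unname(fit$se[paste0("rho_wp_", offspring_sex)])
  s_prod <- sqrt(unname(fit$theta[paste0("rvar_", offspring_sex, "_bmi")]) *
                 unname(fit$theta[paste0("rvar_", offspring_sex, "_ea")]))
  tibble::tibble(
    offspring_sex = offspring_sex,
    covariance = rho * s_prod,
    correlation = rho,
    corr_conf.low = rho - 1.96 * se,
    corr_conf.high = rho + 1.96 * se
  )
}

#' Export an effect table as CSV
#'
#' Full-precision CSV with the raw estimate and CI, standardized direct
#' estimate and CI, indirect and total columns; residual-correlation rows
#' are written to a companion file if requested.
#'
#' @param x An `effect_table`.
#' @param path Output CSV path.
#' @param residual_path Optional CSV path for the residual EA-BMI rows.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(x, path, residual_path = NULL) {
  stopifnot(inherits(x, "effect_table"))
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  if (!is.null(residual_path)) {
    readr::write_csv(attr(x, "residual_correlations"), residual_path, progress = FALSE)
  }
  invisible(path)
}
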