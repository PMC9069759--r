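# Synthetic NTR-like family data.
#
# The generator draws parental phenotype 4-vectors from a multivariate
# normal, offspring residuals from the assembled 12x12 residual
# covariance, forms offspring values as O = a + B P + E, then applies
# family-composition masking (parents-only / offspring-only / one-parent
# / two-parent families), per-person short-survey EA missingness, and
# attaches ages.  Phenotypes are generated on the age-adjusted analysis
# scale; ages feed the age-based filters only.

#' Default generative parameter values
#'
#' The full 100-cell parameter vector of the family model at the package's
#' reference calibration: transmission coefficients at the parsimonious
#' model's published estimates, parental covariances at the published
#' age-adjusted parental block, residual variances chosen so implied
#' offspring variances match the published values (transmission-explained
#' variance subtracted, floored at 10% of the total), within-person
#' residual correlations at the published offspring values, and sibling
#' residual correlations at 0.3 (same trait) / -0.05 (cross trait) -- the
#' latter two are plumbing defaults, not published quantities, and can be
#' overridden.
#'
#' @return Named numeric vector over all model cells (natural scale).
#' @export
default_cell_values <- function() {
  compiled <- compile_model(full_model())
  v <- numeric(nrow(compiled$cells))
  names(v) <- compiled$cells$cell

  # transmission: parsimonious-model pattern
  tr <- .transmission_ref
  for (os in c("son", "daughter")) {
    for (ps in c("father", "mother")) {
      bb <- if (ps == "father") tr[["pat_bmi_bmi"]] else {
        if (os == "son") tr[["mat_bmi_son_bmi"]] else tr[["mat_bmi_daughter_bmi"]]
      }
      v[paste("b", ps, "bmi", os, "bmi", sep = "_")] <- bb
      v[paste("b", ps, "ea", os, "bmi", sep = "_")] <- tr[["ea_bmi"]]
      v[paste("b", ps, "ea", os, "ea", sep = "_")] <- tr[["ea_ea"]]
      v[paste("b", ps, "bmi", os, "ea", sep = "_")] <- tr[["bmi_ea"]]
    }
  }

  SP <- .parental_cov_ref
  v[paste0("var_", .parent_vars)] <- diag(SP)
  ppairs <- utils::combn(.parent_vars, 2)
  for (j in seq_len(ncol(ppairs))) {
    a <- ppairs[1, j]; b <- ppairs[2, j]
    v[paste("rho_p", a, b, sep = "_")] <- SP[a, b] / sqrt(SP[a, a] * SP[b, b])
  }

  # residual variances: reference offspring variance minus what the
  # transmission rows explain, floored at 10% of the total
  B <- matrix(v[compiled$B_idx], 12, 4)
  explained <- diag(B %*% SP %*% t(B))
  names(explained) <- .resid_names
  for (os in c("son", "daughter")) {
    for (t in c("bmi", "ea")) {
      tot <- .offspring_var_ref[[paste(os, t, sep = "_")]]
      expl <- explained[[paste0(os, "1_", t)]]
      v[paste("rvar", os, t, sep = "_")] <- max(tot - expl, 0.1 * tot)
    }
  }
  v["rho_wp_son"] <- .resid_wp_corr_ref[["son"]]
  v["rho_wp_daughter"] <- .resid_wp_corr_ref[["daughter"]]

  sib <- compiled$cells$cell[compiled$cells$block == "resid_sib_corr"]
  trait_of <- function(x) sub("^.*_", "", x)
  first_var <- sub("^rho_r_", "", sib)
  av <- sub("_(son|daughter)[0-9]_(bmi|ea)$", "", first_var)
  bv <- sub("^(son|daughter)[0-9]_(bmi|ea)_", "", first_var)
  same_trait <- trait_of(av) == trait_of(bv)
  v[sib[same_trait]] <- 0.3
  v[sib[!same_trait]] <- -0.05

  rd <- .role_descriptives
  mu_bmi <- stats::setNames(rd$bmi_mean, rd$role)
  mu_ea <- .ea_mean_ref
  v["mu_father_bmi"] <- mu_bmi[["father"]]
  v["mu_father_ea"] <- mu_ea[["father"]]
  v["mu_mother_bmi"] <- mu_bmi[["mother"]]
  v["mu_mother_ea"] <- mu_ea[["mother"]]
  mu_P <- v[paste0("mu_", .parent_vars)]
  for (os in c("son", "daughter")) {
    for (t in c("bmi", "ea")) {
      target <- if (t == "bmi") mu_bmi[[os]] else mu_ea[[os]]
      brow <- B[match(paste0(os, "1_", t), .resid_names), ]
      v[paste("alpha", os, t, sep = "_")] <- target - sum(brow * mu_P)
    }
  }
  v
}

#' Reference free-parameter vector for a model
#'
#' Collapses [default_cell_values()] onto a model's free equality classes
#' (cells sharing a class must share the same default).
#'
#' @param model A `transmission_model`.
#' @return Named theta vector over the model's free classes.
#' @export
reference_parameters <- function(model = model2()) {
  compiled <- compile_model(model)
  v <- default_cell_values()
  free <- compiled$cell_to_free > 0L
  theta <- as.numeric(tapply(v[free], compiled$cell_to_free[free], mean))
  names(theta) <- compiled$classes
  theta
}

#' Configure the synthetic-family generator
#'
#' Defaults mirror the reference cohort: 18% of families have only the
#' parental generation, 45% offspring without parents, 18% offspring with
#' one parent, 19% offspring with both parents; two offspring per family
#' with independent fair genders; an 18% chance per person of the short
#' survey form (which lacks EA); role-specific normal age distributions
#' truncated at 16 years.
#'
#' @param n_families Number of families to generate.
#' @param params Cell-value vector as from [default_cell_values()]
#'   (entries may be overridden by name).
#' @param composition Probabilities of the four family compositions
#'   (`parents_only`, `offspring_only`, `one_parent`, `two_parents`);
#'   must sum to 1.
#' @param n_offspring Offspring per offspring-containing family (0-6;
#'   counts above 3 per gender are truncated at 3).
#' @param offspring_genders Optional fixed composition
#'   `c(n_sons = ..., n_daughters = ...)` overriding random genders.
#' @param ea_missing_prob Per-person probability of the short survey form.
#' @param age_min Lower truncation for ages (years).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(n_families,
                              params = default_cell_values(),
                              composition = c(parents_only = 0.18,
                                              offspring_only = 0.45,
                                              one_parent = 0.18,
                                              two_parents = 0.19),
                              n_offspring = 2L,
                              offspring_genders = NULL,
                              ea_missing_prob = 0.18,
                              age_min = 16,
                              seed = 1L) {
  stopifnot(n_families >= 1)
  comp_names <- c("parents_only", "offspring_only", "one_parent", "two_parents")
  if (!setequal(names(composition), comp_names)) {
    stop("composition must have probabilities for: ",
         paste(comp_names, collapse = ", "), call. = FALSE)
  }
  composition <- composition[comp_names]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-12) {
    stop("composition probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.null(offspring_genders)) {
    stopifnot(setequal(names(offspring_genders), c("n_sons", "n_daughters")),
              all(offspring_genders >= 0), all(offspring_genders <= 3))
  }
  stopifnot(n_offspring >= 0, n_offspring <= 6,
            ea_missing_prob >= 0, ea_missing_prob <= 1)
  structure(
    list(n_families = as.integer(n_families), params = params,
         composition = composition, n_offspring = as.integer(n_offspring),
         offspring_genders = offspring_genders,
         ea_missing_prob = ea_missing_prob, age_min = age_min,
         seed = as.integer(seed)),
    class = "family_sim_config"
  )
}

#' A configuration for fully observed families
#'
#' Convenience wrapper: every family has both parents plus a fixed
#' offspring composition, no short-survey EA missingness.
#'
#' @param n_families Number of families.
#' @param n_sons,n_daughters Offspring per family (0-3 each).
#' @param ... Passed to [family_sim_config()].
#' @return A `family_sim_config`.
#' @export
complete_families_config <- function(n_families, n_sons = 1L, n_daughters = 1L, ...) {
  family_sim_config(
    n_families,
    composition = c(parents_only = 0, offspring_only = 0,
                    one_parent = 0, two_parents = 1),
    n_offspring = n_sons + n_daughters,
    offspring_genders = c(n_sons = n_sons, n_daughters = n_daughters),
    ea_missing_prob = 0,
    ...
  )
}

rtnorm_min <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo))
}

#' Generate a synthetic family dataset
#'
#' @param cfg A [family_sim_config()].
#' @return A [family_dataset()]; the configuration (including the seed) is
#'   attached as attribute `sim_config`.  Families that would end up with
#'   zero observed phenotypes are dropped and counted in the exclusion
#'   log.
#' @examples
#' ds <- simulate_families(family_sim_config(200, seed = 42))
#' ds
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "family_sim_config"))
  compiled <- compile_model(full_model())
  par <- assemble_parameters(compiled, cfg$params[compiled$cells$cell])
  for (blk in list(par$Sigma_P, par$Sigma_E)) {
    ok <- tryCatch({ chol(blk); TRUE }, error = function(e) FALSE)
    if (!ok) stop("configured covariance block is not positive definite",
                  call. = FALSE)
  }
  n <- cfg$n_families

  withr::with_seed(cfg$seed, {
    P <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(par$Sigma_P)
    P <- sweep(P, 2, par$mu_P, "+")
    E <- matrix(stats::rnorm(n * 12), n, 12) %*% chol(par$Sigma_E)
    O <- sweep(P %*% t(par$B), 2, par$alpha, "+") + E
    colnames(P) <- .parent_vars
    colnames(O) <- .resid_names

    comp <- sample(names(cfg$composition), n, replace = TRUE,
                   prob = cfg$composition)
    father_present <- comp %in% c("parents_only", "two_parents")
    mother_present <- father_present
    one_par_is_father <- stats::runif(n) < 0.5
    father_present[comp == "one_parent"] <- one_par_is_father[comp == "one_parent"]
    mother_present[comp == "one_parent"] <- !one_par_is_father[comp == "one_parent"]

    if (!is.null(cfg$offspring_genders)) {
      n_sons <- rep(cfg$offspring_genders[["n_sons"]], n)
      n_daughters <- rep(cfg$offspring_genders[["n_daughters"]], n)
    } else {
      n_sons <- stats::rbinom(n, cfg$n_offspring, 0.5)
      n_daughters <- cfg$n_offspring - n_sons
      n_sons <- pmin(n_sons, 3L)
      n_daughters <- pmin(n_daughters, 3L)
    }
    has_off <- comp != "parents_only"
    n_sons[!has_off] <- 0L
    n_daughters[!has_off] <- 0L

    fam_id <- sprintf("F%06d", seq_len(n))
    rd <- .role_descriptives
    make_member <- function(role, idx, present) {
      if (!any(present)) return(NULL)
      m <- sum(present)
      bmi_col <- paste0(if (is.na(idx)) role else paste0(role, idx), "_bmi")
      ea_col <- paste0(if (is.na(idx)) role else paste0(role, idx), "_ea")
      src <- if (role %in% c("father", "mother")) P else O
      d <- rd[rd$role == role, ]
      age <- rtnorm_min(m, d$age_mean, d$age_sd, cfg$age_min)
      ea <- src[present, ea_col]
      ea[stats::runif(m) < cfg$ea_missing_prob] <- NA_real_
      tibble::tibble(
        family_id = fam_id[present],
        person_id = paste0(fam_id[present], "_", role,
                           if (is.na(idx)) "" else idx),
        role = role,
        birth_index = if (is.na(idx)) NA_integer_ else as.integer(idx),
        age = age,
        bmi = src[present, bmi_col],
        ea = ea
      )
    }
    members <- list(
      make_member("father", NA, father_present),
      make_member("mother", NA, mother_present)
    )
    for (k in 1:3) {
      members <- c(members,
                   list(make_member("son", k, n_sons >= k),
                        make_member("daughter", k, n_daughters >= k)))
    }
    persons <- dplyr::bind_rows(members)
    persons <- persons[order(persons$family_id, persons$person_id), ]
  })

  # drop families whose every phenotype ended up missing
  obs_any <- tapply(!is.na(persons$bmi) | !is.na(persons$ea),
                    persons$family_id, any)
  empty_fams <- names(obs_any)[!obs_any]
  if (length(empty_fams)) {
    persons <- persons[!persons$family_id %in% empty_fams, ]
  }
  ds <- family_dataset(persons)
  ds <- log_filter(ds, "simulated_empty_families_dropped",
                   n_persons_dropped = length(empty_fams))
  attr(ds, "sim_config") <- cfg
  ds
}

#' Parameter-recovery experiment
#'
#' Repeats generate-and-fit `n_replicates` times (replicate r uses seed
#' `cfg$seed + r`) and summarizes, per identified free parameter: the
#' generating truth, mean estimate, empirical SD, bias, and the coverage
#' of the Wald 95% confidence interval.
#'
#' @param cfg A [family_sim_config()].
#' @param model The `transmission_model` to fit.
#' @param n_replicates Number of replicates.
#' @param se Compute SEs (needed for coverage).
#' @return A list with `summary` (tibble per parameter), `n_failed`
#'   (replicates whose fit failed or did not converge; excluded from
#'   summaries), and `fits` (the per-replicate tidy estimates).
#' @export
recovery_experiment <- function(cfg, model = model2(), n_replicates = 10L,
                                se = TRUE) {
  stopifnot(inherits(cfg, "family_sim_config"))
  truth <- reference_parameters_from(cfg$params, model)
  reps <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    fit <- tryCatch({
      ds <- simulate_families(cfg_r)
      f <- fit_fiml(model, ds, se = se)
      if (!f$converged) stop("not converged")
      f
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    td <- tidy(fit)
    td$replicate <- r
    reps[[r]] <- td
  }
  est <- dplyr::bind_rows(reps)
  if (nrow(est) == 0L) stop("all replicates failed", call. = FALSE)
  est <- est[est$identified, ]
  est$truth <- truth[est$term]
  smry <- dplyr::summarise(
    dplyr::group_by(est, .data$term),
    truth = .data$truth[1],
    mean_estimate = mean(.data$estimate),
    empirical_sd = stats::sd(.data$estimate),
    bias = mean(.data$estimate) - .data$truth[1],
    coverage = if (se) mean(.data$conf.low <= .data$truth &
                            .data$truth <= .data$conf.high) else NA_real_,
    .groups = "drop"
  )
  list(summary = smry, n_failed = n_failed, fits = est)
}

# collapse a cell-value vector to a model's free classes
reference_parameters_from <- function(values, model) {
  compiled <- compile_model(model)
  free <- compiled$cell_to_free > 0L
  theta <- as.numeric(tapply(values[compiled$cells$cell][free],
                             compiled$cell_to_free[free], mean))
  names(theta) <- compiled$classes
  theta
}
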