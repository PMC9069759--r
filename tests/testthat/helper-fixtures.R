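# Shared fixtures and independent oracles.

# --- small hand-built family tables -------------------------------------

nuclear_family_persons <- function() {
  tibble::tibble(
    family_id = "f1",
    person_id = c("p1", "p2", "p3", "p4"),
    role = c("father", "mother", "son", "daughter"),
    birth_index = c(NA, NA, 1L, 1L),
    age = c(56, 53, 29, 27),
    bmi = c(26.4, 24.8, 23.1, 22.0),
    ea = c(6, 4, 7, 6)
  )
}

write_person_csv <- function(persons, path = tempfile(fileext = ".csv")) {
  readr::write_csv(persons, path, progress = FALSE)
  path
}

# --- independent oracles --------------------------------------------------

# multivariate normal log density, written from the definition
oracle_mvn_logdens <- function(x, mu, Sigma) {
  k <- length(x)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
          drop(t(d) %*% solve(Sigma) %*% d))
}

# closed-form maximum of the multivariate normal log-likelihood: at the
# sample mean and 1/n covariance the loglik is -n/2 (k log 2pi + log|S| + k)
oracle_mvn_loglik_max <- function(X) {
  n <- nrow(X)
  k <- ncol(X)
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  -n / 2 * (k * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) + k)
}

# regression (GLS-on-moments) oracle: offspring-on-parent coefficients
# implied by the complete-data sample moments
oracle_regression_b <- function(obs, parent_cols, offspring_cols) {
  S <- stats::cov(obs[, c(parent_cols, offspring_cols)])
  p <- length(parent_cols)
  SPP <- S[1:p, 1:p]
  SOP <- S[(p + 1):(p + length(offspring_cols)), 1:p, drop = FALSE]
  SOP %*% solve(SPP)
}

# --- cached fits (expensive fixtures built once per test run) ------------

.fixture_env <- new.env(parent = emptyenv())

cached_complete_ds <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- simulate_families(complete_families_config(4000, seed = 101))
  }
  .fixture_env$ds
}

cached_model2_fit <- function() {
  if (is.null(.fixture_env$fit_m2)) {
    .fixture_env$fit_m2 <- fit_fiml(model2(), cached_complete_ds(), se = TRUE)
  }
  .fixture_env$fit_m2
}

cached_full_fit <- function() {
  if (is.null(.fixture_env$fit_full)) {
    .fixture_env$fit_full <- fit_fiml(full_model(), cached_complete_ds(), se = FALSE)
  }
  .fixture_env$fit_full
}

cached_saturated_fit <- function() {
  if (is.null(.fixture_env$fit_sat)) {
    .fixture_env$fit_sat <- fit_saturated(cached_complete_ds())
  }
  .fixture_env$fit_sat
}

# --- printed summary table used by the covariance/correlation round trip --
# 6x6 age-adjusted covariance (upper triangle incl. diagonal) and the
# printed correlations (lower triangle), per offspring sex; variable order:
# offspring BMI, offspring EA, paternal BMI, maternal BMI, paternal EA,
# maternal EA.
published_cov_table <- function(sex = c("son", "daughter")) {
  sex <- match.arg(sex)
  vars <- c("off_bmi", "off_ea", "pat_bmi", "mat_bmi", "pat_ea", "mat_ea")
  if (sex == "son") {
    variances <- c(9.298, 2.796, 10.492, 19.630, 3.350, 2.593)
    cov_upper <- c(
      -0.791, 1.804, 1.927, -0.405, -0.269,  # off_bmi row
      -0.384, -0.837, 0.860, 0.597,          # off_ea row
      3.277, -0.606, -0.583,                 # pat_bmi row
      -1.402, -1.050,                        # mat_bmi row
      1.509                                  # pat_ea row
    )
    corr_lower <- c(
      -0.154, 0.183, 0.143, -0.073, -0.055,
      -0.071, -0.112, 0.279, 0.220,
      0.228, -0.102, -0.112,
      -0.173, -0.147,
      0.512
    )
  } else {
    variances <- c(13.268, 2.329, 10.492, 19.630, 3.350, 2.593)
    cov_upper <- c(
      -0.965, 2.264, 3.432, -0.434, -0.416,
      -0.436, -0.410, 0.629, 0.651,
      3.277, -0.606, -0.583,
      -1.402, -1.050,
      1.509
    )
    corr_lower <- c(
      -0.173, 0.192, 0.213, -0.065, -0.071,
      -0.088, -0.061, 0.225, 0.265,
      0.228, -0.102, -0.112,
      -0.173, -0.147,
      0.512
    )
  }
  # combn enumerates pairs (1,2),(1,3),...,(5,6): the row-major upper
  # triangle, matching the order the values are listed in above
  pairs <- t(utils::combn(6, 2))
  tibble::tibble(
    var_a = vars[pairs[, 1]],
    var_b = vars[pairs[, 2]],
    covariance = cov_upper,
    var_a_value = variances[pairs[, 1]],
    var_b_value = variances[pairs[, 2]],
    printed_correlation = corr_lower
  )
}
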