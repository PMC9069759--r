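# Reference calibration: published summary statistics from a large Dutch
# twin-family cohort (NTR-like), used as generator defaults and as start
# values in examples.  Phenotypes are on the age-adjusted scale.

# Age-adjusted parental covariance matrix over
# (father BMI, father EA, mother BMI, mother EA).
.parental_cov_ref <- local({
  m <- matrix(c(
    10.492, -0.606,  3.277, -0.583,
    -0.606,  3.350, -1.402,  1.509,
     3.277, -1.402, 19.630, -1.050,
    -0.583,  1.509, -1.050,  2.593
  ), 4, 4, byrow = TRUE)
  dimnames(m) <- list(.slot_names[1:4], .slot_names[1:4])
  m
})

# Age-adjusted offspring phenotype variances by sex and trait.
.offspring_var_ref <- c(
  son_bmi = 9.298, son_ea = 2.796,
  daughter_bmi = 13.268, daughter_ea = 2.329
)

# Within-person residual EA-BMI correlations in the offspring generation.
.resid_wp_corr_ref <- c(son = -0.097, daughter = -0.104)

# Parsimonious-model transmission coefficients (raw, offspring-trait units
# per parent-trait unit): paternal BMI -> offspring BMI shared across
# offspring gender; maternal BMI -> offspring BMI differs by offspring
# gender; cross-trait and EA -> EA coefficients shared across parent and
# offspring gender.
.transmission_ref <- c(
  pat_bmi_bmi = 0.212,
  mat_bmi_son_bmi = 0.098,
  mat_bmi_daughter_bmi = 0.209,
  ea_bmi = -0.066,
  ea_ea = 0.201,
  bmi_ea = -0.024
)

# Descriptives per role: age distribution and unadjusted trait means.
# EA means are derived from the 8-level attainment distribution below.
.role_descriptives <- tibble::tibble(
  role = c("father", "mother", "son", "daughter"),
  age_mean = c(55.88, 53.01, 31.64, 31.91),
  age_sd = c(7.90, 8.04, 14.74, 14.35),
  bmi_mean = c(26.10, 25.66, 23.53, 23.06)
)

# Percentage of persons at each EA level (levels 1-8) per role.
.ea_level_pct <- matrix(c(
  # father, mother, son, daughter
  1.7,  2.3, 1.1, 1.3,
  13.2, 11.3, 7.5, 6.3,
  9.1, 19.5, 6.1, 9.2,
  20.0, 23.1, 20.8, 27.3,
  5.3,  8.7, 2.9, 4.9,
  27.9, 25.5, 29.3, 29.1,
  18.8,  8.9, 25.7, 18.4,
  4.1,  0.8, 6.6, 3.6
), nrow = 8, byrow = TRUE,
  dimnames = list(NULL, c("father", "mother", "son", "daughter")))

.ea_mean_ref <- drop(crossprod(.ea_level_pct / 100, 1:8))[c("father", "mother", "son", "daughter")]

#' Reference calibration constants
#'
#' Summary statistics of age-adjusted BMI and EA in a large Dutch
#' twin-family cohort, used as the default parameterization of the
#' synthetic-family generator ([family_sim_config()]) and in examples:
#' the parental 4x4 covariance matrix, offspring phenotype variances,
#' within-person residual EA-BMI correlations, parsimonious-model
#' transmission coefficients, and per-role age/trait descriptives.
#'
#' @return A named list with elements `parental_cov` (4x4 matrix),
#'   `offspring_var`, `resid_wp_corr`, `transmission`, `role_descriptives`
#'   (tibble), `ea_level_pct` (8x4 matrix of percentages) and `ea_mean`.
#' @examples
#' reference_calibration()$parental_cov
#' @export
reference_calibration <- function() {
  list(
    parental_cov = .parental_cov_ref,
    offspring_var = .offspring_var_ref,
    resid_wp_corr = .resid_wp_corr_ref,
    transmission = .transmission_ref,
    role_descriptives = .role_descriptives,
    ea_level_pct = .ea_level_pct,
    ea_mean = .ea_mean_ref
  )
}
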