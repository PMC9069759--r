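test_that("standardization scales by parent over offspring SD", {
  expect_identical(standardize_coefficient(1, 2.5, 2.5), 1)
  # published raw paternal BMI coefficient against the observed variances
  expect_lt(abs(standardize_coefficient(0.192, sqrt(10.492), sqrt(9.298)) - 0.204),
            5e-4)
  # scale invariance: rescaling the parent variable leaves the
  # standardized coefficient unchanged
  c_ <- 3.7
  expect_equal(standardize_coefficient(0.192 / c_, c_ * sqrt(10.492), sqrt(9.298)),
               standardize_coefficient(0.192, sqrt(10.492), sqrt(9.298)),
               tolerance = 1e-12)
  expect_error(standardize_coefficient(1, -1, 2), "positive")
})

test_that("path decomposition sums correlation-weighted cross paths", {
  # uncorrelated parents: indirect vanishes
  sb <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("bmi", "ea")))
  dec0 <- decompose_effects(sb, diag(4))
  expect_true(all(dec0$indirect == 0))
  expect_equal(dec0$total, dec0$direct)

  # published son-BMI row: direct 0.207 plus three indirect paths
  R <- diag(4)
  R[1, 3] <- R[3, 1] <- 0.228   # paternal BMI - maternal BMI
  R[1, 2] <- R[2, 1] <- -0.102  # paternal BMI - paternal EA
  R[1, 4] <- R[4, 1] <- -0.112  # paternal BMI - maternal EA
  sb2 <- matrix(0, 4, 1)
  sb2[1, 1] <- 0.207   # paternal BMI direct
  sb2[2, 1] <- -0.040  # paternal EA
  sb2[3, 1] <- 0.154   # maternal BMI
  sb2[4, 1] <- -0.030  # maternal EA
  dec <- decompose_effects(sb2, R)
  row <- dec[dec$parent_var == "father_bmi", ]
  expect_lt(abs(row$indirect - 0.043), 1e-3)
  expect_lt(abs(row$total - 0.250), 1e-3)

  # the sum over the three other parental variables is order-invariant
  perm <- c(1, 4, 2, 3)
  dec_p <- decompose_effects(sb2[perm, , drop = FALSE], R[perm, perm])
  expect_equal(dec_p$indirect[dec_p$parent_var == "father_bmi"], row$indirect,
               tolerance = 1e-12)

  expect_error(decompose_effects(sb2, matrix(0.5, 4, 4)), "unit diagonal")
})

test_that("effect tables satisfy total = direct + indirect exactly", {
  et <- effect_table(cached_model2_fit())
  expect_identical(nrow(tibble::as_tibble(et)), 16L)
  expect_true(all(et$total == et$std_estimate + et$indirect))
  # additivity at full precision, not merely to rounding
  expect_lt(max(abs(et$total - (et$std_estimate + et$indirect))), 1e-12)
  # CIs bracket estimates on both scales
  expect_true(all(et$conf.low <= et$estimate & et$estimate <= et$conf.high))
  expect_true(all(pmin(et$std_conf.low, et$std_conf.high) <= et$std_estimate &
                  et$std_estimate <= pmax(et$std_conf.low, et$std_conf.high)))
})

test_that("standardized effects are invariant to the raw measurement scale", {
  # refit with parental BMI rescaled (kg/m^2 -> arbitrary units x 10)
  ds <- cached_complete_ds()
  p <- ds$persons
  p$bmi[p$role %in% c("father", "mother")] <- p$bmi[p$role %in% c("father", "mother")] / 10
  fit_scaled <- fit_fiml(model2(), family_dataset(p), se = FALSE)
  et0 <- effect_table(cached_model2_fit())
  et1 <- effect_table(fit_scaled)
  key <- paste(et0$offspring_sex, et0$offspring_trait, et0$parent_sex, et0$parent_trait)
  key1 <- paste(et1$offspring_sex, et1$offspring_trait, et1$parent_sex, et1$parent_trait)
  bmi_rows <- et0$parent_trait == "bmi"
  # raw coefficients rescale by the factor; standardized ones do not
  expect_equal(et1$std_estimate[match(key[bmi_rows], key1)],
               et0$std_estimate[bmi_rows], tolerance = 1e-4)
  expect_equal(et1$estimate[match(key[bmi_rows], key1)],
               10 * et0$estimate[bmi_rows], tolerance = 1e-3)
})

test_that("residual EA-BMI association recovers the generating correlation", {
  fit <- cached_model2_fit()
  for (sex in c("son", "daughter")) {
    res <- residual_ea_bmi_correlation(fit, sex)
    truth <- reference_calibration()$resid_wp_corr[[sex]]
    expect_lt(abs(res$correlation - truth), 0.05)  # n = 4,000 families
    expect_true(res$correlation > -1 && res$correlation < 1)
    # covariance and correlation are linked by the residual variances
    s_prod <- sqrt(fit$theta[[paste0("rvar_", sex, "_bmi")]] *
                   fit$theta[[paste0("rvar_", sex, "_ea")]])
    expect_equal(res$covariance, res$correlation * s_prod, tolerance = 1e-12)
  }
})

test_that("effect tables export to CSV with residual companion rows", {
  et <- effect_table(cached_model2_fit())
  path <- tempfile(fileext = ".csv")
  rpath <- tempfile(fileext = ".csv")
  write_effect_table(et, path, residual_path = rpath)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(back), 16L)
  expect_equal(back$total, unname(et$total), tolerance = 1e-12)
  rback <- readr::read_csv(rpath, show_col_types = FALSE)
  expect_identical(rback$offspring_sex, c("son", "daughter"))
})
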