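test_that("generation is deterministic given the seed", {
  cfg <- family_sim_config(400, seed = 11)
  d1 <- simulate_families(cfg)
  d2 <- simulate_families(cfg)
  expect_identical(d1$persons, d2$persons)
  # byte-for-byte after serialization
  p1 <- tempfile(); p2 <- tempfile()
  write_families(d1, p1); write_families(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the data
  d3 <- simulate_families(family_sim_config(400, seed = 12))
  expect_false(identical(d1$persons$bmi, d3$persons$bmi))
})

test_that("null transmission yields null parent-offspring correlations", {
  v <- default_cell_values()
  v[grepl("^b_", names(v))] <- 0
  # with no transmission the intercepts are the offspring means themselves
  rd <- reference_calibration()$role_descriptives
  v["alpha_son_bmi"] <- rd$bmi_mean[rd$role == "son"]
  v["alpha_daughter_bmi"] <- rd$bmi_mean[rd$role == "daughter"]
  v["alpha_son_ea"] <- reference_calibration()$ea_mean[["son"]]
  v["alpha_daughter_ea"] <- reference_calibration()$ea_mean[["daughter"]]
  ds <- simulate_families(complete_families_config(30000, params = v, seed = 31))
  om <- family_observations(ds)
  obs <- om$observation
  for (pv in c("father_bmi", "mother_ea")) {
    for (ov in c("son1_bmi", "son1_ea", "daughter1_bmi", "daughter1_ea")) {
      expect_lt(abs(cor(obs[, pv], obs[, ov])), 0.02)
    }
  }
})

test_that("spousal EA correlation matches the configured parental block", {
  cfg <- family_sim_config(
    100000,
    composition = c(parents_only = 1, offspring_only = 0,
                    one_parent = 0, two_parents = 0),
    ea_missing_prob = 0, seed = 37
  )
  ds <- simulate_families(cfg)
  om <- family_observations(ds)
  r <- cor(om$observation[, "father_ea"], om$observation[, "mother_ea"])
  expect_lt(abs(r - 0.512), 0.01)
})

test_that("complete-data sample moments converge to the implied moments", {
  n <- 100000
  ds <- simulate_families(complete_families_config(n, seed = 41))
  om <- family_observations(ds)
  slots <- colnames(om$observation)[colSums(om$mask) > 0]
  obs <- om$observation[, slots]
  mom <- implied_moments(full_model(), reference_parameters(full_model()))
  S <- cov(obs)
  Sigma <- mom$cov[slots, slots]
  # asymptotic SE of a normal covariance: sqrt((s_ii s_jj + s_ij^2)/n)
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n)
  expect_lt(max(abs(S - Sigma) / se), 3.9)
  mu_se <- sqrt(diag(Sigma) / n)
  expect_lt(max(abs(colMeans(obs) - mom$mean[slots]) / mu_se), 3.9)
})

test_that("composition and gender frequencies follow the configuration", {
  ds <- simulate_families(family_sim_config(20000, seed = 43))
  p <- ds$persons
  roles_by_family <- split(p$role, p$family_id)
  n_fam <- length(roles_by_family)
  has_father <- vapply(roles_by_family, function(r) "father" %in% r, logical(1))
  has_mother <- vapply(roles_by_family, function(r) "mother" %in% r, logical(1))
  has_off <- vapply(roles_by_family, function(r) any(r %in% c("son", "daughter")),
                    logical(1))
  expect_lt(abs(mean(!has_off) - 0.18), 0.01)                      # parents only
  expect_lt(abs(mean(has_off & !has_father & !has_mother) - 0.45), 0.01)
  expect_lt(abs(mean(has_off & xor(has_father, has_mother)) - 0.18), 0.01)
  expect_lt(abs(mean(has_off & has_father & has_mother) - 0.19), 0.01)
  # offspring gender marginal is fair
  off <- p$role[p$role %in% c("son", "daughter")]
  expect_lt(abs(mean(off == "son") - 0.5), 0.01)
  # short-survey EA missingness near the configured rate
  expect_lt(abs(mean(is.na(p$ea)) - 0.18), 0.01)
  # ages respect the truncation floor
  expect_gte(min(p$age), 16)
})

test_that("every generated family keeps at least one observed phenotype", {
  ds <- simulate_families(family_sim_config(3000, ea_missing_prob = 1, seed = 47))
  om <- family_observations(ds)
  expect_true(all(rowSums(om$mask) >= 1))
  expect_identical(attr(om, "n_dropped_empty"), 0L)
  expect_identical(exclusion_log(ds)$filter[1], "simulated_empty_families_dropped")
})

test_that("invalid generator configurations are rejected before sampling", {
  expect_error(family_sim_config(10, composition = c(parents_only = 0.5,
                                                     offspring_only = 0.5,
                                                     one_parent = 0.2,
                                                     two_parents = -0.2)),
               "sum to 1|non-negative")
  v <- default_cell_values()
  v[grepl("^rho_r_", names(v))] <- 0.999  # breaks residual-block PSD
  expect_error(simulate_families(complete_families_config(10, params = v, seed = 1)),
               "positive definite")
})

test_that("fits converge under survey-like missingness", {
  cfg <- family_sim_config(1500, seed = 53)
  ok <- 0L
  for (r in 1:4) {
    cfg$seed <- 53L + r
    f <- tryCatch(fit_fiml(model2(), simulate_families(cfg), se = FALSE,
                           polish = FALSE),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
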