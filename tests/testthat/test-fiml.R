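test_that("family log-likelihood matches a hand-written normal density", {
  m2 <- model2()
  th <- reference_parameters(m2)
  mom <- implied_moments(m2, th)

  # fully observed family: 16-dimensional density
  set.seed(7)
  x <- drop(mom$mean + chol(mom$cov) %*% rnorm(16))
  names(x) <- family_slots()$name
  expect_equal(family_loglik(m2, th, x),
               oracle_mvn_logdens(x, mom$mean, mom$cov), tolerance = 1e-10)

  # father BMI only: univariate marginal
  x1 <- rep(NA_real_, 16)
  x1[1] <- 27.3
  expect_equal(family_loglik(m2, th, x1),
               dnorm(27.3, mom$mean[1], sqrt(mom$cov[1, 1]), log = TRUE),
               tolerance = 1e-10)

  # two identical families contribute identically
  expect_identical(family_loglik(m2, th, x), family_loglik(m2, th, x))
  expect_error(family_loglik(m2, th, rep(NA_real_, 16)), "no observed slot")
})

test_that("the analytic FIML score matches central finite differences", {
  ds <- simulate_families(family_sim_config(250, seed = 97))
  om <- family_observations(ds)
  stats <- famtrans:::pattern_stats(om$observation, om$mask)
  for (model in list(full_model(), model2())) {
    compiled <- famtrans:::compile_model(model)
    core <- famtrans:::make_objective(compiled, stats, om$mask)
    th <- famtrans:::align_theta(compiled, reference_parameters(model))
    expect_lt(core$negll(th), 1e9)  # reference point is feasible
    g_an <- core$grad(th)
    g_num <- famtrans:::num_gradient(core$negll, th, h = 1e-6)
    expect_lt(max(abs(g_an - g_num)) / max(abs(g_num)), 1e-6)
  }
})

test_that("saturated FIML on complete data equals the sample moments", {
  ds <- simulate_families(complete_families_config(300, seed = 13))
  om <- family_observations(ds)
  obs <- om$observation[, colSums(om$mask) > 0]
  sat <- fit_saturated(ds)
  expect_true(sat$converged)
  expect_equal(unname(sat$mean), unname(colMeans(obs)), tolerance = 1e-6)
  S_ml <- crossprod(sweep(obs, 2, colMeans(obs))) / nrow(obs)
  expect_equal(unname(sat$cov), unname(S_ml), tolerance = 1e-6)
  expect_equal(sat$loglik, oracle_mvn_loglik_max(obs), tolerance = 1e-6)
})

test_that("saturated EM under missingness matches direct ML optimization", {
  # tiny two-variable problem with one-sided missingness: EM vs optim
  set.seed(3)
  n <- 150
  x <- rnorm(n, 25, 3)
  y <- 0.4 * x + rnorm(n, 10, 2)
  y[1:50] <- NA
  p <- tibble::tibble(
    family_id = paste0("f", 1:n), person_id = paste0("p", 1:n),
    role = "father", birth_index = NA_integer_, age = 50,
    bmi = x, ea = y
  )
  sat <- fit_saturated(family_dataset(p))
  nll <- function(par) {
    mu <- par[1:2]
    L <- matrix(c(par[3], par[4], 0, par[5]), 2, 2)
    S <- L %*% t(L)
    ll <- 0
    for (i in seq_len(n)) {
      if (is.na(y[i])) {
        ll <- ll + dnorm(x[i], mu[1], sqrt(S[1, 1]), log = TRUE)
      } else {
        ll <- ll + oracle_mvn_logdens(c(x[i], y[i]), mu, S)
      }
    }
    -ll
  }
  o <- optim(c(mean(x), mean(y, na.rm = TRUE), 3, 1, 2), nll,
             method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(sat$loglik, -o$value, tolerance = 1e-6)
})

test_that("FIML with an unconstrained regression block equals the GLS oracle", {
  ds <- simulate_families(complete_families_config(800, seed = 17))
  fit <- fit_fiml(full_model(), ds, se = FALSE)
  expect_true(fit$converged)
  om <- family_observations(ds)
  obs <- om$observation[, c(1:4, 5, 6, 11, 12)]
  B_hat <- oracle_regression_b(obs, 1:4, 5:8)
  # slot order of B rows: son1_bmi, son1_ea, daughter1_bmi, daughter1_ea
  got <- rbind(
    fit$theta[paste("b", c("father", "father", "mother", "mother"),
                    c("bmi", "ea", "bmi", "ea"), "son", "bmi", sep = "_")],
    fit$theta[paste("b", c("father", "father", "mother", "mother"),
                    c("bmi", "ea", "bmi", "ea"), "son", "ea", sep = "_")],
    fit$theta[paste("b", c("father", "father", "mother", "mother"),
                    c("bmi", "ea", "bmi", "ea"), "daughter", "bmi", sep = "_")],
    fit$theta[paste("b", c("father", "father", "mother", "mother"),
                    c("bmi", "ea", "bmi", "ea"), "daughter", "ea", sep = "_")]
  )
  expect_lt(max(abs(got - B_hat)), 1e-5)
})

test_that("log-likelihoods are ordered by model nesting", {
  ds <- cached_complete_ds()
  sat <- cached_saturated_fit()
  f_full <- cached_full_fit()
  f_m2 <- cached_model2_fit()
  expect_gte(sat$loglik + 1e-6, f_full$loglik)
  expect_gte(f_full$loglik + 1e-6, f_m2$loglik)
})

test_that("pattern-grouped likelihood equals the per-family sum at the optimum", {
  ds <- simulate_families(family_sim_config(250, seed = 23))
  fit <- fit_fiml(model2(), ds, se = FALSE, polish = FALSE)
  om <- family_observations(ds)
  direct <- sum(vapply(seq_len(nrow(om$observation)), function(i) {
    family_loglik(model2(), fit$theta, om$observation[i, ])
  }, numeric(1)))
  expect_equal(fit$loglik, direct, tolerance = 1e-6)

  # hence removing one family changes the total by exactly its contribution
  drop_id <- om$family_id[7]
  ds_minus <- family_dataset(ds$persons[ds$persons$family_id != drop_id, ])
  om_minus <- family_observations(ds_minus)
  minus <- sum(vapply(seq_len(nrow(om_minus$observation)), function(i) {
    family_loglik(model2(), fit$theta, om_minus$observation[i, ])
  }, numeric(1)))
  expect_equal(direct - minus, family_loglik(model2(), fit$theta, om$observation[7, ]),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to family order and sibling slot relabeling", {
  ds <- simulate_families(family_sim_config(300, seed = 29))
  perm <- withr::with_seed(1, sample(nrow(ds$persons)))
  ds_perm <- family_dataset(ds$persons[perm, ])
  expect_equal(fit_saturated(ds)$loglik, fit_saturated(ds_perm)$loglik,
               tolerance = 1e-6)

  # with exchangeable residual parameters, swapping son1/son2 leaves the
  # family likelihood unchanged
  th <- reference_parameters(full_model())
  x <- rep(NA_real_, 16)
  x[c(1:4, 5:8)] <- c(26, 5, 25, 4.4, 23, 5.5, 24, 5.1)  # parents + 2 sons
  x_swap <- x
  x_swap[5:6] <- x[7:8]
  x_swap[7:8] <- x[5:6]
  expect_equal(family_loglik(full_model(), th, x),
               family_loglik(full_model(), th, x_swap), tolerance = 1e-10)
})

test_that("unidentified parameter classes are reported as dropped", {
  ds <- cached_complete_ds()  # one son + one daughter per family
  fit <- cached_model2_fit()
  expect_identical(fit$n_free_identified, 34L)
  expect_identical(length(fit$dropped), 56L)  # sibling pairs of empty slots
  expect_true(all(grepl("^rho_r_", fit$dropped)))
  expect_true(all(is.na(fit$se[fit$dropped])))
  expect_true(all(!is.na(fit$se[fit$identified])))
})

test_that("Wald intervals bracket the estimates and fit indices behave", {
  fit <- cached_model2_fit()
  id <- fit$identified
  expect_true(all(fit$ci_lower[id] <= fit$theta[id]))
  expect_true(all(fit$theta[id] <= fit$ci_upper[id]))

  sat <- cached_saturated_fit()
  idx <- fit_indices(fit, sat)
  expect_gte(idx$chi_square, 0)
  expect_gte(idx$rmsea, 0)
  # 8 observed slots: 8 + 36 = 44 moments, minus 34 identified parameters
  expect_identical(idx$df, 10L)
  # data generated from the model: good fit expected at this size
  expect_lt(idx$rmsea, 0.05)

  # a model compared against itself as its own reference: chi-square 0
  sat2 <- cached_saturated_fit()
  expect_equal(fit_indices(fit, sat2)$chi_square, idx$chi_square)
  expect_error(fit_indices(fit, fit_saturated(simulate_families(
    complete_families_config(50, seed = 1)))), "same dataset")
})

test_that("model-2 estimates are unbiased with valid interval coverage", {
  cfg <- complete_families_config(5000, seed = 300)
  rec <- recovery_experiment(cfg, model2(), n_replicates = 20, se = TRUE)
  expect_identical(rec$n_failed, 0L)
  s <- rec$summary
  mc_se <- s$empirical_sd / sqrt(20)
  expect_true(all(abs(s$bias) < pmax(3.5 * mc_se, 1e-6)))
  tr <- s[grepl("^b_", s$term), ]
  expect_lt(max(abs(tr$bias)), 0.02)
  expect_true(all(s$coverage >= 0.75))
})
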