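test_that("education labels and Dutch aliases map to the 8-level scale", {
  expect_identical(encode_ea("Elementary school"), 1L)
  expect_identical(encode_ea("PhD degree"), 8L)
  expect_identical(encode_ea("Mbo"), 4L)
  expect_identical(encode_ea(c("mbo", "HAVO", "hbo")), c(4L, 5L, 6L))
  expect_identical(encode_ea("Post-graduate degree"), 8L)
  expect_error(encode_ea("night school"), "unrecognized")
  expect_identical(nrow(ea_scale()), 8L)
})

test_that("CSV ingestion builds canonical observation vectors and masks", {
  path <- write_person_csv(nuclear_family_persons())
  ds <- read_families(path)
  expect_identical(n_families(ds), 1L)
  om <- family_observations(ds)
  expect_identical(sum(om$mask), 8L)  # 4 persons x 2 traits
  expect_true(all(om$mask[1, c("father_bmi", "father_ea", "mother_bmi",
                               "mother_ea", "son1_bmi", "son1_ea",
                               "daughter1_bmi", "daughter1_ea")]))
  expect_identical(unname(om$observation[1, "son1_ea"]), 7)

  # parents-only family: only the 4 parental slots are observed
  parents <- nuclear_family_persons()[1:2, ]
  ds2 <- read_families(write_person_csv(parents))
  om2 <- family_observations(ds2)
  expect_identical(unname(which(om2$mask[1, ])), 1:4)

  # header-only file: empty dataset, no error
  empty_path <- tempfile(fileext = ".csv")
  writeLines("family_id,person_id,role,birth_index,age,bmi,ea", empty_path)
  expect_identical(n_families(read_families(empty_path)), 0L)
})

test_that("EA labels in CSVs are encoded, and schema remapping works", {
  persons <- nuclear_family_persons()
  persons$ea <- c("Hbo", "Mbo", "University degree", "Havo")
  path <- write_person_csv(persons)
  ds <- read_families(path)
  expect_identical(ds$persons$ea, c(6, 4, 7, 5))

  renamed <- nuclear_family_persons()
  names(renamed)[names(renamed) == "bmi"] <- "body_mass_index"
  ds2 <- read_families(write_person_csv(renamed), schema = c(bmi = "body_mass_index"))
  expect_identical(ds2$persons$bmi, nuclear_family_persons()$bmi)
})

test_that("write/read round trip reproduces the persons table", {
  ds <- simulate_families(family_sim_config(60, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_families(ds, path)
  back <- read_families(path)
  expect_equal(back$persons, ds$persons, tolerance = 1e-12)
})

test_that("structural validation rejects malformed person tables", {
  p <- nuclear_family_persons()
  p$birth_index[1] <- 2L  # father with a birth index
  expect_error(family_dataset(p), "birth_index")
  p2 <- nuclear_family_persons()
  p2$person_id[2] <- "p1"
  p2$role[2] <- "father"
  p2$birth_index[2] <- NA_integer_
  expect_error(family_dataset(p2), "duplicate")
  p3 <- nuclear_family_persons()
  p3$role[3] <- "uncle"
  expect_error(family_dataset(p3), "unknown role")
})

test_that("EA under the attainment age is masked, with exact boundary", {
  p <- nuclear_family_persons()
  p$age[3] <- 24  # son, EA present
  p$age[4] <- 25  # daughter, exactly at the boundary
  ds <- family_dataset(p)
  out <- filter_ea_under_age(ds)
  expect_true(is.na(out$persons$ea[3]))
  expect_identical(out$persons$ea[4], 6)
  expect_identical(exclusion_log(out)$n_values_masked, 1L)

  # idempotence: a second application masks nothing further
  out2 <- filter_ea_under_age(out)
  expect_identical(out2$persons, out$persons)
  expect_identical(dplyr::last(exclusion_log(out2)$n_values_masked), 0L)

  # nobody under the age: identical data, count 0
  none <- filter_ea_under_age(family_dataset(nuclear_family_persons()))
  expect_identical(none$persons, family_dataset(nuclear_family_persons())$persons)
  expect_identical(exclusion_log(none)$n_values_masked, 0L)
})

test_that("extreme BMI masking respects the strict inequalities", {
  p <- nuclear_family_persons()
  p$bmi <- c(14.9, 15.0, 46, 30)
  ds <- family_dataset(p)
  out <- filter_bmi_extremes(ds)
  expect_identical(is.na(out$persons$bmi), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(exclusion_log(out)$n_values_masked, 2L)
  expect_identical(filter_bmi_extremes(out)$persons, out$persons)
  expect_error(filter_bmi_extremes(ds, low = 30, high = 20), "smaller")
})

test_that("offspring capping keeps the oldest per gender and reindexes", {
  p <- tibble::tibble(
    family_id = "f1",
    person_id = paste0("p", 1:6),
    role = c("father", "mother", rep("son", 4)),
    birth_index = c(NA, NA, 1L, 2L, 3L, 4L),
    age = c(60, 58, 30, 28, 25, 20),
    bmi = 25, ea = 5
  )
  ds <- family_dataset(p, allow_excess_offspring = TRUE)
  out <- cap_offspring(ds)
  sons <- out$persons[out$persons$role == "son", ]
  expect_identical(sort(sons$age), c(25, 28, 30))
  expect_identical(sons$birth_index[order(-sons$age)], 1:3)
  expect_identical(dplyr::last(exclusion_log(out)$n_persons_dropped), 1L)

  # families within the cap are untouched
  ok <- family_dataset(nuclear_family_persons())
  expect_identical(cap_offspring(ok)$persons, ok$persons)
})

test_that("age adjustment removes age and age-squared trends per role group", {
  # a trait exactly linear in age leaves zero residuals
  n <- 40
  p <- tibble::tibble(
    family_id = paste0("f", 1:n), person_id = paste0("p", 1:n),
    role = "father", birth_index = NA_integer_,
    age = seq(30, 69, length.out = n),
    bmi = 20 + 0.1 * seq(30, 69, length.out = n),
    ea = NA_real_
  )
  adj <- adjust_for_age(family_dataset(p))
  expect_lt(max(abs(adj$persons$bmi)), 1e-8)

  # constant age: residuals are deviations from the group mean
  p2 <- p
  p2$age <- 50
  p2$bmi <- c(21:(20 + n))
  adj2 <- adjust_for_age(family_dataset(p2))
  expect_equal(adj2$persons$bmi, p2$bmi - mean(p2$bmi), tolerance = 1e-10)

  # noisy group: residual-age correlation and ls slope vanish
  set.seed(42)
  n3 <- 1000
  age3 <- runif(n3, 25, 70)
  p3 <- tibble::tibble(
    family_id = paste0("f", 1:n3), person_id = paste0("p", 1:n3),
    role = "mother", birth_index = NA_integer_,
    age = age3, bmi = 20 + 0.1 * age3 + rnorm(n3), ea = NA_real_
  )
  adj3 <- adjust_for_age(family_dataset(p3))
  r <- adj3$persons$bmi
  expect_lt(abs(cor(r, age3)), 0.07)
  expect_lt(abs(sum((age3 - mean(age3)) * r) / sum((age3 - mean(age3))^2)), 1e-8)

  # too few points in a group is an error naming the group
  few <- family_dataset(nuclear_family_persons()[1, ])
  expect_error(adjust_for_age(few), "father")
})

test_that("covariance-to-correlation reproduces the published parental entries", {
  expect_lt(abs(covariance_to_correlation(-0.606, 10.492, 3.350) - (-0.102)), 5e-4)
  expect_lt(abs(covariance_to_correlation(3.277, 10.492, 19.630) - 0.228), 5e-4)
  expect_identical(covariance_to_correlation(0, 2, 3), 0)
  expect_error(covariance_to_correlation(0.1, -1, 2), "positive")
})

test_that("the full published covariance table round-trips to its correlations", {
  for (sex in c("son", "daughter")) {
    tab <- published_cov_table(sex)
    got <- covariance_to_correlation(tab$covariance, tab$var_a_value, tab$var_b_value)
    # printed rounding allows ~0.001; the offspring EA-BMI cells and (for
    # sons) cells involving offspring EA carry a documented extra ~0.001
    tol <- rep(0.0015, nrow(tab))
    tol[tab$var_a == "off_bmi" & tab$var_b == "off_ea"] <- 0.0025
    if (sex == "son") tol[tab$var_a == "off_ea" | tab$var_b == "off_ea"] <- 0.0025
    expect_true(all(abs(got - tab$printed_correlation) < tol),
                info = paste("sex:", sex))
  }
})
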