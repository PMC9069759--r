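# Likelihood-ratio testing of gender-equality constraints with Bonferroni
# control: for each of the four transmission types (BMI->BMI, EA->EA,
# BMI->EA, EA->BMI), equality across offspring gender and equality across
# parent gender are each tested against the full model; the composed
# final model retains only the inequalities the data support.

#' Bonferroni-adjusted test-wise alpha
#'
#' @param family_alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.01, 8)  # 0.00125
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  if (family_alpha <= 0 || family_alpha >= 1 || n_tests < 1) {
    stop("family_alpha must be in (0,1) and n_tests >= 1", call. = FALSE)
  }
  family_alpha / n_tests
}

#' Likelihood-ratio test of nested FIML fits
#'
#' @param restricted,full `fiml_fit` objects on the same dataset, with the
#'   restricted model nested in the full one.
#' @return One-row tibble: `statistic` (twice the log-likelihood gap,
#'   clipped at 0), `df` (difference in identified free-parameter counts)
#'   and `p.value` from the upper chi-square tail.
#' @export
lrt <- function(restricted, full) {
  stopifnot(inherits(restricted, "fiml_fit"), inherits(full, "fiml_fit"))
  if (!isTRUE(all.equal(restricted$data_signature, full$data_signature,
                        tolerance = 1e-8))) {
    stop("fits are not based on the same dataset", call. = FALSE)
  }
  df <- full$n_free_identified - restricted$n_free_identified
  if (df < 0) stop("models are not nested (restricted has more parameters)",
                   call. = FALSE)
  statistic <- max(2 * (full$loglik - restricted$loglik), 0)
  tibble::tibble(
    statistic = statistic,
    df = as.integer(df),
    p.value = if (df == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  )
}

#' Gender-equality likelihood-ratio test suite
#'
#' Fits the full model, then tests 8 equality constraints against it: for
#' each of the four transmission types (parent BMI -> offspring BMI,
#' EA -> EA, BMI -> EA, EA -> BMI), (a) equality across offspring gender
#' and (b) equality across parent gender.  Each test is judged at the
#' Bonferroni-adjusted level `family_alpha / 8`.  A final model composes
#' the constraints of all non-significant tests jointly and is refitted.
#'
#' @param ds A [family_dataset()].
#' @param family_alpha Family-wise significance level (default 0.01).
#' @param se Compute standard errors for the full and final fits.
#' @return A `comparison_report`: list with `tests` (tibble: constraint,
#'   statistic, df, p.value, significant), `family_alpha`, `test_alpha`,
#'   `full_fit`, `final_fit`, `final_model`.
#' @export
gender_equivalence_suite <- function(ds, family_alpha = 0.01, se = FALSE) {
  stopifnot(inherits(ds, "family_dataset"))
  base <- full_model()
  full_fit <- fit_fiml(base, ds, se = se)
  if (!full_fit$converged) {
    warning("full-model fit did not converge; suite results are partial",
            call. = FALSE)
  }
  test_alpha <- bonferroni_alpha(family_alpha, 8L)

  grid <- tidyr::expand_grid(
    parent_trait = c("bmi", "ea"),
    offspring_trait = c("bmi", "ea"),
    across = c("offspring", "parent")
  )
  results <- vector("list", nrow(grid))
  ok <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- constrain_transmission(base, grid$parent_trait[i], grid$offspring_trait[i],
                                across = grid$across[i])
    fit_i <- tryCatch(fit_fiml(m, ds, se = FALSE), error = function(e) NULL)
    if (is.null(fit_i) || !fit_i$converged) {
      results[[i]] <- tibble::tibble(statistic = NA_real_, df = NA_integer_,
                                     p.value = NA_real_)
      ok[i] <- FALSE
    } else {
      results[[i]] <- lrt(fit_i, full_fit)
      ok[i] <- TRUE
    }
  }
  tests <- dplyr::bind_cols(grid, dplyr::bind_rows(results))
  tests$constraint <- sprintf("%s->%s equal across %s gender",
                              toupper(tests$parent_trait),
                              toupper(tests$offspring_trait),
                              ifelse(tests$across == "offspring", "offspring", "parent"))
  tests$significant <- !is.na(tests$p.value) & tests$p.value < test_alpha
  tests <- tests[, c("constraint", "parent_trait", "offspring_trait", "across",
                     "statistic", "df", "p.value", "significant")]
  if (!all(ok)) {
    warning(sum(!ok), " member fit(s) failed; their tests are flagged NA",
            call. = FALSE)
  }

  final_model <- base
  for (i in seq_len(nrow(grid))) {
    if (ok[i] && !tests$significant[i]) {
      final_model <- constrain_transmission(final_model, grid$parent_trait[i],
                                            grid$offspring_trait[i],
                                            across = grid$across[i])
    }
  }
  final_model$name <- "composed"
  final_fit <- tryCatch(fit_fiml(final_model, ds, se = se), error = function(e) NULL)

  structure(
    list(tests = tests, family_alpha = family_alpha, test_alpha = test_alpha,
         full_fit = full_fit, final_fit = final_fit, final_model = final_model),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> 8 gender-equality LRTs, test-wise alpha ",
      format(x$test_alpha), "\n", sep = "")
  print(x$tests[, c("constraint", "statistic", "df", "p.value", "significant")])
  cat("final model: '", x$final_model$name, "' with ",
      n_free_parameters(x$final_model), " free parameters\n", sep = "")
  invisible(x)
}

#' Serialize a comparison report to JSON
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(
    list(
      family_alpha = report$family_alpha,
      test_alpha = report$test_alpha,
      tests = report$tests,
      final_model = report$final_model$name,
      final_n_free = n_free_parameters(report$final_model)
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
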