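# Family-structured phenotype data: ingestion, validation, filtering,
# age adjustment, and conversion to the canonical 16-slot observation
# matrix consumed by the FIML estimator.

.person_cols <- c("family_id", "person_id", "role", "birth_index", "age", "bmi", "ea")
.roles <- c("father", "mother", "son", "daughter")

empty_exclusion_log <- function() {
  tibble::tibble(
    filter = character(0),
    n_values_masked = integer(0),
    n_persons_dropped = integer(0)
  )
}

#' Construct a family dataset
#'
#' Bundles a one-row-per-person phenotype table with a provenance log of
#' applied filters.  Persons are identified by `family_id`, `role`
#' (father/mother/son/daughter) and, for offspring, a within-gender birth
#' index 1-3.  Missing phenotype values are `NA`; no sentinel values are
#' used.
#'
#' @param persons A data frame with columns `family_id`, `person_id`,
#'   `role`, `birth_index` (NA for parents), `age`, `bmi`, `ea`.
#' @param exclusions Optional provenance log (tibble with columns `filter`,
#'   `n_values_masked`, `n_persons_dropped`).
#' @param allow_excess_offspring Permit more than 3 offspring per gender
#'   per family (intended as input to [cap_offspring()]).
#' @return An object of class `family_dataset`.
#' @seealso [read_families()], [family_observations()]
#' @export
family_dataset <- function(persons, exclusions = empty_exclusion_log(),
                           allow_excess_offspring = FALSE) {
  persons <- tibble::as_tibble(persons)
  missing_cols <- setdiff(.person_cols, names(persons))
  if (length(missing_cols)) {
    stop("persons table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  persons <- persons[, .person_cols]
  persons$family_id <- as.character(persons$family_id)
  persons$person_id <- as.character(persons$person_id)
  persons$role <- as.character(persons$role)
  persons$birth_index <- as.integer(persons$birth_index)
  for (col in c("age", "bmi", "ea")) persons[[col]] <- as.numeric(persons[[col]])

  bad_role <- setdiff(unique(persons$role), .roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  is_parent <- persons$role %in% c("father", "mother")
  if (any(!is.na(persons$birth_index[is_parent]))) {
    stop("parents must not carry a birth_index", call. = FALSE)
  }
  if (any(is.na(persons$birth_index[!is_parent]))) {
    stop("offspring require a birth_index (1-3, within gender)", call. = FALSE)
  }
  if (!allow_excess_offspring &&
      any(persons$birth_index[!is_parent] > 3L | persons$birth_index[!is_parent] < 1L)) {
    stop("offspring birth_index out of range 1-3; use cap_offspring() for larger sibships",
         call. = FALSE)
  }
  key <- paste(persons$family_id, persons$role,
               ifelse(is.na(persons$birth_index), 0L, persons$birth_index))
  if (anyDuplicated(key)) {
    stop("duplicate (family_id, role, birth_index) combination(s)", call. = FALSE)
  }
  if (!allow_excess_offspring) {
    counts <- table(persons$family_id[!is_parent], persons$role[!is_parent])
    if (length(counts) && any(counts > 3L)) {
      stop("more than 3 offspring of one gender in a family; ",
           "use read_families(cap = TRUE) or cap_offspring()", call. = FALSE)
    }
  }
  if (any(!is.na(persons$bmi) & persons$bmi <= 0)) {
    stop("bmi must be positive where present", call. = FALSE)
  }
  structure(
    list(persons = persons, exclusions = tibble::as_tibble(exclusions)),
    class = "family_dataset"
  )
}

#' @export
print.family_dataset <- function(x, ...) {
  p <- x$persons
  cat("<family_dataset> ", dplyr::n_distinct(p$family_id), " families, ",
      nrow(p), " persons\n", sep = "")
  cat("  observed: bmi ", sum(!is.na(p$bmi)), ", ea ", sum(!is.na(p$ea)), "\n", sep = "")
  if (nrow(x$exclusions)) {
    cat("  filters applied:\n")
    print(x$exclusions)
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.family_dataset <- function(x, ...) {
  x$persons
}

#' Number of families in a dataset
#' @param ds A [family_dataset()].
#' @return Integer count of distinct families.
#' @export
n_families <- function(ds) {
  stopifnot(inherits(ds, "family_dataset"))
  dplyr::n_distinct(ds$persons$family_id)
}

#' Exclusion (provenance) log of a dataset
#' @param ds A [family_dataset()].
#' @return Tibble with one row per applied filter: `filter`,
#'   `n_values_masked`, `n_persons_dropped`.
#' @export
exclusion_log <- function(ds) {
  stopifnot(inherits(ds, "family_dataset"))
  ds$exclusions
}

log_filter <- function(ds, filter, n_values_masked = 0L, n_persons_dropped = 0L) {
  ds$exclusions <- dplyr::bind_rows(
    ds$exclusions,
    tibble::tibble(
      filter = filter,
      n_values_masked = as.integer(n_values_masked),
      n_persons_dropped = as.integer(n_persons_dropped)
    )
  )
  ds
}

# rebuild without re-validation (internal, after value masking)
replace_persons <- function(ds, persons) {
  ds$persons <- persons
  ds
}

#' Read families from CSV
#'
#' Reads a one-row-per-person CSV (columns `family_id`, `person_id`,
#' `role`, `birth_index`, `age`, `bmi`, `ea`; UTF-8, header required,
#' empty/"NA" = missing) into a [family_dataset()].  `ea` may be given
#' either as a numeric level or as an education label understood by
#' [encode_ea()].
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(bmi = "body_mass_index")`.
#' @param cap If `TRUE`, families with more than 3 offspring of one gender
#'   are reduced via [cap_offspring()]; otherwise such families are an error.
#' @return A [family_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "family_id,person_id,role,birth_index,age,bmi,ea",
#'   "f1,p1,father,,56,26.4,Hbo",
#'   "f1,p2,mother,,53,24.8,Mbo",
#'   "f1,p3,son,1,29,23.1,University degree"
#' ), tf)
#' read_families(tf)
#' @export
read_families <- function(path, schema = NULL, cap = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema column '", schema[[canon]], "' not present in file", call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.person_cols, names(raw))
  if (length(missing_cols)) {
    stop("input CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_num <- function(x) suppressWarnings(as.numeric(x))
  ea_raw <- raw$ea
  ea_num <- as_num(ea_raw)
  is_label <- !is.na(ea_raw) & is.na(ea_num)
  if (any(is_label)) {
    ea_num[is_label] <- encode_ea(ea_raw[is_label])
  }
  persons <- tibble::tibble(
    family_id = raw$family_id,
    person_id = raw$person_id,
    role = tolower(raw$role),
    birth_index = as.integer(as_num(raw$birth_index)),
    age = as_num(raw$age),
    bmi = as_num(raw$bmi),
    ea = ea_num
  )
  ds <- family_dataset(persons, allow_excess_offspring = cap)
  if (cap) ds <- cap_offspring(ds)
  ds
}

#' Write families to CSV
#'
#' Writes the persons table of a dataset in the same CSV dialect
#' [read_families()] reads, so that a write/read round trip reproduces the
#' data.
#'
#' @param ds A [family_dataset()].
#' @param path Output CSV path.
#' @param exclusions_path Optional path for the exclusion log CSV
#'   (columns `filter`, `n_values_masked`, `n_persons_dropped`).
#' @return `path`, invisibly.
#' @export
write_families <- function(ds, path, exclusions_path = NULL) {
  stopifnot(inherits(ds, "family_dataset"))
  readr::write_csv(ds$persons, path, progress = FALSE)
  if (!is.null(exclusions_path)) {
    readr::write_csv(ds$exclusions, exclusions_path, progress = FALSE)
  }
  invisible(path)
}

#' Mask EA reported before the attainment age
#'
#' Educational attainment reported below `min_age` (default 25) may not be
#' final and is set to missing; BMI is untouched.  The number of masked
#' values is appended to the exclusion log.
#'
#' @param ds A [family_dataset()].
#' @param min_age Minimum age (years) at which EA is considered final.
#' @return The filtered [family_dataset()].
#' @export
filter_ea_under_age <- function(ds, min_age = 25) {
  stopifnot(inherits(ds, "family_dataset"))
  p <- ds$persons
  hit <- !is.na(p$ea) & !is.na(p$age) & p$age < min_age
  p$ea[hit] <- NA_real_
  ds <- replace_persons(ds, p)
  log_filter(ds, sprintf("ea_under_age_%g", min_age), n_values_masked = sum(hit))
}

#' Mask extreme BMI values
#'
#' Sensitivity filter: BMI strictly below `low` or strictly above `high`
#' (defaults 15 and 45 kg/m^2, the range outside of which values typically
#' reflect eating disorders or monogenic obesity) is set to missing.
#'
#' @param ds A [family_dataset()].
#' @param low,high Inclusive retention bounds in kg/m^2.
#' @return The filtered [family_dataset()].
#' @export
filter_bmi_extremes <- function(ds, low = 15, high = 45) {
  stopifnot(inherits(ds, "family_dataset"))
  if (low >= high) stop("low must be smaller than high", call. = FALSE)
  p <- ds$persons
  hit <- !is.na(p$bmi) & (p$bmi < low | p$bmi > high)
  p$bmi[hit] <- NA_real_
  ds <- replace_persons(ds, p)
  log_filter(ds, sprintf("bmi_outside_%g_%g", low, high), n_values_masked = sum(hit))
}

#' Cap the number of offspring per gender
#'
#' Families with more than `max_per_gender` offspring of one gender retain
#' the oldest `max_per_gender` of that gender (ties broken by `person_id`
#' in lexicographic order); the birth indices of affected sibships are
#' re-assigned 1..k by decreasing age.  Dropped persons are logged.
#'
#' @param ds A [family_dataset()].
#' @param max_per_gender Maximum offspring per gender per family.
#' @return The reduced [family_dataset()].
#' @export
cap_offspring <- function(ds, max_per_gender = 3L) {
  stopifnot(inherits(ds, "family_dataset"))
  p <- ds$persons
  off <- p$role %in% c("son", "daughter")
  grp <- paste(p$family_id, p$role)
  over <- names(which(table(grp[off]) > max_per_gender))
  if (!length(over)) {
    return(log_filter(ds, sprintf("cap_offspring_%d", max_per_gender)))
  }
  p_keep <- p
  dropped <- 0L
  for (g in over) {
    idx <- which(off & grp == g)
    ord <- idx[order(-p$age[idx], p$person_id[idx])]
    keep <- ord[seq_len(max_per_gender)]
    p_keep$birth_index[keep] <- seq_len(max_per_gender)
    drop_idx <- setdiff(idx, keep)
    dropped <- dropped + length(drop_idx)
    p_keep <- p_keep[-match(drop_idx, seq_len(nrow(p_keep))), , drop = FALSE]
    # recompute row indices after deletion for subsequent groups
    off <- p_keep$role %in% c("son", "daughter")
    grp <- paste(p_keep$family_id, p_keep$role)
    p <- p_keep
  }
  out <- family_dataset(p_keep, exclusions = ds$exclusions)
  log_filter(out, sprintf("cap_offspring_%d", max_per_gender),
             n_persons_dropped = dropped)
}

#' Adjust phenotypes for age
#'
#' Within each role group (father, mother, son, daughter) and each trait,
#' replaces values by the residuals of an ordinary least-squares regression
#' on age and age squared (collinear terms are dropped automatically, so a
#' constant-age group reduces to mean-centering).  Downstream modelling
#' operates on these age-adjusted values.
#'
#' @param ds A [family_dataset()].
#' @return The adjusted [family_dataset()].
#' @export
adjust_for_age <- function(ds) {
  stopifnot(inherits(ds, "family_dataset"))
  p <- ds$persons
  for (role in .roles) {
    for (trait in c("bmi", "ea")) {
      idx <- which(p$role == role & !is.na(p[[trait]]))
      if (!length(idx)) next
      if (any(is.na(p$age[idx]))) {
        stop("age missing for ", role, " persons with observed ", trait, call. = FALSE)
      }
      if (length(idx) < 3L) {
        stop("fewer than 3 (age, ", trait, ") pairs in group '", role,
             "'; cannot age-adjust", call. = FALSE)
      }
      fit <- stats::lm(y ~ age + I(age^2),
                       data = data.frame(y = p[[trait]][idx], age = p$age[idx]))
      p[[trait]][idx] <- stats::residuals(fit)
    }
  }
  ds$persons <- p
  log_filter(ds, "age_adjusted")
}

#' Convert a covariance to a correlation
#'
#' @param cov Covariance between two variables.
#' @param var_a,var_b Positive variances of the two variables.
#' @return `cov / sqrt(var_a * var_b)`; vectorized.
#' @examples
#' covariance_to_correlation(3.277, 10.492, 19.630)  # spousal BMI, 0.228
#' @export
covariance_to_correlation <- function(cov, var_a, var_b) {
  if (any(var_a <= 0) || any(var_b <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  cov / sqrt(var_a * var_b)
}

#' Family observation matrix
#'
#' Maps each family to the canonical 16-slot observation vector (see
#' [family_slots()]) and its missingness mask.  Families with no observed
#' phenotype at all are dropped (their count is returned as an attribute).
#'
#' @param ds A [family_dataset()].
#' @return A list with `observation` (n x 16 numeric matrix, NA = missing),
#'   `mask` (n x 16 logical), and `family_id` (length n); attribute
#'   `n_dropped_empty` counts all-missing families removed.
#' @export
family_observations <- function(ds) {
  stopifnot(inherits(ds, "family_dataset"))
  p <- ds$persons
  fam_ids <- unique(p$family_id)
  n <- length(fam_ids)
  obs <- matrix(NA_real_, n, 16L, dimnames = list(fam_ids, .slot_names))
  fam_row <- match(p$family_id, fam_ids)
  for (trait in c("bmi", "ea")) {
    col <- slot_index(p$role, p$birth_index, rep(trait, nrow(p)))
    val <- p[[trait]]
    keep <- !is.na(val)
    obs[cbind(fam_row[keep], col[keep])] <- val[keep]
  }
  mask <- !is.na(obs)
  empty <- rowSums(mask) == 0L
  if (any(empty)) {
    obs <- obs[!empty, , drop = FALSE]
    mask <- mask[!empty, , drop = FALSE]
    fam_ids <- fam_ids[!empty]
  }
  structure(
    list(observation = obs, mask = mask, family_id = fam_ids),
    n_dropped_empty = sum(empty)
  )
}
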