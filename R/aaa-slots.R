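# Canonical 16-slot family observation layout.
#
# Every family is mapped to a fixed-order vector of 16 phenotype slots:
# father BMI, father EA, mother BMI, mother EA, then BMI/EA for up to
# three sons and three daughters.  All model matrices use this order.

.slot_table <- local({
  parents <- tibble::tibble(
    role = rep(c("father", "mother"), each = 2L),
    birth_index = NA_integer_,
    trait = rep(c("bmi", "ea"), times = 2L)
  )
  offspring <- tidyr::expand_grid(
    role = c("son", "daughter"),
    birth_index = 1:3,
    trait = c("bmi", "ea")
  )
  out <- dplyr::bind_rows(parents, offspring)
  out$slot <- seq_len(nrow(out))
  out$name <- ifelse(
    is.na(out$birth_index),
    paste(out$role, out$trait, sep = "_"),
    paste0(out$role, out$birth_index, "_", out$trait)
  )
  out[, c("slot", "name", "role", "birth_index", "trait")]
})

.slot_names <- .slot_table$name
.parent_slots <- 1:4
.offspring_slots <- 5:16
# residual variable order: the 12 offspring slots
.resid_names <- .slot_names[.offspring_slots]

#' Canonical family observation slots
#'
#' The model observes each family as a fixed-order vector of 16 phenotype
#' slots: BMI and EA for the father, the mother, and up to three sons and
#' three daughters (birth index within gender).  All model-implied moment
#' matrices, observation matrices and parameter names refer to this order.
#'
#' @return A tibble with columns `slot` (1-16), `name` (e.g. `"son2_ea"`),
#'   `role`, `birth_index` (NA for parents) and `trait` (`"bmi"` or `"ea"`).
#' @examples
#' family_slots()
#' @export
family_slots <- function() {
  .slot_table
}

# slot index for a (role, birth_index, trait) triple; vectorized
slot_index <- function(role, birth_index, trait) {
  key <- ifelse(
    role %in% c("father", "mother"),
    paste(role, trait, sep = "_"),
    paste0(role, birth_index, "_", trait)
  )
  match(key, .slot_names)
}
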