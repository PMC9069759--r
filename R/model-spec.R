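# Declarative path-model specification.
#
# The family model regresses the 12 offspring slots (BMI/EA of up to 3
# sons and 3 daughters) on the 4 parental slots:
#
#   O = a + B P + E,   E independent of P
#
# with P ~ N(mu_P, Sigma_P) exogenous, B assembled from 16 transmission
# coefficients (parent trait x parent sex x offspring trait x offspring
# sex, shared across birth order), and Sigma_E assembled from 4 residual
# variances (trait x offspring sex, shared across birth order), 2
# within-person residual EA-BMI correlations, and 60 unconstrained
# pairwise sibling residual correlations.  A model is a table of cells,
# each mapped to a free-parameter equality class or a fixed value.
# Dependence blocks are parameterized as variances + correlations;
# variances are optimized on the log scale and correlations through
# atanh, so every iterate has valid marginal domains (joint positive
# definiteness is checked at evaluation and violations rejected).

.parent_vars <- .slot_names[1:4]

# all model cells of the full specification, in canonical order
build_cells <- function() {
  trans <- tidyr::expand_grid(
    os = c("son", "daughter"), ot = c("bmi", "ea"),
    ps = c("father", "mother"), pt = c("bmi", "ea")
  )
  trans_cells <- tibble::tibble(
    cell = paste("b", trans$ps, trans$pt, trans$os, trans$ot, sep = "_"),
    block = "transmission", transform = "identity"
  )
  pvar_cells <- tibble::tibble(
    cell = paste0("var_", .parent_vars),
    block = "parental_var", transform = "log"
  )
  ppairs <- utils::combn(.parent_vars, 2)
  pcorr_cells <- tibble::tibble(
    cell = paste("rho_p", ppairs[1, ], ppairs[2, ], sep = "_"),
    block = "parental_corr", transform = "atanh"
  )
  rvar_cells <- tibble::tibble(
    cell = paste0("rvar_", c("son_bmi", "son_ea", "daughter_bmi", "daughter_ea")),
    block = "resid_var", transform = "log"
  )
  wp_cells <- tibble::tibble(
    cell = c("rho_wp_son", "rho_wp_daughter"),
    block = "resid_wp_corr", transform = "atanh"
  )
  rpairs <- utils::combn(.resid_names, 2)
  same_person <- sub("_(bmi|ea)$", "", rpairs[1, ]) == sub("_(bmi|ea)$", "", rpairs[2, ])
  rpairs <- rpairs[, !same_person, drop = FALSE]
  sib_cells <- tibble::tibble(
    cell = paste("rho_r", rpairs[1, ], rpairs[2, ], sep = "_"),
    block = "resid_sib_corr", transform = "atanh"
  )
  mean_cells <- tibble::tibble(
    cell = c(paste0("mu_", .parent_vars),
             paste0("alpha_", c("son_bmi", "son_ea", "daughter_bmi", "daughter_ea"))),
    block = "intercept", transform = "identity"
  )
  cells <- dplyr::bind_rows(trans_cells, pvar_cells, pcorr_cells, rvar_cells,
                            wp_cells, sib_cells, mean_cells)
  cells$class <- cells$cell
  cells$fixed <- NA_real_
  cells
}

new_model <- function(name, cells) {
  structure(list(name = name, cells = cells), class = "transmission_model")
}

#' @export
print.transmission_model <- function(x, ...) {
  cat("<transmission_model> '", x$name, "': ", nrow(x$cells), " cells, ",
      n_free_parameters(x), " free parameters\n", sep = "")
  cnt <- table(x$cells$block)
  for (b in names(cnt)) {
    free_b <- dplyr::n_distinct(x$cells$class[x$cells$block == b & is.na(x$cells$fixed)])
    cat(sprintf("  %-16s %3d cells, %3d free classes\n", b, cnt[[b]], free_b))
  }
  invisible(x)
}

#' The full transmission model
#'
#' All 16 parent-offspring transmission coefficients free (2 parent traits
#' x 2 parent sexes x 2 offspring traits x 2 offspring sexes, shared
#' across birth order within offspring sex), a fully free parental 4x4
#' covariance block (4 variances, 2 within-person and 4 spousal
#' covariances), 4 offspring residual variances, 2 within-person residual
#' EA-BMI correlations, 60 unconstrained pairwise sibling residual
#' correlations, and 8 intercepts: 100 free scalars.
#'
#' @return A `transmission_model` object.
#' @examples
#' n_free_parameters(full_model())
#' @export
full_model <- function() {
  new_model("full", build_cells())
}

#' The parsimonious (gender-constrained) transmission model
#'
#' The full model with transmission reduced to 6 equality classes:
#' paternal BMI -> offspring BMI (shared across offspring gender),
#' maternal BMI -> son BMI, maternal BMI -> daughter BMI, parent EA ->
#' offspring BMI (one value), parent EA -> offspring EA (one value), and
#' parent BMI -> offspring EA (one value).  All other blocks are free as
#' in [full_model()]: 90 free scalars.
#'
#' @return A `transmission_model` object.
#' @export
model2 <- function() {
  m <- full_model()
  cl <- m$cells$class
  cl[cl %in% c("b_father_bmi_son_bmi", "b_father_bmi_daughter_bmi")] <- "b_pat_bmi_bmi"
  ea_bmi <- paste("b", rep(c("father", "mother"), each = 2), "ea",
                  c("son", "daughter"), "bmi", sep = "_")
  cl[cl %in% ea_bmi] <- "b_ea_bmi"
  ea_ea <- paste("b", rep(c("father", "mother"), each = 2), "ea",
                 c("son", "daughter"), "ea", sep = "_")
  cl[cl %in% ea_ea] <- "b_ea_ea"
  bmi_ea <- paste("b", rep(c("father", "mother"), each = 2), "bmi",
                  c("son", "daughter"), "ea", sep = "_")
  cl[cl %in% bmi_ea] <- "b_bmi_ea"
  m$cells$class <- cl
  m$name <- "model2"
  m
}

#' Impose an equality constraint on transmission coefficients
#'
#' Merges transmission cells of one type (parent trait -> offspring trait)
#' into shared classes across offspring gender or across parent gender, as
#' used by the gender-difference likelihood-ratio tests.
#'
#' @param model A `transmission_model`.
#' @param parent_trait,offspring_trait `"bmi"` or `"ea"`.
#' @param across `"offspring"` equates son/daughter coefficients within
#'   each parent; `"parent"` equates father/mother coefficients within each
#'   offspring sex.
#' @return The constrained `transmission_model`.
#' @export
constrain_transmission <- function(model, parent_trait, offspring_trait,
                                   across = c("offspring", "parent")) {
  across <- match.arg(across)
  stopifnot(inherits(model, "transmission_model"),
            parent_trait %in% c("bmi", "ea"),
            offspring_trait %in% c("bmi", "ea"))
  # merge through existing equality classes so constraints compose
  merge_classes <- function(cl, members, new_class) {
    cl[cl %in% cl[model$cells$cell %in% members]] <- new_class
    cl
  }
  cl <- model$cells$class
  if (across == "offspring") {
    for (ps in c("father", "mother")) {
      members <- paste("b", ps, parent_trait, c("son", "daughter"),
                       offspring_trait, sep = "_")
      cl <- merge_classes(cl, members,
                          paste("beq", ps, parent_trait, offspring_trait,
                                "anyoff", sep = "_"))
    }
  } else {
    for (os in c("son", "daughter")) {
      members <- paste("b", c("father", "mother"), parent_trait, os,
                       offspring_trait, sep = "_")
      cl <- merge_classes(cl, members,
                          paste("beq", parent_trait, os, offspring_trait,
                                "anypar", sep = "_"))
    }
  }
  model$cells$class <- cl
  model$name <- paste0(model$name, "+eq(", parent_trait, ">", offspring_trait,
                       ",", across, ")")
  model
}

#' Number of free parameters of a model
#' @param model A `transmission_model`.
#' @return Integer count of free equality classes.
#' @export
n_free_parameters <- function(model) {
  stopifnot(inherits(model, "transmission_model"))
  dplyr::n_distinct(model$cells$class[is.na(model$cells$fixed)])
}

#' Model degrees of freedom at full slot coverage
#'
#' The saturated model over the 16 canonical slots has 16 means and
#' 16*17/2 = 136 variances/covariances, 152 distinct moments in total;
#' the model df is 152 minus the model's free-parameter count.
#'
#' @param model A `transmission_model`.
#' @return Integer degrees of freedom.
#' @examples
#' model_df(full_model())  # 52
#' @export
model_df <- function(model) {
  152L - n_free_parameters(model)
}

#' Count sibling residual correlations
#'
#' With k = `n_sons` + `n_daughters` offspring, the residual covariance
#' block contains k(k-1)/2 same-trait correlations per trait and
#' k^2 - k cross-trait cross-person correlations.
#'
#' @param n_sons,n_daughters Offspring counts, 0-3 each.
#' @return Named integer vector `c(same_trait = ..., cross_trait = ...)`,
#'   where `same_trait` is the per-trait count.
#' @examples
#' count_residual_correlations(3, 3)  # 15 per trait, 30 cross-trait
#' @export
count_residual_correlations <- function(n_sons, n_daughters) {
  if (n_sons < 0 || n_sons > 3 || n_daughters < 0 || n_daughters > 3) {
    stop("offspring counts must be in 0..3", call. = FALSE)
  }
  k <- n_sons + n_daughters
  c(same_trait = as.integer(k * (k - 1) / 2), cross_trait = as.integer(k^2 - k))
}

# ---- compilation: cell table -> fast assembly indices -------------------

transform_to_opt <- function(x, transform) {
  switch(transform, identity = x, log = log(x), atanh = atanh(x))
}
transform_from_opt <- function(x, transform) {
  switch(transform, identity = x, log = exp(x), atanh = tanh(x))
}

compile_model <- function(model) {
  cells <- model$cells
  free <- is.na(cells$fixed)
  classes <- unique(cells$class[free])
  cell_to_free <- ifelse(free, match(cells$class, classes), 0L)
  class_transform <- cells$transform[match(classes, cells$class)]
  pos <- stats::setNames(seq_len(nrow(cells)), cells$cell)

  # B: 12 offspring residual vars x 4 parental vars
  B_idx <- matrix(0L, 12, 4, dimnames = list(.resid_names, .parent_vars))
  r_role <- sub("[0-9]+_(bmi|ea)$", "", .resid_names)
  r_trait <- sub("^.*_", "", .resid_names)
  p_role <- sub("_(bmi|ea)$", "", .parent_vars)
  p_trait <- sub("^.*_", "", .parent_vars)
  for (r in 1:12) {
    for (c in 1:4) {
      B_idx[r, c] <- pos[[paste("b", p_role[c], p_trait[c], r_role[r], r_trait[r],
                                sep = "_")]]
    }
  }
  pvar_idx <- pos[paste0("var_", .parent_vars)]
  pcorr_idx <- matrix(0L, 4, 4)
  ppairs <- utils::combn(.parent_vars, 2)
  for (j in seq_len(ncol(ppairs))) {
    a <- match(ppairs[1, j], .parent_vars); b <- match(ppairs[2, j], .parent_vars)
    pcorr_idx[a, b] <- pcorr_idx[b, a] <-
      pos[[paste("rho_p", ppairs[1, j], ppairs[2, j], sep = "_")]]
  }
  rvar_idx <- pos[paste0("rvar_", paste(r_role, r_trait, sep = "_"))]
  RE_idx <- matrix(0L, 12, 12)
  r_person <- sub("_(bmi|ea)$", "", .resid_names)
  for (a in 1:11) {
    for (b in (a + 1):12) {
      nm <- if (r_person[a] == r_person[b]) {
        paste0("rho_wp_", r_role[a])
      } else {
        paste("rho_r", .resid_names[a], .resid_names[b], sep = "_")
      }
      RE_idx[a, b] <- RE_idx[b, a] <- pos[[nm]]
    }
  }
  mu_idx <- pos[paste0("mu_", .parent_vars)]
  alpha_idx <- pos[paste0("alpha_", paste(r_role, r_trait, sep = "_"))]

  list(
    model = model,
    cells = cells,
    classes = classes,
    n_free = length(classes),
    cell_to_free = cell_to_free,
    fixed_values = cells$fixed,
    class_transform = class_transform,
    B_idx = B_idx, pvar_idx = pvar_idx, pcorr_idx = pcorr_idx,
    rvar_idx = rvar_idx, RE_idx = RE_idx,
    mu_idx = mu_idx, alpha_idx = alpha_idx
  )
}

# full cell-value vector from natural-scale free parameters
cell_values <- function(compiled, theta) {
  v <- compiled$fixed_values
  free <- compiled$cell_to_free > 0L
  v[free] <- theta[compiled$cell_to_free[free]]
  names(v) <- compiled$cells$cell
  v
}

# assemble structural matrices from a cell-value vector
assemble_parameters <- function(compiled, values) {
  B <- matrix(values[compiled$B_idx], 12, 4,
              dimnames = list(.resid_names, .parent_vars))
  psd_vec <- sqrt(values[compiled$pvar_idx])
  RP <- diag(4)
  off <- compiled$pcorr_idx > 0L
  RP[off] <- values[compiled$pcorr_idx[off]]
  Sigma_P <- outer(psd_vec, psd_vec) * RP
  dimnames(Sigma_P) <- list(.parent_vars, .parent_vars)
  rsd_vec <- sqrt(values[compiled$rvar_idx])
  RE <- diag(12)
  offE <- compiled$RE_idx > 0L
  RE[offE] <- values[compiled$RE_idx[offE]]
  Sigma_E <- outer(rsd_vec, rsd_vec) * RE
  dimnames(Sigma_E) <- list(.resid_names, .resid_names)
  mu_P <- values[compiled$mu_idx]
  alpha <- values[compiled$alpha_idx]
  list(B = B, Sigma_P = Sigma_P, Sigma_E = Sigma_E,
       mu_P = unname(mu_P), alpha = unname(alpha))
}

moments_from_parameters <- function(par) {
  SPBt <- par$Sigma_P %*% t(par$B)
  Sigma <- rbind(
    cbind(par$Sigma_P, SPBt),
    cbind(t(SPBt), par$B %*% SPBt + par$Sigma_E)
  )
  dimnames(Sigma) <- list(.slot_names, .slot_names)
  mu <- c(par$mu_P, par$alpha + drop(par$B %*% par$mu_P))
  names(mu) <- .slot_names
  list(mean = mu, cov = Sigma)
}

#' Model-implied moments
#'
#' Computes the model-implied mean vector and covariance matrix of the 16
#' canonical slots: parents are exogenous with moments (mu_P, Sigma_P);
#' offspring follow O = a + B P + E, so the implied covariance is
#' `[[Sigma_P, Sigma_P B'], [B Sigma_P, B Sigma_P B' + Sigma_E]]`.
#'
#' @param model A `transmission_model`.
#' @param theta Named numeric vector of free-parameter values on the
#'   natural scale (names = free classes, see [free_parameter_names()]).
#' @param check Verify that the assembled covariance blocks are positive
#'   semi-definite (error if not).
#' @return List with `mean` (length 16) and `cov` (16 x 16), both named by
#'   slot.
#' @export
implied_moments <- function(model, theta, check = TRUE) {
  compiled <- compile_model(model)
  theta <- align_theta(compiled, theta)
  par <- assemble_parameters(compiled, cell_values(compiled, theta))
  if (check) {
    for (blk in list(par$Sigma_P, par$Sigma_E)) {
      ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev))) {
        stop("assembled covariance block is not positive semi-definite",
             call. = FALSE)
      }
    }
  }
  moments_from_parameters(par)
}

align_theta <- function(compiled, theta) {
  if (is.null(names(theta))) {
    stopifnot(length(theta) == compiled$n_free)
    return(as.numeric(theta))
  }
  missing <- setdiff(compiled$classes, names(theta))
  if (length(missing)) {
    stop("theta lacks free parameter(s): ", paste(utils::head(missing, 5),
                                                  collapse = ", "), call. = FALSE)
  }
  as.numeric(theta[compiled$classes])
}

#' Names of a model's free parameters
#' @param model A `transmission_model`.
#' @return Character vector of free equality-class names, in canonical
#'   order (the order `theta` vectors use).
#' @export
free_parameter_names <- function(model) {
  compile_model(model)$classes
}

# ---- serialization ------------------------------------------------------

#' Serialize / deserialize a model definition
#'
#' The cell table (cell name, block, transform, equality class, fixed
#' value) is written as JSON; reading it back reproduces the model.
#'
#' @param model A `transmission_model`.
#' @param path File path.
#' @return `model_to_json` returns `path` invisibly; `model_from_json`
#'   returns the `transmission_model`.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "transmission_model"))
  jsonlite::write_json(
    list(name = model$name, cells = model$cells),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- tibble::as_tibble(x$cells)
  if (is.null(cells$fixed)) cells$fixed <- NA_real_
  cells$fixed <- as.numeric(cells$fixed)
  new_model(x$name, cells[, c("cell", "block", "transform", "class", "fixed")])
}
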