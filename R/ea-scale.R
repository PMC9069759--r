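# 8-level educational attainment scale for the Dutch school system,
# ordered by academic performance requirements.  Treated as continuous
# (levels 1-8) in all downstream computation.

.ea_scale <- tibble::tibble(
  level = 1:8,
  label = c(
    "Elementary school",
    "Lower vocational education",
    "Lower general secondary school",
    "Intermediate vocational education",
    "Upper general secondary school",
    "Higher vocational education",
    "University degree",
    "Post-graduate degree"
  ),
  dutch = c(
    "Basisschool",
    "Vmbo/vocational stream",
    "Mulo, mavo, vmbo/theoretical stream",
    "Mbo",
    "Havo, hbs, atheneum, gymnasium",
    "Hbo",
    "Post-hbo degree",
    "PhD degree"
  )
)

# alias -> level lookup (lower-cased); Dutch equivalents are split on commas
# and slashes so e.g. "mavo" and "vmbo/theoretical stream" both resolve.
.ea_alias_map <- local({
  split_aliases <- function(x) {
    trimws(unlist(strsplit(x, ",", fixed = TRUE)))
  }
  lv <- integer(0)
  nm <- character(0)
  for (i in 1:8) {
    aliases <- c(.ea_scale$label[i], split_aliases(.ea_scale$dutch[i]))
    nm <- c(nm, tolower(aliases))
    lv <- c(lv, rep(i, length(aliases)))
  }
  stats::setNames(lv, nm)
})

#' The 8-level educational attainment scale
#'
#' Highest completed Dutch educational level, ordered by academic
#' performance requirements from elementary school (1) to a post-graduate
#' degree (8).  The scale is treated as a continuous variable in the
#' transmission model.
#'
#' @return A tibble with columns `level`, `label` (canonical English label)
#'   and `dutch` (Dutch equivalents).
#' @examples
#' ea_scale()
#' @export
ea_scale <- function() {
  .ea_scale
}

#' Encode education labels as EA levels
#'
#' Maps canonical labels or Dutch aliases (case-insensitive) of the highest
#' completed educational level to the ordinal 1-8 EA scale.
#'
#' @param label Character vector of education labels.
#' @return Integer vector of EA levels (1-8).
#' @examples
#' encode_ea(c("Elementary school", "PhD degree", "Mbo"))
#' @export
encode_ea <- function(label) {
  stopifnot(is.character(label))
  out <- unname(.ea_alias_map[tolower(trimws(label))])
  out[is.na(label)] <- NA_integer_
  bad <- which(is.na(out) & !is.na(label))
  if (length(bad)) {
    stop("unrecognized educational attainment label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(out)
}
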