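# ggplot2 displays of fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of an effect table
#'
#' Standardized direct effects with 95% CIs, with the total effect
#' overlaid, per parental variable, faceted by offspring sex and trait.
#'
#' @param object An [effect_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$parent <- paste(d$parent_sex, toupper(d$parent_trait))
  d$panel <- paste0(d$offspring_sex, "s: ", toupper(d$offspring_trait))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$std_estimate, y = .data$parent)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$std_conf.low, xmax = .data$std_conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$total), shape = 1, size = 2.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(
      x = "standardized effect (direct; open circle = total)",
      y = NULL,
      title = "Parent-offspring transmission effects"
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a FIML fit
#'
#' Transmission-block estimates with Wald 95% CIs.
#'
#' @param object A `fiml_fit`.
#' @param block Cell block to display (default `"transmission"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiml_fit <- function(object, block = "transmission", ...) {
  d <- tidy(object)
  d <- d[d$block == block & d$identified, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = paste0("FIML estimates ('", object$name, "', ",
                                 block, " block)")) +
    ggplot2::theme_minimal()
}
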