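# Summary figures: the diversity-productivity relationship and the observed
# versus additive yield scatter.

#' Plot yield against richness by environment
#'
#' Scatter of microcosm yields against community richness (log axis) with a
#' linear trend in log richness per environment, faceted by week.
#'
#' @param yields Yield table.
#' @param design Design table.
#' @param weeks Weeks to show (default all present).
#' @return A ggplot object.
#' @export
plot_yield_richness <- function(yields, design, weeks = NULL) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  dat <- yields
  dat$richness <- rich[dat$composition_id]
  if (!is.null(weeks)) dat <- dat[dat$week %in% weeks, , drop = FALSE]
  dat$environment <- normalize_environment(dat$environment)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$richness, y = .data$yield,
                                    colour = .data$environment)) +
    ggplot2::geom_jitter(width = 0.03, alpha = 0.4, size = 0.8) +
    # axis is log10-transformed, so a linear smooth is linear in log richness
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 0.7) +
    ggplot2::scale_x_log10(breaks = c(1, 2, 3, 6, 12)) +
    ggplot2::facet_wrap(~ week, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(beech = "darkorange",
                                            ph5 = "forestgreen",
                                            spruce = "firebrick")) +
    ggplot2::labs(x = "Species richness", y = "Yield (OD 595)",
                  colour = "Environment") +
    ggplot2::theme_bw()
}

#' Plot observed community yields against the additive expectation
#'
#' The observed-versus-additive scatter with the 1:1 line; points below the
#' line indicate negative interactions.
#'
#' @param indices Data frame from [interaction_indices()].
#' @return A ggplot object.
#' @export
plot_observed_additive <- function(indices) {
  ggplot2::ggplot(indices, ggplot2::aes(x = .data$additive,
                                        y = .data$observed,
                                        colour = .data$environment)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::facet_wrap(~ week, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(beech = "darkorange",
                                            ph5 = "forestgreen",
                                            spruce = "firebrick")) +
    ggplot2::labs(x = "Additive expectation (sum of monoculture yields)",
                  y = "Observed community yield", colour = "Environment") +
    ggplot2::theme_bw()
}
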