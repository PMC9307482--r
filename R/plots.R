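#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot VAF trajectories of a cohort
#'
#' One line per (participant, variant) trajectory, VAF against age, on a
#' log VAF scale (low-frequency clones are otherwise invisible).
#'
#' @param object A `cf_cohort`.
#' @param colour_by Column mapped to colour (default `"gene"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cf_cohort <- function(object, colour_by = "gene", ...) {
  df <- tibble::as_tibble(object)
  df$trajectory <- paste(df$participant_id, df$variant_id)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age_years, y = pmax(.data$vaf, 1e-4),
    group = .data$trajectory, colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (years)", y = "VAF", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Plot LiFT classifications: VAF gradient against initial VAF
#'
#' @param object A `cf_lift` from [lift_classify()].
#' @param ... Unused.
#' @return A ggplot, initial VAF (log scale) against per-year VAF gradient,
#'   coloured by call.
#' @export
autoplot.cf_lift <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = pmax(.data$vaf_first, 1e-4),
                                   y = .data$gradient,
                                   colour = .data$call)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(fit = "#2166ac",
                                            filtered = "#e08214")) +
    ggplot2::labs(x = "VAF at first timepoint",
                  y = "VAF gradient (per year)", colour = "LiFT call") +
    ggplot2::theme_minimal()
}

#' Plot fitness posteriors per clone
#'
#' @param object A `cf_fitness` from [infer_posterior()].
#' @param ... Unused.
#' @return A ggplot of the posterior density of fitness per clone.
#' @export
autoplot.cf_fitness <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object$clones)), function(i) {
    tibble::tibble(
      clone = paste(object$clones$variants[[i]], collapse = ","),
      s = object$s_grid,
      density = object$clones$s_density[[i]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$density,
                                   colour = .data$clone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Fitness s (per year)", y = "Posterior mass",
                  colour = "Clone") +
    ggplot2::theme_minimal()
}

#' Plot a referral-time grid
#'
#' @param grid Output of [referral_grid()].
#' @return A ggplot: referral time against initial VAF, one line per
#'   fitness.
#' @export
plot_referral_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$v0, y = .data$referral_years,
                                     colour = factor(.data$s),
                                     group = factor(.data$s))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Initial VAF", y = "Referral time (years)",
                  colour = "Fitness (per yr)") +
    ggplot2::theme_minimal()
}
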