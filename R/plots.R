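# ggplot2 views of simulation results and cross data.

#' Plot genotype trajectories of a simulated release
#'
#' Adult counts per genotype over time, faceted by sex, with the
#' drive-carrier coverage of adult females as a companion panel style of the
#' population-replacement figures. The first replicate is shown unless
#' `rep` selects another.
#'
#' @param object A `gd_sim` object.
#' @param rep Replicate to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gd_sim
#' @export
autoplot.gd_sim <- function(object, rep = 1, ...) {
  traj <- tidy.gd_sim(object)
  traj <- traj[traj$rep == rep & traj$stage != "aquatic", ]
  traj$stage <- factor(traj$stage, c("adult_female", "adult_male"),
                       c("Adult females", "Adult males"))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$day, y = .data$count,
                                     colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stage)) +
    ggplot2::geom_vline(xintercept = object$release_day, linetype = 3) +
    ggplot2::labs(x = "Day", y = "Adults", colour = "Genotype") +
    ggplot2::theme_minimal()
}

#' Plot drive-carrier coverage among adult females
#'
#' One line per replicate of the fraction of adult females carrying at
#' least one drive allele (the hypothetical linked-effector coverage).
#'
#' @param sim A `gd_sim` object.
#' @return A ggplot object.
#' @export
plot_coverage <- function(sim) {
  cov <- effector_coverage(sim)
  ggplot2::ggplot(cov, ggplot2::aes(x = .data$days_pr, y = .data$coverage,
                                    group = .data$rep)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "Days post-release",
                  y = "Females with ≥ 1 drive allele") +
    ggplot2::theme_minimal()
}

#' Box plot of per-family inheritance rates by group
#'
#' @param rates A tibble from [inheritance_rates()].
#' @param group Grouping column name (string).
#' @return A ggplot object.
#' @export
plot_inheritance <- function(rates, group = "parent_sex") {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data[[group]], y = .data$rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Marker inheritance") +
    ggplot2::theme_minimal()
}
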