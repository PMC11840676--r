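#' Depth-profile plot of porewater geochemistry
#'
#' Classic down-core panels: one facet per analyte and site, depth
#' increasing downward.
#'
#' @param profile Porewater profile tibble.
#' @param analytes Character vector of profile columns to plot.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile,
                         analytes = c("SO4_mM", "CH4_mM", "DIC_mM",
                                      "d13C_DIC", "d13C_CH4")) {
  analytes <- intersect(analytes, names(profile))
  long <- tidyr::pivot_longer(profile[, c("site", "depth_cm", analytes)],
                              dplyr::all_of(analytes),
                              names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth_cm)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(site ~ analyte, scales = "free") +
    ggplot2::labs(x = NULL, y = "Depth (cm)")
}

#' Energy-versus-depth plot for an energy table
#'
#' Gibbs energies against depth, one panel per reaction, scenario endpoints
#' as colours, with the exergonic band between zero and the biological
#' energy quantum shaded.
#'
#' @param energies Energy table from [sweep_energies()].
#' @param beq BEQ threshold for the shaded band, kJ mol^-1.
#' @return A ggplot object.
#' @export
plot_energy_depth <- function(energies, beq = -10) {
  ggplot2::ggplot(energies,
                  ggplot2::aes(x = .data$dGr, y = .data$depth_cm,
                               colour = .data$scenario)) +
    ggplot2::annotate("rect", xmin = beq, xmax = 0, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "tan") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(site ~ reaction, scales = "free") +
    ggplot2::labs(x = expression(Delta * G[r] ~ "(kJ mol"^-1 * " reaction)"),
                  y = "Depth (cm)")
}

#' H2 feasibility window plot
#'
#' Minimum, equal-energy, and maximum H2 concentrations per depth on a log
#' scale; the band between minimum and maximum is the window in which both
#' acetate oxidation and CO2 reduction are exergonic.
#'
#' @param windows Window table from [h2_feasibility_window()].
#' @return A ggplot object.
#' @export
plot_h2_window <- function(windows) {
  ggplot2::ggplot(windows, ggplot2::aes(y = .data$depth_cm)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$h2_min_nM,
                                      xmax = .data$h2_max_nM),
                         alpha = 0.2, fill = "steelblue", na.rm = TRUE) +
    ggplot2::geom_path(ggplot2::aes(x = .data$h2_min_nM,
                                    colour = "CO2 reduction = 0"),
                       na.rm = TRUE) +
    ggplot2::geom_path(ggplot2::aes(x = .data$h2_max_nM,
                                    colour = "acetate oxidation = 0"),
                       na.rm = TRUE) +
    ggplot2::geom_path(ggplot2::aes(x = .data$h2_equal_nM,
                                    colour = "equal energy"),
                       linetype = 2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(x = expression(H[2] ~ "(nM)"), y = "Depth (cm)",
                  colour = NULL)
}

#' @export
autoplot.zone_assignment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$depth_cm,
                                  colour = .data$zone)) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Depth (cm)", colour = "Zone")
}

#' @export
autoplot.alpha_profile <- function(object, ...) {
  d <- filter(tidy(object), is.finite(.data$alpha_mean))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$zone, y = .data$alpha_mean,
                                  ymin = .data$alpha_min,
                                  ymax = .data$alpha_max,
                                  colour = .data$site)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "Zone", y = expression(alpha[DIC %->% CH[4]]))
}

#' @export
autoplot.trend_classification <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("mean_BZSZ", "mean_SMTZ", "mean_MZ"),
                        names_to = "group", values_to = "mean_abundance") %>%
    mutate(group = sub("mean_", "", .data$group))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$group,
                                             c("BZSZ", "SMTZ", "MZ")),
                                  y = .data$mean_abundance + 1,
                                  colour = .data$category)) +
    ggplot2::geom_boxplot(na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Zone group",
                  y = expression("Mean abundance + 1 (copies g"^-1 * ")"),
                  colour = "Trend category")
}
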