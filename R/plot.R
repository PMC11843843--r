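#' Plot a pressure--radius sweep
#'
#' @param object An `aorta_sweep` (from [pressure_sweep()] or
#'   [generate_membrane_series()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aorta_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ri, y = .data$P)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "inner radius [mm]", y = "pressure [kPa]") +
    ggplot2::theme_minimal()
}

#' Plot a transmural stress profile
#'
#' Total, isotropic, anisotropic and reaction stress across the deformed
#' wall in one direction, the layout used to contrast high- and low-gradient
#' aortas.
#'
#' @param object An `aorta_profile` (from [transmural_profile()]).
#' @param direction `"theta"` or `"z"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aorta_profile <- function(object, direction = c("theta", "z"), ...) {
  direction <- match.arg(direction)
  cols <- c(total = paste0("sigma_total_", direction),
            isotropic = paste0("sigma_iso_", direction),
            anisotropic = paste0("sigma_aniso_", direction),
            reaction = "reaction_p")
  d <- tibble(
    r = rep(object$r, length(cols)),
    stress = unlist(object[cols], use.names = FALSE),
    component = rep(names(cols), each = nrow(object))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$stress,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "deformed radius [mm]", y = "stress [kPa]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Membrane prediction against the in silico mid-wall stress
#'
#' Pressure--stress curves of both models for one component, from the
#' stacked series attached to a [compare_set()] result.
#'
#' @param comparison An `aorta_comparison`.
#' @param component Column to plot, e.g. `"sigma_total_theta"`.
#' @return A ggplot.
#' @export
plot_stress_comparison <- function(comparison,
                                   component = "sigma_total_theta") {
  s <- attr(comparison, "series")
  stopifnot(!is.null(s), component %in% names(s))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$P, y = .data[[component]],
                                  linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pressure [kPa]", y = paste(component, "[kPa]"),
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Collagen load-bearing fraction by group and pressure
#'
#' Bar chart of the group means (with standard error) of the circumferential
#' collagen fraction at diastolic and systolic pressure.
#'
#' @param load_fractions The `load_fractions` tibble of a
#'   [run_full_evaluation()] report.
#' @return A ggplot.
#' @export
plot_load_fraction <- function(load_fractions) {
  d <- load_fractions %>%
    tidyr::pivot_longer(c("psi_theta_dbp", "psi_theta_sbp"),
                        names_to = "pressure", values_to = "psi") %>%
    dplyr::mutate(pressure = ifelse(grepl("sbp", .data$pressure),
                                    "SBP", "DBP")) %>%
    dplyr::group_by(.data$group, .data$pressure) %>%
    dplyr::summarise(mean = mean(.data$psi),
                     sem = stats::sd(.data$psi) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean,
                                  fill = .data$pressure)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::labs(x = NULL, y = "collagen load-bearing fraction [-]",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
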