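#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prevalence curve
#'
#' @param object A `prevalence_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prevalence_curve
#' @export
autoplot.prevalence_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$age, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#B2182B") +
    ggplot2::labs(x = "age (years)", y = "prevalence p(a)") +
    ggplot2::theme_minimal()
}

#' Plot a cohort trajectory
#'
#' Shows the susceptible (`S`), diseased (`C`) and living (`N`) counts
#' against age.
#'
#' @param object A `cohort_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trajectory
#' @export
autoplot.cohort_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("S", "C", "N"),
                              names_to = "compartment", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$count,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "age (years)", y = "persons") +
    ggplot2::theme_minimal()
}

#' Plot an incidence estimate
#'
#' Negative (flagged) estimates are drawn as points so inconsistent
#' mortality assumptions are visible at a glance.
#'
#' @param object An `incidence_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot incidence_estimate
#' @export
autoplot.incidence_estimate <- function(object, ...) {
  df <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$i_hat)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "age (years)", y = "estimated incidence (per person-year)") +
    ggplot2::theme_minimal()
  if (any(df$flag_negative)) {
    gg <- gg + ggplot2::geom_point(data = df[df$flag_negative, ],
                                   colour = "#B2182B", size = 1)
  }
  gg
}

#' Plot a relative-risk scenario sweep
#'
#' One incidence curve per relative-risk scenario; the sandwich principle is
#' visible as the ordering of the curves wherever prevalence is positive.
#'
#' @param sweep A tibble from [scenario_sweep()].
#' @return A ggplot.
#' @export
plot_scenario_sweep <- function(sweep) {
  stopifnot(all(c("R", "age", "i_hat") %in% names(sweep)))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$age, y = .data$i_hat,
                                      colour = factor(.data$R),
                                      linetype = factor(.data$R))) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "age (years)", y = "estimated incidence (per person-year)",
                  colour = "R", linetype = "R") +
    ggplot2::theme_minimal()
}

#' Plot empirical versus model prevalence
#'
#' Overlays the microsimulation's empirical prevalence (with its 95% Wilson
#' band) on a deterministic model curve — the visual form of the
#' simulator/ODE consistency check.
#'
#' @param empirical A tibble from [empirical_prevalence()].
#' @param model Optional `prevalence_curve` to overlay.
#' @return A ggplot.
#' @export
plot_empirical_prevalence <- function(empirical, model = NULL) {
  stopifnot(all(c("age", "p_hat", "ci_low", "ci_high") %in% names(empirical)))
  gg <- ggplot2::ggplot(empirical, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_hat), linewidth = 0.5) +
    ggplot2::labs(x = "age (years)", y = "prevalence") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    gg <- gg + ggplot2::geom_line(data = tibble::as_tibble(model),
                                  ggplot2::aes(y = .data$p),
                                  colour = "#B2182B", linewidth = 0.7)
  }
  gg
}
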