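#' Plot a Michaelis-Menten fit
#'
#' Rate observations against mean dissolved O2 with the fitted saturation
#' curve and the Km position marked.
#'
#' @param object an `mm_fit` from [fit_michaelis_menten()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  if (object$fit_kind == "low_level") {
    d <- object$data
    curve <- tibble(
      t_hours = seq(min(d$t_hours), max(d$t_hours), length.out = 200))
    curve$DO_nM <- mm_depletion_do((curve$t_hours - d$t_hours[1]) / 24,
                                   object$S0, object$Km, object$vmax)
    return(ggplot2::ggplot(d, ggplot2::aes(.data$t_hours, .data$DO_nM)) +
             ggplot2::geom_point() +
             ggplot2::geom_line(data = curve, colour = "steelblue") +
             ggplot2::labs(x = "time (h)", y = "dissolved O2 (nM)",
                           title = sprintf("integrated MM depletion: Km = %.3g nM",
                                           object$Km)))
  }
  d <- object$data
  curve <- tibble(do_nM = exp(seq(log(max(min(d$do_nM), 1e-3)),
                                  log(max(d$do_nM)), length.out = 200)))
  curve$rate <- predict_rate(object, curve$do_nM)
  ggplot2::ggplot(d, ggplot2::aes(.data$do_nM, .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$Km, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean dissolved O2 (nM)",
                  y = "rate (nmol L^-1 day^-1)",
                  title = sprintf("Km = %.3g nM, vmax = %.3g", object$Km,
                                  object$vmax))
}

#' Plot a percentage-of-OCR power law
#'
#' Log-log scatter of the nitrite-oxidation share of oxygen consumption
#' against dissolved O2, with the fitted power law and the 100% line.
#'
#' @param object a `power_law_fit` from [fit_power_law()].
#' @param target_pct horizontal reference percentage (default 100).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.power_law_fit <- function(object, target_pct = 100, ...) {
  mf <- object$model$model
  d <- tibble(DO_nM = 10^mf$ld, pct = 10^mf$lp)
  curve <- tibble(DO_nM = 10^seq(min(mf$ld), max(mf$ld), length.out = 100))
  curve$pct <- object$a * curve$DO_nM^object$b
  ggplot2::ggplot(d, ggplot2::aes(.data$DO_nM, .data$pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = target_pct, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean dissolved O2 (nM)",
                  y = "nitrite oxidation (% of OCR)",
                  title = sprintf("pct = %.3g DO^%.3g (r2 = %.2f)", object$a,
                                  object$b, object$r2))
}

#' Plot a Delta(15,18) deviation profile
#'
#' Deviation from the 1:1 dual-isotope line against depth (depth increasing
#' downward), with the zero line and the peak-deviation depth marked.
#'
#' @param object a `deviation_profile` from [deviation_profile()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.deviation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$Delta_15_18, .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "peak_depth_m"),
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(Delta * "(15,18) (‰)"),
                  y = "depth (m)")
}

#' Quick-look station profile plot
#'
#' Dissolved O2 (log scale), nitrite and chlorophyll against depth for a
#' simulated or observed station profile.
#'
#' @param profile a data frame with `depth_m`, `DO_nM`, `NO2_nM`,
#'   `chl_mg_m3`.
#' @return a ggplot with one facet per variable.
#' @export
plot_profile <- function(profile) {
  .need_cols(profile, c("depth_m", "DO_nM"), "plot_profile")
  long <- profile |>
    dplyr::select(dplyr::any_of(c("depth_m", "DO_nM", "NO2_nM",
                                  "chl_mg_m3"))) |>
    tidyr::pivot_longer(-"depth_m", names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(y = "depth (m)", x = NULL)
}
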