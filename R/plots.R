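#' Plot a simulated or observed concentration-time profile
#'
#' Concentration versus time on a log10 concentration axis, one line per
#' matrix.
#'
#' @param object A `pbpk_profile` (or any profile tibble).
#' @param matrices Matrices to show (default `"plasma"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pbpk_profile
#' @export
autoplot.pbpk_profile <- function(object, matrices = "plasma", ...) {
  df <- dplyr::filter(object, .data$matrix %in% matrices,
                      .data$conc_ng_per_ml > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$conc_ng_per_ml,
                                   colour = .data$matrix)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @param object An `allometric_fit`.
#' @param ... Unused.
#' @rdname allometric_fit
#' @method autoplot allometric_fit
#' @export
autoplot.allometric_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(
    bw_kg = exp(seq(log(min(pts$bw_kg)), log(max(pts$bw_kg) * 20),
                    length.out = 100)))
  grid$cl <- predict(object, grid$bw_kg)
  ggplot2::ggplot(pts, ggplot2::aes(.data$bw_kg, .data$cl)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Body weight (kg)", y = "Clearance (L/h)",
                  title = sprintf("CL = %.3g x BW^%.3g", object$a, object$b)) +
    ggplot2::theme_bw()
}

#' Plot a parameter sensitivity scan
#'
#' Plasma concentration-time profiles, one curve per scanned parameter value.
#'
#' @param object A `pbpk_psa` result (see [psa()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pbpk_psa
#' @export
autoplot.pbpk_psa <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(object,
                  value_lab = factor(signif(.data$value, 3)),
                  profile = purrr::map(.data$profile,
                                       ~dplyr::select(.x, "time_h", "conc_ng_per_ml"))),
    "profile")
  df <- dplyr::filter(df, .data$conc_ng_per_ml > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$conc_ng_per_ml,
                                   colour = .data$value_lab)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  colour = "value") +
    ggplot2::theme_bw()
}

#' Predicted-versus-observed plot
#'
#' Observed points over the predicted curve, log10 concentration axis.
#'
#' @param pred Predicted profile (single matrix).
#' @param obs Observed profile.
#' @return A ggplot object.
#' @export
plot_pred_obs <- function(pred, obs) {
  ggplot2::ggplot() +
    ggplot2::geom_line(data = dplyr::filter(pred, .data$conc_ng_per_ml > 0),
                       ggplot2::aes(.data$time_h, .data$conc_ng_per_ml)) +
    ggplot2::geom_point(data = dplyr::filter(obs, .data$conc_ng_per_ml > 0),
                        ggplot2::aes(.data$time_h, .data$conc_ng_per_ml),
                        shape = 1, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)") +
    ggplot2::theme_bw()
}
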