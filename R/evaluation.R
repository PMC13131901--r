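#' Predictive-performance statistics
#'
#' Point metrics comparing predicted and observed exposure:
#' * `fold_error(pred, obs)` — the ratio `pred / obs`;
#' * `afe(pred, obs)` — the average fold error,
#'   \eqn{10^{\mathrm{mean}(\log_{10}(pred/obs))}};
#' * `rmse_log(pred, obs)` — the root mean square error of log10-transformed
#'   values, \eqn{\sqrt{\mathrm{mean}((\log_{10} pred - \log_{10} obs)^2)}}.
#'
#' All inputs must be strictly positive; `afe` and `rmse_log` operate on
#' time-matched vectors. Logs are base 10 throughout.
#'
#' @param pred,obs Predicted and observed values (vectors of equal length for
#'   `afe` / `rmse_log`).
#' @return A numeric scalar.
#' @examples
#' fold_error(143, 136)
#' afe(c(2, 0.5), c(1, 1))    # 1: reciprocal symmetry
#' rmse_log(10, 1)            # 1 log10 unit
#' @export
fold_error <- function(pred, obs) {
  check_pos_pairs(pred, obs)
  pred / obs
}

#' @rdname fold_error
#' @export
afe <- function(pred, obs) {
  check_pos_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' @rdname fold_error
#' @export
rmse_log <- function(pred, obs) {
  check_pos_pairs(pred, obs)
  sqrt(mean((log10(pred) - log10(obs))^2))
}

check_pos_pairs <- function(pred, obs) {
  if (length(pred) == 0 || length(obs) == 0) {
    abort("pred and obs must be non-empty.")
  }
  if (length(pred) != length(obs)) abort("pred and obs lengths differ.")
  if (any(!is.finite(pred) | pred <= 0) || any(!is.finite(obs) | obs <= 0)) {
    abort("pred and obs must be strictly positive and finite.")
  }
  invisible(TRUE)
}

#' Evaluate a predicted profile against observations
#'
#' Computes the AUC ratio over a stated window (both AUCs by the log-linear
#' trapezoidal rule), the average fold error and log-scale RMSE over all
#' matched concentration points, and the 2-fold acceptance flag
#' (`0.5 <= AUC ratio <= 2`). Predicted concentrations are evaluated at the
#' observed sampling times by log-linear interpolation of the (densely
#' sampled) predicted curve — the same interpolation convention as the AUC
#' rule. Observed values at or below zero (below the quantification limit) are
#' excluded from AFE/RMSE and counted.
#'
#' @param pred Predicted profile (single matrix): `time_h`, `conc_ng_per_ml`.
#' @param obs Observed profile, same schema.
#' @param auc_window_h AUC window end in hours (default 24, the 24 h following
#'   the first dose).
#' @return A one-row tibble: `auc_obs`, `auc_pred`, `auc_ratio`, `afe`,
#'   `rmse`, `n_matched`, `n_blq`, `pass_2fold`.
#' @export
evaluate_profile <- function(pred, obs, auc_window_h = 24) {
  stopifnot(all(c("time_h", "conc_ng_per_ml") %in% names(pred)),
            all(c("time_h", "conc_ng_per_ml") %in% names(obs)))
  pred <- dplyr::arrange(tibble::as_tibble(pred), .data$time_h)
  obs <- dplyr::arrange(tibble::as_tibble(obs), .data$time_h)
  if (max(obs$time_h) < min(pred$time_h) || min(obs$time_h) > max(pred$time_h)) {
    abort("Predicted and observed profiles have no overlapping time support.")
  }

  auc_obs <- auc_loglinear(obs$time_h, obs$conc_ng_per_ml,
                           t_end = min(auc_window_h, max(obs$time_h)))
  auc_pred <- auc_loglinear(pred$time_h, pred$conc_ng_per_ml,
                            t_end = min(auc_window_h, max(pred$time_h)))

  blq <- obs$conc_ng_per_ml <= 0
  omatch <- obs[!blq, , drop = FALSE]
  if (nrow(omatch) == 0) abort("No quantifiable observed points to match.")
  cpred <- interp_conc(pred$time_h, pred$conc_ng_per_ml, omatch$time_h)
  ok <- cpred > 0
  if (!any(ok)) abort("No matched time points with positive predictions.")

  ratio <- fold_error(auc_pred, auc_obs)
  tibble::tibble(
    auc_obs = auc_obs,
    auc_pred = auc_pred,
    auc_ratio = ratio,
    afe = afe(cpred[ok], omatch$conc_ng_per_ml[ok]),
    rmse = rmse_log(cpred[ok], omatch$conc_ng_per_ml[ok]),
    n_matched = sum(ok),
    n_blq = sum(blq),
    pass_2fold = ratio >= 0.5 & ratio <= 2
  )
}
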