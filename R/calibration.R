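#' Calibrate the specific permeability-surface-area product to mouse plasma PK
#'
#' Middle-out calibration step: the single parameter `SpecPStc` is optimized
#' against an observed mouse plasma concentration-time profile while the
#' systemic clearance is held fixed at its NCA-derived value. The objective is
#' the relative (1/prediction-squared weighted) least squares
#' \deqn{\sum_i (C_{obs,i} - C_{pred,i})^2 / C_{pred,i}^2,}
#' minimized by bounded scalar search over `log10(SpecPStc)` — the two
#' compounds' calibrated values differ by two orders of magnitude, so the
#' search is carried out on the log scale.
#'
#' @param observed Observed plasma profile: a data frame with `time_h` and
#'   `conc_ng_per_ml` (>= 4 points).
#' @param compound A `pbpk_compound` (its `spec_pstc` is ignored).
#' @param physiology A `pbpk_physiology` for the calibration species.
#' @param regimen The dosing regimen of the observed study.
#' @param clearance_L_h Fixed systemic clearance input (absolute, L/h),
#'   typically from [observed_clearance()].
#' @param species Calibration species label (default `"mouse"`).
#' @param bounds Search bounds on `SpecPStc` (mL/s/mL), default `c(1e-6, 1)`.
#' @param tol Relative convergence tolerance of the scalar search.
#' @return An object of class `spec_pstc_fit`: `spec_pstc`, `objective`,
#'   `at_bound` (logical), `bounds`, and a `fitted` tibble of observed vs
#'   predicted concentrations. Supports [tidy()] and [glance()].
#' @export
fit_spec_pstc <- function(observed, compound, physiology, regimen,
                          clearance_L_h, species = "mouse",
                          bounds = c(1e-6, 1), tol = 1e-5) {
  stopifnot(all(c("time_h", "conc_ng_per_ml") %in% names(observed)))
  obs <- dplyr::arrange(tibble::as_tibble(observed), .data$time_h)
  obs <- dplyr::filter(obs, .data$conc_ng_per_ml > 0)
  if (nrow(obs) < 4) abort("Calibration needs >= 4 positive observed points.")
  if (any(bounds <= 0) || bounds[1] >= bounds[2]) {
    abort("bounds must be positive and increasing.")
  }
  kp <- predict_kp(compound, physiology, species)
  duration <- max(obs$time_h)

  objective <- function(log10_ps) {
    mod <- pbpk_model(compound, physiology, species, clearance_L_h,
                      kp = kp, spec_pstc = 10^log10_ps)
    sim <- simulate_pbpk(mod, regimen, duration_h = duration,
                         output_times = sort(unique(c(0, obs$time_h))))
    pred <- profile_matrix(sim, "plasma")
    cp <- pred$conc_ng_per_ml[match(obs$time_h, pred$time_h)]
    if (any(!is.finite(cp)) || any(cp <= 0)) return(Inf)
    sum((obs$conc_ng_per_ml - cp)^2 / cp^2)
  }

  opt <- optimize(objective, interval = log10(bounds), tol = tol)
  if (!is.finite(opt$objective)) {
    abort("Calibration objective non-finite across the search bracket.")
  }
  ps_hat <- 10^opt$minimum
  at_bound <- min(abs(opt$minimum - log10(bounds))) < 2 * tol
  if (at_bound) {
    warn(sprintf("Fitted SpecPStc %.3g is at a search bound [%g, %g].",
                 ps_hat, bounds[1], bounds[2]))
  }

  mod <- pbpk_model(compound, physiology, species, clearance_L_h,
                    kp = kp, spec_pstc = ps_hat)
  sim <- simulate_pbpk(mod, regimen, duration_h = duration,
                       output_times = sort(unique(c(0, obs$time_h))))
  pred <- profile_matrix(sim, "plasma")
  fitted <- tibble::tibble(
    time_h = obs$time_h,
    observed = obs$conc_ng_per_ml,
    predicted = pred$conc_ng_per_ml[match(obs$time_h, pred$time_h)]
  )
  structure(list(
    spec_pstc = ps_hat,
    objective = opt$objective,
    at_bound = at_bound,
    bounds = bounds,
    compound = compound$name,
    species = species,
    fitted = fitted
  ), class = "spec_pstc_fit")
}

#' @export
print.spec_pstc_fit <- function(x, ...) {
  cat(sprintf("<spec_pstc_fit> %s (%s): SpecPStc = %.4g mL/s/mL, objective %.4g%s\n",
              x$compound, x$species, x$spec_pstc, x$objective,
              if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

#' @method tidy spec_pstc_fit
#' @export
tidy.spec_pstc_fit <- function(x, ...) {
  tibble::tibble(term = "spec_pstc", estimate = x$spec_pstc)
}

#' @method glance spec_pstc_fit
#' @export
glance.spec_pstc_fit <- function(x, ...) {
  tibble::tibble(spec_pstc = x$spec_pstc, objective = x$objective,
                 at_bound = x$at_bound, nobs = nrow(x$fitted))
}
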