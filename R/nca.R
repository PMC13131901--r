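#' Area under the curve by the log-linear trapezoidal rule
#'
#' Per interval, when the concentration is strictly decreasing and both ends
#' are positive the logarithmic trapezoid \eqn{(C_1 - C_2)\Delta t /
#' \ln(C_1/C_2)} is used; otherwise (rising, flat, or zero/negative
#' concentrations) the linear trapezoid \eqn{(C_1 + C_2)\Delta t / 2}. The
#' log rule is exact on mono-exponential decay at any sampling times.
#'
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations at `time` (ng/mL).
#' @param t_end Optional right end of the integration window; the profile is
#'   truncated at `t_end` (with log-linear interpolation of the concentration
#'   at `t_end` if it falls inside a sampled interval).
#' @return The AUC (ng/mL·h).
#' @examples
#' auc_loglinear(c(0, 1), c(100, 100))   # flat: 100
#' auc_loglinear(c(0, 1), c(50, 100))    # rising: linear rule, 75
#' @export
auc_loglinear <- function(time, conc, t_end = NULL) {
  stopifnot(is.numeric(time), is.numeric(conc), length(time) == length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (anyDuplicated(time)) abort("Duplicated timestamps are not allowed.")
  if (!is.null(t_end)) {
    if (sum(time <= t_end) < 2) abort("Need >= 2 points with time <= t_end.")
    if (max(time) > t_end) {
      c_end <- interp_conc(time, conc, t_end)
      keep <- time < t_end
      time <- c(time[keep], t_end)
      conc <- c(conc[keep], c_end)
    }
  }
  if (length(time) < 2) abort("Need at least 2 points to compute an AUC.")
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  dt <- diff(time)
  uselog <- c2 < c1 & c1 > 0 & c2 > 0
  seg <- (c1 + c2) * dt / 2
  seg[uselog] <- (c1[uselog] - c2[uselog]) * dt[uselog] /
    log(c1[uselog] / c2[uselog])
  sum(seg)
}

# Log-linear interpolation of concentration at time t (linear when either
# bracketing concentration is non-positive) -- the same convention as the AUC
# rule.
interp_conc <- function(time, conc, t) {
  vapply(t, function(tt) {
    if (tt <= min(time)) return(conc[which.min(time)])
    if (tt >= max(time)) return(conc[which.max(time)])
    i <- findInterval(tt, time)
    t1 <- time[i]; t2 <- time[i + 1]
    c1 <- conc[i]; c2 <- conc[i + 1]
    if (tt == t1) return(c1)
    w <- (tt - t1) / (t2 - t1)
    if (c1 > 0 && c2 > 0 && c2 < c1) {
      exp(log(c1) + w * (log(c2) - log(c1)))
    } else {
      c1 + w * (c2 - c1)
    }
  }, numeric(1))
}

#' Observed clearance from dose and AUC
#'
#' `CL = Dose / AUC`, with the unit convention used throughout the package:
#' dose in micrograms per kg and AUC in ng/mL·h (= µg/L·h) give clearance in
#' mL/h/kg (equivalently L/h/kg when divided by 1000).
#'
#' @param dose_ug_kg Dose, µg/kg.
#' @param auc_ng_h_ml AUC, ng/mL·h.
#' @return Clearance, mL/h/kg.
#' @examples
#' observed_clearance(13.18, 255)  # monkey: ~51.7 mL/h/kg
#' @export
observed_clearance <- function(dose_ug_kg, auc_ng_h_ml) {
  if (any(dose_ug_kg <= 0)) abort("Dose must be > 0.")
  if (any(auc_ng_h_ml <= 0)) abort("AUC must be > 0.")
  # ug/kg over ug/L.h -> L/h/kg; x1000 -> mL/h/kg
  dose_ug_kg / auc_ng_h_ml * 1000
}

#' Non-compartmental summary of a concentration-time profile
#'
#' Computes `AUC_last` by the log-linear trapezoidal rule, the terminal rate
#' constant (log-linear regression on the last `n_lambda_z` positive points),
#' the extrapolated `AUC_inf`, and clearance from the administered dose.
#'
#' @param profile A profile tibble with `time_h` and `conc_ng_per_ml` (a
#'   single matrix; see [profile_matrix()]).
#' @param dose_ug_kg Administered dose, µg/kg; taken from the profile's
#'   `dose_ug_kg` column if absent.
#' @param t_end Optional AUC window end (h).
#' @param n_lambda_z Number of terminal positive points for the
#'   extrapolation (default 3).
#' @return A one-row tibble: `auc_last`, `auc_inf`, `lambda_z`,
#'   `cl_ml_h_kg`, `dose_ug_kg`, `n_points`.
#' @export
nca_summary <- function(profile, dose_ug_kg = NULL, t_end = NULL,
                        n_lambda_z = 3) {
  stopifnot(all(c("time_h", "conc_ng_per_ml") %in% names(profile)))
  mx <- if ("matrix" %in% names(profile)) profile$matrix else "plasma"
  if (length(unique(mx)) > 1) {
    abort("Profile contains multiple matrices; select one with profile_matrix().")
  }
  if (!"dose_ug_kg" %in% names(profile) && is.null(dose_ug_kg)) {
    abort("Supply dose_ug_kg (not present in the profile).")
  }
  dose_ug_kg <- dose_ug_kg %||% unique(profile$dose_ug_kg)
  stopifnot(length(dose_ug_kg) == 1L)
  time <- profile$time_h; conc <- profile$conc_ng_per_ml
  auc_last <- auc_loglinear(time, conc, t_end = t_end)

  pos <- which(conc > 0)
  lambda_z <- NA_real_; auc_inf <- NA_real_
  if (length(pos) >= n_lambda_z) {
    tail_i <- utils::tail(pos, n_lambda_z)
    fit <- lm(log(conc[tail_i]) ~ time[tail_i])
    lz <- -unname(coef(fit)[2])
    if (is.finite(lz) && lz > 0) {
      lambda_z <- lz
      auc_inf <- auc_last + conc[max(pos)] / lz
    }
  }
  tibble::tibble(
    auc_last = auc_last,
    auc_inf = auc_inf,
    lambda_z = lambda_z,
    cl_ml_h_kg = observed_clearance(dose_ug_kg, auc_last),
    dose_ug_kg = dose_ug_kg,
    n_points = length(time)
  )
}
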