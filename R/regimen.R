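#' Define an intravenous dosing regimen
#'
#' Builds the dose-event table for an IV regimen: bolus doses
#' (`infusion_h = 0`) or zero-order infusions, optionally repeated on a fixed
#' interdose interval (e.g. a 6-hour infusion daily for 7 days).
#'
#' @param dose_ug_kg Dose per administration, in micrograms per kg body weight.
#' @param infusion_h Infusion duration in hours; `0` for an IV bolus.
#' @param n_doses Number of administrations.
#' @param interval_h Interdose interval in hours (ignored when `n_doses = 1`).
#' @param start_h Time of the first administration, hours.
#' @return A tibble of class `pbpk_regimen` with columns `start_h`,
#'   `dose_ug_kg`, `infusion_h`.
#' @examples
#' iv_regimen(13)                                  # single bolus
#' iv_regimen(13, infusion_h = 6, n_doses = 7, interval_h = 24)
#' @export
iv_regimen <- function(dose_ug_kg, infusion_h = 0, n_doses = 1,
                       interval_h = 24, start_h = 0) {
  stopifnot(is.numeric(dose_ug_kg), length(dose_ug_kg) == 1L)
  if (dose_ug_kg <= 0) abort("Dose amounts must be > 0.")
  if (infusion_h < 0) abort("Infusion duration must be >= 0.")
  if (n_doses < 1) abort("n_doses must be >= 1.")
  if (n_doses > 1 && interval_h <= 0) abort("interval_h must be > 0.")
  if (n_doses > 1 && infusion_h > interval_h) {
    abort("Infusion windows overlap: infusion_h exceeds interval_h.")
  }
  out <- tibble::tibble(
    start_h = start_h + (seq_len(n_doses) - 1) * ifelse(n_doses > 1, interval_h, 0),
    dose_ug_kg = dose_ug_kg,
    infusion_h = infusion_h
  )
  class(out) <- c("pbpk_regimen", class(out))
  out
}

as_regimen <- function(x) {
  if (inherits(x, "pbpk_regimen")) return(x)
  stopifnot(is.data.frame(x),
            all(c("start_h", "dose_ug_kg", "infusion_h") %in% names(x)))
  if (any(x$dose_ug_kg <= 0)) abort("Dose amounts must be > 0.")
  if (any(x$infusion_h < 0)) abort("Infusion durations must be >= 0.")
  structure(tibble::as_tibble(x), class = c("pbpk_regimen", class(tibble::tibble())))
}

# Total administered amount (ug) at time t for a regimen in absolute units.
administered_ug <- function(events, t) {
  vapply(t, function(tt) {
    done <- pmax(0, pmin(tt - events$start_h,
                         pmax(events$infusion_h, 0)))
    bolus <- events$infusion_h == 0
    sum(events$amount_ug[bolus] * (events$start_h[bolus] <= tt)) +
      sum(ifelse(events$infusion_h > 0,
                 events$amount_ug * done / events$infusion_h, 0))
  }, numeric(1))
}
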