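#' Renal filtration clearance
#'
#' The filtration floor of systemic clearance: `CL_R = fup x GFR`.
#'
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param gfr Glomerular filtration rate (any volume/time unit; the result is
#'   in the same unit).
#' @return `fup * gfr`.
#' @examples
#' renal_filtration_cl(1, 6)        # 6 L/h
#' @export
renal_filtration_cl <- function(fup, gfr) {
  if (any(!is.finite(fup) | fup <= 0 | fup > 1)) {
    abort("fup must lie in (0, 1].")
  }
  if (any(!is.finite(gfr) | gfr <= 0)) abort("GFR must be > 0.")
  fup * gfr
}

#' Species clearance records for the additional-clearance method
#'
#' Splits each species' observed systemic clearance into a renal filtration
#' component `CL_R = fup x GFR` and the residual additional clearance
#' `CL_add = CL_obs - CL_R`, and expresses the latter as a percentage of
#' `CL_obs`. A species with `CL_obs < CL_R` has `CL_add` clamped to 0 with a
#' warning.
#'
#' @param data A data frame with one row per species: columns `species`,
#'   `cl_obs` (volume/time), `fup` (fraction) and `gfr` (same volume/time unit
#'   as `cl_obs`; use per-kg or absolute units consistently).
#' @return A tibble adding `cl_r`, `cl_add`, `pct_cl_add`.
#' @examples
#' recs <- clearance_records(tibble::tibble(
#'   species = c("mouse", "rat"), cl_obs = c(1049, 2890),
#'   fup = c(0.0255, 0.1665), gfr = c(840, 314)))
#' @export
clearance_records <- function(data) {
  stopifnot(all(c("species", "cl_obs", "fup", "gfr") %in% names(data)))
  out <- dplyr::mutate(tibble::as_tibble(data),
                       cl_r = renal_filtration_cl(.data$fup, .data$gfr),
                       cl_add = .data$cl_obs - .data$cl_r)
  if (any(out$cl_add < 0)) {
    warn(paste0("CL_obs < CL_R for: ",
                paste(out$species[out$cl_add < 0], collapse = ", "),
                "; CL_add clamped to 0."))
    out$cl_add <- pmax(out$cl_add, 0)
  }
  dplyr::mutate(out, pct_cl_add = .data$cl_add / .data$cl_obs * 100)
}

#' Human clearance by the additional-clearance approach (Method 1)
#'
#' The percentage of observed clearance not explained by renal filtration
#' (`%CL_add`) is computed per preclinical species, averaged geometrically,
#' and the human clearance is back-calculated from the human filtration
#' clearance:
#' \deqn{CL_{human} = \frac{CL_{R,human}}{100 - \overline{\%CL_{add}}} \times 100}
#' with \eqn{CL_{R,human} = fu_{p,human} \times GFR_{human}}. When every
#' species has `%CL_add = 0` the method reduces exactly to renal filtration;
#' isolated zero values are floored at 0.1% with a warning (the geometric mean
#' is undefined at zero). A geometric mean at or above 100% is an error.
#'
#' @param records Output of [clearance_records()] (or any data frame with a
#'   `pct_cl_add` column), one row per preclinical species.
#' @param fup_human Human fraction unbound.
#' @param gfr_human Human GFR (the result is in the same volume/time unit).
#' @return A list: `cl_human`, `cl_r_human`, `pct_cl_add_mean` (geometric),
#'   and the per-species `records`.
#' @export
additional_clearance_human <- function(records, fup_human, gfr_human) {
  stopifnot("pct_cl_add" %in% names(records), nrow(records) >= 1)
  pct <- records$pct_cl_add
  if (any(pct < 0 | pct >= 100)) {
    abort("Each species %CL_add must lie in [0, 100).")
  }
  if (all(pct == 0)) {
    gm <- 0  # filtration-only limit: CL_human = fup x GFR exactly
  } else {
    if (any(pct == 0)) {
      warn("%CL_add of 0 floored at 0.1% for the geometric mean.")
      pct[pct == 0] <- 0.1
    }
    gm <- exp(mean(log(pct)))
  }
  if (gm >= 100) abort("Geometric mean %CL_add >= 100%; human CL undefined.")
  cl_r_h <- renal_filtration_cl(fup_human, gfr_human)
  list(
    cl_human = cl_r_h / (100 - gm) * 100,
    cl_r_human = cl_r_h,
    pct_cl_add_mean = gm,
    records = records
  )
}

#' Fit the allometric power law CL = a x BW^b (Method 2)
#'
#' Ordinary least squares of `log(CL)` on `log(BW)`; the coefficient is
#' `a = exp(intercept)` and the exponent `b` is the slope. Clearances should
#' be ABSOLUTE (volume/time), the standard convention for the power law;
#' convert per-kg values with the species body weight first.
#'
#' @param data A data frame with columns `bw_kg` and `cl` (absolute), one row
#'   per species; at least 2 rows with distinct body weights.
#' @return An object of class `allometric_fit` with elements `a`, `b`,
#'   `r_squared`, `points`, and the underlying `lm` fit. Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @examples
#' fit <- allometric_fit(tibble::tibble(bw_kg = c(0.025, 0.25, 5),
#'                                      cl = 2 * c(0.025, 0.25, 5)^0.75))
#' predict(fit, bw_kg = 50)
#' @export
allometric_fit <- function(data) {
  stopifnot(all(c("bw_kg", "cl") %in% names(data)))
  if (nrow(data) < 2) abort("Allometric fit needs >= 2 species points.")
  if (any(data$bw_kg <= 0) || any(data$cl <= 0)) {
    abort("Body weights and clearances must be > 0.")
  }
  if (length(unique(data$bw_kg)) < 2) {
    abort("Allometric fit is singular: body weights are not distinct.")
  }
  fit <- lm(log(cl) ~ log(bw_kg), data = data)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(data$cl) - mean(log(data$cl)))^2)
  structure(list(
    a = exp(unname(coef(fit)[1])),
    b = unname(coef(fit)[2]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    points = tibble::as_tibble(data),
    fit = fit
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> CL = %.4g x BW^%.4g (R2 on log scale %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @param object An `allometric_fit`.
#' @param bw_kg Body weight(s) at which to predict, kg.
#' @param ... Unused.
#' @rdname allometric_fit
#' @export
predict.allometric_fit <- function(object, bw_kg, ...) {
  stopifnot(all(bw_kg > 0))
  object$a * bw_kg^object$b
}

#' @method tidy allometric_fit
#' @export
tidy.allometric_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance allometric_fit
#' @export
glance.allometric_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r.squared = x$r_squared,
                 nobs = nrow(x$points))
}

#' Single-species scaling from monkey (Method 3)
#'
#' `CL_human = CL_monkey x (BW_human / BW_monkey)^exponent` with the fixed
#' allometric exponent 0.75 by default.
#'
#' @param cl_monkey Monkey absolute clearance (volume/time).
#' @param bw_monkey,bw_human Body weights, kg (defaults 5 and 50).
#' @param exponent Allometric exponent (default 0.75).
#' @return Scaled human clearance, same unit as `cl_monkey`.
#' @examples
#' single_species_scale(1, 5, 50)  # 10^0.75 ~ 5.62
#' @export
single_species_scale <- function(cl_monkey, bw_monkey = 5, bw_human = 50,
                                 exponent = 0.75) {
  if (any(c(cl_monkey, bw_monkey, bw_human) <= 0)) {
    abort("Clearance and body weights must be > 0.")
  }
  cl_monkey * (bw_human / bw_monkey)^exponent
}
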