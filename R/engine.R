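#' Assemble a permeability-limited whole-body PBPK model
#'
#' Builds the ODE system simulated by [simulate_pbpk()]. The lung sits in
#' series with the cardiac output between the venous and arterial blood pools;
#' the liver receives the hepatic artery plus the portal outflow of gut and
#' spleen. Every tissue is split into a flow-connected extracellular space and
#' an intracellular space connected by a permeability term with
#' \eqn{PS_t = SpecPStc \times V_{ic,t}} (the specific permeability-surface
#' area product scaled by intracellular volume). Under the default
#' `ps_driving = "unbound"` convention only unbound drug crosses the cell
#' membrane, so the exchange rate carries the tissue extracellular unbound
#' fraction: flux \eqn{PS_t fu_t (C_{ec,t} - C_{ic,t}/Kp_t)}; this is the
#' convention under which the bundled `SpecPStc` values were calibrated, and a
#' very highly bound compound (fup 0.1%) therefore enters cells orders of
#' magnitude more slowly than a weakly bound one at the same `SpecPStc`.
#' `ps_driving = "total"` drops the \eqn{fu_t} factor (flux
#' \eqn{PS_t (C_{ec,t} - C_{ic,t}/Kp_t)}). The equilibrium ratio
#' \eqn{C_{ic}/C_{ec} \to Kp_t} is identical under both conventions; only the
#' uptake rate differs. Systemic clearance removes
#' drug from venous plasma at rate \eqn{CL \times C_{plasma}}; blood and
#' plasma concentrations are related by the blood-to-plasma ratio,
#' \eqn{C_{blood} = BPR \times C_{plasma}}.
#'
#' Flow terms carry blood concentration: tissue inflow is
#' \eqn{Q_t C_{art,blood}} and outflow \eqn{Q_t \cdot BPR \cdot C_{ec,t}}
#' (the extracellular space is held in plasma-equivalent concentration units).
#' The clearance construct is empirical: the observed or projected systemic
#' clearance is supplied as `clearance_L_h` and acts on total venous plasma,
#' which makes the distribution-free identity
#' \eqn{AUC_{0-\infty} = Dose/CL} exact.
#'
#' @param compound A `pbpk_compound`.
#' @param physiology A `pbpk_physiology`.
#' @param species Species label; selects `fup`/`bpr` entries.
#' @param clearance_L_h Systemic (plasma) clearance input, L/h; `>= 0`.
#' @param kp Optional `pbpk_kpset`; defaults to
#'   `predict_kp(compound, physiology, species)`.
#' @param spec_pstc,bpr Optional overrides (used by calibration and PSA).
#' @param ps_driving `"unbound"` (default) or `"total"`: whether the
#'   permeability exchange is driven by unbound or total extracellular
#'   concentration.
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(compound, physiology, species, clearance_L_h,
                       kp = NULL, spec_pstc = NULL, bpr = NULL,
                       ps_driving = c("unbound", "total")) {
  ps_driving <- match.arg(ps_driving)
  stopifnot(inherits(compound, "pbpk_compound"),
            inherits(physiology, "pbpk_physiology"))
  if (!is.finite(clearance_L_h) || clearance_L_h < 0) {
    abort("clearance_L_h must be finite and >= 0.")
  }
  bpr <- bpr %||% species_param(compound, "bpr", species)
  spec_pstc <- spec_pstc %||% compound$spec_pstc
  if (spec_pstc < 0) abort("spec_pstc must be >= 0.")
  kp <- kp %||% predict_kp(compound, physiology, species)

  tis <- physiology$tissues
  kp_map <- setNames(kp$kp, kp$tissue)
  fut_map <- setNames(kp$fut, kp$tissue)
  if (!all(tis$tissue %in% names(kp_map))) {
    abort(paste0("Missing Kp for tissue(s): ",
                 paste(setdiff(tis$tissue, names(kp_map)), collapse = ", ")))
  }
  if (!"lung" %in% tis$tissue) abort("Physiology must contain a lung tissue.")

  v_ec <- tis$volume_L * tis$ecf
  v_ic <- tis$volume_L * (1 - tis$ecf)
  fu_drive <- if (ps_driving == "unbound") unname(fut_map[tis$tissue]) else
    rep(1, nrow(tis))
  structure(list(
    compound = compound$name,
    species = species,
    body_weight_kg = physiology$body_weight_kg,
    tissue = tis$tissue,
    Q = tis$flow_L_h,
    v_ec = v_ec,
    v_ic = v_ic,
    ps = spec_pstc * v_ic * 3600 * fu_drive,  # mL/s per mL cell volume -> L/h
    ps_driving = ps_driving,
    kp = unname(kp_map[tis$tissue]),
    bpr = bpr,
    cl = clearance_L_h,
    co = physiology$cardiac_output_L_h,
    v_ven = physiology$blood_volume_L * 2 / 3,
    v_art = physiology$blood_volume_L * 1 / 3,
    spec_pstc = spec_pstc
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s in %s: CL %.4g L/h, BPR %.3g, SpecPStc %.3g, %d tissues\n",
              x$compound, x$species, x$cl, x$bpr, x$spec_pstc,
              length(x$tissue)))
  invisible(x)
}

pbpk_rhs <- function(model) {
  nt <- length(model$tissue)
  i_lung <- match("lung", model$tissue)
  i_liver <- match("liver", model$tissue)
  i_gut <- match("gut", model$tissue)
  i_spleen <- match("spleen", model$tissue)
  portal <- c(i_gut, i_spleen)
  portal <- portal[!is.na(portal)]
  has_liver <- !is.na(i_liver)
  # tissues whose venous outflow returns directly to the venous pool
  direct <- setdiff(seq_len(nt), c(i_lung, if (has_liver) c(i_liver, portal)))
  q_liver_total <- if (has_liver) model$Q[i_liver] + sum(model$Q[portal]) else 0

  Q <- model$Q; v_ec <- model$v_ec; v_ic <- model$v_ic
  ps <- model$ps; kp <- model$kp; bpr <- model$bpr
  cl <- model$cl; co <- model$co
  v_ven <- model$v_ven; v_art <- model$v_art

  function(t, y, parms) {
    c_ven <- y[1] / v_ven             # venous blood conc
    c_art <- y[2] / v_art             # arterial blood conc
    ec <- y[3:(2 + nt)]
    ic <- y[(3 + nt):(2 + 2 * nt)]
    c_ec <- ec / v_ec                 # plasma-equivalent
    c_ic <- ic / v_ic
    flux <- ps * (c_ec - c_ic / kp)

    inflow <- Q * c_art
    outflow <- Q * bpr * c_ec
    d_ec <- inflow - outflow - flux
    # lung: perfused by the full cardiac output from the venous pool
    d_ec[i_lung] <- co * c_ven - co * bpr * c_ec[i_lung] - flux[i_lung]
    if (has_liver) {
      liver_in <- Q[i_liver] * c_art + sum(Q[portal] * bpr * c_ec[portal])
      liver_out <- q_liver_total * bpr * c_ec[i_liver]
      d_ec[i_liver] <- liver_in - liver_out - flux[i_liver]
      venous_return <- sum(outflow[direct]) + liver_out
    } else {
      venous_return <- sum(outflow[direct])
    }

    c_pl_ven <- c_ven / bpr
    d_ven <- venous_return - co * c_ven - cl * c_pl_ven + parms[["inf_rate"]]
    d_art <- co * bpr * c_ec[i_lung] - sum(Q[-i_lung]) * c_art
    d_clr <- cl * c_pl_ven
    list(c(d_ven, d_art, d_ec, flux, d_clr))
  }
}

#' Simulate a PBPK model under a dosing regimen
#'
#' Integrates the model ODEs with a stiff-capable solver ([deSolve::lsoda()],
#' relative tolerance `1e-8`, absolute tolerance `1e-12` in amount units).
#' Infusions enter the venous pool as zero-order input over the stated
#' duration; integration is restarted at every dose boundary so the forcing is
#' exact. At a bolus time the reported concentration is the post-dose value.
#'
#' @param model A `pbpk_model`.
#' @param regimen A `pbpk_regimen` (see [iv_regimen()]); doses are per kg and
#'   converted with the model's body weight.
#' @param duration_h Simulation duration, hours.
#' @param output_interval_h Output grid spacing, hours (default 0.5).
#' @param output_times Optional explicit output times (overrides the grid).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `pbpk_profile`, long format: `time_h`,
#'   `conc_ng_per_ml`, `matrix` (`"plasma"`, `"blood"` or a tissue name, total
#'   tissue concentration), `compound`, `species`, `dose_ug_kg`. The attribute
#'   `"balance"` carries a per-time mass balance tibble (`administered_ug`,
#'   `in_body_ug`, `cleared_ug`).
#' @examples
#' mtm <- load_compound(mtmpbpk_example("compounds/mtm.yaml"))
#' mod <- pbpk_model(mtm, species_physiology("human"), "human", clearance_L_h = 5)
#' sim <- simulate_pbpk(mod, iv_regimen(13, infusion_h = 6), duration_h = 24)
#' dplyr::filter(sim, matrix == "plasma")
#' @export
simulate_pbpk <- function(model, regimen, duration_h,
                          output_interval_h = 0.5, output_times = NULL,
                          rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(model, "pbpk_model"))
  regimen <- as_regimen(regimen)
  if (duration_h <= 0) abort("duration_h must be > 0.")

  events <- dplyr::mutate(tibble::as_tibble(regimen),
                          amount_ug = .data$dose_ug_kg * model$body_weight_kg)
  out_times <- output_times %||% seq(0, duration_h, by = output_interval_h)
  # canonicalize to nanosecond-scale precision so near-identical times from
  # different grid constructions collapse to one output row
  out_times <- sort(unique(round(out_times, 9)))
  # floating-point-safe: times a hair beyond the end snap to the end
  out_times[out_times > duration_h & out_times < duration_h + 1e-6] <- duration_h
  out_times <- unique(out_times)
  if (min(out_times) < 0 || max(out_times) > duration_h) {
    abort("output times must lie within [0, duration_h].")
  }

  breaks <- sort(unique(c(0, duration_h,
                          events$start_h,
                          events$start_h + events$infusion_h)))
  breaks <- breaks[breaks >= 0 & breaks <= duration_h]

  nt <- length(model$tissue)
  rhs <- pbpk_rhs(model)
  y <- numeric(2 + 2 * nt + 1)
  res <- matrix(NA_real_, nrow = length(out_times), ncol = length(y),
                dimnames = list(NULL, NULL))
  filled <- logical(length(out_times))
  eps <- 1e-9

  for (k in seq_len(length(breaks) - 1)) {
    a <- breaks[k]; b <- breaks[k + 1]
    # bolus doses at the segment start
    bol <- events$infusion_h == 0 & abs(events$start_h - a) < 1e-12
    if (any(bol)) y[1] <- y[1] + sum(events$amount_ug[bol])
    ia <- which(abs(out_times - a) <= eps)
    if (length(ia)) {  # post-dose value at the segment start
      res[ia, ] <- matrix(y, nrow = length(ia), ncol = length(y), byrow = TRUE)
      filled[ia] <- TRUE
    }
    # constant infusion rate over the open segment
    mid <- (a + b) / 2
    act <- events$infusion_h > 0 &
      events$start_h < mid & (events$start_h + events$infusion_h) > mid
    rate <- sum(events$amount_ug[act] / events$infusion_h[act])

    sel <- which(out_times > a + eps & out_times < b - eps)
    times_seg <- c(a, out_times[sel], b)
    sol <- deSolve::lsoda(y, times_seg, rhs, parms = c(inf_rate = rate),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      abort(paste0("ODE solver failed in segment [", a, ", ", b, "] h; istate = ",
                   attr(sol, "istate")[1]))
    }
    # rows map to out_times by construction: row 1 = a, last row = b
    if (length(sel)) {
      res[sel, ] <- sol[1 + seq_along(sel), -1, drop = FALSE]
      filled[sel] <- TRUE
    }
    ib <- which(abs(out_times - b) <= eps)
    if (length(ib)) {
      res[ib, ] <- matrix(sol[nrow(sol), -1], nrow = length(ib),
                          ncol = length(y), byrow = TRUE)
      filled[ib] <- TRUE
    }
    y <- sol[nrow(sol), -1]
  }
  if (!all(filled)) abort("Internal error: output grid not fully covered.")

  a_ven <- res[, 1]; a_art <- res[, 2]
  a_ec <- res[, 3:(2 + nt), drop = FALSE]
  a_ic <- res[, (3 + nt):(2 + 2 * nt), drop = FALSE]
  cleared <- res[, ncol(res)]

  c_plasma <- a_ven / model$v_ven / model$bpr
  c_blood <- a_ven / model$v_ven
  v_tis <- model$v_ec + model$v_ic
  c_tis <- sweep(a_ec + a_ic, 2, v_tis, "/")
  colnames(c_tis) <- model$tissue

  dose_total <- sum(events$dose_ug_kg)
  prof <- dplyr::bind_rows(
    tibble::tibble(time_h = out_times, conc_ng_per_ml = c_plasma, matrix = "plasma"),
    tibble::tibble(time_h = out_times, conc_ng_per_ml = c_blood, matrix = "blood"),
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(time_h = out_times),
                       tibble::as_tibble(c_tis)),
      -"time_h", names_to = "matrix", values_to = "conc_ng_per_ml")
  )
  prof <- dplyr::mutate(prof,
                        compound = model$compound,
                        species = model$species,
                        dose_ug_kg = dose_total)
  prof <- dplyr::arrange(prof, .data$matrix, .data$time_h)

  balance <- tibble::tibble(
    time_h = out_times,
    administered_ug = administered_ug(events, out_times),
    in_body_ug = a_ven + a_art + rowSums(a_ec) + rowSums(a_ic),
    cleared_ug = cleared
  )
  attr(prof, "balance") <- balance
  class(prof) <- c("pbpk_profile", class(prof))
  prof
}

#' Extract one matrix from a simulated or observed profile
#'
#' @param profile A profile tibble (long format).
#' @param matrix Matrix label, e.g. `"plasma"` or `"liver"`.
#' @return A tibble restricted to that matrix, ordered by time.
#' @export
profile_matrix <- function(profile, matrix = "plasma") {
  out <- dplyr::filter(profile, .data$matrix == !!matrix)
  if (nrow(out) == 0) abort(paste0("Profile has no rows for matrix '", matrix, "'."))
  dplyr::arrange(out, .data$time_h)
}

#' Read / write concentration-time profiles
#'
#' Profiles are exchanged as plain CSV with the schema
#' `time_h, conc_ng_per_ml, matrix, compound, species, dose_ug_kg`.
#'
#' @param profile A profile tibble.
#' @param path File path.
#' @return `read_profile()` returns the profile tibble; `write_profile()`
#'   returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  cols <- c("time_h", "conc_ng_per_ml", "matrix", "compound", "species",
            "dose_ug_kg")
  stopifnot(all(cols %in% names(profile)))
  utils::write.csv(profile[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("time_h", "conc_ng_per_ml", "matrix") %in% names(out)))
  out
}
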