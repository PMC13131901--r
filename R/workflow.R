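#' Derive species observed clearances from published study AUCs
#'
#' Observed systemic clearance per preclinical species as `Dose / AUC_obs`
#' from the published study-level AUCs ([observed_auc_table()]). For the
#' monkey, where two dose levels were studied per compound, the higher dose is
#' used (the low-dose MTMSA-Trp study fell outside the 2-fold acceptance
#' criterion).
#'
#' @param compound_name `"MTM"` or `"MTMSA-Trp"`.
#' @param observed Study AUC table (defaults to the bundled published values).
#' @return A tibble: `species`, `dose_ug_kg`, `auc_obs_ng_h_ml`,
#'   `cl_obs_ml_h_kg`, `bw_kg`, `cl_obs_abs_L_h`, `fup`, `gfr_ml_h_kg`.
#' @export
species_observed_cl <- function(compound_name,
                                observed = observed_auc_table()) {
  compound <- compound_library()[[compound_name]]
  if (is.null(compound)) abort(paste0("Unknown compound: ", compound_name))
  obs <- dplyr::filter(observed, .data$compound == compound_name,
                       .data$species != "human")
  obs <- dplyr::slice_max(dplyr::group_by(obs, .data$species),
                          .data$dose_ug_kg, n = 1)
  obs <- dplyr::ungroup(obs)

  purrr::pmap_dfr(obs, function(compound, species, dose_ug_kg, infusion_h,
                                auc_obs_ng_h_ml) {
    phys <- species_physiology(species)
    cl_kg <- observed_clearance(dose_ug_kg, auc_obs_ng_h_ml)
    tibble::tibble(
      species = species,
      dose_ug_kg = dose_ug_kg,
      auc_obs_ng_h_ml = auc_obs_ng_h_ml,
      cl_obs_ml_h_kg = cl_kg,
      bw_kg = phys$body_weight_kg,
      cl_obs_abs_L_h = cl_kg * phys$body_weight_kg / 1000,
      fup = species_param(compound_library()[[compound]], "fup", species),
      gfr_ml_h_kg = phys$gfr_L_h / phys$body_weight_kg * 1000
    )
  })
}

#' Project human clearance by the three interspecies methods
#'
#' * `"additional"` (Method 1): renal filtration plus the geometric-mean
#'   residual clearance percentage across mouse, rat and monkey
#'   ([additional_clearance_human()]).
#' * `"allometric"` (Method 2): `CL = a x BW^b` fitted to the three species'
#'   absolute clearances and extrapolated to 50 kg ([allometric_fit()]).
#' * `"single_species"` (Method 3): monkey clearance scaled by
#'   `(BW_human / BW_monkey)^0.75` ([single_species_scale()]).
#'
#' @param compound_name `"MTM"` or `"MTMSA-Trp"`.
#' @param method One of `"additional"`, `"allometric"`, `"single_species"`.
#' @param observed Study AUC table (defaults to the bundled published values).
#' @param human_physiology Human physiology (defaults to the bundled
#'   13-year-old, 50-kg male).
#' @return A list: `cl_human_L_h` (absolute), `method`, `compound`, and
#'   method-specific `details`.
#' @examples
#' project_human_clearance("MTM", "additional")$cl_human_L_h
#' @export
project_human_clearance <- function(compound_name,
                                    method = c("additional", "allometric",
                                               "single_species"),
                                    observed = observed_auc_table(),
                                    human_physiology = species_physiology("human")) {
  method <- match.arg(method)
  compound <- compound_library()[[compound_name]]
  cltab <- species_observed_cl(compound_name, observed)
  fup_h <- species_param(compound, "fup", "human")
  bw_h <- human_physiology$body_weight_kg

  res <- switch(method,
    additional = {
      recs <- clearance_records(tibble::tibble(
        species = cltab$species,
        cl_obs = cltab$cl_obs_ml_h_kg,
        fup = cltab$fup,
        gfr = cltab$gfr_ml_h_kg))
      m1 <- additional_clearance_human(recs, fup_h, human_physiology$gfr_L_h)
      list(cl = m1$cl_human, details = m1)
    },
    allometric = {
      fit <- allometric_fit(tibble::tibble(bw_kg = cltab$bw_kg,
                                           cl = cltab$cl_obs_abs_L_h))
      list(cl = predict(fit, bw_kg = bw_h), details = fit)
    },
    single_species = {
      mk <- dplyr::filter(cltab, .data$species == "monkey")
      if (nrow(mk) == 0) abort("No monkey clearance available for Method 3.")
      list(cl = single_species_scale(mk$cl_obs_abs_L_h, mk$bw_kg, bw_h),
           details = mk)
    })
  list(cl_human_L_h = res$cl, method = method, compound = compound_name,
       details = res$details)
}

#' Model-derived human exposure comparison
#'
#' Simulates both compounds at the stated IV bolus dose in the bundled human
#' physiology, MTM under the additional-clearance approach (the preferred
#' comparator) and MTMSA-Trp under each requested clearance method, and
#' tabulates plasma and liver AUC over the window, the liver partition
#' (`AUC_liver / AUC_plasma`) and the exposure ratios versus MTM.
#'
#' @param dose_ug_kg IV bolus dose (default 13 µg/kg).
#' @param methods Clearance methods for MTMSA-Trp.
#' @param duration_h,output_interval_h Simulation window (default 24 h at
#'   30-minute intervals).
#' @param observed Study AUC table used to derive the species clearances.
#' @return A tibble with one MTM row and one row per MTMSA-Trp method:
#'   `compound`, `method`, `cl_human_L_h`, `auc_plasma`, `auc_liver`,
#'   `liver_partition`, `ratio_plasma_vs_mtm`, `ratio_liver_vs_mtm`.
#' @export
human_exposure_table <- function(dose_ug_kg = 13,
                                 methods = c("additional", "allometric",
                                             "single_species"),
                                 duration_h = 24, output_interval_h = 0.5,
                                 observed = observed_auc_table()) {
  phys <- species_physiology("human")
  reg <- iv_regimen(dose_ug_kg)
  lib <- compound_library()

  one_run <- function(compound_name, method) {
    cl <- project_human_clearance(compound_name, method, observed, phys)
    mod <- pbpk_model(lib[[compound_name]], phys, "human", cl$cl_human_L_h)
    sim <- simulate_pbpk(mod, reg, duration_h = duration_h,
                         output_interval_h = output_interval_h)
    pl <- profile_matrix(sim, "plasma")
    lv <- profile_matrix(sim, "liver")
    auc_pl <- auc_loglinear(pl$time_h, pl$conc_ng_per_ml)
    auc_lv <- auc_loglinear(lv$time_h, lv$conc_ng_per_ml)
    tibble::tibble(compound = compound_name, method = method,
                   cl_human_L_h = cl$cl_human_L_h,
                   auc_plasma = auc_pl, auc_liver = auc_lv,
                   liver_partition = auc_lv / auc_pl)
  }

  mtm <- one_run("MTM", "additional")
  trp <- purrr::map_dfr(methods, ~one_run("MTMSA-Trp", .x))
  out <- dplyr::bind_rows(mtm, trp)
  dplyr::mutate(out,
                ratio_plasma_vs_mtm = .data$auc_plasma / mtm$auc_plasma,
                ratio_liver_vs_mtm = .data$auc_liver / mtm$auc_liver)
}

#' Run the full middle-out PBPK workflow end to end
#'
#' Executes the complete pipeline: (1) generate the synthetic "observed"
#' study set; (2) calibrate the mouse `SpecPStc` for each compound against the
#' synthetic mouse study; (3) simulate rat and monkey and evaluate against
#' the synthetic observations (cross-species evaluation table); (4) derive
#' species observed clearances from published AUCs; (5) project human
#' clearance by all three methods; (6) simulate human MTM under the 6-h
#' infusion daily x7 regimen and evaluate against the synthetic clinical
#' stand-in, plus both compounds at a 13 µg/kg bolus for 24 h at 30-minute
#' intervals; (7) assemble the human exposure comparison table; (8) run the
#' parameter sensitivity analysis on the human MTMSA-Trp model.
#'
#' Deterministic for a fixed `seed`.
#'
#' @param seed Integer seed for the synthetic data.
#' @param noise_cv Noise CV of the synthetic observations.
#' @param out_dir Optional directory; when given, each stage writes a CSV.
#' @param run_psa Run stage 8 (default `TRUE`).
#' @return A list of stage outputs: `studies`, `calibration`,
#'   `preclinical_eval`, `species_clearance`, `human_clearance`, `human_mtm_eval`,
#'   `exposure_table`, `psa_ranking`, `psa`.
#' @export
run_workflow <- function(seed = 1, noise_cv = 0.15, out_dir = NULL,
                         run_psa = TRUE) {
  lib <- compound_library()
  studies <- make_study_set(seed = seed, noise_cv = noise_cv)

  # (2) SpecPStc calibration on the synthetic mouse studies
  calibration <- purrr::map_dfr(names(lib), function(cn) {
    st <- dplyr::filter(studies, .data$compound == cn, .data$species == "mouse")
    fit <- fit_spec_pstc(st$profile[[1]], lib[[cn]],
                         species_physiology("mouse"),
                         iv_regimen(st$dose_ug_kg, infusion_h = st$infusion_h),
                         clearance_L_h = st$clearance_L_h)
    dplyr::mutate(glance(fit), compound = cn, .before = 1)
  })

  # (3) cross-species evaluation against the synthetic observations
  preclinical_eval <- purrr::pmap_dfr(
    dplyr::filter(studies, .data$species != "human"),
    function(compound, species, dose_ug_kg, infusion_h, auc_obs_ng_h_ml,
             clearance_L_h, profile) {
      phys <- species_physiology(species)
      mod <- pbpk_model(lib[[compound]], phys, species, clearance_L_h)
      sim <- simulate_pbpk(mod, iv_regimen(dose_ug_kg, infusion_h = infusion_h),
                           duration_h = 24, output_interval_h = 0.25)
      ev <- evaluate_profile(profile_matrix(sim, "plasma"), profile)
      dplyr::mutate(ev, compound = compound, species = species,
                    dose_ug_kg = dose_ug_kg, .before = 1)
    })

  # (4) species observed clearances; (5) human projections
  species_clearance <- purrr::map_dfr(names(lib), function(cn) {
    dplyr::mutate(species_observed_cl(cn), compound = cn, .before = 1)
  })
  human_clearance <- purrr::map_dfr(names(lib), function(cn) {
    purrr::map_dfr(c("additional", "allometric", "single_species"),
                   function(m) {
                     p <- project_human_clearance(cn, m)
                     tibble::tibble(compound = cn, method = m,
                                    cl_human_L_h = p$cl_human_L_h)
                   })
  })

  # (6) human MTM multiple-dose verification vs synthetic clinical stand-in
  clin <- dplyr::filter(studies, .data$species == "human", .data$compound == "MTM")
  cl_mtm <- project_human_clearance("MTM", "additional")$cl_human_L_h
  phys_h <- species_physiology("human")
  mod_h <- pbpk_model(lib[["MTM"]], phys_h, "human", cl_mtm)
  sim_h <- simulate_pbpk(mod_h,
                         iv_regimen(13, infusion_h = 6, n_doses = 7,
                                    interval_h = 24),
                         duration_h = 7 * 24, output_interval_h = 0.5)
  human_mtm_eval <- evaluate_profile(profile_matrix(sim_h, "plasma"),
                                     clin$profile[[1]], auc_window_h = 24)

  # (7) exposure comparison table (13 ug/kg bolus, 24 h at 30-min intervals)
  exposure_table <- human_exposure_table()

  # (8) PSA on the human MTMSA-Trp model under allometric (Method 2) clearance
  psa_scans <- NULL
  psa_rank <- NULL
  if (run_psa) {
    cl_m2 <- project_human_clearance("MTMSA-Trp", "allometric")$cl_human_L_h
    psa_scans <- dplyr::bind_rows(
      psa(lib[["MTMSA-Trp"]], phys_h, "bpr", clearance_L_h = cl_m2),
      psa(lib[["MTMSA-Trp"]], phys_h, "fup", clearance_L_h = cl_m2),
      psa(lib[["MTMSA-Trp"]], phys_h, "logp", clearance_L_h = cl_m2))
    psa_rank <- psa_ranking(psa_scans)
  }

  out <- list(
    studies = studies,
    calibration = calibration,
    preclinical_eval = preclinical_eval,
    species_clearance = species_clearance,
    human_clearance = human_clearance,
    human_mtm_eval = human_mtm_eval,
    exposure_table = exposure_table,
    psa_ranking = psa_rank,
    psa = psa_scans
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(df, file.path(out_dir, nm),
                                            row.names = FALSE)
    wr(calibration, "calibration.csv")
    wr(preclinical_eval, "preclinical_evaluation.csv")
    wr(species_clearance, "species_clearance.csv")
    wr(human_clearance, "human_clearance.csv")
    wr(human_mtm_eval, "human_mtm_evaluation.csv")
    wr(exposure_table, "human_exposure_table.csv")
    if (!is.null(psa_rank)) wr(psa_rank, "psa_ranking.csv")
  }
  out
}
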