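# Shared fixtures: bundled compounds/physiologies are loaded once per test run.
mtm <- load_compound(mtmpbpk_example("compounds/mtm.yaml"))
trp <- load_compound(mtmpbpk_example("compounds/mtmsa-trp.yaml"))
phys_human <- species_physiology("human")
phys_mouse <- species_physiology("mouse")

# Minimal custom physiology: lung + one rest-of-body compartment. Used for
# closed-form oracles; composition is set equal to plasma so that Kp = 1 when
# logP = 0 and fup = 1.
tiny_physiology <- function(v_rest_ec = 1e-6, v_rest_ic = 1e-6,
                            v_lung = 1e-6, blood_L = 3.5, co = 3000,
                            plasma_like = TRUE) {
  comp <- if (plasma_like) {
    list(f_nl = 0.0035, f_ph = 0.00225, f_w = 0.945)
  } else {
    list(f_nl = 0.0219, f_ph = 0.014, f_w = 0.811)
  }
  tissues <- tibble::tibble(
    tissue = c("lung", "rest"),
    flow_L_h = c(co, co),
    volume_L = c(v_lung, v_rest_ec + v_rest_ic),
    ecf = c(0.5, v_rest_ec / (v_rest_ec + v_rest_ic)),
    f_nl = comp$f_nl, f_ph = comp$f_ph, f_w = comp$f_w
  )
  structure(list(
    species = "synthetic", body_weight_kg = 50,
    cardiac_output_L_h = co, gfr_L_h = 6, blood_volume_L = blood_L,
    plasma_composition = list(f_nl = 0.0035, f_ph = 0.00225, f_w = 0.945),
    tissues = tissues
  ), class = "pbpk_physiology")
}

plasma_auc <- function(sim, t_end = NULL) {
  pl <- profile_matrix(sim, "plasma")
  auc_loglinear(pl$time_h, pl$conc_ng_per_ml, t_end = t_end)
}

# Output grid dense enough to integrate an IV bolus profile to infinity by the
# log-trapezoid rule: sub-mixing-time resolution over the venous spike, fine
# distribution phase, log-spaced terminal phase.
auc_inf_times <- function(t_max) {
  sort(unique(c(seq(0, 0.1, by = 0.001), seq(0.1, 4, by = 0.02),
                seq(4, 48, by = 0.2),
                exp(seq(log(48), log(t_max), length.out = 300)))))
}
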