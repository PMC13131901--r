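test_that("the same seed reproduces a study exactly", {
  a <- make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0.15, seed = 123,
                  clearance_L_h = 0.026, physiology = phys_mouse)
  b <- make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0.15, seed = 123,
                  clearance_L_h = 0.026, physiology = phys_mouse)
  expect_identical(a$conc_ng_per_ml, b$conc_ng_per_ml)
  d <- make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0.15, seed = 124,
                  clearance_L_h = 0.026, physiology = phys_mouse)
  expect_false(identical(a$conc_ng_per_ml, d$conc_ng_per_ml))
})

test_that("noise-free output round-trips through NCA to the target AUC", {
  prof <- make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0, seed = 1,
                     target_auc_ng_h_ml = 1906, physiology = phys_mouse)
  expect_equal(auc_loglinear(prof$time_h, prof$conc_ng_per_ml), 1906,
               tolerance = 0.005)
  # and the implied generating clearance is recorded
  expect_gt(attr(prof, "clearance_L_h"), 0)
})

test_that("an unreachable target AUC raises an error", {
  expect_error(
    make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0, seed = 1,
               target_auc_ng_h_ml = 1e12, cl_bounds = c(1e-4, 10),
               physiology = phys_mouse),
    "unreachable")
})

test_that("empirical noise CV matches the requested CV (Monte Carlo)", {
  concs <- vapply(1:60, function(s) {
    p <- make_study(mtm, "mouse", iv_regimen(2000),
                    sampling_times_h = c(1, 4), noise_cv = 0.1, seed = s,
                    clearance_L_h = 0.026, physiology = phys_mouse)
    p$conc_ng_per_ml[1]
  }, numeric(1))
  expect_equal(stats::sd(concs) / mean(concs), 0.1, tolerance = 0.35)
  # noise is unbiased on the natural scale
  p0 <- make_study(mtm, "mouse", iv_regimen(2000), sampling_times_h = c(1, 4),
                   noise_cv = 0, seed = 1, clearance_L_h = 0.026,
                   physiology = phys_mouse)
  expect_equal(mean(concs) / p0$conc_ng_per_ml[1], 1, tolerance = 0.05)
})

test_that("BLQ censoring zeroes values below the LLOQ", {
  p <- make_study(mtm, "mouse", iv_regimen(2000), noise_cv = 0, seed = 1,
                  clearance_L_h = 1, lloq_ng_ml = 1e6, physiology = phys_mouse)
  expect_true(all(p$conc_ng_per_ml == 0))
})

test_that("the full study set regenerates deterministically and hits its AUCs", {
  set1 <- make_study_set(seed = 5, noise_cv = 0)
  expect_equal(nrow(set1), 9)
  aucs <- vapply(set1$profile, function(p)
    auc_loglinear(p$time_h, p$conc_ng_per_ml), numeric(1))
  expect_equal(aucs / set1$auc_obs_ng_h_ml, rep(1, 9), tolerance = 0.005)
  set2 <- make_study_set(seed = 5, noise_cv = 0)
  expect_identical(set1$clearance_L_h, set2$clearance_L_h)
})
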