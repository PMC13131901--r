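test_that("mass is conserved: administered = body burden + cleared", {
  mod <- pbpk_model(mtm, phys_human, "human", clearance_L_h = 5)
  sim <- simulate_pbpk(mod, iv_regimen(13, infusion_h = 6), duration_h = 24)
  b <- attr(sim, "balance")
  expect_true(all(abs(b$in_body_ug + b$cleared_ug - b$administered_ug) <=
                    1e-3 * max(b$administered_ug)))
  # administered ramps linearly over the 6-h infusion
  expect_equal(b$administered_ug[b$time_h == 3], 13 * 50 / 2)
  expect_equal(max(b$administered_ug), 13 * 50)
})

test_that("with zero clearance the body burden stays equal to the dose", {
  mod <- pbpk_model(mtm, phys_human, "human", clearance_L_h = 0)
  sim <- simulate_pbpk(mod, iv_regimen(13), duration_h = 24)
  b <- attr(sim, "balance")
  expect_true(all(abs(b$in_body_ug - 13 * 50) <= 1e-3 * 13 * 50))
  expect_true(all(b$cleared_ug <= 1e-6 * 13 * 50))
})

test_that("output grid arithmetic: 24 h at 0.5 h gives 49 points", {
  mod <- pbpk_model(mtm, phys_human, "human", clearance_L_h = 5)
  sim <- simulate_pbpk(mod, iv_regimen(13, infusion_h = 6), duration_h = 24)
  expect_equal(nrow(profile_matrix(sim, "plasma")), 49)
})

test_that("the linear system scales proportionally with dose", {
  mod <- pbpk_model(trp, phys_human, "human", clearance_L_h = 1)
  s1 <- profile_matrix(simulate_pbpk(mod, iv_regimen(13), 24), "plasma")
  s2 <- profile_matrix(simulate_pbpk(mod, iv_regimen(26), 24), "plasma")
  expect_equal(s2$conc_ng_per_ml, 2 * s1$conc_ng_per_ml, tolerance = 1e-6)
})

test_that("all concentrations stay non-negative", {
  mod <- pbpk_model(trp, phys_mouse, "mouse", clearance_L_h = 0.01)
  sim <- simulate_pbpk(mod, iv_regimen(2000), duration_h = 24)
  expect_true(all(sim$conc_ng_per_ml >= 0))
})

test_that("with no elimination, tissues approach the Kp-implied equilibrium", {
  kp <- predict_kp(mtm, phys_human, "human")
  # total-concentration driving and a large SpecPStc: equilibrium in hours
  mod <- pbpk_model(mtm, phys_human, "human", clearance_L_h = 0,
                    kp = kp, spec_pstc = 0.05, ps_driving = "total")
  sim <- simulate_pbpk(mod, iv_regimen(13), duration_h = 96,
                       output_times = c(0, 48, 96))
  pl <- profile_matrix(sim, "plasma")
  cp <- pl$conc_ng_per_ml[pl$time_h == 96]
  for (t in c("liver", "muscle", "adipose")) {
    ts <- profile_matrix(sim, t)
    ct <- ts$conc_ng_per_ml[ts$time_h == 96]
    ecf <- phys_human$tissues$ecf[phys_human$tissues$tissue == t]
    kpt <- kp$kp[kp$tissue == t]
    expect_equal(ct / cp, ecf + (1 - ecf) * kpt, tolerance = 0.01, info = t)
  }
})

test_that("degenerate model reproduces the one-compartment closed form", {
  # single rest-of-body tissue with PS = 0 and negligible tissue volumes:
  # all drug stays in blood, so Cp(t) = Dose/(BPR Vb) exp(-CL t / (BPR Vb))
  phys <- tiny_physiology()
  cl <- 5; vb <- 3.5; bpr <- 0.671; dose <- 13 * 50
  mod <- pbpk_model(mtm, phys, "human", clearance_L_h = cl, spec_pstc = 0)
  tt <- c(0.5, 1, 2, 4, 8)
  sim <- simulate_pbpk(mod, iv_regimen(13), duration_h = 8, output_times = tt)
  pl <- profile_matrix(sim, "plasma")
  veff <- bpr * vb
  expect_equal(pl$conc_ng_per_ml, dose / veff * exp(-cl * tt / veff),
               tolerance = 2e-3)
})

test_that("AUC to infinity equals Dose/CL regardless of distribution", {
  # distribution-free clearance oracle, >= 20 half-lives simulated
  cases <- list(list(mtm, phys_human, "human", 7),
                list(mtm, phys_mouse, "mouse", 0.026),
                list(trp, phys_mouse, "mouse", 0.0013))
  for (cs in cases) {
    mod <- pbpk_model(cs[[1]], cs[[2]], cs[[3]], clearance_L_h = cs[[4]])
    dose <- 100
    sim <- simulate_pbpk(mod, iv_regimen(dose), duration_h = 2000,
                         output_times = auc_inf_times(2000))
    pl <- profile_matrix(sim, "plasma")
    auc <- auc_loglinear(pl$time_h, pl$conc_ng_per_ml)
    expect_equal(auc / (dose * mod$body_weight_kg / cs[[4]]), 1,
                 tolerance = 0.01, info = cs[[1]]$name)
  }
})

test_that("solver rejects invalid inputs", {
  expect_error(pbpk_model(mtm, phys_human, "human", clearance_L_h = -1),
               "clearance")
  mod <- pbpk_model(mtm, phys_human, "human", 1)
  expect_error(simulate_pbpk(mod, iv_regimen(13), duration_h = -1), "duration")
  expect_error(iv_regimen(-5), "Dose")
  expect_error(iv_regimen(5, infusion_h = 30, n_doses = 2, interval_h = 24),
               "overlap")
})

test_that("profiles round-trip through the CSV schema", {
  mod <- pbpk_model(mtm, phys_human, "human", 5)
  sim <- simulate_pbpk(mod, iv_regimen(13), duration_h = 4,
                       output_interval_h = 1)
  tmp <- tempfile(fileext = ".csv")
  write_profile(sim, tmp)
  back <- read_profile(tmp)
  expect_equal(nrow(back), nrow(sim))
  expect_equal(profile_matrix(back, "plasma")$conc_ng_per_ml,
               profile_matrix(sim, "plasma")$conc_ng_per_ml)
})
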