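test_that("species clearances derive from the published dose/AUC pairs", {
  cl <- species_observed_cl("MTM")
  expect_setequal(cl$species, c("mouse", "rat", "monkey"))
  # monkey uses the higher published dose level
  expect_equal(cl$dose_ug_kg[cl$species == "monkey"], 13.18)
  expect_equal(cl$cl_obs_ml_h_kg[cl$species == "rat"], 500 / 173 * 1000)
  cl2 <- species_observed_cl("MTMSA-Trp")
  expect_equal(cl2$dose_ug_kg[cl2$species == "monkey"], 4.19)
})

test_that("the three human clearance projections are ordered sensibly", {
  m1 <- project_human_clearance("MTM", "additional")
  m2 <- project_human_clearance("MTM", "allometric")
  m3 <- project_human_clearance("MTM", "single_species")
  expect_true(all(c(m1$cl_human_L_h, m2$cl_human_L_h, m3$cl_human_L_h) > 0))
  # the additional-clearance method captures the large non-filtration
  # component that the allometric fits miss for this compound
  expect_gt(m1$cl_human_L_h, m2$cl_human_L_h)
  # method details are exposed for inspection
  expect_s3_class(m2$details, "allometric_fit")
  expect_equal(m3$cl_human_L_h,
               single_species_scale(m3$details$cl_obs_abs_L_h, 5, 50))
  # MTMSA-Trp clears far slower than MTM under every method
  for (m in c("additional", "allometric", "single_species")) {
    expect_lt(project_human_clearance("MTMSA-Trp", m)$cl_human_L_h,
              project_human_clearance("MTM", m)$cl_human_L_h)
  }
})

test_that("the exposure comparison table has the expected structure", {
  tab <- human_exposure_table(methods = c("additional", "allometric",
                                          "single_species"))
  expect_equal(nrow(tab), 4)  # 1 MTM row + 3 MTMSA-Trp rows
  expect_equal(tab$compound[1], "MTM")
  expect_equal(tab$ratio_plasma_vs_mtm[1], 1)
  expect_equal(tab$ratio_liver_vs_mtm[1], 1)
  expect_true(all(tab$liver_partition > 0))
  # higher exposure for the analog under every clearance method
  expect_true(all(tab$ratio_plasma_vs_mtm[-1] > 1))
})

test_that("the end-to-end workflow runs, is deterministic, and writes CSVs", {
  out_dir <- tempfile("wf")
  wf <- run_workflow(seed = 42, noise_cv = 0.1, out_dir = out_dir,
                     run_psa = TRUE)
  expect_equal(nrow(wf$calibration), 2)
  expect_equal(nrow(wf$preclinical_eval), 8)   # 2 compounds x 4 studies
  expect_equal(nrow(wf$human_clearance), 6)    # 2 compounds x 3 methods
  expect_equal(nrow(wf$exposure_table), 4)
  expect_s3_class(wf$human_mtm_eval, "tbl_df")
  expect_equal(wf$psa_ranking$parameter[1], "bpr")
  expect_true(all(file.exists(file.path(out_dir, c(
    "calibration.csv", "preclinical_evaluation.csv", "species_clearance.csv",
    "human_clearance.csv", "human_mtm_evaluation.csv",
    "human_exposure_table.csv", "psa_ranking.csv")))))
  # deterministic: the synthetic stage drives all randomness
  s1 <- make_study_set(seed = 42, noise_cv = 0.1)
  s2 <- make_study_set(seed = 42, noise_cv = 0.1)
  expect_identical(s1$profile, s2$profile)
})
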