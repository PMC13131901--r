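test_that("fold error, AFE and RMSE follow their definitions", {
  expect_equal(fold_error(143, 136), 143 / 136)
  expect_equal(fold_error(7, 7), 1)
  expect_error(fold_error(1, 0), "positive")

  expect_equal(afe(c(2, 0.5), c(1, 1)), 1)           # reciprocal symmetry
  expect_equal(afe(c(5, 9), c(5, 9)), 1)
  expect_equal(afe(c(10, 10), c(1, 1)), 10)

  expect_equal(rmse_log(c(3, 7), c(3, 7)), 0)
  expect_equal(rmse_log(10, 1), 1)                   # one decade off
  expect_error(rmse_log(numeric(), numeric()), "non-empty")
})

test_that("AFE is antisymmetric under swapping pred and obs (property)", {
  set.seed(3)
  for (i in 1:20) {
    p <- exp(stats::rnorm(6)); o <- exp(stats::rnorm(6))
    expect_equal(afe(p, o) * afe(o, p), 1, tolerance = 1e-12)
    expect_gte(rmse_log(p, o), 0)
    # RMSE invariant to common rescaling of both series
    expect_equal(rmse_log(p, o), rmse_log(10 * p, 10 * o), tolerance = 1e-12)
  }
})

test_that("profile evaluation is exact for a self-comparison", {
  tt <- seq(0.5, 24, by = 0.5)
  prof <- tibble::tibble(time_h = tt, conc_ng_per_ml = 80 * exp(-0.2 * tt))
  ev <- evaluate_profile(prof, prof)
  expect_equal(ev$auc_ratio, 1)
  expect_equal(ev$afe, 1)
  expect_equal(ev$rmse, 0)
  expect_true(ev$pass_2fold)
})

test_that("a 3-fold overprediction fails the 2-fold band", {
  tt <- seq(0.5, 24, by = 0.5)
  obs <- tibble::tibble(time_h = tt, conc_ng_per_ml = 80 * exp(-0.2 * tt))
  pred <- dplyr::mutate(obs, conc_ng_per_ml = conc_ng_per_ml * 3)
  ev <- evaluate_profile(pred, obs)
  expect_equal(ev$auc_ratio, 3, tolerance = 1e-9)
  expect_equal(ev$afe, 3, tolerance = 1e-9)
  expect_false(ev$pass_2fold)
})

test_that("an underprediction with AUC ratio 0.46 is flagged out of band", {
  # the low-dose monkey scenario shape: prediction at 46% of observation
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 24)
  obs <- tibble::tibble(time_h = tt, conc_ng_per_ml = 40 * exp(-0.15 * tt))
  pred <- dplyr::mutate(obs, conc_ng_per_ml = conc_ng_per_ml * 0.46)
  ev <- evaluate_profile(pred, obs)
  expect_equal(ev$auc_ratio, 0.46, tolerance = 1e-9)
  expect_false(ev$pass_2fold)
})

test_that("BLQ observations are excluded and counted", {
  tt <- c(1, 2, 4, 8)
  obs <- tibble::tibble(time_h = tt, conc_ng_per_ml = c(10, 5, 0, 1))
  pred <- tibble::tibble(time_h = seq(0, 8, 0.5),
                         conc_ng_per_ml = 12 * exp(-0.3 * seq(0, 8, 0.5)))
  ev <- evaluate_profile(pred, obs)
  expect_equal(ev$n_blq, 1)
  expect_equal(ev$n_matched, 3)
})

test_that("interpolation onto observed times is log-linear in concentration", {
  # predicted curve sampled coarsely; an observed time between samples must be
  # matched by geometric (not arithmetic) interpolation on a decaying segment
  pred <- tibble::tibble(time_h = c(0, 2), conc_ng_per_ml = c(100, 25))
  obs <- tibble::tibble(time_h = c(0.5, 1.5),
                        conc_ng_per_ml = c(100 * 0.25^0.25, 100 * 0.25^0.75))
  ev <- evaluate_profile(pred, obs, auc_window_h = 2)
  expect_equal(ev$afe, 1, tolerance = 1e-12)  # geometric interpolation exact
})

test_that("disjoint time supports are rejected", {
  a <- tibble::tibble(time_h = 1:3, conc_ng_per_ml = c(1, 1, 1))
  b <- tibble::tibble(time_h = 10:12, conc_ng_per_ml = c(1, 1, 1))
  expect_error(evaluate_profile(a, b), "overlap")
})
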