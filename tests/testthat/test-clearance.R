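test_that("renal filtration clearance is fup x GFR with guarded domain", {
  expect_equal(renal_filtration_cl(1, 6), 6)
  expect_equal(renal_filtration_cl(0.1826, 6), 1.0956)
  expect_error(renal_filtration_cl(0, 6), "fup")
  expect_error(renal_filtration_cl(1.1, 6), "fup")
  expect_error(renal_filtration_cl(0.5, -1), "GFR")
})

test_that("clearance records split CL_obs into filtration and residual", {
  recs <- clearance_records(tibble::tibble(
    species = c("mouse", "rat", "monkey"),
    cl_obs = c(1049.3, 2890.2, 51.7),
    fup = c(0.0255, 0.1665, 0.1186),
    gfr = c(840, 312, 150)))
  expect_equal(recs$cl_r, recs$fup * recs$gfr)
  expect_equal(recs$pct_cl_add, (recs$cl_obs - recs$cl_r) / recs$cl_obs * 100)
  expect_true(all(recs$pct_cl_add >= 0 & recs$pct_cl_add < 100))
  # a species with CL_obs below filtration is clamped with a warning
  expect_warning(
    low <- clearance_records(tibble::tibble(
      species = "rat", cl_obs = 10, fup = 0.5, gfr = 100)),
    "clamped")
  expect_equal(low$cl_add, 0)
})

test_that("additional-clearance method matches the printed formula", {
  # %CL_add = {50, 50, 50} with CL_R,human = 1 -> CL_human = 2
  recs <- tibble::tibble(pct_cl_add = c(50, 50, 50))
  out <- additional_clearance_human(recs, fup_human = 1, gfr_human = 1)
  expect_equal(out$cl_human, 2)
  # geometric mean is exp(mean(log)); brute-force cross-check
  pct <- c(25, 100 * (1 - 1 / exp(2)), 60)
  out2 <- additional_clearance_human(tibble::tibble(pct_cl_add = pct), 0.5, 10)
  expect_equal(out2$pct_cl_add_mean, prod(pct)^(1 / 3), tolerance = 1e-12)
  expect_equal(out2$cl_human, 5 / (100 - prod(pct)^(1 / 3)) * 100)
})

test_that("filtration-only limit: all %CL_add = 0 gives fup x GFR exactly", {
  recs <- tibble::tibble(pct_cl_add = c(0, 0, 0))
  out <- additional_clearance_human(recs, fup_human = 0.1826, gfr_human = 6)
  expect_identical(out$cl_human, 0.1826 * 6)
})

test_that("geometric mean is bounded by the arithmetic mean (property)", {
  set.seed(7)
  for (i in 1:20) {
    pct <- stats::runif(3, 1, 99)
    out <- additional_clearance_human(tibble::tibble(pct_cl_add = pct), 0.5, 1)
    expect_lte(out$pct_cl_add_mean, mean(pct) + 1e-12)
  }
})

test_that("out-of-range %CL_add is rejected", {
  expect_error(additional_clearance_human(
    tibble::tibble(pct_cl_add = c(50, 101)), 0.5, 1), "100")
})

test_that("allometric fit recovers a noise-free power law exactly", {
  bw <- c(0.025, 0.25, 5)
  fit <- allometric_fit(tibble::tibble(bw_kg = bw, cl = 2 * bw^0.75))
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 0.75, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(predict(fit, 50), 2 * 50^0.75, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate, c(2, 0.75), tolerance = 1e-10)

  # two points give the exact interpolating power law
  fit2 <- allometric_fit(tibble::tibble(bw_kg = c(1, 10), cl = c(3, 30)))
  expect_equal(fit2$b, 1, tolerance = 1e-12)
  expect_error(allometric_fit(tibble::tibble(bw_kg = c(1, 1), cl = c(1, 2))),
               "singular")
})

test_that("allometric exponent is recovered under multiplicative noise", {
  set.seed(11)
  bw <- c(0.02, 0.25, 5, 70)
  b_hat <- replicate(30, {
    cl <- 1.5 * bw^0.75 * exp(stats::rnorm(4, 0, 0.1))
    allometric_fit(tibble::tibble(bw_kg = bw, cl = cl))$b
  })
  # slope SE for this design at sd 0.1 is ~0.03; the median of 30 draws is
  # comfortably within 0.05 of the truth
  expect_lt(abs(stats::median(b_hat) - 0.75), 0.05)
})

test_that("single-species scaling follows the fixed-exponent closed form", {
  expect_equal(single_species_scale(1, 5, 50), 10^0.75)
  expect_equal(single_species_scale(1, 5, 50, exponent = 1), 10)
  expect_equal(single_species_scale(2.7, 5, 5), 2.7)
  expect_error(single_species_scale(-1, 5, 50), "positive|> 0")
})
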