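test_that("forward simulation halves EDV at equal elastances", {
  gt <- ground_truth(ees = 1.5, ea = 1.5, edv = 100, v0 = 0, pad = 60, pep = 96)
  obs <- simulate_forward(gt)
  expect_equal(obs$sv, 50)
  expect_equal(obs$dbp, 60)
  expect_gt(obs$sbp, obs$dbp)
})

test_that("forward observations satisfy every model equation simultaneously", {
  set.seed(41)
  for (i in 1:50) {
    r <- runif(1, 0.8, 2.5)
    ea <- runif(1, 1.0, 2.0)
    gt <- ground_truth(ees = r * ea, ea = ea, edv = runif(1, 70, 130),
                       pad = runif(1, 60, 85), pep = runif(1, 80, 115))
    obs <- tryCatch(simulate_forward(gt), error = function(e) NULL)
    if (is.null(obs)) next  # infeasible draw (back-solved SBP below DBP)
    # the true ratio zeroes the coupling residual of the emitted observation
    pes <- estimate_pes(obs$sbp, obs$dbp)
    expect_lt(abs(coupling_residual(r, obs$dbp, pes, obs$et, obs$pep)), 1e-10)
    # feasibility invariants
    expect_gt(obs$sbp, obs$dbp)
    expect_gt(obs$et, 0)
    expect_gt(obs$sv, 0)
  }
})

test_that("forward then inverse recovers the constructed textbook subject", {
  # ratio 1.5 with Ea chosen so Pes = 91.5 gives SV = 61 and EDV = 101.666...
  edv <- 61 * (1 + 1 / 1.5)
  ea <- 91.5 / 61
  gt <- ground_truth(ees = 1.5 * ea, ea = ea, edv = edv, pad = 73, pep = 96)
  obs <- simulate_forward(gt)
  expect_equal(obs$sv, 61, tolerance = 1e-12)
  res <- estimate_subject(obs)
  expect_equal(res$estimate$edv_calc, edv, tolerance = 1e-6)
  expect_equal(res$coupling$ees_over_ea, 1.5, tolerance = 1e-6)
})

test_that("infeasible ground truths are rejected with the offending state", {
  # elastances so small that the peak isovolumic pressure sits below Pad
  gt <- ground_truth(ees = 0.02, ea = 0.01, edv = 90, pad = 73, pep = 96)
  expect_error(simulate_forward(gt), "infeasible")
  # nonzero V0 breaks the exact round trip and is refused
  gt2 <- ground_truth(ees = 1.5, ea = 1.0, edv = 100, v0 = 10, pad = 70, pep = 96)
  expect_error(simulate_forward(gt2), "v0")
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n = 15, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$observations, b$observations)
  # a different seed changes the cohort
  c <- generate_cohort(cohort_config(n = 15, seed = 8))
  expect_false(identical(a$observations, c$observations))
})

test_that("generated observables land near the intended cohort summaries", {
  cohort <- generate_cohort(cohort_config(n = 400, seed = 5))
  obs <- cohort$observations
  expect_gt(mean(obs$sbp), 105); expect_lt(mean(obs$sbp), 130)
  expect_gt(mean(obs$dbp), 63);  expect_lt(mean(obs$dbp), 83)
  expect_gt(mean(obs$pep_ms), 85); expect_lt(mean(obs$pep_ms), 107)
  expect_gt(mean(obs$et_ms), 200); expect_lt(mean(obs$et_ms), 400)
  expect_gt(mean(obs$sv_ml), 45);  expect_lt(mean(obs$sv_ml), 75)
  expect_gt(mean(obs$edv_ref_ml), 80); expect_lt(mean(obs$edv_ref_ml), 110)
})

test_that("noise-free cohorts give zero bias and zero percentage error", {
  cfg <- cohort_config(n = 24, seed = 13,
                       noise_sd = list(pressure = 0, timing = 0, sv = 0))
  cohort <- generate_cohort(cfg)
  res <- estimate_cohort(cohort$observations)
  rep <- bland_altman(res$edv_ref_ml, res$edv_calc_ml)
  expect_lt(abs(rep$bias), 1e-6)
  expect_lt(rep$percentage_error, 1e-6)
  expect_true(rep$acceptable)
})

test_that("percentage error grows with any single noise source", {
  base <- list(pressure = 0, timing = 0, sv = 0)
  pe_for <- function(noise) {
    cohort <- generate_cohort(cohort_config(n = 150, seed = 21, noise_sd = noise))
    res <- estimate_cohort(cohort$observations)
    ok <- !res$excluded
    bland_altman(res$edv_ref_ml[ok], res$edv_calc_ml[ok])$percentage_error
  }
  for (src in names(base)) {
    ladder <- vapply(c(0, 1, 3, 6), function(s) {
      noise <- base; noise[[src]] <- s
      pe_for(noise)
    }, numeric(1))
    expect_true(all(diff(ladder) >= 0),
                info = sprintf("noise source: %s", src))
  }
})

test_that("noisy-cohort bias matches a tenfold brute-force rerun within Monte-Carlo error", {
  run_bias <- function(n, seed) {
    cohort <- generate_cohort(cohort_config(n = n, seed = seed))
    res <- estimate_cohort(cohort$observations)
    ok <- !res$excluded & is.finite(res$edv_calc_ml)
    d <- res$edv_ref_ml[ok] - res$edv_calc_ml[ok]
    c(bias = mean(d), se = sd(d) / sqrt(sum(ok)))
  }
  small <- run_bias(100, seed = 33)
  big <- run_bias(1000, seed = 34)
  expect_lt(abs(small["bias"] - big["bias"]),
            3 * sqrt(small["se"]^2 + big["se"]^2))
})

test_that("impossible sampling configurations hit the resample cap loudly", {
  cfg <- cohort_config(n = 5, seed = 2, resample_cap = 50,
                       sbp = list(family = "normal", mean = 40, sd = 1))
  expect_error(generate_cohort(cfg), "resample cap")
})
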