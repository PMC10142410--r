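test_that("end-systolic pressure follows the linear cuff form", {
  expect_equal(estimate_pes(117, 73), 0.205 * 117 + 0.898 * 73 + 0.4214)
  expect_equal(estimate_pes(117, 73), 89.9604, tolerance = 1e-12)
  # result sits between the cuff pressures for physiological inputs
  for (i in 1:25) {
    dbp <- runif(1, 50, 95)
    sbp <- dbp + runif(1, 15, 60)
    pes <- estimate_pes(sbp, dbp)
    expect_gt(pes, dbp)
    expect_lt(pes, sbp)
  }
  # intercept-only contract case, validation disabled
  expect_equal(estimate_pes(0, 0, validate = FALSE), 0.4214)
})

test_that("end-systolic pressure validation names the offending field", {
  expect_error(estimate_pes(100, 100), "sbp")
  expect_error(estimate_pes(90, 100), "sbp")
  expect_error(estimate_pes(100, -5), "dbp")
  expect_error(estimate_pes(-1, -5), "dbp")
})

test_that("the cuff form is affine in both pressures", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(2, 40, 200)
    b <- runif(2, 40, 200)
    lin <- function(p) estimate_pes(p[1], p[2], validate = FALSE) - 0.4214
    expect_equal(lin(a + b), lin(a) + lin(b), tolerance = 1e-12)
    expect_equal(lin(3.7 * a), 3.7 * lin(a), tolerance = 1e-12)
  }
})

test_that("peak isovolumic pressure scales with the timing ratio and slope ratio", {
  expect_equal(pmax_from_timings(70, et = 300, pep = 100, k = 0.53),
               70 * (1 + 3 * 0.53))
  expect_equal(pmax_from_timings(70, et = 300, pep = 100, k = 0.53), 181.3,
               tolerance = 1e-12)
  # k = 0 collapses to the diastolic pressure; ET/PEP = k = 1 doubles it
  expect_equal(pmax_from_timings(70, et = 123, pep = 45, k = 0), 70)
  expect_equal(pmax_from_timings(70, et = 100, pep = 100, k = 1), 140)
  # strict monotonicity in each argument
  base <- pmax_from_timings(70, 300, 100, 0.53)
  expect_gt(pmax_from_timings(71, 300, 100, 0.53), base)
  expect_gt(pmax_from_timings(70, 301, 100, 0.53), base)
  expect_gt(pmax_from_timings(70, 300, 100, 0.54), base)
  expect_lt(pmax_from_timings(70, 300, 101, 0.53), base)
  expect_error(pmax_from_timings(70, 300, 0, 0.53), "pep")
  expect_error(pmax_from_timings(70, 300, -10, 0.53), "pep")
})

test_that("coupling ratio from pressures is the relative pressure reserve", {
  expect_equal(coupling_from_pressures(180, 90), 1)
  expect_equal(coupling_from_pressures(90, 90), 0)
  expect_equal(coupling_from_pressures(181.3, 89.9604),
               (181.3 - 89.9604) / 89.9604, tolerance = 1e-12)
  expect_error(coupling_from_pressures(180, 0), "pes")
  expect_error(coupling_from_pressures(180, -3), "pes")
})

test_that("timing and pressure forms compose to the theoretical coupling equation", {
  set.seed(17)
  for (i in 1:200) {
    pad <- runif(1, 40, 110)
    pes <- runif(1, pad, 140)
    et <- runif(1, 150, 450)
    pep <- runif(1, 60, 140)
    k <- runif(1, 0.2, 1.2)
    composed <- coupling_from_pressures(pmax_from_timings(pad, et, pep, k), pes)
    direct <- pad / pes * (1 + k * et / pep) - 1
    expect_equal(composed, direct, tolerance = 1e-12)
  }
})

test_that("EDV follows from stroke volume and the coupling ratio", {
  est <- estimate_edv(sv = 61, ees_over_ea = 1.5)
  expect_s3_class(est, "edv_estimate")
  expect_equal(est$edv_calc, 61 * (1 + 1 / 1.5), tolerance = 1e-12)
  expect_equal(est$edv_calc, 101.66666666667, tolerance = 1e-10)
  expect_equal(est$esv_calc, est$edv_calc - 61)
  # equal elastances double the stroke volume; huge coupling shrinks ESV to 0
  expect_equal(estimate_edv(50, 1)$edv_calc, 100)
  expect_lt(estimate_edv(50, 1e9)$edv_calc - 50, 1e-6)
  # nonzero V0 shifts the estimate additively
  expect_equal(estimate_edv(50, 1, v0 = 10)$edv_calc, 110)
  expect_error(estimate_edv(50, 0), "ees_over_ea")
  expect_error(estimate_edv(50, -1), "ees_over_ea")
  expect_error(estimate_edv(0, 1), "sv")
})

test_that("EDV estimate is monotone decreasing in the coupling ratio", {
  ratios <- seq(0.3, 5, by = 0.1)
  edvs <- vapply(ratios, function(r) estimate_edv(61, r)$edv_calc, numeric(1))
  expect_true(all(diff(edvs) < 0))
})

test_that("coupling round-trips through the volume identity at V0 = 0", {
  set.seed(23)
  for (i in 1:200) {
    r <- runif(1, 0.05, 20)
    sv <- runif(1, 20, 120)
    est <- estimate_edv(sv, r)
    expect_equal(sv / (est$edv_calc - sv), r, tolerance = 1e-12)
  }
})

test_that("beat observations enforce their physiological invariants", {
  obs <- beat_observation("s1", 117, 73, 96, 286, 61, edv_ref = 91)
  expect_s3_class(obs, "beat_observation")
  expect_error(beat_observation("s", 100, 100, 96, 286, 61), "sbp")
  expect_error(beat_observation("s", 117, 73, 0, 286, 61), "pep")
  expect_error(beat_observation("s", 117, 73, 96, -1, 61), "et")
  expect_error(beat_observation("s", 117, 73, 96, 286, -61), "sv")
  # reference EDV must leave a positive end-systolic volume
  expect_error(beat_observation("s", 117, 73, 96, 286, 61, edv_ref = 55),
               "edv_ref")
  # validation can be disabled for contract-only exploration
  expect_silent(beat_observation("s", 100, 100, 96, 286, 61, validate = FALSE))
})
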