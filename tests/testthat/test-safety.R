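test_that("single-pulse skin limits match the ANSI closed form", {
  expect_equal(round(mpe_single_pulse(816), 2), 34.12)
  expect_identical(mpe_single_pulse(700), 20)
  expect_equal(mpe_single_pulse(750), 20 * 10^0.1)
  expect_error(mpe_single_pulse(650), "wavelength")
  expect_error(mpe_single_pulse(1100), "wavelength")
})

test_that("extended-exposure limits match the ANSI closed form", {
  # the 1.5 s limit prints as 2.07 (the exact value 2.0769 truncates)
  expect_equal(floor(mpe_exposure(816, 1.5) * 100) / 100, 2.07)
  expect_equal(round(mpe_exposure(816, 0.3), 2), 1.39)
  expect_equal(mpe_exposure(700, 1), 1.1)
  expect_error(mpe_exposure(816, 0), "t_s")
})

test_that("per-pulse limits divide the exposure limit over the pulse train", {
  expect_equal(round(mpe_per_pulse_in_scan(816, 1.5, 2000), 2), 0.69)
  expect_equal(round(mpe_per_pulse_in_scan(816, 0.3, 2000), 2), 2.31)
  # halving the repetition rate doubles the per-pulse allowance exactly
  expect_equal(mpe_per_pulse_in_scan(816, 0.3, 1000),
               2 * mpe_per_pulse_in_scan(816, 0.3, 2000))
  expect_error(mpe_per_pulse_in_scan(816, 0.1, 5), "fewer than one pulse")
})

test_that("limits increase with wavelength and scale as t^0.25", {
  lams <- seq(700, 1050, by = 50)
  expect_true(all(diff(vapply(lams, mpe_single_pulse, numeric(1))) > 0))
  expect_true(all(diff(vapply(lams, mpe_exposure, numeric(1),
                              t_s = 1)) > 0))
  expect_equal(mpe_exposure(816, 16) / mpe_exposure(816, 1), 2)
})

test_that("compliance checking uses the binding limit inclusively", {
  ok <- check_compliance(816, 0.3, 2000, 0.17)
  expect_true(ok$compliant)
  expect_gt(ok$margin, 1)
  bad <- check_compliance(816, 0.3, 2000, 40)  # above the single-pulse limit
  expect_false(bad$compliant)
  lim <- check_compliance(816, 0.3, 2000, 0)$binding_limit
  expect_true(check_compliance(816, 0.3, 2000, lim)$compliant)
})
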