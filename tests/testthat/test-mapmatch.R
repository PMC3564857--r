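test_that("well-separated expected blockages are left unmerged", {
  tab <- expected_rotations(data.frame(base_index = c(2400, 2450, 2500)))
  out <- merge_unresolvable(tab, resolution = 2)
  expect_equal(out$base_index, tab$base_index)
  expect_false(any(out$merged))
})

test_that("close groups collapse to their middle member", {
  # three mismatches spanning 8 bases (~1.5 turns) within a 2-turn window
  tab <- expected_rotations(data.frame(base_index = c(2492, 2496, 2500,
                                                      2600)))
  out <- merge_unresolvable(tab, resolution = 2)
  expect_equal(out$base_index, c(2496, 2600))
  expect_equal(out$merged, c(TRUE, FALSE))
  expect_equal(out$n_in_group, c(3L, 1L))
  # even-sized group: the lower median is retained
  two <- expected_rotations(data.frame(base_index = c(2492, 2496)))
  expect_equal(merge_unresolvable(two, 2)$base_index, 2492)
})

test_that("calibration is y = A + x with the analytically forced offset", {
  ex <- c(-535, -516, -499, -478)
  m0 <- match_and_calibrate(ex, ex)
  expect_equal(m0$A, 0)
  expect_equal(m0$sd_turns, 0)
  m <- match_and_calibrate(ex + 0.05, ex)
  expect_equal(m$A, 0.05)
  expect_equal(m$sd_turns, 0)
  expect_equal(m$n_matched, 4)
  expect_error(match_and_calibrate(-470, ex), "at least 2")
})

test_that("turn spread converts to bases through half the helical repeat", {
  set.seed(33)
  ex <- -seq(470, 540, by = 10)
  m <- match_and_calibrate(ex + rnorm(8, 0.1, 0.5), ex)
  expect_equal(m$sd_bases, m$sd_turns * 10.45 / 2)
  # 0.5 turns is 2.6 bases at 10.45 bp/turn
  expect_equal(0.5 * 10.45 / 2, 2.6125)
  expect_equal(round(0.5 * 10.45 / 2, 1), 2.6)
})

test_that("calibration is translation-equivariant", {
  set.seed(34)
  ex <- -seq(470, 540, by = 9)
  fitted <- ex + rnorm(length(ex), 0, 0.4)
  base <- match_and_calibrate(fitted, ex)
  for (c0 in c(-2, 0.7, 5)) {
    shifted <- match_and_calibrate(fitted + c0, ex)
    expect_equal(shifted$A, base$A + c0, tolerance = 1e-9)
    expect_equal(shifted$sd_turns, base$sd_turns, tolerance = 1e-9)
    expect_equal(shifted$pairs$expected_rotation,
                 base$pairs$expected_rotation)
  }
})

test_that("missing and extra blockages are reported, not dropped", {
  ex <- -c(540, 520, 500, 480)
  fitted <- -c(540.1, 499.8, 480.2)       # -520 went undetected
  m <- match_and_calibrate(fitted, ex)
  expect_equal(m$n_matched, 3)
  expect_equal(m$unmatched_expected, -520)
  expect_length(m$unmatched_fitted, 0)
  m2 <- match_and_calibrate(c(fitted, -460), ex)  # spurious extra fit
  expect_equal(m2$n_matched, 3)
  expect_equal(m2$unmatched_fitted, -460)
})

test_that("a large common offset raises the rotation-skid flag", {
  ex <- -c(540, 520, 500, 480)
  expect_true(match_and_calibrate(ex + 5, ex)$skid_suspected)
  expect_false(match_and_calibrate(ex + 0.3, ex)$skid_suspected)
})

test_that("the signature gap fingerprints the construct", {
  uni <- expected_rotations(data.frame(base_index = seq(2400, 2600, 50)))
  g <- signature_gap(uni)
  expect_equal(g$gap, 2 * 50 / 10.45)
  # a blockage-free span flanked by close mismatches, as in the tested
  # construct: a ~19-turn gap between -507 and -488
  fig <- c(-470, -475, -480, -484, -488, -507, -511, -515)
  g2 <- signature_gap(fig)
  expect_equal(g2$gap, 19)
  expect_equal(c(g2$from, g2$to), c(-507, -488))
  # removing one interior blockage doubles the local gap
  g3 <- signature_gap(setdiff(uni$expected_rotation, uni$expected_rotation[3]))
  expect_equal(g3$gap, 4 * 50 / 10.45)
  expect_error(signature_gap(-470), "at least 2")
})
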