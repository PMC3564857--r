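test_that("plectoneme reference shape is a normalized even bump", {
  expect_identical(reference_shape(0), 1)
  expect_equal(reference_shape(1), 0)
  expect_equal(reference_shape(-1.3), 0)
  s <- seq(0.01, 0.99, by = 0.01)
  # evenness is exact, not approximate
  expect_identical(reference_shape(s), reference_shape(-s))
  # strictly decreasing in |sigma| until the narrow bell underflows
  v <- reference_shape(s)
  expect_true(all(diff(v) <= 0))
  expect_true(all(diff(v[v > 1e-12]) < 0))
  # a wide bell decreases strictly over the whole domain
  expect_true(all(diff(reference_shape(s, plecto_width = 0.5)) < 0))
  # the width parameter is the half-width at mid-height
  for (w in c(0.02, 0.025, 0.1, 0.5)) {
    expect_equal(reference_shape(w, plecto_width = w), 0.5)
  }
})

test_that("migration regime extension is linear with intercept N0", {
  p <- sim_params()
  expect_equal(migration_height(0, p), p$H0)
  expect_equal(migration_height(-p$N0, p), 0)
  expect_equal(migration_height(-600, sim_params(N0 = 1200, H0 = 2.76)),
               1.38)
  expect_error(migration_height(-1300, p), "exceeds N0")
})

test_that("blocked extension is a rescaled shifted reference curve", {
  p <- sim_params()
  # apex value: reference_shape(0) = 1
  expect_equal(blocked_height(-480, Ri = -480, Ni = 720, p),
               p$H0 * 720 / p$N0)
  # Ni = N0, Ri = 0 reduces to the bare reference curve
  R <- seq(-50, 50, by = 5)
  expect_equal(blocked_height(R, 0, p$N0, p),
               p$H0 * reference_shape(R / p$N0, p$plecto_width))
  expect_error(blocked_height(-480, -480, 0, p), "Ni must be")
  expect_error(blocked_height(-480, -480, 1300, p), "Ni must be")
})

test_that("segment apexes with Ni = N0 - |Ri| lie on the migration line", {
  p <- sim_params()
  for (Ri in c(-470, -500.5, -535.9)) {
    expect_equal(blocked_height(Ri, Ri, p$N0 - abs(Ri), p),
                 migration_height(Ri, p))
  }
})

test_that("one bead turn advances the junction half a helical repeat", {
  p <- sim_params()
  s <- step_hj(hj_state(), -2, numeric(0), p)
  expect_equal(s$junction_position, 10.45)
  expect_true(is.na(s$blocked_at))
})

test_that("a mismatch blocks advancement and stores plectoneme turns", {
  p <- sim_params()
  s <- step_hj(hj_state(), -20, mismatches = 52.25, p)
  expect_equal(s$blocked_at, 52.25)
  # 52.25 * 2 / 10.45 = 10 turns to reach the block, remainder stored
  expect_equal(s$plectoneme_turns, 10)
  expect_equal(s$junction_position, 52.25)
})

test_that("the ratchet is reversible above the block", {
  p <- sim_params()
  s0 <- step_hj(hj_state(), -20, 52.25, p)
  s1 <- step_hj(step_hj(s0, +5, 52.25, p), -5, 52.25, p)
  expect_equal(s1, s0)
  # also through a full unblock-and-reblock cycle
  s2 <- step_hj(step_hj(s0, +15, 52.25, p), -15, 52.25, p)
  expect_equal(s2, s0)
})

test_that("junction position never passes a mismatch while advancing", {
  p <- sim_params()
  set.seed(11)
  for (rep in 1:20) {
    mis <- sort(runif(3, 20, 200))
    s <- hj_state()
    for (dR in runif(30, -8, 6)) {
      s <- step_hj(s, dR, mis, p)
      # starting at the center, the first mismatch can never be passed
      expect_lte(s$junction_position, mis[1] + 1e-9)
      if (!is.na(s$blocked_at)) {
        expect_equal(s$junction_position, s$blocked_at)
      }
    }
  }
})

test_that("turns are conserved exactly by the state machine", {
  p <- sim_params()
  set.seed(12)
  for (rep in 1:20) {
    mis <- sort(runif(2, 30, 150))
    s <- hj_state()
    applied <- 0
    # drift negative so the junction never fully resorbs (no clamping)
    steps <- runif(25, -6, 2)
    for (dR in steps) {
      s <- step_hj(s, dR, mis, p)
      applied <- applied + dR
      if (s$junction_position == 0) break
      absorbed <- -(2 * s$junction_position / p$hr_dna +
                      s$plectoneme_turns)
      expect_equal(absorbed, applied, tolerance = 1e-12)
    }
  }
})
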