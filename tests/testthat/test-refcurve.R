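test_that("N0 is the zero-height intercept of the migration line", {
  p <- sim_params()
  R <- -(400:460)
  d <- data.frame(rotation_turns = R, height_um = migration_height(R, p))
  est <- estimate_N0(d)
  expect_equal(est$N0, 1200)
  expect_equal(est$H0_intercept, p$H0)
  expect_error(estimate_N0(d[1:3, ]), "at least 5")
  bad <- data.frame(rotation_turns = R, height_um = seq(0, 1, length.out = 61))
  expect_error(estimate_N0(bad), "not a migration regime")
})

test_that("noisy N0 estimates agree with the closed-form OLS oracle", {
  set.seed(21)
  p <- sim_params()
  R <- -seq(380, 478, by = 2)
  h <- migration_height(R, p) + rnorm(length(R), 0, 0.03)
  est <- estimate_N0(data.frame(rotation_turns = R, height_um = h))
  # normal equations written out independently of lm()
  x <- abs(R)
  b <- sum((x - mean(x)) * (h - mean(h))) / sum((x - mean(x))^2)
  a <- mean(h) - b * mean(x)
  expect_equal(est$N0, -a / b, tolerance = 1e-10)
  expect_lt(abs(est$N0 - 1200), 2 * est$N0_se + 1e-9)
})

test_that("the spline reference reproduces a noiseless bell to 1e-3", {
  p <- sim_params(noise_sd_slow = 0, seed = 2)
  tr <- simulate_reference_trace(p, R_max = 60, step = 0.5)
  ref <- fit_reference(tr, N0 = p$N0)
  pred <- predict(ref, tr$rotation_turns / p$N0)
  expect_lt(max(abs(pred - tr$height_um / p$H0)), 1e-3)
  expect_lt(abs(predict(ref, 0) - 1), 1e-3)
})

test_that("the fitted reference is even by construction", {
  run <- make_run(noise = 0.035, seed = 4)
  s <- runif(50, 0, run$ref$sigma_max)
  expect_identical(predict(run$ref, s), predict(run$ref, -s))
  expect_true(all(is.na(predict(run$ref, run$ref$sigma_max + c(0.01, 1)))))
})

test_that("doubling the number of spline pieces is a small perturbation", {
  p <- sim_params(seed = 6)
  tr <- simulate_reference_trace(p)
  r8 <- fit_reference(tr, N0 = p$N0, n_pieces = 8)
  r16 <- fit_reference(tr, N0 = p$N0, n_pieces = 16)
  s <- seq(0, min(r8$sigma_max, r16$sigma_max), length.out = 100)
  expect_lt(max(abs(predict(r8, s) - predict(r16, s))) * r8$H0,
            p$noise_sd_slow)
})

test_that("degenerate reference inputs are rejected", {
  p <- sim_params(noise_sd_slow = 0, seed = 2)
  tr <- simulate_reference_trace(p)
  expect_error(fit_reference(tr[1:10, ], N0 = 1200, n_pieces = 8),
               "fewer points")
  onesided <- tr[tr$rotation_turns > 5, ]
  expect_error(fit_reference(onesided, N0 = 1200), "both signs")
})

test_that("a re-acquired reference reveals a rotation-skid offset", {
  p <- sim_params(seed = 9)
  first <- simulate_reference_trace(p)
  p2 <- sim_params(seed = 10)
  again <- simulate_reference_trace(p2, apex_offset = 3)
  ref <- fit_reference(first, N0 = p$N0, end_trace = again)
  expect_equal(ref$skid_offset, 3, tolerance = 0.5)
})

test_that("reference curves survive a JSON round trip", {
  run <- make_run(seed = 5)
  path <- tempfile(fileext = ".json")
  write_refcurve(run$ref, path)
  back <- read_refcurve(path)
  s <- seq(-run$ref$sigma_max, run$ref$sigma_max, length.out = 50)
  expect_equal(predict(back, s), predict(run$ref, s))
  expect_equal(back$N0, run$ref$N0)
  unlink(path)
})
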