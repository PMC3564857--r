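test_that("weighted residuals follow the relative-height weighting rule", {
  ref <- make_clean_ref()
  Ri <- -480; Ni <- 720
  R <- seq(-500, -479, by = 1)
  seg <- data.frame(rotation_turns = R,
                    height_um = ref$H0 * Ni / ref$N0 *
                      predict(ref, (R - Ri) / Ni))
  r <- blockage_residuals(seg, Ri, Ni, ref)
  # points exactly on the rescaled reference have zero residual
  expect_equal(r$residuals, rep(0, nrow(seg)))
  expect_equal(r$n_excluded, 0)
  # weight = exp(3 * (hrel - 1)): 1 at the apex, e^-1.5 at half height
  seg2 <- data.frame(rotation_turns = c(Ri, Ri - 10),
                     height_um = ref$H0 * Ni / ref$N0 * c(1, 0.5))
  r2 <- blockage_residuals(seg2, Ri, Ni, ref)
  expect_equal(r2$weights, c(1, exp(-1.5)))
  expect_equal(r2$weights[2], 0.2231, tolerance = 1e-3)
  # monotone in hrel: the lower curve is down-weighted
  hrel <- seq(0.2, 1, by = 0.1)
  w <- exp(3 * (hrel - 1))
  expect_true(all(diff(w) > 0))
})

test_that("points outside the reference domain are excluded and counted", {
  ref <- make_clean_ref()
  p <- sim_params()
  seg <- data.frame(rotation_turns = c(-480, -479, -100),
                    height_um = c(1.6, 1.6, 1.0))
  r <- blockage_residuals(seg, Ri = -480, Ni = 700, ref)
  expect_equal(r$n_excluded, 1)   # sigma = 380/700 beyond the data domain
  expect_equal(sum(r$included), 2)
})

test_that("noiseless curve-segments are recovered to 1e-3 turns", {
  ref <- make_clean_ref()
  p <- sim_params()
  for (Ri in c(-470.2, -500.8, -535.5)) {
    seg <- make_segment(Ri, p$N0 - abs(Ri), p)
    f <- fit_blockage(seg, ref)
    expect_true(f$converged)
    expect_equal(f$Ri, Ri, tolerance = 1e-3)
    expect_equal(f$Ni, p$N0 - abs(Ri), tolerance = 1)
  }
})

test_that("fitted Ri is invariant to the choice of N0", {
  run <- make_run(seed = 3)
  rt <- simulate_reference_trace(run$params)
  ref1200 <- fit_reference(rt, N0 = 1200)
  ref1000 <- fit_reference(rt, N0 = 1000)
  segs <- detect_segments(run$trace)
  expect_gt(length(segs), 0)
  for (s in segs) {
    f1 <- fit_blockage(s, ref1200)
    f2 <- fit_blockage(s, ref1000)
    expect_lt(abs(f1$Ri - f2$Ri), 1e-2)
    # Ni absorbs the rescaling
    expect_equal(f1$Ni / f2$Ni, 1.2, tolerance = 1e-3)
  }
})

test_that("the LM optimum agrees with a coarse grid search", {
  ref <- make_clean_ref()
  p <- sim_params()
  set.seed(17)
  for (rep in 1:3) {
    Ri <- runif(1, -530, -470)
    Ni <- p$N0 - abs(Ri)
    seg <- make_segment(Ri, Ni, p, noise = 0.02)
    f <- fit_blockage(seg, ref)
    obj <- function(a, b) sum(blockage_residuals(seg, a, b,
                                                 ref)$residuals_um^2)
    # profile over a 0.25-turn Ri grid, Ni minimized at each node
    grid_Ri <- seq(Ri - 3, Ri + 3, by = 0.25)
    prof <- vapply(grid_Ri, function(a) {
      optimize(function(b) obj(a, b), c(Ni - 60, Ni + 60))$objective
    }, numeric(1))
    expect_lte(abs(f$Ri - grid_Ri[which.min(prof)]), 0.25 + 1e-9)
    expect_lte(f$rss, min(prof) + 1e-9)
  }
})

test_that("the detector reproduces ground-truth segment labels", {
  p <- sim_params(noise_sd_slow = 0, seed = 19)
  mis <- c(2460, 2520, 2580, 2650, 2710)
  tr <- simulate_protocol_run(p, mis, R_start = -465, R_stop = -530)
  segs <- detect_segments(tr)
  expect_length(segs, 5)
  labels <- vapply(segs, function(s) {
    ids <- s$segment_id[s$segment_id > 0]
    as.integer(names(which.max(table(ids))))
  }, integer(1))
  expect_setequal(labels, 1:5)
  # repeated descents over one blockage collapse into one segment
  for (s in segs) {
    expect_gte(nrow(s), 6)
    expect_gte(diff(range(s$rotation_turns)), 5)
  }
})

test_that("zero-noise bootstrap returns zero spread", {
  ref <- make_clean_ref()
  Ri <- -500.8; Ni <- ref$N0 - 500.8
  R <- seq(-524, -499, by = 1)
  seg <- data.frame(rotation_turns = R,
                    height_um = ref$H0 * Ni / ref$N0 *
                      predict(ref, (R - Ri) / Ni))
  f <- fit_blockage(seg, ref)
  fb <- bootstrap_fits(list(f), n_boot = 20, seed = 1)[[1]]
  expect_equal(fb$boot_sd, 0, tolerance = 1e-6)
  expect_equal(fb$boot_bias, 0, tolerance = 1e-6)
  expect_identical(fb$n_boot, 20L)
})

test_that("too few pooled upper-half residuals is an error", {
  ref <- make_clean_ref()
  p <- sim_params()
  seg <- make_segment(-500.8, p$N0 - 500.8, p, n = 8)
  f <- fit_blockage(seg, ref)
  expect_error(bootstrap_fits(list(f), n_boot = 10),
               "pooled upper-half residuals")
})

test_that("bootstrap spread scales roughly linearly with noise", {
  sds <- vapply(c(0.02, 0.04), function(ns) {
    run <- make_run(noise = ns, seed = 23,
                    mismatches = c(2500, 2610, 2700),
                    R_start = -465, R_stop = -530)
    fits <- fit_blockages(run$trace, run$ref, n_boot = 100, seed = 23)
    mean(vapply(fits, `[[`, 0, "boot_sd"))
  }, numeric(1))
  expect_gt(sds[2] / sds[1], 2 * 0.7)
  expect_lt(sds[2] / sds[1], 2 * 1.3)
})

test_that("the upper-half threshold is not a sensitive choice", {
  run <- make_run(noise = 0.035, seed = 25,
                  mismatches = c(2500, 2610, 2700),
                  R_start = -465, R_stop = -530)
  segs <- detect_segments(run$trace)
  fits <- lapply(segs, fit_blockage, ref = run$ref)
  sds <- vapply(c(0.4, 0.5, 0.6), function(th) {
    mean(vapply(bootstrap_fits(fits, n_boot = 100, seed = 25,
                               upper_half = th),
                `[[`, 0, "boot_sd"))
  }, numeric(1))
  expect_lt(max(sds) / min(sds), 2)
})
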