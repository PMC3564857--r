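test_that("exponential fits recover the generating time scale", {
  wt <- simulate_waiting_times(200, tau = 19, seed = 40)
  mle <- fit_exponential(wt)
  expect_lt(abs(mle$tau - 19) / 19, 0.1)
  expect_true(mle$ci[1] < mle$tau && mle$tau < mle$ci[2])
  hist_fit <- fit_exponential(wt, method = "histogram")
  expect_lt(abs(hist_fit$tau - 19) / 19, 0.25)
  # shorter waiting times at the higher temperature
  wt37 <- simulate_waiting_times(200, tau = 3, seed = 42)
  expect_lt(fit_exponential(wt37)$tau, mle$tau)
})

test_that("degenerate and invalid waiting-time sets are handled", {
  expect_equal(fit_exponential(rep(7, 12))$tau, 7)
  expect_equal(fit_exponential(rep(7, 12), method = "histogram")$tau, 7)
  expect_error(fit_exponential(c(1, 2, -1, 3, 4)), "non-positive")
  expect_error(fit_exponential(c(1, 2, 3)), "at least 5")
})

test_that("activation enthalpy matches the closed-form Arrhenius law", {
  expect_equal(arrhenius_enthalpy(5, 30, 5, 37)$Ea_kbT, 0)
  ar <- arrhenius_enthalpy(19, 30, 3, 37)
  expect_equal(ar$Ea_kbT, 82.6, tolerance = 0.01)
  expect_equal(ar$Ea_kJ_mol, 206, tolerance = 0.01)
  # swapping the two conditions leaves the enthalpy unchanged
  sw <- arrhenius_enthalpy(3, 37, 19, 30)
  expect_equal(sw$Ea_kbT, ar$Ea_kbT)
  expect_error(arrhenius_enthalpy(19, 30, 3, 30), "must differ")
  # exact round trip through the generating formula
  for (Ea in c(20, 80, 150)) {
    tau2 <- arrhenius_tau(19, 30, 37, Ea_kbT = Ea)
    expect_equal(arrhenius_enthalpy(19, 30, tau2, 37)$Ea_kbT, Ea)
  }
})

test_that("the kbT and kJ/mol scales stay mutually consistent", {
  ar <- arrhenius_enthalpy(19, 30, 3, 37)
  expect_equal(ar$Ea_kJ_mol / ar$Ea_kbT, 300 * 8.31446 / 1000,
               tolerance = 1e-6)
})

test_that("waiting times at two temperatures recover the enthalpy", {
  Ea <- 80
  tau30 <- 19
  tau37 <- arrhenius_tau(tau30, 30, 37, Ea_kbT = Ea)
  t1 <- fit_exponential(simulate_waiting_times(400, tau30, seed = 43))
  t2 <- fit_exponential(simulate_waiting_times(400, tau37, seed = 44))
  est <- arrhenius_enthalpy(t1$tau, 30, t2$tau, 37)
  expect_lt(abs(est$Ea_kbT - Ea) / Ea, 0.2)
})

test_that("torque follows linear twist elasticity with a critical flag", {
  z <- torque_estimate(0, L1 = 2500)
  expect_equal(z$gamma, 0)
  expect_false(z$beyond_critical)
  t20 <- torque_estimate(20, C = 95, L1 = 2500)
  expect_equal(t20$gamma, 4.14 * 2 * pi * 20 * 95 / 2500)
  expect_true(t20$gamma > 18.5 && t20$gamma < 21)
  expect_true(t20$beyond_critical)
  expect_equal(torque_estimate(20, C = 90, L1 = 2500)$gamma, 18.7,
               tolerance = 0.05)
  expect_equal(torque_estimate(20, C = 100, L1 = 2500)$gamma, 20.8,
               tolerance = 0.05)
  expect_error(torque_estimate(20, L1 = 0), "positive")
})

test_that("torque is linear in delta_R and C and inverse in L1", {
  base <- torque_estimate(10, C = 95, L1 = 2000)$gamma
  for (k in c(0.5, 2, 3)) {
    expect_equal(torque_estimate(10 * k, C = 95, L1 = 2000)$gamma, base * k)
    expect_equal(torque_estimate(10, C = 95 * k, L1 = 2000)$gamma, base * k)
    expect_equal(torque_estimate(10, C = 95, L1 = 2000 * k)$gamma, base / k)
  }
  # sign of the winding does not matter
  expect_equal(torque_estimate(-10, C = 95, L1 = 2000)$gamma, base)
})

test_that("junction side arms shorten the tether as 2 bases per base", {
  tl <- tether_length(13200, 2386)
  expect_equal(tl$tether_bp, 13200 - 2 * 2386)
  expect_equal(round(tl$tether_bp / 1000, 1), 8.4)
  expect_equal(tl$tether_nm, 8428 * 0.30)
  expect_equal(tether_length(13200, 2386, rise_per_bp = 0.34)$tether_nm,
               8428 * 0.34)
  expect_error(tether_length(13200, 7000), "beyond")
})
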