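test_that("Nernst fraction has the logistic endpoints and midpoint", {
  fcn <- ferricyanide_couple()
  expect_identical(nernst_fraction(0.2, fcn), 0.5)
  expect_gt(nernst_fraction(5, fcn), 1 - 1e-12)
  expect_lt(nernst_fraction(-5, fcn), 1e-12)

  # independent scalar evaluation: thermal voltage RT/F at 310.15 K
  vt <- 8.314462618 * 310.15 / 96485.332
  expect_equal(nernst_fraction(0.5, fcn, 310.15),
               1 / (1 + exp(-(0.5 - 0.2) / vt)), tolerance = 1e-12)
  expect_gt(nernst_fraction(0.5, fcn), 0.9999)

  grid <- seq(-0.5, 1, by = 0.01)
  expect_true(all(diff(nernst_fraction(grid, fcn)) >= 0))
  expect_error(nernst_fraction(Inf, fcn), "finite")
  expect_error(nernst_fraction(0.2, fcn, temperature = -1), "temperature")
})

test_that("Faraday charge is linear in moles with the oxidation sign", {
  expect_identical(faraday_charge(0), 0)
  # full oxidation of 3 ml of 5 mM, one electron: 1.5e-5 mol
  expect_equal(faraday_charge(1.5e-5), -96485.332 * 1.5e-5, tolerance = 1e-12)
  expect_equal(abs(faraday_charge(1.5e-5)), 1.447, tolerance = 1e-3)
  expect_equal(faraday_charge(0.75e-5), faraday_charge(1.5e-5) / 2)
  expect_gt(faraday_charge(1.5e-5, direction = "reduction"), 0)
  expect_error(faraday_charge(-1e-6), "nonnegative")
})

test_that("charge integration is the cumulative trapezoid of current", {
  tr <- current_trace(seq(0, 100, by = 1), rep(-1e-3, 101))
  q <- integrate_charge(tr)
  expect_equal(q[1], 0)
  expect_equal(tail(q, 1), -0.1, tolerance = 1e-12)

  expect_equal(integrate_charge(current_trace(0:10, rep(0, 11))),
               rep(0, 11))

  ramp <- current_trace(seq(0, 100, by = 0.5),
                        seq(0, -2e-3, length.out = 201))
  expect_equal(tail(integrate_charge(ramp), 1), -0.1, tolerance = 1e-9)

  expect_error(integrate_charge(current_trace(0, 1e-3)), "2 samples")
})

test_that("bulk electrolysis relaxes to the Nernst endpoint and conserves charge", {
  st <- electrolysis_state()
  fcn <- ferricyanide_couple()
  k_e <- log(100) / 900

  sim <- simulate_bulk_electrolysis(st, signal_schedule(0.5, 5 / k_e),
                                    k_e = k_e)
  feq <- nernst_fraction(0.5, fcn)
  expect_equal(tail(sim$frac_ox, 1), feq, tolerance = 0.01)

  # the stated rate gives >= 99% interconversion within 15 minutes
  sim15 <- simulate_bulk_electrolysis(st, signal_schedule(0.5, 900),
                                      k_e = k_e)
  expect_gte(tail(sim15$frac_ox, 1), 0.99 * feq - 1e-9)

  # charge-conversion consistency with no cell term
  q <- tail(integrate_charge(sim15$trace), 1)
  dmol <- (tail(sim15$frac_ox, 1) - st$frac_ox) * st$volume * st$total_conc
  expect_equal(q, faraday_charge(dmol), tolerance = 5e-3)

  expect_error(simulate_bulk_electrolysis(st, signal_schedule(0.5, 10),
                                          dt = 20), "exceeds")
})

test_that("oxidized fraction stays in [0,1] and conservation holds on random schedules", {
  set.seed(401)
  st <- electrolysis_state()
  for (i in 1:15) {
    ns <- sample(1:4, 1)
    sch <- signal_schedule(runif(ns, -0.6, 0.8),
                           runif(ns, 60, 1200))
    sim <- simulate_bulk_electrolysis(st, sch, k_cell = 0)
    expect_true(all(sim$frac_ox >= 0 & sim$frac_ox <= 1))
    q <- tail(integrate_charge(sim$trace), 1)
    dmol <- (tail(sim$frac_ox, 1) - st$frac_ox) * st$volume * st$total_conc
    q_f <- faraday_charge(abs(dmol),
                          direction = if (dmol >= 0) "oxidation" else "reduction")
    expect_lt(abs(q - q_f), max(5e-3 * abs(q_f), 2e-6))
  }
})

test_that("total |charge| is nondecreasing in oxidation duration", {
  durations <- c(30, 120, 300, 600, 900, 1800)
  q <- vapply(durations, function(d) {
    sim <- simulate_bulk_electrolysis(electrolysis_state(),
                                      signal_schedule(0.5, d))
    abs(tail(integrate_charge(sim$trace), 1))
  }, numeric(1))
  expect_true(all(diff(q) >= 0))
})

test_that("repeated ON/OFF cycling returns to the same two plateaus", {
  sch <- signal_schedule(rep(c(0.5, -0.3), 4), rep(2700, 8))
  sim <- simulate_bulk_electrolysis(electrolysis_state(), sch)
  # sample at the end of each half cycle
  ends <- vapply(1:8, function(i) {
    sim$frac_ox[which.min(abs(sim$times - i * 2700))]
  }, numeric(1))
  highs <- ends[seq(1, 8, by = 2)]
  lows <- ends[seq(2, 8, by = 2)]
  expect_lt(max(highs) - min(highs), 1e-3)
  expect_lt(max(lows) - min(lows), 1e-3)
  expect_gt(min(highs), 0.95)
  expect_lt(max(lows), 0.05)
})

test_that("halving the integration step barely changes the solution", {
  sch <- signal_schedule(c(0.5, -0.3), c(600, 600))
  s1 <- simulate_bulk_electrolysis(electrolysis_state(), sch, dt = 2)
  s2 <- simulate_bulk_electrolysis(electrolysis_state(), sch, dt = 1)
  f1 <- approx(s1$times, s1$frac_ox, xout = c(300, 600, 900, 1200))$y
  f2 <- approx(s2$times, s2$frac_ox, xout = c(300, 600, 900, 1200))$y
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("cell-mediated re-reduction pulls the oxidized fraction down", {
  sch <- signal_schedule(0.5, 1800)
  s0 <- simulate_bulk_electrolysis(electrolysis_state(), sch, k_cell = 0)
  s1 <- simulate_bulk_electrolysis(electrolysis_state(), sch,
                                   k_cell = 2e-3, cell_density = 0.2)
  expect_lt(tail(s1$frac_ox, 1), tail(s0$frac_ox, 1))
  # open-circuit segment: only the cell term acts, frac decays
  sch2 <- signal_schedule(c(0.5, NA), c(900, 3600))
  s2 <- simulate_bulk_electrolysis(electrolysis_state(), sch2,
                                   k_cell = 2e-3, cell_density = 0.2)
  i_on_end <- which.min(abs(s2$times - 900))
  expect_lt(tail(s2$frac_ox, 1), s2$frac_ox[i_on_end])
  # with no cells an open circuit holds the state
  s3 <- simulate_bulk_electrolysis(electrolysis_state(), sch2, k_cell = 0)
  expect_equal(tail(s3$frac_ox, 1), s3$frac_ox[which.min(abs(s3$times - 900))],
               tolerance = 1e-9)
})

test_that("type constructors reject out-of-invariant values", {
  expect_error(redox_couple(n = 0), "n must be")
  expect_error(electrolysis_state(frac_ox = 1.2), "frac_ox")
  expect_error(electrolysis_state(total_conc = 0), "total_conc")
  expect_error(signal_schedule(0.5, -10), "durations")
  expect_error(current_trace(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(current_trace(c(0, 1), c(1, NA)), "finite")
})
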