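test_that("closed-form simulator has the right limits", {
  kp <- kinetic_params(1e3, 1e-3, 1e4, 1e-2)
  zero <- simulate_sensorgram(kp, 100, 50, conc = 0)
  expect_true(all(zero$response == 0))

  # single active site: association plateau Rmax * kaC/(kaC + kd)
  kp1 <- kinetic_params(1e3, 1e-3, 1e3, 1e-3)
  sg <- simulate_sensorgram(kp1, 100, 0, conc = 1e-5,
                            times = seq(0, 300, 0.5) * 100, t_assoc = 25000)
  plateau <- 100 * 0.01 / 0.011
  expect_equal(max(sg$response), plateau, tolerance = 1e-6)
  expect_equal(plateau, 90.909, tolerance = 1e-4)

  # dissociation decays to zero
  late <- simulate_sensorgram(kp, 100, 50, 1e-5,
                              times = c(0, 300, 1e6), t_assoc = 300)
  expect_lt(late$response[3], 1e-8)
})

test_that("plateau at each concentration matches the two-site binding curve", {
  kp <- kinetic_params(2.7e2, 0.216e-4, 8.9e2, 26e-4)
  for (conc in c(2.5e-6, 10e-6, 40e-6)) {
    sg <- simulate_sensorgram(kp, 80, 120, conc,
                              times = seq(0, 1e7, length.out = 50),
                              t_assoc = 1e7)
    expected <- 80 * kp$ka1 * conc / (kp$ka1 * conc + kp$kd1) +
      120 * kp$ka2 * conc / (kp$ka2 * conc + kp$kd2)
    expect_equal(max(sg$response), expected, tolerance = 1e-6)
  }
})

test_that("closed forms agree with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  times <- seq(0, 2700, by = 5)
  cases <- list(
    list(kp = kinetic_params(2.7e2, 0.216e-4, 8.9e2, 26e-4),
         rmax1 = 100, rmax2 = 100, conc = 10e-6),
    list(kp = kinetic_params(1e4, 5e-3, 5e2, 2e-4),
         rmax1 = 60, rmax2 = 140, conc = 2.5e-6),
    list(kp = kinetic_params(1e3, 1e-3, 1e5, 1e-1),
         rmax1 = 30, rmax2 = 200, conc = 40e-6)
  )
  for (cs in cases) {
    closed <- simulate_sensorgram(cs$kp, cs$rmax1, cs$rmax2, cs$conc,
                                  times, 300)$response
    ode <- ode_sensorgram(cs$kp, cs$rmax1, cs$rmax2, cs$conc, times, 300)
    expect_lt(max(abs(closed - ode)) / max(abs(closed)), 1e-6)
  }
})

test_that("baseline correction subtracts blanks and undoes drift", {
  kp <- kinetic_params(1e3, 1e-3, 1e4, 1e-2)
  sg <- simulate_sensorgram(kp, 100, 50, 1e-5, seq(0, 900, 2), 300)
  zeros <- sensorgram(sg$time, rep(0, nrow(sg)), 0, 300)
  expect_equal(baseline_correct(sg, zeros)$response, sg$response)
  expect_true(all(baseline_correct(sg, sg)$response == 0))

  drift <- sensorgram(sg$time, 0.01 * sg$time + 2, 0, 300)
  drifted <- sensorgram(sg$time, sg$response + drift$response, 1e-5, 300)
  expect_equal(baseline_correct(drifted, drift)$response, sg$response,
               tolerance = 1e-12)

  # mismatched grids: refuse unless interpolation is requested
  blank_coarse <- sensorgram(seq(0, 900, 10), 0.01 * seq(0, 900, 10) + 2,
                             0, 300)
  expect_error(baseline_correct(drifted, blank_coarse), "interpolate")
  fixed <- baseline_correct(drifted, blank_coarse, interpolate = TRUE)
  expect_equal(fixed$response, sg$response, tolerance = 1e-9)
})

test_that("invalid kinetic inputs are rejected", {
  expect_error(kinetic_params(-1, 1e-3, 1e3, 1e-2), "ka1")
  expect_error(simulate_sensorgram(kinetic_params(1, 1, 1, 1), 100, 100, -1),
               "conc")
  expect_error(sensorgram(c(0, 1, 1), c(0, 0, 0), 1e-6, 0.5), "increasing")
})

test_that("the KD1 <= KD2 relabelling convention is enforced", {
  kp <- kinetic_params(ka1 = 8.9e2, kd1 = 26e-4,   # weaker site given first
                       ka2 = 2.7e2, kd2 = 0.216e-4)
  expect_lte(kp$KD1, kp$KD2)
  expect_equal(kp$ka1, 2.7e2)
  expect_equal(kp$KD1, equilibrium_kd(2.7e2, 0.216e-4))
})
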