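baseline_kp <- function() kinetic_params(2.7e2, 0.216e-4, 8.9e2, 26e-4)

test_that("noiseless fits recover the generating parameters", {
  kp <- baseline_kp()
  sg <- simulate_sensorgram(kp, 100, 100, 10e-6, seq(0, 2700, 2), 300)
  fit <- fit_heterogeneous(sg)
  est <- coef(fit)
  # compare as ratios so the tolerance is relative even for tiny rates
  for (nm in c("ka1", "kd1", "ka2", "kd2")) {
    expect_equal(est[[nm]] / kp[[nm]], 1, tolerance = 1e-3)
  }
  expect_equal(est[["KD1"]] / kp$KD1, 1, tolerance = 1e-3)
  expect_equal(est[["rmax1"]], 100, tolerance = 1e-3)
  expect_lt(fit$per_conc$rss, 1e-8)
})

test_that("fits are invariant to swapping site labels in the start", {
  kp <- baseline_kp()
  sg <- simulate_sensorgram(kp, 100, 100, 20e-6, seq(0, 2700, 2), 300)
  starts_fwd <- list(c(ka1 = 1e3, kd1 = 1e-5, ka2 = 1e3, kd2 = 1e-3))
  starts_rev <- list(c(ka1 = 1e3, kd1 = 1e-3, ka2 = 1e3, kd2 = 1e-5))
  f1 <- fit_heterogeneous(sg, starts = starts_fwd)
  f2 <- fit_heterogeneous(sg, starts = starts_rev)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_lte(coef(f1)[["KD1"]], coef(f1)[["KD2"]])
})

test_that("noisy fits recover rates with small median error across seeds", {
  # both dissociation timescales resolvable within the acquisition window,
  # the regime where the two-site fit is identifiable from a single curve
  kp <- kinetic_params(1e4, 5e-4, 1e3, 5e-3)
  times <- seq(0, 2700, 3)
  plateau <- max(simulate_sensorgram(kp, 100, 100, 10e-6, times,
                                     300)$response)
  rel_err <- sapply(1:20, function(s) {
    sg <- gen_sensorgram(kp, 100, 100, 10e-6, dt = 3,
                         noise_sd = 0.01 * plateau, seed = 100 + s)
    est <- coef(fit_heterogeneous(sg))
    abs(c(est[["ka1"]] / kp$ka1, est[["kd1"]] / kp$kd1,
          est[["ka2"]] / kp$ka2, est[["kd2"]] / kp$kd2) - 1)
  })
  expect_true(all(apply(rel_err, 1, median) < 0.05))
})

test_that("averaged KD is the mean of per-concentration ratios", {
  kp <- baseline_kp()
  sgs <- lapply(c(5e-6, 20e-6), function(cc)
    simulate_sensorgram(kp, 100, 100, cc, seq(0, 2700, 2), 300))
  fit <- fit_heterogeneous(sgs)
  expect_equal(nrow(fit$per_conc), 2L)
  expect_equal(coef(fit)[["KD1"]] /
                 mean(fit$per_conc$kd1 / fit$per_conc$ka1), 1,
               tolerance = 1e-12)
  expect_false(is.na(fit$sds[["ka1"]]))
})

test_that("spr_fit methods are coherent with the per-curve estimates", {
  kp <- baseline_kp()
  sg <- simulate_sensorgram(kp, 100, 100, 10e-6, seq(0, 2700, 4), 300)
  fit <- fit_heterogeneous(sg)
  res <- residuals(fit)
  expect_length(res, 1L)
  expect_lt(max(abs(res[[1]])), 1e-4)
  pred <- predict(fit)
  expect_equal(pred, sg$response, tolerance = 1e-4)
  sims <- simulate(fit, nsim = 2, seed = 5, noise_sd = 1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "sensorgram")
  expect_output(print(fit), "site 1")
  expect_output(print(summary(fit)), "Averaged parameters")
})

test_that("equilibrium constants follow kd/ka", {
  expect_equal(equilibrium_kd(2, 2), 1)
  expect_equal(equilibrium_kd(2.73e2, 0.11e-4) * 1e8, 4.03, tolerance = 1e-3)
  expect_error(equilibrium_kd(0, 1), "positive")
})

test_that("free energies use the 55.3 M standard state", {
  expect_equal(free_energy(55.3), 0)
  expect_equal(free_energy(0.64e-7), -51.0, tolerance = 1e-3)
  # halving KD tightens binding by exactly RT ln 2
  expect_equal(free_energy(1e-6 / 2) - free_energy(1e-6),
               -8.314e-3 * 298.15 * log(2))
  expect_true(free_energy(1e-6) < free_energy(1e-5))  # monotone in KD
  expect_equal(free_energy(1e-6, unit = "kcal") * 4.184, free_energy(1e-6))
  expect_error(free_energy(-1), "positive")
})

test_that("ligand-induced free-energy shifts are antisymmetric and signed", {
  base <- reported_kp(kinetics_reference$baseline_dmso)
  pred <- reported_kp(kinetics_reference$prednisone)
  dd <- delta_delta_g(pred, base)
  expect_equal(unname(delta_delta_g(base, base)), c(0, 0))
  expect_equal(delta_delta_g(base, pred), -dd)
  # prednisone lowers KD2 13-fold: it favors the interaction at site 2
  expect_lt(dd[["site2"]], 0)
  expect_equal(dd[["site2"]], 8.314e-3 * 298.15 * log(0.38 / 5.0),
               tolerance = 1e-9)
})

test_that("fold changes carry magnitude and direction", {
  base <- reported_kp(kinetics_reference$baseline_dmso)
  fc <- fold_change(base, base)
  expect_equal(fc$factor, c(1, 1))
  expect_equal(fc$direction, c("unchanged", "unchanged"))
  pred <- reported_kp(kinetics_reference$prednisone)
  fc2 <- fold_change(pred, base)
  expect_equal(fc2$direction[2], "decrease")
  expect_equal(fold_change(base, pred)$factor, fc2$factor)  # symmetric ratio
})
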