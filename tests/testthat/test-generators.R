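test_that("ligand-table generator honours counts, determinism and marginals", {
  cfg0 <- generator_config(seed = 1, n_ligands = 0)
  expect_equal(nrow(gen_ligand_table(cfg0)), 0L)

  cfg <- generator_config(seed = 1, n_ligands = 100)
  expect_identical(gen_ligand_table(cfg), gen_ligand_table(cfg))

  # each single-filter pass count is Binomial(10000, 0.5): within 3 sigma
  half <- setNames(rep(0.5, 6),
                   c("mass", "solubility", "bbb", "plasma", "references",
                     "fatty_acid"))
  big <- gen_ligand_table(generator_config(seed = 7, n_ligands = 10000,
                                           filter_pass_fractions = half))
  counts <- c(
    mass = sum(big$mass > 100 & big$mass < 900),
    solubility = sum(big$solubility > 1),
    bbb = sum(big$bbb_penetration > 50),
    plasma = sum(big$plasma_conc > 0.5),
    references = sum(big$ad_refs >= 2),
    fatty_acid = sum(!big$is_fatty_acid)
  )
  expect_true(all(abs(counts - 5000) <= 3 * 50))
})

test_that("generator config validates its fields", {
  expect_error(generator_config(filter_pass_fractions = c(mass = 1.2)),
               "named")
  bad <- setNames(c(1.2, rep(0.5, 5)),
                  c("mass", "solubility", "bbb", "plasma", "references",
                    "fatty_acid"))
  expect_error(generator_config(filter_pass_fractions = bad), "\\[0, 1\\]")
  expect_error(generator_config(n_ligands = -1), "integer")
})

test_that("binding-site generator plants recoverable cluster structure", {
  cfg <- generator_config(seed = 3, n_clusters = 3, sites_per_cluster = 10,
                          site_jitter = 0)
  sites <- gen_binding_sites(cfg)
  expect_length(sites, 30L)
  labels <- vapply(sites, `[[`, integer(1), "true_cluster")
  expect_equal(as.vector(table(labels)), rep(10L, 3))
  # jitter = 0: every site in a cluster is its archetype
  for (g in 1:3) {
    series <- lapply(sites[labels == g], site_to_series)
    expect_true(all(vapply(series, identical, logical(1), series[[1]])))
  }
  expect_identical(gen_binding_sites(cfg), gen_binding_sites(cfg))
  expect_error(
    gen_binding_sites(generator_config(site_jitter = 12), archetype_size = 9),
    "jitter"
  )
  all_res <- unlist(lapply(sites, function(s) s$residues$number))
  expect_true(all(all_res >= 1 & all_res <= 585))
})

test_that("sensorgram generator matches the closed form and calibrates noise", {
  kp <- kinetic_params(1e3, 1e-3, 1e4, 1e-2)
  zero <- gen_sensorgram(kp, 100, 50, conc = 0, dt = 5)
  expect_true(all(zero$response == 0))

  clean <- gen_sensorgram(kp, 100, 50, conc = 1e-5, dt = 1, noise_sd = 0)
  oracle <- simulate_sensorgram(kp, 100, 50, 1e-5,
                                seq(0, 2700, by = 1), 300)
  expect_identical(clean$response, oracle$response)

  noisy <- gen_sensorgram(kp, 100, 50, conc = 1e-5, dt = 1, noise_sd = 1,
                          seed = 11)
  expect_gte(nrow(noisy), 2000L)
  resid_sd <- sd(noisy$response - oracle$response)
  expect_gt(resid_sd, 0.9)
  expect_lt(resid_sd, 1.1)
  expect_identical(
    gen_sensorgram(kp, 100, 50, 1e-5, dt = 5, noise_sd = 1, seed = 2),
    gen_sensorgram(kp, 100, 50, 1e-5, dt = 5, noise_sd = 1, seed = 2)
  )
})
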