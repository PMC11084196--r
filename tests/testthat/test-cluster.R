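test_that("dendrogram cuts honour k and relabel clusters by size", {
  sites <- gen_binding_sites(generator_config(seed = 4, n_clusters = 2,
                                              sites_per_cluster = 5,
                                              site_jitter = 1))
  d <- site_distance_matrix(sites)
  singletons <- hierarchical_cluster(d, k = nrow(d))
  expect_equal(sort(unname(singletons$labels)), seq_len(nrow(d)))
  one <- hierarchical_cluster(d, k = 1)
  expect_true(all(one$labels == 1L))
  expect_error(hierarchical_cluster(d, k = nrow(d) + 1L), "exceeds")

  # unbalanced clusters: label 1 must be the larger group
  cfgA <- generator_config(seed = 5, n_clusters = 2, sites_per_cluster = 3,
                           site_jitter = 0)
  sitesA <- gen_binding_sites(cfgA)
  extra <- gen_binding_sites(generator_config(seed = 6, n_clusters = 1,
                                              sites_per_cluster = 4,
                                              site_jitter = 1),
                             centers = 525L)
  mixed <- c(sitesA, extra)
  for (i in seq_along(mixed)) mixed[[i]]$ligand_id <- sprintf("M%02d", i)
  model <- cluster_sites(mixed, k = 3)
  sizes <- vapply(model$clusters, `[[`, integer(1), "n")
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
})

test_that("residue frequencies count member ligands, not multiplicity", {
  st <- residue_frequency(toy_sites())
  expect_equal(st$n, 2L)
  expect_equal(st$a, 3L)
  freq <- setNames(st$freq$count, st$freq$number)
  expect_equal(freq[c("1", "2", "3")], c(`1` = 1L, `2` = 2L, `3` = 1L))
  expect_equal(st$freq$percent[st$freq$number == 2], 100)

  solo <- residue_frequency(list(binding_site("only", c(5, 9, 100))))
  expect_true(all(solo$freq$count == 1L))
  expect_equal(solo$a, 3L)

  trip <- replicate(3, binding_site("t", c(7, 8)), simplify = FALSE)
  expect_true(all(residue_frequency(trip)$freq$count == 3L))
})

test_that("ligand ranks follow the shared-residue frequency score", {
  ranks <- rank_ligands(toy_sites())
  expect_equal(ranks$R, c(1.5, 1.5))
  expect_equal(ranks$ligand_id, c("A", "B"))  # tie broken by id

  # singleton cluster: every residue has frequency 1/1, so R = site size
  m <- 6L
  solo <- list(binding_site("s", sort(sample(1:585, m))))
  expect_equal(rank_ligands(solo)$R, m)

  # a superset site never ranks below its subset within the same cluster
  members <- list(binding_site("sub", c(10, 20, 30)),
                  binding_site("sup", c(10, 20, 30, 40)),
                  binding_site("oth", c(20, 40, 50)))
  r <- rank_ligands(members)
  expect_gte(r$R[r$ligand_id == "sup"], r$R[r$ligand_id == "sub"])

  # permutation invariance: renaming ligands leaves the scores unchanged
  renamed <- members
  for (i in seq_along(renamed)) renamed[[i]]$ligand_id <- sprintf("Z%d", i)
  expect_setequal(rank_ligands(renamed)$R, r$R)

  # bookkeeping consistency: summing the presence indicator over members
  # recovers each residue frequency
  st <- residue_frequency(members)
  for (i in seq_len(nrow(st$freq))) {
    res <- st$freq$number[i]
    k_sum <- sum(vapply(members, function(s) res %in% s$residues$number,
                        logical(1)))
    expect_equal(k_sum, st$freq$count[i])
  }
})

test_that("representative selection is deterministic under ties", {
  members <- list(binding_site("b2", c(1, 2)), binding_site("a1", c(1, 2)),
                  binding_site("c3", c(1, 3)))
  model <- cluster_sites(members, k = 1)
  reps <- select_representatives(model, top_m = 2)
  expect_equal(reps$ligand_id, c("a1", "b2"))  # tie -> smaller id first
  whole <- select_representatives(model, top_m = 10)
  expect_equal(nrow(whole), 3L)
})

test_that("clustering recovers the planted five-cluster partition exactly", {
  skip_if_not_installed("mclust")
  cfg <- generator_config(seed = 12, n_clusters = 5, sites_per_cluster = 8,
                          site_jitter = 2)
  sites <- gen_binding_sites(cfg)
  truth <- vapply(sites, `[[`, integer(1), "true_cluster")
  model <- cluster_sites(sites, k = 5)
  ari <- mclust::adjustedRandIndex(model$labels, truth)
  expect_equal(ari, 1.0)
  expect_equal(sum(vapply(model$clusters, `[[`, integer(1), "n")),
               length(sites))
})
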