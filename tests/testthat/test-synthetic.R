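test_that("config validation catches inconsistent settings", {
  expect_error(synthetic_config(n_clusters = 2, moas_per_cluster = c(4, 3, 3)),
               "moas_per_cluster")
  expect_error(synthetic_config(p_within = 0.8, p_between = 0.5),
               "equal 1")
  expect_error(synthetic_config(moa_count_distribution = c(0.5, 0.4)),
               "probability vector")
  expect_error(synthetic_config(prevalence_weights = c(1, -1)), "positive")
  expect_error(synthetic_config(p_within = 1.2, p_between = -0.2), "0, 1")
})

test_that("same config and seed give byte-identical output", {
  cfg <- synthetic_config(n_species = 60, seed = 7)
  s1 <- suppressMessages(generate_incidence(cfg))
  s2 <- suppressMessages(generate_incidence(cfg))
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth$partition, s2$truth$partition)
  expect_identical(growth_forms(s1$matrix), growth_forms(s2$matrix))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); suppressMessages(generate_incidence(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("drawn MoA counts are truncated with a warning when infeasible", {
  cfg <- synthetic_config(n_clusters = 2, moas_per_cluster = c(2, 2),
                          n_species = 200, prevalence_weights = rep(1, 4),
                          seed = 11)
  expect_warning(sim <- suppressMessages(generate_incidence(cfg)),
                 "truncated")
  expect_true(all(colSums(sim$matrix) <= 4))
})

test_that("pure within-cluster sampling is recovered exactly by the pipeline", {
  cfg <- synthetic_config(p_within = 1, p_between = 0,
                          prevalence_weights = rep(1, 10), seed = 42)
  sim <- suppressMessages(generate_incidence(cfg))
  f <- filter_matrix(merge_moa_groups(sim$matrix),
                     filter_policy(iterate_to_fixed_point = TRUE))
  # every species' MoA set lies inside one planted cluster
  truth <- sim$truth$partition
  for (s in species_ids(sim$matrix)) {
    hit <- moa_ids(sim$matrix)[unclass(sim$matrix)[, s] == 1L]
    expect_length(unique(truth[hit]), 1)
  }
  part <- cut_dendrogram(agglomerate(to_distance(proximity_matrix(f))), 3)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(part[rownames(f)],
                                         truth[rownames(f)]), 1)
})

test_that("realized prevalence matches expectation under uniform sampling", {
  cfg <- synthetic_config(n_clusters = 1, moas_per_cluster = 10,
                          n_species = 10000, p_within = 1, p_between = 0,
                          prevalence_weights = rep(1, 10), seed = 5)
  sim <- suppressMessages(generate_incidence(cfg))
  # with uniform weights and one cluster a species with m MoAs includes any
  # given MoA with probability m/10
  p_m <- cfg$moa_count_distribution
  mm <- seq_along(p_m)
  expec <- cfg$n_species * sum(mm * p_m) / 10
  vr <- cfg$n_species * (sum(mm * p_m) / 10 - sum((mm / 10)^2 * p_m))
  z <- (rowSums(sim$matrix) - expec) / sqrt(vr)
  expect_true(all(abs(z) < 3))
})

test_that("empirical MoA-count distribution matches the configured one", {
  cfg <- synthetic_config(n_species = 5000, seed = 123)
  sim <- suppressMessages(generate_incidence(cfg))
  obs <- tabulate(colSums(sim$matrix), nbins = 10)
  gof <- chisq.test(obs, p = cfg$moa_count_distribution)
  expect_gt(gof$p.value, 0.01)
})

test_that("scenario presets exhibit their advertised behaviour", {
  presets <- scenario_presets()
  expect_named(presets, c("paperlike", "prevalence_driven",
                          "similarity_driven"))

  # paperlike: 10 x ~100 after fixed-point filtering
  sim <- suppressMessages(generate_incidence(presets$paperlike))
  fp <- filter_matrix(merge_moa_groups(sim$matrix),
                      filter_policy(iterate_to_fixed_point = TRUE))
  expect_equal(nrow(fp), 10L)
  expect_gte(ncol(fp), 95L); expect_lte(ncol(fp), 110L)

  # prevalence_driven: proximity and prevalence weights strongly correlated
  simp <- suppressMessages(generate_incidence(presets$prevalence_driven))
  f <- filter_matrix(merge_moa_groups(simp$matrix), filter_policy())
  r <- correlate_networks(build_prevalence_network(f),
                          build_proximity_network(proximity_matrix(f)))
  expect_gt(r$estimate, 0.7)

  # similarity_driven: planted three clusters recovered exactly
  skip_if_not_installed("mclust")
  sims <- suppressMessages(generate_incidence(presets$similarity_driven))
  fs <- filter_matrix(merge_moa_groups(sims$matrix),
                      filter_policy(iterate_to_fixed_point = TRUE))
  part <- cut_dendrogram(agglomerate(to_distance(proximity_matrix(fs))), 3)
  expect_equal(mclust::adjustedRandIndex(part[rownames(fs)],
                                         sims$truth$partition[rownames(fs)]),
               1)
})

test_that("config YAML and ground-truth JSON round trip", {
  cfg <- synthetic_config(n_species = 33, seed = 2)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, fy)
  back <- read_config_yaml(fy)
  expect_equal(unclass(back), unclass(cfg))

  sim <- suppressMessages(generate_incidence(cfg))
  fj <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, fj)
  parsed <- jsonlite::read_json(fj)
  expect_equal(unlist(parsed$partition), sim$truth$partition)
})
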