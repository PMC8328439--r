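# Generators: determinism, stated limits, and round-trip structure.

test_that("scat generator validates its configuration", {
  expect_error(diet_sim_config(n_scats_per_species = c(harbour = 0)),
               "at least one scat")
  bad <- default_archetypes()
  bad[[1]]$mean <- c(0.5, 0.5, 0, 0, 0, 0.1)
  expect_error(diet_sim_config(archetypes = bad), "summing to 1")
  bad2 <- default_archetypes()
  bad2[[2]]$concentration <- 0
  expect_error(diet_sim_config(archetypes = bad2), "concentration")
  w <- matrix(c(0.6, 0.6), 1, 2, dimnames = list("harbour", NULL))
  expect_error(diet_sim_config(n_scats_per_species = c(harbour = 5),
                               archetypes = default_archetypes()[1:2],
                               species_cluster_weights = w),
               "probability vectors")
})

test_that("identical seed and config give byte-identical scat tables", {
  cfg <- diet_sim_config(n_scats_per_species = c(harbour = 12, grey = 6),
                         seed = 42)
  s1 <- simulate_scats(cfg)
  s2 <- simulate_scats(cfg)
  expect_identical(s1$parts, s2$parts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_scats(diet_sim_config(
    n_scats_per_species = c(harbour = 12, grey = 6), seed = 43))
  expect_false(identical(s1$parts, s3$parts))
})

test_that("infinite concentration with one archetype collapses to its mean", {
  arch <- default_archetypes()[1]
  arch[[1]]$concentration <- Inf
  cfg <- diet_sim_config(n_scats_per_species = c(harbour = 5),
                         archetypes = arch,
                         species_cluster_weights = matrix(
                           1, 1, 1, dimnames = list("harbour", NULL)),
                         seed = 7)
  sim <- simulate_scats(cfg)
  tr <- as.matrix(sim$truth[functional_groups()])
  target <- arch[[1]]$mean
  target[target * cfg$scat_mass_g < 1] <- 0
  target <- target / sum(target)
  for (i in seq_len(nrow(tr))) {
    expect_equal(unname(tr[i, ]), target, tolerance = 1e-12)
  }
  # and reconstruction returns that same composition
  cm <- diet_composition(sim$parts, sim_allometry())
  expect_equal(max(abs(cm$props[sim$truth$scat_id, ] - tr)), 0,
               tolerance = 1e-9)
})

test_that("two well-separated archetypes are recovered by clustering", {
  arch <- list(
    list(label = "flat", mean = c(0.8, 0.1, 0.025, 0.025, 0.025, 0.025),
         concentration = 200),
    list(label = "pelagic", mean = c(0.025, 0.025, 0.025, 0.025, 0.8, 0.1),
         concentration = 200))
  cfg <- diet_sim_config(
    n_scats_per_species = c(harbour = 50, grey = 50), archetypes = arch,
    species_cluster_weights = matrix(0.5, 2, 2,
                                     dimnames = list(c("harbour", "grey"),
                                                     NULL)),
    seed = 3)
  sim <- simulate_scats(cfg)
  cm <- diet_composition(sim$parts, sim_allometry())
  wc <- ward_cluster(scale_matrix(cm), 2)
  truth <- sim$truth[match(cm$meta$scat_id, sim$truth$scat_id), ]
  ri <- rand_index(wc$labels, as.integer(factor(truth$archetype)))
  expect_gt(ri, 0.95)
})

test_that("whisker generator limits behave as stated", {
  # near-zero residual variance: segments equal the individual mean
  cfg <- isotope_sim_config(
    sigma_true = list(harbour = diag(1e-16, 2), grey = diag(1e-16, 2)),
    n_individuals = c(harbour = 3, grey = 3), segments_range = c(4L, 4L),
    seed = 5)
  sim <- simulate_whiskers(cfg)
  for (id in unique(sim$series$individual)) {
    seg <- sim$series[sim$series$individual == id, c("d13C", "d15N")]
    a <- sim$alpha[sim$alpha$individual == id, c("alpha_d13C", "alpha_d15N")]
    expect_lt(max(abs(sweep(as.matrix(seg), 2, as.numeric(a)))), 1e-6)
  }
  # near-zero between-individual variance: everyone sits at mu_true
  cfg2 <- isotope_sim_config(
    omega_true = list(harbour = diag(1e-16, 2), grey = diag(1e-16, 2)),
    n_individuals = c(harbour = 4, grey = 4), seed = 6)
  sim2 <- simulate_whiskers(cfg2)
  a <- as.matrix(sim2$alpha[sim2$alpha$species == "harbour",
                            c("alpha_d13C", "alpha_d15N")])
  expect_lt(max(abs(sweep(a, 2, cfg2$mu_true$harbour))), 1e-6)
})

test_that("whisker grand mean is within 3 standard errors of mu_true", {
  cfg <- isotope_sim_config(n_individuals = c(harbour = 10, grey = 10),
                            segments_range = c(10L, 10L), seed = 8)
  sim <- simulate_whiskers(cfg)
  for (sp in c("harbour", "grey")) {
    a <- sim$alpha[sim$alpha$species == sp, ]
    for (j in 1:2) {
      v <- a[[c("alpha_d13C", "alpha_d15N")[j]]]
      se <- stats::sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - cfg$mu_true[[sp]][j]), 3 * se + 1e-12)
    }
  }
  # positions spaced 10 mm
  expect_true(all(diff(sim$series$segment_mm[sim$series$individual ==
                                               sim$series$individual[1]]) == 10))
})

test_that("whisker generator rejects invalid covariances and ranges", {
  expect_error(isotope_sim_config(
    omega_true = list(harbour = matrix(c(1, 2, 2, 1), 2),
                      grey = diag(2)),
    sigma_true = list(harbour = diag(2), grey = diag(2))),
    "positive-definite")
  expect_error(isotope_sim_config(segments_range = c(2L, 5L)), ">= 3")
})

test_that("dive generator: U/V proportions drive the TAD filter", {
  all_u <- simulate_dives(dive_sim_config(n_individuals = 1, n_dives = 50,
                                          prop_u = 1, seed = 2))
  expect_true(all(compute_tad(all_u$dives) >= 0.9))
  all_v <- simulate_dives(dive_sim_config(n_individuals = 1, n_dives = 50,
                                          prop_u = 0, seed = 2))
  expect_true(all(compute_tad(all_v$dives) < 0.9))
  expect_error(dive_sim_config(prop_u = 1.2), "prop_u")
  expect_error(dive_sim_config(spread_u_km = 0), "spreads")
  d1 <- simulate_dives(dive_sim_config(seed = 9))
  d2 <- simulate_dives(dive_sim_config(seed = 9))
  expect_identical(d1$dives, d2$dives)
})
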