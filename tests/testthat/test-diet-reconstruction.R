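# Counting rules, allometric mass reconstruction, grouping and the
# composition matrix.

test_that("count_individuals follows the paired/unpaired/beak rules", {
  p5 <- make_parts("s1", "Merlangius merlangus", "otolith", "paired")
  p5 <- p5[rep(1, 5), ]
  expect_identical(count_individuals(p5), 3L)

  mixed <- rbind(p5, make_parts("s1", "Merlangius merlangus",
                                "parasphenoid", "unpaired")[rep(1, 4), ])
  expect_identical(count_individuals(mixed), 4L)

  beaks <- make_parts("s1", "Loligo spp.",
                      c(rep("upper_beak", 3), rep("lower_beak", 5)),
                      c(rep("upper_beak", 3), rep("lower_beak", 5)))
  expect_identical(count_individuals(beaks), 5L)

  expect_warning(z <- count_individuals(p5[0, ]), "no parts")
  expect_identical(z, 0L)
})

test_that("count_individuals equals brute-force enumeration up to 8 parts", {
  # all multisets over two paired structure types and one unpaired type
  for (na in 0:4) for (nb in 0:4) for (nc in 0:4) {
    n <- na + nb + nc
    if (n < 1 || n > 8) next
    parts <- make_parts("s", "Merlangius merlangus",
                        c(rep("otolith", na), rep("dentary", nb),
                          rep("parasphenoid", nc)),
                        c(rep("paired", na + nb), rep("unpaired", nc)))
    expected <- max(c(if (na) ceiling(na / 2), if (nb) ceiling(nb / 2),
                      if (nc) nc, 0))
    expect_identical(count_individuals(parts), as.integer(expected))
  }
})

test_that("mass reconstruction: direct arithmetic and imputation", {
  # toy allometry L = 10 * OL, M = 0.001 * L^3; one pair with OL 4 mm
  allo <- data.frame(taxon = "Merlangius merlangus",
                     measurement_kind = "otolith_length",
                     length_form = "linear", length_a = 0, length_b = 10,
                     mass_form = "power", mass_a = 0.001, mass_b = 3,
                     stringsAsFactors = FALSE)
  pair <- make_parts("s1", "Merlangius merlangus", "otolith", "paired",
                     measurement = c(4, 4))
  rec <- reconstruct_scat_mass(pair, allo)
  expect_equal(rec$individuals$length_mm, 40)
  expect_equal(rec$individuals$mass_g, 64)
  expect_equal(rec$taxa$count, 1L)

  # count 3 with measured masses {10, 20} -> imputation at the mean, total 45
  parts <- make_parts("s1", "Merlangius merlangus", "otolith", "paired",
                      measurement = c(10, 10, 20, 20, NA))
  rec2 <- reconstruct_scat_mass(parts, identity_allometry())
  expect_equal(rec2$taxa$count, 3L)
  expect_equal(sort(rec2$individuals$mass_g), c(10, 15, 20))
  expect_equal(rec2$taxa$mass_g, 45)

  # count equal to measured count: no imputation, exact sum
  parts3 <- make_parts("s1", "Merlangius merlangus", "otolith", "paired",
                       measurement = c(10, 10, 20, 20))
  rec3 <- reconstruct_scat_mass(parts3, identity_allometry())
  expect_equal(rec3$taxa$mass_g, 30)
  expect_false(any(rec3$individuals$imputed))

  # unknown taxon errors by name
  bad <- make_parts("s1", "Unknownfish", "otolith", "paired", 5)
  expect_error(reconstruct_scat_mass(bad, allo), "Unknownfish")

  # zero measured in one scat: dataset-wide fallback with warning
  two <- rbind(
    make_parts("s1", "Merlangius merlangus", "otolith", "paired", c(10, 10)),
    make_parts("s2", "Merlangius merlangus", "otolith", "paired",
               measurement = NA))
  expect_warning(rec4 <- reconstruct_scat_mass(two, identity_allometry()),
                 "dataset-wide")
  expect_equal(rec4$taxa$mass_g[rec4$taxa$scat_id == "s2"], 10)
})

test_that("functional group assignment applies the inclusive 200 mm split", {
  sch <- group_scheme()
  expect_equal(assign_functional_group("Pleuronectes platessa", 150, sch),
               "small_benthic_flatfish")
  expect_equal(assign_functional_group("Solea solea", 200, sch),
               "large_benthic_flatfish")
  expect_equal(assign_functional_group("Loligo spp.", 50, sch),
               "pelagic_squid")
  expect_equal(assign_functional_group("Loligo spp.", 5000, sch),
               "pelagic_squid")
  expect_error(assign_functional_group("Dragonfish", 100, sch), "unknown")
})

test_that("composition matrix rows are normalized proportions", {
  ind <- data.frame(
    scat_id = c("a", "a", "b"), species = "harbour", date = "2010-06-01",
    taxon = c("Clupea harengus", "Merlangius merlangus", "Clupea harengus"),
    length_mm = 100, mass_g = c(30, 70, 12), imputed = FALSE,
    stringsAsFactors = FALSE)
  cm <- build_composition_matrix(ind)
  expect_equal(unname(cm$props["a", c("pelagic_fish", "demersal_fish")]),
               c(0.3, 0.7))
  expect_equal(unname(cm$props["b", "pelagic_fish"]), 1)
  expect_equal(unname(rowSums(cm$props)), rep(1, 2), tolerance = 1e-9)
  expect_equal(cm$meta$season, c("spring_summer", "spring_summer"))
  expect_error(build_composition_matrix(ind[0, ]), "no reconstructed mass")
})

test_that("mass is conserved from taxa to groups", {
  sim <- simulate_scats(diet_sim_config(
    n_scats_per_species = c(harbour = 20, grey = 10), seed = 14))
  rec <- reconstruct_scat_mass(sim$parts, sim_allometry())
  cm <- build_composition_matrix(rec$individuals)
  by_taxon <- tapply(rec$taxa$mass_g, rec$taxa$scat_id, sum)
  by_group <- rowSums(cm$masses)
  expect_equal(as.numeric(by_group[names(by_taxon)]), as.numeric(by_taxon),
               tolerance = 1e-9)
})

test_that("synthetic scats round-trip to the generating composition", {
  sim <- simulate_scats(diet_sim_config(
    n_scats_per_species = c(harbour = 40, grey = 20), seed = 21))
  cm <- diet_composition(sim$parts, sim_allometry())
  tr <- as.matrix(sim$truth[functional_groups()])
  expect_lt(max(abs(cm$props[sim$truth$scat_id, ] - tr)), 0.02)
})

test_that("scale_matrix matches scale() semantics", {
  m <- cbind(a = c(0, 1), b = c(3, 3))
  expect_warning(s <- scale_matrix(m), "constant")
  expect_equal(s[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(s[, "b"]), c(0, 0))
  # idempotent on standardized input
  set.seed(1)
  x <- matrix(rnorm(30), 10)
  s1 <- scale_matrix(x)
  expect_equal(scale_matrix(s1), s1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(scale_matrix(x[1, , drop = FALSE]), "2 rows")
})

test_that("season derivation splits April-September vs October-March", {
  expect_equal(season_of(c("2010-04-01", "2010-09-30", "2010-10-01",
                           "2011-03-31")),
               c("spring_summer", "spring_summer", "autumn_winter",
                 "autumn_winter"))
})
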