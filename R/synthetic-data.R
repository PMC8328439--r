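#' Functional prey groups
#'
#' The six functional prey groups used throughout the diet analyses, in the
#' canonical column order of composition matrices.
#'
#' @return Character vector of length 6.
#' @export
functional_groups <- function() {
  c("small_benthic_flatfish", "large_benthic_flatfish", "benthic_nonflatfish",
    "demersal_fish", "pelagic_fish", "pelagic_squid")
}

#' Configuration for the synthetic scat generator
#'
#' Scats are generated from a mixture of diet "archetypes": each scat draws an
#' archetype according to its species' weights, then a composition from a
#' Dirichlet distribution with mean equal to the archetype composition and the
#' given concentration. `concentration = Inf` is the degenerate limit where
#' every scat composition equals the archetype mean exactly.
#'
#' @param n_scats_per_species Named integer vector, scats per species
#'   (default 100 harbour, 50 grey).
#' @param archetypes List of archetypes, each a list with `label`, `mean`
#'   (non-negative length-6 vector summing to 1, ordered as
#'   [functional_groups()]) and `concentration` (> 0, possibly `Inf`).
#' @param species_cluster_weights Matrix (species x archetypes) of mixture
#'   weights, rows summing to 1. Row names must match
#'   `names(n_scats_per_species)`.
#' @param parts_per_scat Integer range (length 2): number of prey individuals
#'   generated per non-empty functional group of a scat.
#' @param scat_mass_g Total reconstructed mass per scat in grams.
#' @param date_range Character length-2, ISO dates bounding the simulated
#'   sampling dates.
#' @param seed Integer seed; the generator has no global random state.
#' @return Object of class `diet_sim_config`.
#' @export
diet_sim_config <- function(n_scats_per_species = c(harbour = 100, grey = 50),
                            archetypes = default_archetypes(),
                            species_cluster_weights = NULL,
                            parts_per_scat = c(1L, 3L),
                            scat_mass_g = 1000,
                            date_range = c("2002-01-15", "2019-12-15"),
                            seed = 1L) {
  if (any(n_scats_per_species < 1)) {
    stop("at least one scat per species must be requested", call. = FALSE)
  }
  if (is.null(names(n_scats_per_species))) {
    stop("`n_scats_per_species` must be named by species", call. = FALSE)
  }
  for (a in archetypes) {
    if (length(a$mean) != 6L || any(a$mean < 0) ||
        abs(sum(a$mean) - 1) > 1e-8) {
      stop("each archetype mean must be a non-negative length-6 vector summing to 1",
           call. = FALSE)
    }
    if (is.na(a$concentration) || a$concentration <= 0) {
      stop("archetype concentration must be > 0", call. = FALSE)
    }
  }
  if (is.null(species_cluster_weights)) {
    k <- length(archetypes)
    sp <- names(n_scats_per_species)
    if (k == 6L && setequal(sp, c("harbour", "grey"))) {
      # default to the observed per-species scat distribution across the six
      # empirical clusters (harbour concentrated on the two flatfish-led
      # clusters; grey spread across cluster types)
      species_cluster_weights <- rbind(
        harbour = c(0.290, 0.565, 0.062, 0.000, 0.021, 0.062),
        grey = c(0.247, 0.221, 0.143, 0.117, 0.273, 0.000))[sp, ]
      species_cluster_weights <-
        species_cluster_weights / rowSums(species_cluster_weights)
    } else {
      species_cluster_weights <- matrix(1 / k, length(sp), k,
                                        dimnames = list(sp, NULL))
    }
  }
  if (any(abs(rowSums(species_cluster_weights) - 1) > 1e-8) ||
      any(species_cluster_weights < 0)) {
    stop("species_cluster_weights rows must be probability vectors", call. = FALSE)
  }
  structure(list(n_scats_per_species = n_scats_per_species,
                 archetypes = archetypes,
                 species_cluster_weights = species_cluster_weights,
                 parts_per_scat = as.integer(parts_per_scat),
                 scat_mass_g = scat_mass_g,
                 date_range = date_range,
                 seed = as.integer(seed)),
            class = "diet_sim_config")
}

#' Default diet archetypes
#'
#' Six archetypes mimicking the empirically observed cluster typologies: two
#' flatfish-dominated mixtures (large- and small-flatfish led), an almost pure
#' demersal cluster, a squid-led mixed cluster, an almost pure pelagic-fish
#' cluster and a benthic non-flatfish cluster.
#'
#' @param concentration Dirichlet concentration shared by all archetypes.
#' @return List of archetype definitions for [diet_sim_config()].
#' @export
default_archetypes <- function(concentration = 50) {
  mk <- function(label, mean) list(label = label, mean = mean / sum(mean),
                                   concentration = concentration)
  list(
    mk("large_flatfish_led", c(0.15, 0.65, 0.05, 0.07, 0.05, 0.03)),
    mk("small_flatfish_led", c(0.65, 0.15, 0.05, 0.07, 0.05, 0.03)),
    mk("demersal",           c(0.02, 0.02, 0.02, 0.90, 0.02, 0.02)),
    mk("squid_mixed",        c(0.02, 0.15, 0.02, 0.20, 0.11, 0.50)),
    mk("pelagic",            c(0.02, 0.02, 0.02, 0.02, 0.90, 0.02)),
    mk("benthic_other",      c(0.05, 0.05, 0.80, 0.06, 0.02, 0.02))
  )
}

#' Toy allometry table used by the scat generator
#'
#' One representative taxon per functional group, each with an invertible
#' linear measurement-to-length and length-to-mass model, so that any target
#' prey mass maps to an exact hard-part measurement and the generated scats
#' round-trip through the diet reconstruction without error. Flatfish are
#' covered by two taxa whose admissible mass ranges land below (plaice) and at
#' or above (sole) the 200 mm large-flatfish threshold.
#'
#' @return An allometry table `data.frame` (see [read_allometry()] for the
#'   schema).
#' @export
sim_allometry <- function() {
  data.frame(
    taxon = c("Pleuronectes platessa", "Solea solea", "Callionymus lyra",
              "Merlangius merlangus", "Clupea harengus", "Loligo spp."),
    measurement_kind = c("otolith_length", "otolith_length", "otolith_length",
                         "otolith_length", "otolith_width",
                         "lower_rostral_length"),
    length_form = "linear",
    length_a = 0,
    length_b = c(10, 10, 5, 12, 8, 50),
    mass_form = "linear",
    mass_a = c(0, -399, 0, 0, 0, 0),
    mass_b = c(10, 2, 4, 5, 3, 2),
    stringsAsFactors = FALSE
  )
}

# taxon representing each functional group in the generator
sim_group_taxa <- function() {
  c(small_benthic_flatfish = "Pleuronectes platessa",
    large_benthic_flatfish = "Solea solea",
    benthic_nonflatfish = "Callionymus lyra",
    demersal_fish = "Merlangius merlangus",
    pelagic_fish = "Clupea harengus",
    pelagic_squid = "Loligo spp.")
}

# invert the linear/power models of one allometry row: mass (g) -> measurement
invert_allometry <- function(row, mass) {
  len <- switch(row$mass_form,
                linear = (mass - row$mass_a) / row$mass_b,
                power = (mass / row$mass_a)^(1 / row$mass_b),
                stop("unknown mass model form: ", row$mass_form))
  switch(row$length_form,
         linear = (len - row$length_a) / row$length_b,
         power = (len / row$length_a)^(1 / row$length_b),
         stop("unknown length model form: ", row$length_form))
}

#' Simulate a scat hard-part table with known diet composition
#'
#' Each synthetic scat draws an archetype, then a Dirichlet composition around
#' the archetype mean; prey individuals (paired otoliths, or upper/lower squid
#' beaks) are then synthesized with measurements chosen so that the
#' reconstructed mass proportions equal the drawn composition exactly.
#' Functional-group masses below 1 g are dropped and the composition
#' renormalized (the returned truth reflects what the parts encode).
#'
#' @param config A [diet_sim_config()].
#' @return List of class `scat_sim` with elements `parts` (a scat hard-part
#'   table), `truth` (scat_id, species, archetype label and the 6-group true
#'   composition) and `config`.
#' @export
simulate_scats <- function(config) {
  stopifnot(inherits(config, "diet_sim_config"))
  set.seed(config$seed)
  allo <- sim_allometry()
  taxa <- sim_group_taxa()
  groups <- functional_groups()
  dates <- as.Date(config$date_range)

  parts <- list()
  truth <- list()
  sid <- 0L
  for (sp in names(config$n_scats_per_species)) {
    w <- config$species_cluster_weights[sp, ]
    for (i in seq_len(config$n_scats_per_species[[sp]])) {
      sid <- sid + 1L
      scat_id <- sprintf("%s_%04d", sp, sid)
      arch_idx <- sample.int(length(config$archetypes), 1, prob = w)
      arch <- config$archetypes[[arch_idx]]
      p <- if (is.infinite(arch$concentration)) arch$mean else
        rdirichlet1(arch$mean * arch$concentration)
      mass <- p * config$scat_mass_g
      keep <- mass >= 1
      mass[!keep] <- 0
      p_true <- mass / sum(mass)
      date <- dates[1] + floor(stats::runif(1) * as.numeric(diff(dates) + 1))
      for (g in which(mass > 0)) {
        taxon <- taxa[[groups[g]]]
        row <- allo[allo$taxon == taxon, ]
        n_ind <- sample_range(config$parts_per_scat[1], config$parts_per_scat[2])
        # keep each individual's mass >= 1 g so the toy allometries stay on
        # the correct side of the flatfish length threshold
        n_ind <- max(1L, min(n_ind, floor(mass[g])))
        m_each <- mass[g] / n_ind
        meas <- invert_allometry(row, m_each)
        if (groups[g] == "pelagic_squid") {
          parts[[length(parts) + 1L]] <- data.frame(
            scat_id = scat_id, species = sp, date = as.character(date),
            taxon = taxon,
            structure = rep(c("lower_beak", "upper_beak"), each = n_ind),
            structure_class = rep(c("lower_beak", "upper_beak"), each = n_ind),
            measurable = rep(c(TRUE, FALSE), each = n_ind),
            measurement = c(rep(meas, n_ind), rep(NA_real_, n_ind)),
            measurement_kind = row$measurement_kind,
            stringsAsFactors = FALSE)
        } else {
          parts[[length(parts) + 1L]] <- data.frame(
            scat_id = scat_id, species = sp, date = as.character(date),
            taxon = taxon, structure = "otolith", structure_class = "paired",
            measurable = TRUE,
            measurement = rep(meas, 2 * n_ind),
            measurement_kind = row$measurement_kind,
            stringsAsFactors = FALSE)
        }
      }
      tr <- data.frame(scat_id = scat_id, species = sp,
                       archetype = arch$label, stringsAsFactors = FALSE)
      tr[groups] <- as.list(p_true)
      truth[[sid]] <- tr
    }
  }
  structure(list(parts = do.call(rbind, parts),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "scat_sim")
}

#' Configuration for the synthetic whisker-isotope generator
#'
#' @param mu_true Named list (per species) of true mean isotopic values
#'   (delta13C, delta15N) in permil.
#' @param omega_true Named list of true between-individual 2x2 covariance
#'   matrices (permil^2), symmetric positive definite.
#' @param sigma_true Named list of true within-individual (residual) 2x2
#'   covariance matrices (permil^2).
#' @param n_individuals Named integer vector of individuals per species.
#' @param segments_range Integer range of whisker segments per individual
#'   (minimum 3).
#' @param seed Integer seed.
#' @return Object of class `isotope_sim_config`.
#' @export
isotope_sim_config <- function(
    mu_true = list(harbour = c(-15.5, 17.5), grey = c(-15.0, 16.5)),
    omega_true = list(harbour = matrix(c(0.30, 0.05, 0.05, 0.20), 2),
                      grey = matrix(c(0.20, 0.05, 0.05, 0.70), 2)),
    sigma_true = list(harbour = diag(c(0.15, 0.15)),
                      grey = diag(c(0.15, 0.15))),
    n_individuals = c(harbour = 8, grey = 10),
    segments_range = c(6L, 14L),
    seed = 1L) {
  species <- names(n_individuals)
  for (sp in species) {
    assert_spd(omega_true[[sp]], "omega_true")
    assert_spd(sigma_true[[sp]], "sigma_true")
  }
  if (any(segments_range < 3)) {
    stop("segments per individual must be >= 3", call. = FALSE)
  }
  structure(list(mu_true = mu_true, omega_true = omega_true,
                 sigma_true = sigma_true, n_individuals = n_individuals,
                 segments_range = as.integer(segments_range),
                 seed = as.integer(seed)),
            class = "isotope_sim_config")
}

#' Simulate whisker isotope series with known hierarchical parameters
#'
#' For each individual i of species k, the individual-level mean alpha_i is
#' drawn from a bivariate Student distribution with degrees of freedom equal
#' to its segment count, location `mu_true[[k]]` and scale `omega_true[[k]]`;
#' each segment measurement is then bivariate normal around alpha_i with
#' residual covariance `sigma_true[[k]]`. Segments are spaced 10 mm from the
#' whisker base.
#'
#' @param config An [isotope_sim_config()].
#' @return List of class `whisker_sim` with `series` (data.frame: individual,
#'   species, segment_mm, d13C, d15N), `alpha` (true individual means) and
#'   `config`.
#' @export
simulate_whiskers <- function(config) {
  stopifnot(inherits(config, "isotope_sim_config"))
  set.seed(config$seed)
  out <- list()
  alph <- list()
  for (sp in names(config$n_individuals)) {
    mu <- config$mu_true[[sp]]
    Om <- config$omega_true[[sp]]
    Si <- config$sigma_true[[sp]]
    for (i in seq_len(config$n_individuals[[sp]])) {
      id <- sprintf("%s_%02d", toupper(substr(sp, 1, 1)), i)
      n_seg <- sample_range(config$segments_range[1], config$segments_range[2])
      a <- drop(rmvt2(1, df = n_seg, mu = mu, scale = Om))
      y <- rmvnorm2(n_seg, a, Si)
      out[[length(out) + 1L]] <- data.frame(
        individual = id, species = sp, segment_mm = 10 * seq_len(n_seg),
        d13C = y[, 1], d15N = y[, 2], stringsAsFactors = FALSE)
      alph[[length(alph) + 1L]] <- data.frame(
        individual = id, species = sp, alpha_d13C = a[1], alpha_d15N = a[2],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(series = do.call(rbind, out),
                 alpha = do.call(rbind, alph),
                 config = config),
            class = "whisker_sim")
}

#' Configuration for the synthetic dive generator
#'
#' @param n_individuals Number of tracked individuals.
#' @param n_dives Dives per individual.
#' @param prop_u Proportion of U-shaped (likely foraging) dives, in [0, 1].
#' @param centers_u Matrix (n x 2, lon/lat degrees) of foraging centers for
#'   U-shaped dives; each U dive is assigned one center at random.
#' @param center_v Lon/lat center of the dispersed non-foraging (V-shaped)
#'   dive cloud.
#' @param spread_u_km,spread_v_km Spatial standard deviation (km) around the
#'   centers; both must be > 0.
#' @param depth_range,duration_range Max-depth (m) and duration (s) ranges.
#' @param seed Integer seed.
#' @return Object of class `dive_sim_config`.
#' @export
dive_sim_config <- function(n_individuals = 3, n_dives = 200, prop_u = 0.5,
                            centers_u = matrix(c(1.2, 50.2), 1),
                            center_v = c(1.0, 50.0),
                            spread_u_km = 5, spread_v_km = 40,
                            depth_range = c(5, 50),
                            duration_range = c(60, 400),
                            seed = 1L) {
  if (prop_u < 0 || prop_u > 1) stop("prop_u must be in [0, 1]", call. = FALSE)
  if (spread_u_km <= 0 || spread_v_km <= 0) {
    stop("spatial spreads must be > 0", call. = FALSE)
  }
  centers_u <- matrix(centers_u, ncol = 2)
  structure(list(n_individuals = n_individuals, n_dives = n_dives,
                 prop_u = prop_u, centers_u = centers_u, center_v = center_v,
                 spread_u_km = spread_u_km, spread_v_km = spread_v_km,
                 depth_range = depth_range, duration_range = duration_range,
                 seed = as.integer(seed)),
            class = "dive_sim_config")
}

#' Simulate a dive table
#'
#' U-shaped dives get flat-bottomed intermediate-depth profiles (nine
#' intermediate depths between 92% and 100% of the max depth, hence a time
#' allocation at depth (TAD) index near 1) spatially clustered around the
#' foraging centers; V-shaped dives get symmetric descent/ascent profiles
#' (TAD near 0.56) dispersed around `center_v`. The tag-provided
#' `percent_area` field carries the profile TAD.
#'
#' @param config A [dive_sim_config()].
#' @return List of class `dive_sim` with `dives` (a dive table data.frame) and
#'   `config`. The `is_u` column records the generating mode.
#' @export
simulate_dives <- function(config) {
  stopifnot(inherits(config, "dive_sim_config"))
  set.seed(config$seed)
  n_tot <- config$n_individuals * config$n_dives
  rows <- vector("list", n_tot)
  t0 <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")
  r <- 0L
  for (ind in seq_len(config$n_individuals)) {
    id <- sprintf("IND%02d", ind)
    for (d in seq_len(config$n_dives)) {
      r <- r + 1L
      is_u <- stats::runif(1) < config$prop_u
      maxd <- stats::runif(1, config$depth_range[1], config$depth_range[2])
      dur <- stats::runif(1, config$duration_range[1], config$duration_range[2])
      if (is_u) {
        prof <- maxd * stats::runif(9, 0.92, 1.0)
        ci <- config$centers_u[sample.int(nrow(config$centers_u), 1), ]
        sd_km <- config$spread_u_km
      } else {
        prof <- maxd * c(0.2, 0.4, 0.6, 0.8, 1.0, 0.8, 0.6, 0.4, 0.2)
        ci <- config$center_v
        sd_km <- config$spread_v_km
      }
      prof <- pmin(prof, maxd)
      lat <- ci[2] + stats::rnorm(1, 0, sd_km / 111.32)
      lon <- ci[1] + stats::rnorm(1, 0, sd_km / (111.32 * cos(ci[2] * pi / 180)))
      row <- data.frame(individual = id,
                        start_time = format(t0 + (d - 1) * 3600,
                                            "%Y-%m-%dT%H:%M:%SZ"),
                        max_depth_m = maxd, duration_s = dur,
                        percent_area = mean(prof) / maxd,
                        stringsAsFactors = FALSE)
      row[paste0("depth", 1:9)] <- as.list(prof)
      row$lon <- lon
      row$lat <- lat
      row$is_u <- is_u
      rows[[r]] <- row
    }
  }
  structure(list(dives = do.call(rbind, rows), config = config),
            class = "dive_sim")
}
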