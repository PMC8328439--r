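# Shared fixtures and independent oracles.

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

# Independent Ward.D2 oracle: greedy merges computed from raw points, merge
# cost sqrt(2 * nA*nB/(nA+nB) * ||cA - cB||^2) (equals the Euclidean distance
# for singletons). Ties broken toward the lowest-index pair.
ward_oracle <- function(x) {
  n <- nrow(x)
  cl <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  labels_at <- list()
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(cl)[-length(cl)]) for (j in (i + 1):length(cl)) {
      a <- cl[[i]]; b <- cl[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                     sum((ca - cb)^2))
      if (cost < best[1] - 1e-12) best <- c(cost, i, j)
    }
    heights[step] <- best[1]
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl <- cl[-best[3]]
    labels_at[[length(cl)]] <- lapply(cl, sort)
  }
  list(heights = heights, labels_at = labels_at)
}

ward_oracle_labels <- function(oracle, k, n) {
  lab <- integer(n)
  for (ci in seq_along(oracle$labels_at[[k]])) {
    lab[oracle$labels_at[[k]][[ci]]] <- ci
  }
  lab
}

# Build hard-part rows compactly
make_parts <- function(scat_id, taxon, structure, class, measurement = NA,
                       species = "harbour", date = "2010-06-01") {
  n <- max(length(structure), length(measurement))
  data.frame(scat_id = scat_id, species = species, date = date,
             taxon = taxon, structure = rep_len(structure, n),
             structure_class = rep_len(class, n),
             measurable = !is.na(rep_len(measurement, n)),
             measurement = rep_len(measurement, n),
             measurement_kind = "otolith_length", stringsAsFactors = FALSE)
}

# Identity-ish allometry: length = measurement, mass = length (1 g per mm)
identity_allometry <- function(taxon = "Merlangius merlangus") {
  data.frame(taxon = taxon, measurement_kind = "otolith_length",
             length_form = "linear", length_a = 0, length_b = 1,
             mass_form = "linear", mass_a = 0, mass_b = 1,
             stringsAsFactors = FALSE)
}

# Reduced MCMC settings for tests (Gibbs mixes fast; keep suites quick)
quick_fit <- function(seed = 1L, chains = 2, iterations = 800, warmup = 400) {
  fit_config(chains = chains, iterations = iterations, warmup = warmup,
             retain = 1000, seed = seed)
}

# Monte-Carlo rejection oracle for the intersection area of two 95% ellipses:
# sample uniformly inside ellipse A (disk transform) and scale the fraction
# landing inside B by A's analytic area. Far lower variance than box
# rejection at the same n.
mc_ellipse_intersection <- function(ca, A, cb, B, p = 0.95, n = 1e6) {
  q <- stats::qchisq(p, 2)
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  disk <- cbind(r * cos(th), r * sin(th))
  pts <- sweep(sqrt(q) * disk %*% chol(A), 2, ca, `+`)
  d <- sweep(pts, 2, cb)
  inb <- rowSums((d %*% solve(B)) * d) <= q
  area_a <- pi * q * sqrt(det(A))
  mean(inb) * area_a
}

# Well-separated two-blob matrix for clustering tests
two_blobs <- function(n_per = 10, sep = 10, d = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = sep), n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}
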