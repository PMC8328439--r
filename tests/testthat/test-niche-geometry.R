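# Ellipse geometry, overlap proportions, probability grids and prey overlay.

test_that("ellipse_from_points matches direct mean/covariance formulas", {
  pts <- rbind(c(-16, 17), c(-15, 18), c(-14.5, 16.5), c(-15.5, 17.2),
               c(-16.2, 17.8))
  e <- ellipse_from_points(pts)
  expect_equal(e$center, colMeans(pts))
  expect_equal(e$shape, stats::cov(pts))
  expect_error(ellipse_from_points(pts[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(ellipse_from_points(line), "collinear")
})

test_that("ellipse equivariance under affine maps", {
  set.seed(41)
  pts <- matrix(rnorm(60), 30, 2)
  A <- matrix(c(2, 0.5, -0.3, 1.5), 2)
  b <- c(3, -1)
  e1 <- ellipse_from_points(pts)
  e2 <- ellipse_from_points(sweep(pts %*% t(A), 2, b, `+`))
  expect_equal(e2$center, drop(A %*% e1$center) + b)
  expect_equal(e2$shape, A %*% e1$shape %*% t(A))
  expect_equal(ellipse_area(e2), abs(det(A)) * ellipse_area(e1),
               tolerance = 1e-9)
})

test_that("ellipse_area closed form and homogeneity", {
  e <- niche_ellipse(c(0, 0), diag(2), 0.95)
  expect_equal(ellipse_area(e), pi * stats::qchisq(0.95, 2),
               tolerance = 1e-12)
  e2 <- niche_ellipse(c(0, 0), 2 * diag(2), 0.95)
  expect_equal(ellipse_area(e2), 2 * ellipse_area(e))
  e3 <- niche_ellipse(c(0, 0), diag(2), 1e-9)
  expect_lt(ellipse_area(e3), 1e-6)
  expect_error(niche_ellipse(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("ellipse_overlap: identity, disjoint and nested analytic cases", {
  e <- niche_ellipse(c(0, 0), diag(2))
  same <- ellipse_overlap(e, e)
  expect_equal(same$prop_union, 1, tolerance = 1e-3)
  expect_equal(same$a_in_b, 1, tolerance = 1e-3)

  far <- ellipse_overlap(e, niche_ellipse(c(100, 0), diag(2)))
  expect_equal(far$intersection, 0)
  expect_equal(far$prop_union, 0)

  nested <- ellipse_overlap(e, niche_ellipse(c(0, 0), 4 * diag(2)))
  expect_equal(nested$a_in_b, 1, tolerance = 1e-3)
  expect_equal(nested$prop_union, 0.25, tolerance = 1e-3)
  expect_equal(nested$b_in_a, 0.25, tolerance = 1e-3)
})

test_that("polygonal intersection converges in vertex count", {
  set.seed(42)
  ea <- niche_ellipse(c(0, 0), crossprod(matrix(rnorm(4), 2)) + diag(0.5, 2))
  eb <- niche_ellipse(c(1, 0.5),
                      crossprod(matrix(rnorm(4), 2)) + diag(0.5, 2))
  a360 <- ellipse_overlap(ea, eb, vertices = 360)$intersection
  a720 <- ellipse_overlap(ea, eb, vertices = 720)$intersection
  expect_lt(abs(a720 - a360) / a360, 0.001)
})

test_that("ellipse_overlap agrees with a Monte-Carlo rejection oracle", {
  set.seed(43)
  for (rep in 1:5) {
    A <- crossprod(matrix(rnorm(4), 2)) + diag(0.3, 2)
    B <- crossprod(matrix(rnorm(4), 2)) + diag(0.3, 2)
    ca <- rnorm(2, 0, 0.5)
    cb <- rnorm(2, 0, 0.5)
    ov <- ellipse_overlap(niche_ellipse(ca, A), niche_ellipse(cb, B))
    mc <- mc_ellipse_intersection(ca, A, cb, B)
    expect_lt(abs(ov$intersection - mc) / max(mc, 1e-3), 0.005)
  }
})

test_that("summarize_overlap: self-comparison and species-swap symmetry", {
  set.seed(44)
  pred_a <- array(rnorm(150 * 40 * 2), c(150, 40, 2))
  pred_b <- array(rnorm(150 * 40 * 2, 0.7), c(150, 40, 2))
  sa <- ellipse_set(pred_a, "A")
  sb <- ellipse_set(pred_b, "B")
  self <- summarize_overlap(sa, sa, vertices = 180)
  expect_equal(self$p_area_b_gt_a, 0)  # identical areas, strict inequality
  expect_equal(self$summary$median[self$summary$quantity == "prop_union"], 1,
               tolerance = 1e-3)
  ab <- summarize_overlap(sa, sb, vertices = 180)
  ba <- summarize_overlap(sb, sa, vertices = 180)
  expect_equal(ab$summary$median[ab$summary$quantity == "prop_union"],
               ba$summary$median[ba$summary$quantity == "prop_union"],
               tolerance = 1e-6)
  expect_equal(ab$summary$median[ab$summary$quantity == "a_in_b"],
               ba$summary$median[ba$summary$quantity == "b_in_a"],
               tolerance = 1e-6)
  expect_true(all(ab$summary$lower <= ab$summary$median + 1e-12 &
                    ab$summary$median <= ab$summary$upper + 1e-12))
  sc <- ellipse_set(pred_b[1:10, , ], "C")
  expect_error(summarize_overlap(sa, sc), "paired")
})

test_that("membership grid: limits, AND bound, and center membership", {
  set.seed(45)
  pred_a <- array(rnorm(100 * 60 * 2, 0, 0.3), c(100, 60, 2))
  pred_b <- array(rnorm(100 * 60 * 2, 1.5, 0.3), c(100, 60, 2))
  sa <- ellipse_set(pred_a, "A")
  sb <- ellipse_set(pred_b, "B")
  expect_warning(membership_grid(list(sa, sb), n = 40), "coarser")
  g <- membership_grid(list(sa, sb), xlim = c(-4, 6), ylim = c(-4, 6),
                       n = 60)
  # center of A's cloud: membership about 1
  ix <- which.min(abs(g$x - 0))
  iy <- which.min(abs(g$y - 0))
  expect_gt(g$membership$A[ix, iy], 0.99)
  # far corner: zero
  expect_equal(g$membership$A[1, 1], 0)
  # joint <= min of marginals everywhere
  expect_true(all(g$joint <= pmin(g$membership$A, g$membership$B) + 1e-12))
  # product rule differs but respects [0, 1]
  g2 <- membership_grid(list(sa, sb), xlim = c(-4, 6), ylim = c(-4, 6),
                        n = 60, joint_rule = "product")
  expect_true(all(g2$joint >= 0 & g2$joint <= 1))
})

test_that("prey overlay shifts by the TEF and classifies membership", {
  tef <- tef_spec()
  expect_equal(tef$shift, c(2.4, 2.6))
  set.seed(46)
  pred <- array(rnorm(200 * 50 * 2, c(-13.6, 16.6), 0.4), c(200, 50, 2))
  # note: rnorm recycles mean over the flattened array; build explicitly
  pred[, , 1] <- rnorm(200 * 50, -13.6, 0.4)
  pred[, , 2] <- rnorm(200 * 50, 16.6, 0.4)
  s <- ellipse_set(pred, "harbour")
  prey <- data.frame(prey = c("at_center", "far"),
                     d13C = c(-16.0, -30), d15N = c(14.0, 0))
  out <- prey_overlay(prey, list(s), tef)
  expect_equal(out$d13C_shifted, c(-13.6, -27.6))
  expect_equal(out$d15N_shifted, c(16.6, 2.6))
  expect_gt(out$p_harbour[1], 0.99)
  expect_equal(out$p_harbour[2], 0)
  expect_equal(as.character(out$band_harbour), c("high", "low"))
  # zero TEF classifies the raw point
  out0 <- prey_overlay(data.frame(prey = "raw", d13C = -13.6, d15N = 16.6),
                       list(s), tef_spec(0, 1, 0, 1))
  expect_gt(out0$p_harbour, 0.99)
  # TEF jitter propagates uncertainty without leaving [0, 1]
  outj <- prey_overlay(prey, list(s), tef, jitter_n = 100, seed = 2)
  expect_true(all(outj$p_harbour >= 0 & outj$p_harbour <= 1))
})
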