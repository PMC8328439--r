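# Standard-ellipse isotopic niches: areas, overlap/nestedness proportions,
# probability-of-membership grids and TEF-shifted prey overlays.

#' Standard ellipse
#'
#' An ellipse in (delta13C, delta15N) space defined by a center, a 2x2 shape
#' covariance and a confidence level p: the boundary is the set of points at
#' squared Mahalanobis distance equal to the chi-square(2 df) quantile at p.
#'
#' @param center Numeric length-2 center (permil).
#' @param shape 2x2 symmetric positive-definite covariance (permil^2).
#' @param p Confidence level in (0, 1), default 0.95.
#' @return Object of class `niche_ellipse`.
#' @export
niche_ellipse <- function(center, shape, p = 0.95) {
  stopifnot(length(center) == 2, p > 0, p < 1)
  assert_spd(shape, "shape")
  structure(list(center = as.numeric(center), shape = shape, p = p),
            class = "niche_ellipse")
}

#' Fit a standard ellipse to points
#'
#' Center = sample mean, shape = sample covariance; collinear (or fewer than
#' 3) points are an error.
#'
#' @param points n x 2 matrix of (delta13C, delta15N) values, n >= 3.
#' @param p Confidence level.
#' @return A [niche_ellipse()].
#' @export
ellipse_from_points <- function(points, p = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  S <- stats::cov(points)
  if (!is_spd(S)) stop("points are collinear; ellipse is degenerate",
                       call. = FALSE)
  niche_ellipse(colMeans(points), S, p)
}

#' Area of a standard ellipse
#'
#' area = pi * q_p * sqrt(det(shape)), with q_p the chi-square(2 df) quantile
#' at the ellipse's confidence level.
#'
#' @param e A [niche_ellipse()].
#' @return Area in permil^2.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "niche_ellipse"))
  pi * stats::qchisq(e$p, df = 2) * sqrt(det(e$shape))
}

#' Polygonal boundary of an ellipse
#'
#' @param e A [niche_ellipse()].
#' @param vertices Number of boundary vertices (default 360).
#' @return vertices x 2 matrix tracing the boundary counter-clockwise.
#' @export
ellipse_boundary <- function(e, vertices = 360) {
  q <- sqrt(stats::qchisq(e$p, df = 2))
  th <- seq(0, 2 * pi, length.out = vertices + 1)[-(vertices + 1)]
  circ <- cbind(cos(th), sin(th))
  sweep(q * circ %*% chol(e$shape), 2, e$center, `+`)
}

# Shoelace area of a polygon (n x 2 matrix, implicitly closed)
polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of polygon `subject` by convex polygon `clip`
# (both n x 2, counter-clockwise). Vectorized over subject vertices.
clip_polygon <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    # inside = left of directed edge a -> b
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    cx <- out[, 1]; cy <- out[, 2]
    side <- ex * (cy - a[2]) - ey * (cx - a[1])
    inside <- side >= 0
    nxt <- c(seq_len(nrow(out))[-1], 1L)
    side2 <- side[nxt]
    inside2 <- inside[nxt]
    cross <- inside != inside2
    t <- side / (side - side2)
    ix <- cx + t * (out[nxt, 1] - cx)
    iy <- cy + t * (out[nxt, 2] - cy)
    # assemble in traversal order: kept vertex first, crossing point after it
    xs <- c(cx[inside], ix[cross])
    ys <- c(cy[inside], iy[cross])
    o <- order(c(which(inside), which(cross) + 0.5))
    out <- cbind(xs[o], ys[o])
  }
  if (is.null(out) || nrow(out) < 3) NULL else out
}

#' Overlap between two ellipses
#'
#' Intersection area by polygonal approximation (>= 360 boundary vertices
#' each) and convex polygon clipping, plus the derived proportions.
#'
#' @param ea,eb [niche_ellipse()] objects.
#' @param vertices Boundary vertices per ellipse (default 360).
#' @return List: `intersection` (permil^2), `area_a`, `area_b`,
#'   `prop_union` (intersection / union), `a_in_b` (intersection / area_a),
#'   `b_in_a` (intersection / area_b).
#' @export
ellipse_overlap <- function(ea, eb, vertices = 360) {
  pa <- ellipse_boundary(ea, vertices)
  pb <- ellipse_boundary(eb, vertices)
  inter <- polygon_area(clip_polygon(pa, pb))
  a <- ellipse_area(ea)
  b <- ellipse_area(eb)
  list(intersection = inter, area_a = a, area_b = b,
       prop_union = inter / (a + b - inter),
       a_in_b = inter / a, b_in_a = inter / b)
}

#' Per-draw ellipse set from posterior-predictive individuals
#'
#' Fits one standard ellipse per retained posterior draw to the m predicted
#' individual-level values of that draw.
#'
#' @param pred Array (draws x m x 2) from [posterior_predict_individuals()].
#' @param species Species label carried along.
#' @param p Confidence level (default 0.95).
#' @return Object of class `ellipse_set`: `centers` (n x 2), `shapes`
#'   (2 x 2 x n), `p`, `species`.
#' @export
ellipse_set <- function(pred, species = "", p = 0.95) {
  n <- dim(pred)[1]
  centers <- matrix(NA_real_, n, 2)
  shapes <- array(NA_real_, c(2, 2, n))
  for (j in seq_len(n)) {
    pts <- pred[j, , ]
    centers[j, ] <- colMeans(pts)
    shapes[, , j] <- stats::cov(pts)
  }
  structure(list(centers = centers, shapes = shapes, p = p, species = species),
            class = "ellipse_set")
}

set_ellipse <- function(set, j) {
  niche_ellipse(set$centers[j, ], set$shapes[, , j], set$p)
}

#' Summarize niche overlap across paired posterior draws
#'
#' For each draw j, computes the two ellipse areas and their overlap on the
#' paired ellipses (same j for both species), then reports posterior medians,
#' 95% credible intervals and exceedance probabilities.
#'
#' @param set_a,set_b [ellipse_set()] objects with the same number of draws
#'   (paired by draw index).
#' @param vertices Boundary vertices per ellipse (default 360).
#' @return List of class `overlap_summary` with `summary` (data.frame of
#'   median/lower/upper for areas and proportions), `p_area_b_gt_a`,
#'   `p_a_nested_gt_b`, and the per-draw `draws` data.frame.
#' @export
summarize_overlap <- function(set_a, set_b, vertices = 360) {
  n <- nrow(set_a$centers)
  if (nrow(set_b$centers) != n) {
    stop("ellipse sets are not paired (unequal draw counts)", call. = FALSE)
  }
  qa <- stats::qchisq(set_a$p, 2)
  res <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("area_a", "area_b", "intersection",
                                        "prop_union", "a_in_b", "b_in_a")))
  for (j in seq_len(n)) {
    ov <- ellipse_overlap(set_ellipse(set_a, j), set_ellipse(set_b, j),
                          vertices)
    res[j, ] <- c(ov$area_a, ov$area_b, ov$intersection, ov$prop_union,
                  ov$a_in_b, ov$b_in_a)
  }
  summ <- data.frame(
    quantity = colnames(res),
    median = apply(res, 2, stats::median),
    lower = apply(res, 2, function(x) ci95(x)[1]),
    upper = apply(res, 2, function(x) ci95(x)[2]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summ,
                 p_area_b_gt_a = mean(res[, "area_b"] > res[, "area_a"]),
                 p_a_nested_gt_b = mean(res[, "a_in_b"] > res[, "b_in_a"]),
                 draws = as.data.frame(res),
                 species = c(set_a$species, set_b$species)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  s <- x$summary
  fmt <- function(q, scale = 1, unit = "") {
    r <- s[s$quantity == q, ]
    sprintf("%.1f%s [%.1f-%.1f]", r$median * scale, unit, r$lower * scale,
            r$upper * scale)
  }
  cat(sprintf("Niche areas: %s = %s permil^2, %s = %s permil^2\n",
              x$species[1], fmt("area_a"), x$species[2], fmt("area_b")))
  cat(sprintf("Overlap: %s of the total niche area\n",
              fmt("prop_union", 100, "%")))
  cat(sprintf("Nestedness: %s-in-%s %s; %s-in-%s %s\n",
              x$species[1], x$species[2], fmt("a_in_b", 100, "%"),
              x$species[2], x$species[1], fmt("b_in_a", 100, "%")))
  cat(sprintf("P(area %s > area %s) = %.2f; P(%s more nested) = %.2f\n",
              x$species[2], x$species[1], x$p_area_b_gt_a,
              x$species[1], x$p_a_nested_gt_b))
  invisible(x)
}

# membership of points (n x 2) in one ellipse, vectorized
points_in_ellipse <- function(pts, center, shape, q) {
  d <- sweep(pts, 2, center)
  inv <- chol2inv(chol(shape))
  md <- rowSums((d %*% inv) * d)
  md <= q
}

#' Membership probability at arbitrary points
#'
#' Fraction of the set's ellipses containing each point.
#'
#' @param set An [ellipse_set()].
#' @param pts n x 2 matrix of (delta13C, delta15N) points.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
membership_probability <- function(set, pts) {
  pts <- matrix(pts, ncol = 2)
  q <- stats::qchisq(set$p, 2)
  n <- nrow(set$centers)
  acc <- numeric(nrow(pts))
  for (j in seq_len(n)) {
    acc <- acc + points_in_ellipse(pts, set$centers[j, ], set$shapes[, , j], q)
  }
  acc / n
}

#' Probability-of-membership and joint-overlap grids
#'
#' On a regular (delta13C, delta15N) grid, computes per species the fraction
#' of the posterior ellipses containing each cell center, and the joint
#' overlap probability: the fraction of paired draws j whose two ellipses
#' both contain the point (per-draw AND rule; the product of marginals is
#' available via `joint_rule = "product"`).
#'
#' @param sets List of two [ellipse_set()] objects (paired draws).
#' @param xlim,ylim Grid extent; defaults to the ellipse extents padded by 2
#'   permil.
#' @param n Cells per axis (default 200; < 50 warns).
#' @param joint_rule `"and"` (default) or `"product"`.
#' @return Object of class `probability_grid`: `x`, `y`, `membership` (list of
#'   matrices per species), `joint` matrix.
#' @export
membership_grid <- function(sets, xlim = NULL, ylim = NULL, n = 200,
                            joint_rule = c("and", "product")) {
  joint_rule <- match.arg(joint_rule)
  if (n < 50) warning("grid coarser than 50 x 50; probabilities will be lumpy")
  ext <- sapply(sets, function(s) {
    r <- sqrt(stats::qchisq(s$p, 2))
    sdmax <- sqrt(max(apply(s$shapes, 3, function(m) max(diag(m)))))
    c(min(s$centers[, 1]) - r * sdmax, max(s$centers[, 1]) + r * sdmax,
      min(s$centers[, 2]) - r * sdmax, max(s$centers[, 2]) + r * sdmax)
  })
  if (is.null(xlim)) xlim <- c(min(ext[1, ]) - 2, max(ext[2, ]) + 2)
  if (is.null(ylim)) ylim <- c(min(ext[3, ]) - 2, max(ext[4, ]) + 2)
  x <- seq(xlim[1], xlim[2], length.out = n)
  y <- seq(ylim[1], ylim[2], length.out = n)
  pts <- cbind(rep(x, times = n), rep(y, each = n))
  ndr <- nrow(sets[[1]]$centers)
  q <- stats::qchisq(sets[[1]]$p, 2)
  in_a <- in_b <- joint <- numeric(nrow(pts))
  for (j in seq_len(ndr)) {
    ia <- points_in_ellipse(pts, sets[[1]]$centers[j, ],
                            sets[[1]]$shapes[, , j], q)
    ib <- points_in_ellipse(pts, sets[[2]]$centers[j, ],
                            sets[[2]]$shapes[, , j], q)
    in_a <- in_a + ia
    in_b <- in_b + ib
    if (joint_rule == "and") joint <- joint + (ia & ib)
  }
  ma <- matrix(in_a / ndr, n, n)
  mb <- matrix(in_b / ndr, n, n)
  mj <- if (joint_rule == "and") matrix(joint / ndr, n, n) else ma * mb
  membership <- list(ma, mb)
  names(membership) <- vapply(sets, function(s) s$species, character(1))
  structure(list(x = x, y = y, membership = membership, joint = mj),
            class = "probability_grid")
}

#' Trophic enrichment factor specification
#'
#' Mean isotopic shift from prey tissue to consumer tissue, with standard
#' deviations. Defaults are the grey-seal whisker values used for both
#' species: +2.4 (SD 1.3) permil for delta13C and +2.6 (SD 1.2) permil for
#' delta15N.
#'
#' @param d13C_shift,d13C_sd,d15N_shift,d15N_sd TEF means and SDs (permil).
#' @return Object of class `tef_spec`.
#' @export
tef_spec <- function(d13C_shift = 2.4, d13C_sd = 1.3,
                     d15N_shift = 2.6, d15N_sd = 1.2) {
  stopifnot(is.finite(c(d13C_shift, d13C_sd, d15N_shift, d15N_sd)))
  structure(list(shift = c(d13C_shift, d15N_shift),
                 sd = c(d13C_sd, d15N_sd)),
            class = "tef_spec")
}

#' Compare prey isotopic values with the consumer niches
#'
#' Shifts each prey mean by the TEF and evaluates the shifted point against
#' both species' posterior ellipse sets, classifying membership into
#' probability bands (high >= 0.75, low < 0.25, else intermediate). TEF
#' uncertainty can optionally be propagated by Monte-Carlo jitter of the prey
#' points.
#'
#' @param prey Data.frame with columns `prey`, `d13C`, `d15N` (raw prey
#'   values, permil).
#' @param sets List of two [ellipse_set()] objects.
#' @param tef A [tef_spec()].
#' @param jitter_n If > 0, number of Monte-Carlo TEF draws per prey; the
#'   reported probability is then averaged over draws (default 0: mean shift
#'   only).
#' @param seed Seed for the jitter.
#' @return Data.frame: prey, shifted coordinates, one membership probability
#'   and band per species.
#' @export
prey_overlay <- function(prey, sets, tef = tef_spec(), jitter_n = 0,
                         seed = 1L) {
  stopifnot(all(c("prey", "d13C", "d15N") %in% names(prey)))
  shifted <- cbind(prey$d13C + tef$shift[1], prey$d15N + tef$shift[2])
  out <- data.frame(prey = prey$prey, d13C_shifted = shifted[, 1],
                    d15N_shifted = shifted[, 2], stringsAsFactors = FALSE)
  band <- function(p) cut(p, c(-Inf, 0.25, 0.75, Inf),
                          labels = c("low", "intermediate", "high"))
  for (s in sets) {
    if (jitter_n > 0) {
      set.seed(seed)
      p <- vapply(seq_len(nrow(shifted)), function(i) {
        jit <- cbind(stats::rnorm(jitter_n, shifted[i, 1], tef$sd[1]),
                     stats::rnorm(jitter_n, shifted[i, 2], tef$sd[2]))
        mean(membership_probability(s, jit))
      }, numeric(1))
    } else {
      p <- membership_probability(s, shifted)
    }
    out[[paste0("p_", s$species)]] <- p
    out[[paste0("band_", s$species)]] <- band(p)
  }
  out
}
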