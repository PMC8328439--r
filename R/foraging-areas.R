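# Likely foraging areas from dive records: faster-U-shaped-dive selection and
# kernel density contours.

#' Time-allocation-at-depth (TAD) index of dives
#'
#' Returns the tag-provided `percent_area` when present; otherwise a proxy,
#' the mean of the nine intermediate depths divided by the max depth (values
#' near 1 indicate flat-bottomed U dives; a monotone linear ramp gives 0.5).
#' Rows using the proxy are flagged in the `"proxy"` attribute.
#'
#' @param dives Dive table data.frame with `max_depth_m`, optionally
#'   `percent_area` and `depth1`..`depth9`.
#' @return Numeric TAD per dive in [0, 1], with attribute `proxy` (logical).
#' @export
compute_tad <- function(dives) {
  has_pa <- "percent_area" %in% names(dives) && !all(is.na(dives$percent_area))
  depth_cols <- paste0("depth", 1:9)
  has_prof <- all(depth_cols %in% names(dives))
  if (!has_pa && !has_prof) {
    stop("neither percent_area nor the nine intermediate depths are available",
         call. = FALSE)
  }
  tad <- if (has_pa) dives$percent_area else rep(NA_real_, nrow(dives))
  proxy <- is.na(tad)
  if (any(proxy)) {
    if (!has_prof) stop("percent_area missing and no intermediate depths",
                        call. = FALSE)
    prof <- as.matrix(dives[proxy, depth_cols])
    tad[proxy] <- rowMeans(prof) / dives$max_depth_m[proxy]
  }
  attr(tad, "proxy") <- proxy
  tad
}

#' Vertical descent speed of dives
#'
#' First intermediate depth divided by 10% of the dive duration (m/s).
#'
#' @param dives Dive table with `depth1` and `duration_s`.
#' @return Numeric speed per dive (m/s).
#' @export
descent_speed <- function(dives) {
  if (any(dives$duration_s <= 0)) stop("non-positive dive duration",
                                       call. = FALSE)
  dives$depth1 / (0.1 * dives$duration_s)
}

#' Select the faster U-shaped (likely foraging) dives
#'
#' Per individual: keep dives with TAD >= `tad_threshold` whose descent speed
#' exceeds the individual's `speed_quantile` quantile of U-shaped-dive descent
#' speeds (default: the median). Thresholds are configurable because the
#' defining vertical-approach method is external to this package.
#'
#' @param dives Dive table.
#' @param tad_threshold TAD cut for U-shaped dives (default 0.9).
#' @param speed_quantile Quantile of the per-individual U-dive descent speed
#'   that a selected dive must exceed (default 0.5).
#' @return The selected subset of `dives` (with `tad` and `descent_speed`
#'   columns appended); empty with a warning if nothing passes.
#' @export
select_faster_u <- function(dives, tad_threshold = 0.9, speed_quantile = 0.5) {
  dives$tad <- as.numeric(compute_tad(dives))
  dives$descent_speed <- descent_speed(dives)
  keep <- logical(nrow(dives))
  for (id in unique(dives$individual)) {
    rows <- which(dives$individual == id)
    is_u <- dives$tad[rows] >= tad_threshold
    if (!any(is_u)) next
    thr <- stats::quantile(dives$descent_speed[rows][is_u], speed_quantile,
                           names = FALSE)
    keep[rows] <- is_u & dives$descent_speed[rows] > thr
  }
  if (!any(keep)) warning("no dives pass the faster-U selection")
  dives[keep, , drop = FALSE]
}

# Lambert azimuthal equal-area projection (spherical), km
.earth_r <- 6371.0088
project_aeqd <- function(lon, lat, center) {
  l0 <- center[1] * pi / 180; p0 <- center[2] * pi / 180
  l <- lon * pi / 180; p <- lat * pi / 180
  k <- sqrt(2 / (1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)))
  cbind(x = .earth_r * k * cos(p) * sin(l - l0),
        y = .earth_r * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0)))
}

unproject_aeqd <- function(x, y, center) {
  l0 <- center[1] * pi / 180; p0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  out <- cbind(lon = rep(center[1], length(x)), lat = rep(center[2], length(x)))
  nz <- rho > 1e-9
  cc <- 2 * asin(pmin(1, rho[nz] / (2 * .earth_r)))
  p <- asin(cos(cc) * sin(p0) + y[nz] * sin(cc) * cos(p0) / rho[nz])
  l <- l0 + atan2(x[nz] * sin(cc),
                  rho[nz] * cos(p0) * cos(cc) - y[nz] * sin(p0) * sin(cc))
  out[nz, ] <- cbind(l * 180 / pi, p * 180 / pi)
  out
}

#' Kernel-density foraging contours
#'
#' Projects dive surface positions to a metric plane (azimuthal equal-area
#' centered on the data centroid, preserving the area semantics of density
#' contours), estimates a 2D Gaussian kernel density (normal-reference
#' bandwidth per axis by default) and extracts the density isopleths enclosing
#' the requested probability masses. Contours are nested by construction
#' (higher mass = lower density threshold).
#'
#' @param dives Selected dive table with `lon` and `lat` columns (e.g., from
#'   [select_faster_u()]); >= 10 dives recommended (fewer warns).
#' @param levels Probability masses (default 0.5, 0.75, 0.95).
#' @param bandwidth Optional scalar bandwidth override (km); default normal
#'   reference rule per axis.
#' @param n_grid Grid cells per axis (default 200).
#' @return Object of class `foraging_contours`: `individual`, `center`
#'   (lon/lat of projection center), `kde` (x, y in km, z density), `levels`,
#'   `thresholds`, `contours` (per level: list of polygons with `x`, `y`,
#'   `lon`, `lat`).
#' @export
kernel_contours <- function(dives, levels = c(0.5, 0.75, 0.95),
                            bandwidth = NULL, n_grid = 200) {
  stopifnot(all(c("lon", "lat") %in% names(dives)))
  n <- nrow(dives)
  if (n < 2) stop("need at least 2 dive locations", call. = FALSE)
  if (n < 10) warning("fewer than 10 selected dives; contours may be unstable")
  center <- c(mean(dives$lon), mean(dives$lat))
  xy <- project_aeqd(dives$lon, dives$lat, center)
  uniq <- xy[!duplicated(xy), , drop = FALSE]
  if (nrow(uniq) < 2 || max(stats::dist(uniq)) < 1e-6) {
    stop("all dive locations identical; kernel density undefined",
         call. = FALSE)
  }
  h <- if (is.null(bandwidth)) {
    c(MASS::bandwidth.nrd(xy[, 1]), MASS::bandwidth.nrd(xy[, 2]))
  } else rep(bandwidth, 2)
  h[h <= 0] <- max(h, 1e-3)
  pad <- 2 * max(h)
  lims <- c(range(xy[, 1]) + c(-pad, pad), range(xy[, 2]) + c(-pad, pad))
  kde <- MASS::kde2d(xy[, 1], xy[, 2], h = h, n = n_grid, lims = lims)
  cell <- diff(kde$x[1:2]) * diff(kde$y[1:2])
  z <- kde$z / (sum(kde$z) * cell)  # renormalize to integrate to 1
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(z[ord]) * cell
  levels <- sort(levels)
  thresholds <- vapply(levels, function(lv) {
    z[ord][which(cum >= lv)[1]]
  }, numeric(1))
  contours <- lapply(seq_along(levels), function(i) {
    cl <- grDevices::contourLines(kde$x, kde$y, z, levels = thresholds[i])
    lapply(cl, function(p) {
      ll <- unproject_aeqd(p$x, p$y, center)
      list(x = p$x, y = p$y, lon = ll[, 1], lat = ll[, 2])
    })
  })
  names(contours) <- paste0("p", levels * 100)
  structure(list(individual = unique(dives$individual), center = center,
                 kde = list(x = kde$x, y = kde$y, z = z),
                 levels = levels, thresholds = thresholds,
                 contours = contours),
            class = "foraging_contours")
}

#' Probability mass enclosed by a density threshold
#'
#' @param fc A [kernel_contours()] result.
#' @param threshold Density threshold.
#' @return Fraction of the kernel density mass in cells at or above the
#'   threshold.
#' @export
contour_mass <- function(fc, threshold) {
  cell <- diff(fc$kde$x[1:2]) * diff(fc$kde$y[1:2])
  sum(fc$kde$z[fc$kde$z >= threshold]) * cell
}

#' Per-individual foraging areas from a dive table
#'
#' Runs the faster-U selection and kernel contours for each individual.
#'
#' @inheritParams select_faster_u
#' @inheritParams kernel_contours
#' @return Named list of [kernel_contours()] results (individuals with no
#'   selected dives are skipped with a warning).
#' @export
foraging_areas <- function(dives, tad_threshold = 0.9, speed_quantile = 0.5,
                           levels = c(0.5, 0.75, 0.95), bandwidth = NULL,
                           n_grid = 200) {
  sel <- select_faster_u(dives, tad_threshold, speed_quantile)
  out <- list()
  for (id in unique(dives$individual)) {
    di <- sel[sel$individual == id, , drop = FALSE]
    if (nrow(di) < 2) {
      warning("individual ", id, ": fewer than 2 selected dives; skipped")
      next
    }
    out[[id]] <- kernel_contours(di, levels = levels, bandwidth = bandwidth,
                                 n_grid = n_grid)
  }
  out
}

#' Export foraging contours as GeoJSON
#'
#' @param fc A [kernel_contours()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(fc, path) {
  features <- list()
  for (lv in names(fc$contours)) {
    for (p in fc$contours[[lv]]) {
      coords <- cbind(p$lon, p$lat)
      coords <- rbind(coords, coords[1, ])
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(individual = fc$individual, level = lv),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(coords)),
                                                  function(i) coords[i, ]))))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
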