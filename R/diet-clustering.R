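# Agglomerative clustering of scats by composition, cluster-number selection,
# and bootstrap confidence intervals on cluster composition and scat
# distribution.

#' Ward.D2 clustering of a scaled composition matrix
#'
#' Agglomerative clustering by the Ward.D2 criterion (Lance-Williams update on
#' Euclidean distances; Murtagh & Legendre 2014 variant), as implemented in
#' `stats::hclust`. Deterministic given input order.
#'
#' @param scaled Numeric matrix (scats x groups), typically from
#'   [scale_matrix()].
#' @param k Number of clusters, `1 <= k <= nrow(scaled)`.
#' @return List with `labels` (integer vector in 1..k, in tree cut order) and
#'   `tree` (the `hclust` object).
#' @export
ward_cluster <- function(scaled, k) {
  n <- nrow(scaled)
  if (k < 1 || k > n) stop("k must be between 1 and the number of rows",
                           call. = FALSE)
  tree <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

# Within-cluster sum of squares of a labelled matrix
wss_of <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

# Calinski-Harabasz pseudo-F (higher better)
calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  w <- wss_of(x, labels)
  tot <- sum(sweep(x, 2, colMeans(x))^2)
  ((tot - w) / (k - 1)) / (w / (n - k))
}

# Davies-Bouldin index (lower better)
davies_bouldin <- function(x, labels) {
  labs <- sort(unique(labels))
  cent <- t(vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(labs), function(i) {
    xs <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cent[i, ])^2)))
  }, numeric(1))
  k <- length(labs)
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

#' Select the number of clusters by majority vote
#'
#' Votes over a reduced index panel: mean silhouette width (max),
#' Calinski-Harabasz (max), Davies-Bouldin (min) and a within-SS elbow
#' (maximum second difference of the within-cluster sum of squares). Ties are
#' broken toward smaller k. `fixed_k` overrides the vote (to reproduce a
#' published cluster count).
#'
#' @param scaled Scaled composition matrix.
#' @param k_range Candidate k values, within `[2, n - 1]`.
#' @param fixed_k Optional integer override.
#' @return List with `k`, `votes` (one vote per index) and `indices` (the raw
#'   index values per candidate k).
#' @export
select_k <- function(scaled, k_range = 2:8, fixed_k = NULL) {
  if (length(k_range) == 0) stop("empty k range", call. = FALSE)
  n <- nrow(scaled)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop("k range must lie within [2, n - 1]", call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  d <- stats::dist(scaled)
  sil <- ch <- db <- wss <- stats::setNames(numeric(length(k_range)),
                                            k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- stats::cutree(tree, k = k)
    sil[i] <- mean(cluster::silhouette(lab, d)[, 3])
    ch[i] <- calinski_harabasz(scaled, lab)
    db[i] <- davies_bouldin(scaled, lab)
    wss[i] <- wss_of(scaled, lab)
  }
  # elbow: maximum second difference of within-SS (interior candidates only)
  elbow_k <- if (length(k_range) >= 3) {
    d2 <- diff(wss, differences = 2)
    k_range[which.max(d2) + 1L]
  } else k_range[1]
  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             davies_bouldin = k_range[which.min(db)],
             wss_elbow = elbow_k)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_sel <- min(winners)
  if (!is.null(fixed_k)) k_sel <- as.integer(fixed_k)
  list(k = k_sel, votes = votes,
       indices = data.frame(k = k_range, silhouette = sil,
                            calinski_harabasz = ch, davies_bouldin = db,
                            wss = wss))
}

#' Per-cluster diet composition by species
#'
#' For every cluster x species cell: the percentage of total reconstructed
#' prey mass by functional group over the member scats (sums to 100). Empty
#' cells are reported as `NA`.
#'
#' @param labels Integer cluster labels aligned with the rows of `cm`.
#' @param cm A `composition_matrix` (the unscaled matrix is used).
#' @return Array (cluster x species x group) of percentages.
#' @export
cluster_composition <- function(labels, cm) {
  stopifnot(inherits(cm, "composition_matrix"),
            length(labels) == nrow(cm$masses))
  labs <- sort(unique(labels))
  sp <- unique(cm$meta$species)
  groups <- colnames(cm$masses)
  out <- array(NA_real_, c(length(labs), length(sp), length(groups)),
               dimnames = list(paste0("cluster", labs), sp, groups))
  for (i in seq_along(labs)) for (j in seq_along(sp)) {
    sel <- labels == labs[i] & cm$meta$species == sp[j]
    if (!any(sel)) next
    m <- colSums(cm$masses[sel, , drop = FALSE])
    out[i, j, ] <- 100 * m / sum(m)
  }
  out
}

#' Bootstrap confidence intervals for a scat-level statistic
#'
#' Resamples the rows in scope with replacement (`N` out of `N`), recomputes
#' the statistic on each resample, and returns the empirical 2.5% and 97.5%
#' percentiles per statistic component.
#'
#' @param rows Data.frame or matrix of the scats in scope (one row per scat).
#' @param statistic Function mapping a resampled `rows` to a numeric vector.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Matrix with rows `lower`/`upper` and one column per statistic
#'   component; attribute `"draws"` holds the B x p resample statistics.
#' @export
bootstrap_ci <- function(rows, statistic, B = 1000, seed = 1L) {
  n <- nrow(rows)
  stopifnot(n >= 1)
  set.seed(seed)
  proto <- statistic(rows)
  raw <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    statistic(rows[idx, , drop = FALSE])
  }, proto)
  draws <- if (length(proto) == 1L) matrix(raw, ncol = 1) else t(raw)
  colnames(draws) <- names(proto)
  ci <- apply(draws, 2, ci95)
  rownames(ci) <- c("lower", "upper")
  attr(ci, "draws") <- draws
  ci
}

#' Cluster composition with bootstrap confidence intervals
#'
#' All N scats of a cluster are resampled with replacement N times, B times;
#' by default the resampling pool is the whole cluster across species
#' (`within_species = TRUE` restricts the pool to the species' own scats).
#'
#' @inheritParams cluster_composition
#' @param B,seed Bootstrap settings.
#' @param within_species Resample within species x cluster instead of within
#'   cluster.
#' @return Data.frame: cluster, species, group, percent, lower, upper.
#' @export
cluster_composition_ci <- function(labels, cm, B = 1000, seed = 1L,
                                   within_species = FALSE) {
  est <- cluster_composition(labels, cm)
  labs <- sort(unique(labels))
  sp <- unique(cm$meta$species)
  groups <- colnames(cm$masses)
  out <- list()
  for (i in seq_along(labs)) {
    in_cl <- labels == labs[i]
    for (j in seq_along(sp)) {
      in_sp <- cm$meta$species == sp[j]
      if (!any(in_cl & in_sp)) next
      pool <- if (within_species) in_cl & in_sp else in_cl
      rows <- cbind(cm$masses[pool, , drop = FALSE],
                    is_sp = as.numeric(in_sp[pool]))
      stat <- function(r) {
        m <- colSums(r[r[, "is_sp"] == 1, groups, drop = FALSE])
        if (sum(m) == 0) rep(NA_real_, length(groups)) else 100 * m / sum(m)
      }
      ci <- bootstrap_ci(rows, stat, B = B,
                         seed = child_seed(seed, i * 100 + j))
      out[[length(out) + 1L]] <- data.frame(
        cluster = labs[i], species = sp[j], group = groups,
        percent = est[i, j, ], lower = ci["lower", ], upper = ci["upper", ],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Distribution of scats across clusters, with bootstrap CIs
#'
#' Percentage of each species' scats falling in each cluster, optionally
#' stratified by season and year-class. Strata with fewer than `min_n` scats
#' are suppressed (with a notice column).
#'
#' @param labels Integer cluster labels aligned with `cm` rows.
#' @param cm A `composition_matrix`.
#' @param by_season Stratify by season and year-class.
#' @param year_breaks Lower edges of year classes (3-year bins by default).
#' @param min_n Minimum scats per stratum (default 8).
#' @param B,seed Bootstrap settings.
#' @return Data.frame: species (stratum columns if requested), cluster,
#'   n, percent, lower, upper, suppressed.
#' @export
scat_distribution <- function(labels, cm, by_season = FALSE,
                              year_breaks = seq(2002, 2017, by = 3),
                              min_n = 8, B = 1000, seed = 1L) {
  stopifnot(inherits(cm, "composition_matrix"))
  meta <- cm$meta
  k_labs <- sort(unique(labels))
  strata <- if (by_season) {
    yr <- as.integer(format(as.Date(meta$date), "%Y"))
    yc <- year_breaks[findInterval(yr, year_breaks)]
    interaction(meta$species, meta$season, yc, drop = TRUE)
  } else factor(meta$species)
  out <- list()
  si <- 0L
  for (s in levels(strata)) {
    si <- si + 1L
    sel <- strata == s
    n <- sum(sel)
    suppressed <- n < min_n
    lab_s <- labels[sel]
    pct <- 100 * vapply(k_labs, function(l) mean(lab_s == l), numeric(1))
    if (!suppressed) {
      rows <- data.frame(lab = lab_s)
      stat <- function(r) 100 * vapply(k_labs, function(l) mean(r$lab == l),
                                       numeric(1))
      ci <- bootstrap_ci(rows, stat, B = B, seed = child_seed(seed, si))
      lo <- ci["lower", ]; hi <- ci["upper", ]
    } else {
      message("stratum ", s, " has ", n, " scats (< ", min_n, "): suppressed")
      pct <- rep(NA_real_, length(k_labs))
      lo <- hi <- rep(NA_real_, length(k_labs))
    }
    out[[si]] <- data.frame(stratum = s, cluster = k_labs, n = n,
                            percent = pct, lower = lo, upper = hi,
                            suppressed = suppressed,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export an hclust tree in Newick format
#'
#' @param tree An `hclust` object.
#' @return Single Newick string (with merge heights as branch lengths).
#' @export
tree_newick <- function(tree) {
  n <- length(tree$labels %||% seq_len(nrow(tree$merge) + 1))
  labs <- tree$labels %||% as.character(seq_len(n))
  node_str <- character(nrow(tree$merge))
  node_h <- numeric(nrow(tree$merge))
  leaf <- function(i, parent_h) sprintf("%s:%g", labs[i], parent_h)
  for (m in seq_len(nrow(tree$merge))) {
    h <- tree$height[m]
    parts <- vapply(tree$merge[m, ], function(ch) {
      if (ch < 0) leaf(-ch, h) else
        sprintf("%s:%g", node_str[ch], h - node_h[ch])
    }, character(1))
    node_str[m] <- sprintf("(%s,%s)", parts[1], parts[2])
    node_h[m] <- h
  }
  paste0(node_str[nrow(tree$merge)], ";")
}
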