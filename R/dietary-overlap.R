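# Pianka dietary overlap between the pooled diet compositions of the two
# species, with a resampling confidence interval.

#' Pianka dietary overlap index
#'
#' O = sum(P_iA * P_iB) / sqrt(sum(P_iA^2) * sum(P_iB^2)). The square-root
#' denominator is the standard Pianka (1973) form: it is the only version
#' bounded by 1 (Cauchy-Schwarz) and consistent with an index that "ranges
#' from 0 to 1". Inputs may be proportions or percentages; each vector is
#' normalized to sum to 1 first.
#'
#' @param p_a,p_b Non-negative resource-use vectors of equal length.
#' @return Overlap O in [0, 1].
#' @export
pianka_index <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b))
  if (any(p_a < 0) || any(p_b < 0)) stop("negative proportions", call. = FALSE)
  if (sum(p_a) <= 0 || sum(p_b) <= 0) {
    stop("zero composition vector", call. = FALSE)
  }
  a <- p_a / sum(p_a)
  b <- p_b / sum(p_b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Resampling confidence interval for the Pianka index
#'
#' Given bootstrap sets of diet compositions for each species (e.g., the
#' per-resample pooled compositions from [bootstrap_ci()]), draws `R` random
#' pairings (one composition from each set, with replacement) and computes the
#' Pianka index per pairing; the CI is the empirical 2.5/97.5 percentile.
#'
#' @param comps_a,comps_b Matrices (resamples x groups) of diet compositions.
#' @param R Number of random pairings (default 10000).
#' @param seed Integer seed.
#' @return List with `ci` (length-2), and `values` (the R indices).
#' @export
pianka_ci <- function(comps_a, comps_b, R = 10000, seed = 1L) {
  comps_a <- as.matrix(comps_a)
  comps_b <- as.matrix(comps_b)
  if (nrow(comps_a) == 0 || nrow(comps_b) == 0) {
    stop("empty composition set", call. = FALSE)
  }
  set.seed(seed)
  ia <- sample.int(nrow(comps_a), R, replace = TRUE)
  ib <- sample.int(nrow(comps_b), R, replace = TRUE)
  a <- comps_a[ia, , drop = FALSE]
  b <- comps_b[ib, , drop = FALSE]
  a <- a / rowSums(a)
  b <- b / rowSums(b)
  o <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  list(ci = ci95(o), values = o)
}

#' Substantial-segregation flag
#'
#' Dietary segregation is considered substantial when the Pianka index is
#' strictly below 0.4.
#'
#' @param o Pianka index in [0, 1].
#' @param threshold Segregation threshold (default 0.4).
#' @return Logical.
#' @export
segregation_flag <- function(o, threshold = 0.4) {
  stopifnot(o >= 0, o <= 1)
  o < threshold
}

#' Full dietary-overlap analysis between two species
#'
#' Computes the pooled per-species compositions from a composition matrix, the
#' Pianka index, its resampling CI (bootstrap over scats within species,
#' then random pairings) and the segregation flag.
#'
#' @param cm A `composition_matrix` containing exactly two species.
#' @param B Bootstrap resamples per species (default 1000).
#' @param R Random pairings (default 10000).
#' @param seed Integer seed.
#' @return List of class `overlap_result`: `O`, `ci`, `segregated`,
#'   `composition` (species x group percentages).
#' @export
dietary_overlap <- function(cm, B = 1000, R = 10000, seed = 1L) {
  comp <- species_diet_composition(cm)
  if (nrow(comp) != 2) stop("need exactly two species", call. = FALSE)
  o <- pianka_index(comp[1, ], comp[2, ])
  boot <- lapply(seq_len(2), function(j) {
    sp <- rownames(comp)[j]
    rows <- cm$masses[cm$meta$species == sp, , drop = FALSE]
    stat <- function(r) {
      m <- colSums(r)
      100 * m / sum(m)
    }
    attr(bootstrap_ci(rows, stat, B = B, seed = child_seed(seed, j)), "draws")
  })
  ci <- pianka_ci(boot[[1]], boot[[2]], R = R, seed = child_seed(seed, 99))
  structure(list(O = o, ci = ci$ci, segregated = segregation_flag(o),
                 composition = comp),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Pianka dietary overlap O = %.2f [%.2f-%.2f]%s\n",
              x$O, x$ci[1], x$ci[2],
              if (x$segregated) " (substantial segregation)" else ""))
  invisible(x)
}
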