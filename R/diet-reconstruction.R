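# Scat hard-part records -> prey counts, reconstructed ingested mass, and the
# scats x functional-group composition matrix.

#' Default functional-group scheme
#'
#' Maps each prey taxon observed in seal scats to its functional group.
#' Flatfish taxa carry the group `"benthic_flatfish"` and are split into small
#' (< threshold) and large (>= threshold) at `threshold_mm` per reconstructed
#' individual body length; all other taxa map directly.
#'
#' @param path Optional CSV with columns `taxon,group` to override the scheme
#'   shipped with the package.
#' @param threshold_mm Flatfish size threshold in mm (boundary inclusive for
#'   "large").
#' @return Object of class `group_scheme`: list with `map` (data.frame) and
#'   `threshold_mm`.
#' @export
group_scheme <- function(path = NULL, threshold_mm = 200) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.csv",
                        package = "trophicniche")
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "group") %in% names(map)))
  ok <- c("benthic_flatfish", functional_groups())
  bad <- setdiff(unique(map$group), ok)
  if (length(bad)) stop("unknown group(s) in scheme: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(map = map, threshold_mm = threshold_mm),
            class = "group_scheme")
}

#' Season from sampling date
#'
#' Spring/summer is April-September; autumn/winter is October-March.
#'
#' @param date Date vector (or coercible).
#' @return Character vector, `"spring_summer"` or `"autumn_winter"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 4 & m <= 9, "spring_summer", "autumn_winter")
}

#' Count prey individuals from diagnostic hard parts
#'
#' Fish: the larger of (a) half the number of paired structures, rounded up,
#' taken per paired structure type, and (b) the count of unpaired structures
#' per type. Cephalopods: the larger of the upper- and lower-beak counts.
#'
#' @param parts Data.frame of hard parts for a single scat x taxon, with
#'   columns `structure` and `structure_class` (one of `paired`, `unpaired`,
#'   `upper_beak`, `lower_beak`).
#' @return Integer count (0 with a warning for empty input).
#' @export
count_individuals <- function(parts) {
  if (nrow(parts) == 0L) {
    warning("no parts supplied; count is 0")
    return(0L)
  }
  cls <- parts$structure_class
  if (any(cls %in% c("upper_beak", "lower_beak"))) {
    return(max(sum(cls == "upper_beak"), sum(cls == "lower_beak")))
  }
  counts <- integer(0)
  for (s in unique(parts$structure[cls == "paired"])) {
    counts <- c(counts, as.integer(ceiling(sum(parts$structure == s) / 2)))
  }
  for (s in unique(parts$structure[cls == "unpaired"])) {
    counts <- c(counts, sum(parts$structure == s))
  }
  max(counts)
}

# Evaluate an allometry row: measurement (mm) -> length (mm) -> mass (g)
apply_allometry <- function(row, measurement) {
  len <- switch(row$length_form,
                linear = row$length_a + row$length_b * measurement,
                power = row$length_a * measurement^row$length_b,
                stop("unknown length model form: ", row$length_form))
  mass <- switch(row$mass_form,
                 linear = row$mass_a + row$mass_b * len,
                 power = row$mass_a * len^row$mass_b,
                 stop("unknown mass model form: ", row$mass_form))
  list(length_mm = len, mass_g = mass)
}

# Group measurable parts of one scat x taxon into measured individuals.
# Paired structures: measurements are paired two-by-two in sorted order and
# averaged (an odd leftover stands alone); beaks: each measurable lower (or
# upper) beak is one individual; unpaired: one individual per part.
measured_individuals <- function(parts) {
  meas <- parts[parts$measurable %in% TRUE & !is.na(parts$measurement), ]
  if (nrow(meas) == 0L) return(numeric(0))
  out <- numeric(0)
  for (cl in unique(meas$structure_class)) {
    m <- sort(meas$measurement[meas$structure_class == cl])
    if (cl == "paired") {
      idx <- seq_along(m)
      grp <- ceiling(idx / 2)
      out <- c(out, tapply(m, grp, mean))
    } else {
      out <- c(out, m)
    }
  }
  unname(out)
}

#' Reconstruct ingested prey mass per scat and taxon
#'
#' Each measurable hard part is converted to a body length and mass through
#' the allometry table. When the estimated number of individuals exceeds the
#' number measured, the surplus is imputed at the within-scat mean mass of
#' measured conspecifics; if none were measured in that scat, the dataset-wide
#' mean for the taxon is used (with a warning).
#'
#' @param parts A scat hard-part table (multiple scats allowed).
#' @param allometry Allometry table data.frame (see [read_allometry()]).
#' @return List with `individuals` (one row per reconstructed prey individual:
#'   scat_id, species, date, taxon, length_mm, mass_g, imputed) and `taxa`
#'   (per scat x taxon totals: count, mass_g).
#' @export
reconstruct_scat_mass <- function(parts, allometry) {
  missing_taxa <- setdiff(unique(parts$taxon[parts$measurable %in% TRUE]),
                          allometry$taxon)
  if (length(missing_taxa)) {
    stop("taxon missing from allometry table: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  key <- interaction(parts$scat_id, parts$taxon, drop = TRUE)
  pieces <- split(parts, key)

  # First pass: measured individuals per scat x taxon
  recs <- lapply(pieces, function(p) {
    row <- allometry[allometry$taxon == p$taxon[1], ][1, ]
    meas <- measured_individuals(p)
    conv <- if (length(meas)) apply_allometry(row, meas) else
      list(length_mm = numeric(0), mass_g = numeric(0))
    list(scat_id = p$scat_id[1], species = p$species[1], date = p$date[1],
         taxon = p$taxon[1], count = count_individuals(p),
         length_mm = conv$length_mm, mass_g = conv$mass_g)
  })

  # Dataset-wide per-taxon means, fallback for scats with no measured parts
  all_len <- unlist(unname(lapply(recs, function(r)
    stats::setNames(r$length_mm, rep(r$taxon, length(r$length_mm))))))
  taxon_mean_len <- tapply(unname(all_len), names(all_len), mean)
  all_mass <- unlist(unname(lapply(recs, function(r)
    stats::setNames(r$mass_g, rep(r$taxon, length(r$mass_g))))))
  taxon_mean_mass <- tapply(unname(all_mass), names(all_mass), mean)

  ind <- list()
  tot <- list()
  for (r in recs) {
    n_meas <- length(r$mass_g)
    lens <- r$length_mm
    masses <- r$mass_g
    imput <- rep(FALSE, n_meas)
    if (r$count > n_meas) {
      n_imp <- r$count - n_meas
      if (n_meas > 0) {
        lens <- c(lens, rep(mean(r$length_mm), n_imp))
        masses <- c(masses, rep(mean(r$mass_g), n_imp))
      } else if (!is.na(taxon_mean_mass[r$taxon])) {
        warning(sprintf(
          "scat %s: no measured %s; imputing %d individual(s) at the dataset-wide mean",
          r$scat_id, r$taxon, n_imp))
        lens <- c(lens, rep(taxon_mean_len[[r$taxon]], n_imp))
        masses <- c(masses, rep(taxon_mean_mass[[r$taxon]], n_imp))
      } else {
        warning(sprintf(
          "scat %s: taxon %s has no measured individuals anywhere; dropped",
          r$scat_id, r$taxon))
        next
      }
      imput <- c(imput, rep(TRUE, n_imp))
    }
    if (length(masses) == 0) next
    ind[[length(ind) + 1L]] <- data.frame(
      scat_id = r$scat_id, species = r$species, date = r$date, taxon = r$taxon,
      length_mm = lens, mass_g = masses, imputed = imput,
      stringsAsFactors = FALSE)
    tot[[length(tot) + 1L]] <- data.frame(
      scat_id = r$scat_id, species = r$species, date = r$date, taxon = r$taxon,
      count = r$count, mass_g = sum(masses), stringsAsFactors = FALSE)
  }
  list(individuals = do.call(rbind, ind), taxa = do.call(rbind, tot))
}

#' Assign prey individuals to functional groups
#'
#' Flatfish taxa are split by reconstructed body length at the scheme
#' threshold (boundary inclusive for "large"); all other taxa map directly.
#'
#' @param taxon Character vector of taxon labels.
#' @param length_mm Reconstructed body lengths (mm), same length as `taxon`.
#' @param scheme A [group_scheme()].
#' @return Character vector of functional groups.
#' @export
assign_functional_group <- function(taxon, length_mm, scheme) {
  idx <- match(taxon, scheme$map$taxon)
  if (anyNA(idx)) {
    stop("unknown taxon (not in functional-group scheme): ",
         paste(unique(taxon[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  g <- scheme$map$group[idx]
  flat <- g == "benthic_flatfish"
  g[flat] <- ifelse(length_mm[flat] >= scheme$threshold_mm,
                    "large_benthic_flatfish", "small_benthic_flatfish")
  g
}

#' Build the scats x functional-group composition matrix
#'
#' Rows are non-empty scats; columns the six functional groups; cells the
#' proportion of the scat's total reconstructed prey mass. Scats with zero
#' reconstructed mass are excluded with a warning.
#'
#' @param individuals Data.frame of reconstructed prey individuals as returned
#'   by [reconstruct_scat_mass()].
#' @param scheme A [group_scheme()].
#' @return Object of class `composition_matrix`: list with `props` (row-sum-1
#'   matrix), `masses` (grams), and `meta` (scat_id, species, date, season).
#' @export
build_composition_matrix <- function(individuals, scheme = group_scheme()) {
  if (is.null(individuals) || nrow(individuals) == 0L ||
      all(individuals$mass_g <= 0)) {
    stop("no reconstructed mass in input", call. = FALSE)
  }
  grp <- assign_functional_group(individuals$taxon, individuals$length_mm,
                                 scheme)
  groups <- functional_groups()
  scats <- unique(individuals$scat_id)
  masses <- matrix(0, length(scats), length(groups),
                   dimnames = list(scats, groups))
  agg <- tapply(individuals$mass_g,
                list(factor(individuals$scat_id, scats),
                     factor(grp, groups)), sum)
  agg[is.na(agg)] <- 0
  masses[, ] <- agg
  tot <- rowSums(masses)
  if (any(tot <= 0)) {
    warning(sum(tot <= 0), " scat(s) with zero reconstructed mass excluded")
    masses <- masses[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  props <- masses / tot
  first <- individuals[!duplicated(individuals$scat_id), ]
  first <- first[match(rownames(masses), first$scat_id), ]
  meta <- data.frame(scat_id = first$scat_id, species = first$species,
                     date = first$date, season = season_of(first$date),
                     stringsAsFactors = FALSE)
  structure(list(props = props, masses = masses, meta = meta),
            class = "composition_matrix")
}

#' Column-standardize a composition matrix
#'
#' Centers every column to mean 0 and divides by its sample standard deviation
#' (n - 1 denominator), as R's `scale()` does. Constant columns are left
#' centered (all zeros) with a warning.
#'
#' @param x A `composition_matrix` or a plain numeric matrix (>= 2 rows).
#' @return Numeric matrix of standardized values.
#' @export
scale_matrix <- function(x) {
  m <- if (inherits(x, "composition_matrix")) x$props else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 rows to scale", call. = FALSE)
  ctr <- sweep(m, 2, colMeans(m))
  sds <- apply(m, 2, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) {
    warning("constant column(s) left centered: ",
            paste(colnames(m)[const], collapse = ", "))
    sds[const] <- 1
  }
  sweep(ctr, 2, sds, `/`)
}

#' Reconstruct the full diet pipeline from a hard-part table
#'
#' Convenience wrapper: counts, allometric mass reconstruction, functional
#' group assignment and composition matrix in one call.
#'
#' @inheritParams reconstruct_scat_mass
#' @inheritParams build_composition_matrix
#' @return A `composition_matrix`.
#' @export
diet_composition <- function(parts, allometry, scheme = group_scheme()) {
  rec <- reconstruct_scat_mass(parts, allometry)
  build_composition_matrix(rec$individuals, scheme)
}

#' Pooled diet composition per species
#'
#' Percentage of total reconstructed prey mass per functional group for each
#' species, pooling all of the species' scats (mass-weighted, not a mean of
#' per-scat proportions).
#'
#' @param cm A `composition_matrix`.
#' @return Matrix (species x 6 groups) of percentages summing to 100 by row.
#' @export
species_diet_composition <- function(cm) {
  stopifnot(inherits(cm, "composition_matrix"))
  sp <- unique(cm$meta$species)
  out <- t(vapply(sp, function(s) {
    m <- colSums(cm$masses[cm$meta$species == s, , drop = FALSE])
    100 * m / sum(m)
  }, numeric(ncol(cm$masses))))
  rownames(out) <- sp
  out
}
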