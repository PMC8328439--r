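# CSV readers/writers for the documented schemas. All files UTF-8 with
# ISO-8601 dates.

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a scat hard-part table
#'
#' Columns: `scat_id, species, date, taxon, structure, structure_class,
#' measurable, measurement, measurement_kind` (measurements in mm).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_scat_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("scat_id", "species", "date", "taxon", "structure",
                   "structure_class", "measurable", "measurement",
                   "measurement_kind"), "scat table")
  df$measurable <- as.logical(df$measurable)
  bad <- df$measurable & (is.na(df$measurement) | df$measurement <= 0)
  if (any(bad)) stop("measurable part(s) without a positive measurement",
                     call. = FALSE)
  df
}

#' Read an allometry coefficient table
#'
#' Columns: `taxon, measurement_kind, length_form, length_a, length_b,
#' mass_form, mass_a, mass_b`; forms are `linear` (a + b x) or `power`
#' (a x^b), measurement/length in mm, mass in g.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_allometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("taxon", "measurement_kind", "length_form", "length_a",
                   "length_b", "mass_form", "mass_a", "mass_b"),
             "allometry table")
  df
}

#' Read a whisker isotope table
#'
#' Columns: `individual, species, segment_mm, d13C, d15N` (permil).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_whiskers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("individual", "species", "segment_mm", "d13C", "d15N"),
             "whisker table")
  df
}

#' Read a dive table
#'
#' Columns: `individual, start_time, max_depth_m, duration_s, percent_area,
#' depth1..depth9, lon, lat` (`percent_area` may be NA; depths m, duration s,
#' WGS84 degrees).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_dives <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("individual", "start_time", "max_depth_m", "duration_s",
                   paste0("depth", 1:9), "lon", "lat"), "dive table")
  if (any(df$max_depth_m <= 1.5)) {
    warning("dives at or above the 1.5 m tag recording threshold present")
  }
  df
}

#' Read a prey isotope table
#'
#' Columns: `prey, d13C, d15N` (raw prey values, permil). The default file is
#' a synthetic stand-in with plausible Eastern-English-Channel values (the
#' reference prey dataset is not redistributable); replace it with measured
#' values for real analyses.
#'
#' @param path CSV file; default the synthetic table shipped with the package.
#' @return data.frame.
#' @export
read_prey <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "prey_isotopes_synthetic.csv",
                        package = "trophicniche")
  }
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("prey", "d13C", "d15N"), "prey table")
}

#' Read the capture-record table
#'
#' Morphometrics, tracking and whisker summaries of the captured individuals
#' (one row per individual). The packaged default transcribes the published
#' capture table of the study colony.
#'
#' @param path CSV file; default the packaged table.
#' @return data.frame.
#' @export
read_capture_records <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "capture_records.csv",
                        package = "trophicniche")
  }
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("species", "individual", "body_mass_kg", "tracking_days",
               "whisker_length_mm", "n_segments"), "capture records")
}

#' Write synthetic datasets to CSV
#'
#' Writes the tables of a simulation object (`scat_sim`, `whisker_sim` or
#' `dive_sim`) into a directory using the reader schemas above.
#'
#' @param sim A simulation result.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (inherits(sim, "scat_sim")) {
    wr(sim$parts, "scats.csv")
    wr(sim$truth, "scat_truth.csv")
    wr(sim_allometry(), "allometry.csv")
  } else if (inherits(sim, "whisker_sim")) {
    wr(sim$series, "whiskers.csv")
    wr(sim$alpha, "whisker_truth.csv")
  } else if (inherits(sim, "dive_sim")) {
    wr(sim$dives, "dives.csv")
  } else stop("not a simulation object", call. = FALSE)
  invisible(files)
}
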