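# Measurement-table schema, CSV ingest and fixture output.
#
# The tidy input is one row per (microcosm, plant, tissue). Element
# contents arrive as percent (how labs report them) and are stored as
# mass fractions; isotope composition arrives as atom percent or as
# delta permil and is stored as atom fraction. CSV dialect is fixed:
# UTF-8, comma separator, "." decimal, mandatory header.

.REQUIRED_COLUMNS <- c("microcosm_id", "treatment", "species", "plant_role",
                       "tissue", "biomass_g", "c_content_pct",
                       "n_content_pct", "label_13C", "label_15N")
.ROLES <- c("orchid", "pine")
.TISSUES <- c("aboveground", "belowground")

#' Validate a measurement table
#'
#' Checks the tidy measurement schema row by row and returns the table
#' with internal columns (`c_content`, `n_content` as fractions;
#' `af_13C`, `af_15N` as atom fractions) guaranteed present. Error
#' messages cite 1-based data row numbers.
#'
#' @param measurements A data frame in the measurement schema (see
#'   [read_measurements()] for the column dictionary).
#' @return The validated table as a tibble.
#' @export
validate_measurements <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  missing_cols <- setdiff(.REQUIRED_COLUMNS, names(m))
  if (length(missing_cols) > 0L) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("af_13C", "af_15N") %in% names(m))) {
    m <- .ingest_isotope_columns(m)
  }
  if (!all(c("c_content", "n_content") %in% names(m))) {
    m$c_content <- m$c_content_pct / 100
    m$n_content <- m$n_content_pct / 100
  }

  fail <- function(rows, what) {
    stop("invalid measurement row(s) ", paste(utils::head(rows, 5L),
                                              collapse = ", "),
         ": ", what, call. = FALSE)
  }
  chk <- function(bad, what) if (any(bad)) fail(which(bad), what)
  chk(!m$treatment %in% c("labelled", "control"),
      "treatment must be 'labelled' or 'control'")
  chk(!m$plant_role %in% .ROLES,
      "plant_role must be 'orchid' or 'pine'")
  chk(!m$tissue %in% .TISSUES,
      "tissue must be 'aboveground' or 'belowground'")
  chk(!is.finite(m$biomass_g) | m$biomass_g <= 0,
      "biomass_g must be positive")
  chk(!is.finite(m$c_content) | m$c_content <= 0 | m$c_content >= 1,
      "carbon content must be in (0, 100) percent")
  chk(!is.finite(m$n_content) | m$n_content <= 0 | m$n_content >= 1,
      "nitrogen content must be in (0, 100) percent")
  chk(m$c_content + m$n_content >= 1,
      "carbon + nitrogen content cannot reach 100 percent")
  chk(!is.finite(m$af_13C) | m$af_13C < 0 | m$af_13C > 1,
      "13C atom fraction outside [0, 1]")
  chk(!is.finite(m$af_15N) | m$af_15N < 0 | m$af_15N > 1,
      "15N atom fraction outside [0, 1]")
  lab <- m$treatment == "labelled"
  chk(lab & !m$label_13C %in% .ROLES,
      "labelled rows must name the 13C-labelled plant role")
  chk(lab & !m$label_15N %in% .ROLES,
      "labelled rows must name the 15N-labelled plant role")

  dup <- duplicated(m[, c("microcosm_id", "plant_role", "tissue")])
  chk(dup, "duplicate (microcosm, plant, tissue) entry")
  m
}

.ingest_isotope_columns <- function(m) {
  has_atom <- all(c("atom_pct_13C", "atom_pct_15N") %in% names(m))
  has_delta <- all(c("delta13C_permil", "delta15N_permil") %in% names(m))
  if (has_atom) {
    m$af_13C <- m$atom_pct_13C / 100
    m$af_15N <- m$atom_pct_15N / 100
  } else if (has_delta) {
    m$af_13C <- delta_to_atom_fraction(m$delta13C_permil, "C13")
    m$af_15N <- delta_to_atom_fraction(m$delta15N_permil, "N15")
  } else {
    stop("no isotope composition columns found: provide either ",
         "atom_pct_13C + atom_pct_15N or delta13C_permil + delta15N_permil",
         call. = FALSE)
  }
  m
}

#' Read a tidy measurement CSV
#'
#' Expected columns (one row per microcosm x plant x tissue):
#' \describe{
#'   \item{microcosm_id}{microcosm identifier}
#'   \item{treatment}{`"labelled"` or `"control"`}
#'   \item{species}{species name}
#'   \item{plant_role}{`"orchid"` or `"pine"`}
#'   \item{tissue}{`"aboveground"` or `"belowground"`}
#'   \item{biomass_g}{tissue dry biomass, g}
#'   \item{c_content_pct, n_content_pct}{element contents, percent}
#'   \item{label_13C, label_15N}{which plant role received each label in
#'     this microcosm (`"orchid"`/`"pine"`; ignored for controls)}
#' }
#' plus isotope composition as either `atom_pct_13C` + `atom_pct_15N`
#' (atom percent) or `delta13C_permil` + `delta15N_permil` (permil
#' against VPDB / atmospheric N2) -- detected by column name and
#' converted to atom fraction at ingest.
#'
#' @param path Path to the CSV file.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_measurements(m)
}

#' Write a simulated experiment to a fixture directory
#'
#' Writes `measurements.csv` (the tidy measurement table),
#' `ground_truth.csv` and `config.yaml` (the generating configuration).
#' Re-reading the CSVs reproduces the tables bit-identically.
#'
#' @param sim A simulation result from [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(is.list(sim), all(c("measurements", "ground_truth", "config")
                              %in% names(sim)))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir, call. = FALSE)
  }
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.yaml")
  )
  readr::write_csv(sim$measurements, paths[["measurements"]], progress = FALSE)
  readr::write_csv(sim$ground_truth, paths[["ground_truth"]], progress = FALSE)
  yaml::write_yaml(unclass(sim$config), paths[["config"]])
  invisible(paths)
}
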