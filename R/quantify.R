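# End-to-end quantification: measurements -> pools -> directional
# transfer estimates -> net transfer -> pattern call, plus the run
# manifest and the text report.

#' Quantify interplant tracer transfer from a measurement table
#'
#' Runs the full tracer mass balance: control baselines, atom-fraction
#' excess, per-plant pools, per-direction detection against the
#' dispersion-based threshold, per-microcosm percent transferred,
#' replicate summaries (mean +/- SE), bootstrap net transfer, and the
#' pattern call for each element and orchid/pine pair.
#'
#' A receiving plant whose biomass-weighted excess does not clear the
#' detection threshold has its pool reported as 0 micrograms with flag
#' `below_detection` (the raw value is kept in `mass_ug_raw`); a
#' direction counts as detected at pair level when more than half of
#' its replicate microcosms detect. All randomness (the net-transfer
#' bootstrap) flows from the single `seed`.
#'
#' @param measurements Measurement table ([read_measurements()] /
#'   [simulate_experiment()]) or a path to a measurement CSV.
#' @param analytical_sd_permil IRMS precision in permil used for the
#'   detection threshold (default 0.15).
#' @param n_boot Bootstrap resamples for the net-transfer interval.
#' @param seed Integer seed for the bootstrap.
#' @param conf Net-transfer interval coverage.
#' @return A `transfer_analysis` list: `pools` (per plant x element),
#'   `transfers` (per direction x element summaries), `patterns` (per
#'   pair x element), `controls`, `manifest`.
#' @export
quantify_transfer <- function(measurements, analytical_sd_permil = 0.15,
                              n_boot = 10000, seed = 1L, conf = 0.95) {
  input_path <- NULL
  if (is.character(measurements) && length(measurements) == 1L) {
    input_path <- measurements
    measurements <- read_measurements(measurements)
  }
  measurements <- validate_measurements(measurements)
  if (!any(measurements$treatment == "labelled")) {
    stop("no labelled microcosms found", call. = FALSE)
  }

  pools <- build_pools(measurements)
  controls <- attr(pools, "controls")
  notes <- character()

  # detection for every received-via-network pool
  rec <- pools$pool_kind == "received_via_network"
  pools$detected <- NA
  pools$threshold <- NA_real_
  if (any(rec)) {
    det <- mapply(function(ape, csd, caf, element) {
      d <- detect_transfer(ape, control_sd = csd, control_af = caf,
                           analytical_sd_permil = analytical_sd_permil,
                           element = element)
      c(detected = d$detected, threshold = d$threshold)
    }, pools$ape_bw[rec], pools$control_sd_bw[rec], pools$control_af_bw[rec],
    pools$element[rec])
    pools$detected[rec] <- as.logical(det["detected", ])
    pools$threshold[rec] <- det["threshold", ]
  }
  pools$mass_ug_raw <- pools$mass_ug
  suppress <- rec & !pools$detected
  pools$mass_ug[suppress] <- 0
  pools$flag[suppress] <- "below_detection"

  n_negative <- sum(pools$flag == "below_zero")
  n_below <- sum(suppress)
  if (n_negative > 0) {
    notes <- c(notes, sprintf(
      "%d pool(s) carry negative excess (below_zero); retained, not clipped",
      n_negative))
  }
  if (n_below > 0) {
    notes <- c(notes, sprintf(
      "%d recipient pool(s) below detection threshold; reported as 0 ug",
      n_below))
  }

  # one row per microcosm x element: donor + recipient pool, direction
  donors <- pools[pools$pool_kind == "assimilated_by_label",
                  c("microcosm_id", "element", "plant_role", "species",
                    "mass_ug")]
  names(donors)[names(donors) == "plant_role"] <- "donor_role"
  names(donors)[names(donors) == "species"] <- "donor_species"
  names(donors)[names(donors) == "mass_ug"] <- "assimilated_ug"
  recips <- pools[pools$pool_kind == "received_via_network",
                  c("microcosm_id", "element", "plant_role", "species",
                    "mass_ug", "detected", "threshold")]
  names(recips)[names(recips) == "plant_role"] <- "recipient_role"
  names(recips)[names(recips) == "species"] <- "recipient_species"
  names(recips)[names(recips) == "mass_ug"] <- "transferred_ug"
  per_mc <- dplyr::inner_join(donors, recips,
                              by = c("microcosm_id", "element"))
  per_mc$pair <- ifelse(per_mc$donor_role == "orchid",
                        per_mc$donor_species, per_mc$recipient_species)
  per_mc$percent <- mapply(function(tr, as_) {
    if (pmax(tr, 0) + as_ <= 0) return(NA_real_)
    percent_transferred(tr, max(as_, 0))
  }, per_mc$transferred_ug, per_mc$assimilated_ug)

  se <- function(x) stats::sd(x) / sqrt(length(x))
  transfers <- dplyr::summarise(
    dplyr::group_by(per_mc, .data$pair, .data$element, .data$donor_role,
                    .data$donor_species, .data$recipient_role,
                    .data$recipient_species),
    n = dplyr::n(),
    amount_ug = mean(.data$transferred_ug),
    amount_se = se(.data$transferred_ug),
    percent_se = se(.data$percent),
    percent = mean(.data$percent),
    n_detected = sum(.data$detected),
    detected = sum(.data$detected) > dplyr::n() / 2,
    threshold_af = mean(.data$threshold),
    .groups = "drop"
  )

  # net transfer + pattern per pair x element
  withr::local_seed(as.integer(seed))
  pattern_rows <- list()
  for (pair in unique(transfers$pair)) {
    for (element in unique(transfers$element)) {
      sub <- per_mc[per_mc$pair == pair & per_mc$element == element, ]
      o2p <- sub$transferred_ug[sub$donor_role == "orchid"]
      p2o <- sub$transferred_ug[sub$donor_role == "pine"]
      dsub <- transfers[transfers$pair == pair &
                          transfers$element == element, ]
      det_o2p <- isTRUE(dsub$detected[dsub$donor_role == "orchid"])
      det_p2o <- isTRUE(dsub$detected[dsub$donor_role == "pine"])
      net <- if (length(o2p) >= 1L && length(p2o) >= 1L) {
        net_transfer(o2p, p2o, n_boot = n_boot,
                     seed = sample.int(.Machine$integer.max, 1L),
                     conf = conf)
      } else {
        NULL
      }
      cls <- classify_pattern(det_o2p, det_p2o, net)
      if (!is.null(net) && net$flag == "ci_unavailable") {
        notes <- c(notes, sprintf(
          "net-transfer CI unavailable for %s/%s (n < 2 in a direction)",
          pair, element))
      }
      pattern_rows[[length(pattern_rows) + 1L]] <- tibble::tibble(
        pair = pair,
        element = element,
        pattern = cls$pattern,
        net_direction = cls$net_direction,
        net_ug = cls$net_ug,
        ci_lower = cls$ci[1L],
        ci_upper = cls$ci[2L]
      )
    }
  }
  patterns <- dplyr::bind_rows(pattern_rows)

  manifest <- list(
    package = "mycotrace",
    version = as.character(utils::packageVersion("mycotrace")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (is.null(input_path)) {
      list(kind = "in-memory table", rows = nrow(measurements))
    } else {
      list(kind = "csv", path = input_path,
           md5 = unname(tools::md5sum(input_path)),
           rows = nrow(measurements))
    },
    parameters = list(analytical_sd_permil = analytical_sd_permil,
                      n_boot = n_boot, seed = as.integer(seed),
                      conf = conf),
    thresholds_af = stats::setNames(
      as.list(transfers$threshold_af),
      sprintf("%s_%s_to_%s", transfers$element, transfers$donor_role,
              transfers$recipient_role)),
    warnings = notes
  )

  structure(
    list(pools = pools, per_microcosm = per_mc, transfers = transfers,
         patterns = patterns, controls = controls, manifest = manifest),
    class = "transfer_analysis"
  )
}

#' @export
print.transfer_analysis <- function(x, ...) {
  cat(transfer_report(x), sep = "\n")
  invisible(x)
}

.fmt <- function(x, digits = 3) formatC(signif(x, digits), format = "fg",
                                        big.mark = "")

#' Render a transfer analysis as a plain-text report
#'
#' A deterministic, figure-free summary: per pair and element, the two
#' directional amounts and percent-transferred values (mean +/- SE over
#' replicate microcosms), ASCII arrows for detected directions, the
#' net-transfer interval and the pattern call. Byte-identical across
#' runs on the same input.
#'
#' @param x A `transfer_analysis` from [quantify_transfer()], or a list
#'   with elements `transfers` and `patterns` (e.g. re-read from the
#'   CSVs written by the command-line interface).
#' @return A character vector of report lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
transfer_report <- function(x) {
  transfers <- x$transfers
  patterns <- x$patterns
  if (is.null(transfers) || nrow(transfers) == 0L) {
    stop("empty transfer table: nothing to report", call. = FALSE)
  }
  el_name <- c(C13 = "Carbon (13C)", N15 = "Nitrogen (15N)")
  lines <- c("# Interplant tracer transfer report", "")
  for (pair in unique(transfers$pair)) {
    tp <- transfers[transfers$pair == pair, ]
    lines <- c(lines, sprintf("## Pair: %s <-> %s",
                              tp$donor_species[tp$donor_role == "orchid"][1],
                              tp$donor_species[tp$donor_role == "pine"][1]),
               "")
    for (element in unique(tp$element)) {
      te <- tp[tp$element == element, ]
      pe <- patterns[patterns$pair == pair & patterns$element == element, ]
      lines <- c(lines, sprintf("### %s", el_name[[element]]))
      for (k in seq_len(nrow(te))) {
        row <- te[k, ]
        arrow <- if (row$detected) "-->" else "-x->"
        lines <- c(lines, sprintf(
          "  %-6s %s %-6s  %s ug +/- %s (%s%% +/- %s of donor uptake, n = %d)%s",
          row$donor_role, arrow, row$recipient_role,
          .fmt(row$amount_ug), .fmt(row$amount_se, 2),
          .fmt(row$percent), .fmt(row$percent_se, 2), row$n,
          if (row$detected) "" else "  [below detection]"))
      }
      if (nrow(pe) == 1L) {
        lines <- c(lines, switch(
          pe$pattern,
          none = "  pattern: none -- no detectable transfer in either direction",
          unidirectional = sprintf(
            "  pattern: unidirectional, %s",
            gsub("_", " ", pe$net_direction)),
          bidirectional_no_net = sprintf(
            "  pattern: bidirectional, no net transfer (net %s ug, %s%% CI [%s, %s] spans 0)",
            .fmt(pe$net_ug), "95", .fmt(pe$ci_lower), .fmt(pe$ci_upper)),
          bidirectional_net = sprintf(
            "  pattern: bidirectional with NET transfer ==> %s (net %s ug, CI [%s, %s])",
            gsub("_", " ", pe$net_direction), .fmt(abs(pe$net_ug)),
            .fmt(pe$ci_lower), .fmt(pe$ci_upper))
        ))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(x$manifest) && length(x$manifest$warnings) > 0L) {
    lines <- c(lines, "## Warnings",
               paste0("  - ", x$manifest$warnings), "")
  }
  lines
}

#' Write the outputs of a transfer analysis to a directory
#'
#' Writes `pools.csv`, `transfers.csv`, `patterns.csv`, the text report
#' (`report.md`) and the run manifest (`manifest.json`).
#'
#' @param x A `transfer_analysis`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "transfer_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pools = file.path(dir, "pools.csv"),
             transfers = file.path(dir, "transfers.csv"),
             patterns = file.path(dir, "patterns.csv"),
             report = file.path(dir, "report.md"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(x$pools, paths[["pools"]], progress = FALSE)
  readr::write_csv(x$transfers, paths[["transfers"]], progress = FALSE)
  readr::write_csv(x$patterns, paths[["patterns"]], progress = FALSE)
  writeLines(transfer_report(x), paths[["report"]])
  jsonlite::write_json(x$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
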