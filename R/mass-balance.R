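# Elemental mass balance: enrichment -> tracer micrograms per tissue,
# tissue masses -> per-plant pools.

#' Tracer mass in one tissue
#'
#' Converts atom-fraction excess into micrograms of tracer held in a
#' tissue: excess times the element content (mass fraction) times the dry
#' biomass in grams, scaled by 1e6 to express grams of tracer element as
#' micrograms. Linear in each argument. The factor of 1e6 is applied here
#' and nowhere else.
#'
#' @param ape Atom-fraction excess (dimensionless; may be negative when
#'   a noisy labelled measurement falls below the control baseline).
#' @param element_content Element mass fraction of the tissue in (0, 1)
#'   (i.e. C% or N% divided by 100).
#' @param biomass_g Tissue dry biomass in grams, > 0.
#' @return Tracer mass in micrograms.
#' @examples
#' tissue_tracer_mass(0.01, 0.02, 1)  # 200 ug
#' @export
tissue_tracer_mass <- function(ape, element_content, biomass_g) {
  if (any(!is.finite(biomass_g)) || any(biomass_g <= 0)) {
    stop("biomass_g must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(element_content)) ||
      any(element_content <= 0 | element_content >= 1)) {
    stop("element_content must be a mass fraction strictly inside (0, 1); ",
         "divide percent values by 100 first", call. = FALSE)
  }
  ape * element_content * biomass_g * 1e6
}

#' Aggregate per-tissue tracer masses into a whole-plant pool
#'
#' Whole-plant tracer is the sum of per-tissue masses -- mass-weighted
#' aggregation is the only conservation-respecting choice; averaging
#' atom percents across tissues is not. The per-tissue breakdown is
#' retained, and a `below_zero` flag on any tissue propagates to the
#' pool.
#'
#' @param tissue_masses_ug Named numeric vector of per-tissue tracer
#'   masses (micrograms); names are tissue identifiers and must be
#'   unique.
#' @param flags Optional character vector of per-tissue flags
#'   (`"ok"`/`"below_zero"`), recycled against `tissue_masses_ug`.
#' @return A list with `mass_ug` (total), `breakdown` (the input vector)
#'   and `flag`.
#' @examples
#' plant_pool(c(aboveground = 150, belowground = 50))
#' @export
plant_pool <- function(tissue_masses_ug, flags = "ok") {
  nm <- names(tissue_masses_ug)
  if (length(tissue_masses_ug) > 1L &&
      (is.null(nm) || anyDuplicated(nm) > 0L)) {
    stop("duplicate or missing tissue identifiers in a single plant pool",
         call. = FALSE)
  }
  flags <- rep_len(flags, length(tissue_masses_ug))
  list(
    mass_ug = sum(tissue_masses_ug),
    breakdown = tissue_masses_ug,
    flag = if (any(flags == "below_zero")) "below_zero" else "ok"
  )
}

# Per-(species, tissue, element) control baselines pooled across control
# microcosms: mean atom fraction (defines atom%_control), its sd and n.
control_baselines <- function(measurements) {
  ctrl <- measurements[measurements$treatment == "control", , drop = FALSE]
  long <- tidyr::pivot_longer(
    ctrl[, c("species", "tissue", "af_13C", "af_15N")],
    cols = c("af_13C", "af_15N"),
    names_to = "element", values_to = "af"
  )
  long$element <- ifelse(long$element == "af_13C", "C13", "N15")
  dplyr::summarise(
    dplyr::group_by(long, .data$species, .data$tissue, .data$element),
    control_af = mean(.data$af),
    control_sd = stats::sd(.data$af),
    n_control = dplyr::n(),
    .groups = "drop"
  )
}

#' Build per-plant tracer pools from a measurement table
#'
#' The core bookkeeping step of the tracer mass balance. For every
#' labelled microcosm and element it produces two pools: the pool of the
#' plant that received the label directly (`assimilated_by_label`: 13C
#' fixed from 13CO2 or 15N taken up through the soaked leaves) and the
#' pool of the other plant in the same microcosm
#' (`received_via_network`: tracer that moved through the shared fungal
#' mycelium). Control microcosms emit no pools; they only parameterize
#' the natural-abundance baseline, pooled per (species, tissue, element)
#' across all control microcosms.
#'
#' Per-tissue excess is converted to micrograms with
#' [tissue_tracer_mass()] and summed over tissues; the aboveground /
#' belowground breakdown is kept so transfer to the shoots of the
#' receiving plant remains visible.
#'
#' @param measurements A validated measurement table as returned by
#'   [read_measurements()] or [simulate_experiment()].
#' @return A tibble with one row per (labelled microcosm, plant,
#'   element): `microcosm_id`, `element`, `species`, `plant_role`,
#'   `pool_kind`, `mass_ug`, per-tissue masses
#'   (`mass_aboveground_ug`, `mass_belowground_ug`), the biomass-weighted
#'   mean excess `ape_bw` with its matching control dispersion
#'   `control_sd_bw` and operating composition `control_af_bw` (inputs to
#'   [detect_transfer()]), and `flag`. The control summary table is
#'   attached as attribute `"controls"`.
#' @export
build_pools <- function(measurements) {
  measurements <- validate_measurements(measurements)
  ctrl <- control_baselines(measurements)
  lab <- measurements[measurements$treatment == "labelled", , drop = FALSE]
  if (nrow(lab) == 0L) {
    out <- empty_pools_table()
    attr(out, "controls") <- ctrl
    return(out)
  }

  long <- tidyr::pivot_longer(
    lab,
    cols = c("af_13C", "af_15N"),
    names_to = "element", values_to = "af"
  )
  long$element <- ifelse(long$element == "af_13C", "C13", "N15")
  long$content <- ifelse(long$element == "C13", long$c_content, long$n_content)
  long$label_role <- ifelse(long$element == "C13", long$label_13C, long$label_15N)

  long <- dplyr::left_join(long, ctrl,
                           by = c("species", "tissue", "element"))
  if (anyNA(long$control_af)) {
    miss <- unique(long[is.na(long$control_af),
                        c("species", "tissue", "element")])
    stop("no control microcosm data for: ",
         paste(sprintf("%s/%s/%s", miss$species, miss$tissue, miss$element),
               collapse = ", "),
         " -- add unlabelled control rows for these species/tissues",
         call. = FALSE)
  }

  long$ape <- long$af - long$control_af
  long$tissue_mass_ug <-
    tissue_tracer_mass(long$ape, long$content, long$biomass_g)
  long$pool_kind <- ifelse(long$plant_role == long$label_role,
                           "assimilated_by_label", "received_via_network")

  w_mean <- function(x, w) sum(x * w) / sum(w)
  pools <- dplyr::summarise(
    dplyr::group_by(long, .data$microcosm_id, .data$element,
                    .data$species, .data$plant_role, .data$pool_kind),
    mass_ug = sum(.data$tissue_mass_ug),
    mass_aboveground_ug = sum(.data$tissue_mass_ug[.data$tissue == "aboveground"]),
    mass_belowground_ug = sum(.data$tissue_mass_ug[.data$tissue == "belowground"]),
    ape_bw = w_mean(.data$ape, .data$biomass_g),
    control_sd_bw = sqrt(sum((.data$biomass_g * .data$control_sd)^2)) /
      sum(.data$biomass_g),
    control_af_bw = w_mean(.data$control_af, .data$biomass_g),
    flag = if (any(.data$ape < 0)) "below_zero" else "ok",
    .groups = "drop"
  )
  attr(pools, "controls") <- ctrl
  pools
}

empty_pools_table <- function() {
  tibble::tibble(
    microcosm_id = character(), element = character(), species = character(),
    plant_role = character(), pool_kind = character(), mass_ug = numeric(),
    mass_aboveground_ug = numeric(), mass_belowground_ug = numeric(),
    ape_bw = numeric(), control_sd_bw = numeric(), control_af_bw = numeric(),
    flag = character()
  )
}
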