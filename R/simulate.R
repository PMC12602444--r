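# Synthetic dual-labelling microcosm experiments with known ground
# truth.
#
# The generative model mirrors the reciprocal labelling design: in
# orientation A the orchid shoot is labelled with 13CO2 while the pine
# receives foliar 15N; orientation B swaps the labels. Each labelled
# microcosm draws a donor tracer uptake T (lognormal), passes a fixed
# fraction phi of it to the partner plant through the shared fungal
# network, spreads retained and received tracer over aboveground and
# belowground tissues, converts tracer mass to atom fraction through
# each tissue's element pool (biomass x content), adds the
# natural-abundance baseline, and finally adds Gaussian measurement
# noise in permil -- instrument space, where IRMS precision is quoted.
# Control microcosms are baseline + noise only.

.PHI_NAMES <- c("C_orchid_to_pine", "C_pine_to_orchid",
                "N_orchid_to_pine", "N_pine_to_orchid")

#' Configure a synthetic dual-labelling microcosm experiment
#'
#' Defaults describe a 12-month orchid/pine microcosm series: four
#' labelled microcosms per labelling orientation plus four unlabelled
#' controls, IRMS precision 0.15 permil, natural abundance at
#' delta13C = -27 permil (C3 tissue) and delta15N = 0 permil. The
#' default transfer fractions reproduce a bidirectional exchange with
#' net carbon flow toward the orchid; see [transfer_scenarios()] for
#' the named scenario set.
#'
#' @param orchid_species,pine_species Species names carried into the
#'   output tables.
#' @param n_labelled Labelled microcosms per orientation (two
#'   orientations are always generated).
#' @param n_control Unlabelled control microcosms.
#' @param biomass_g Named list (`orchid`, `pine`) of named vectors
#'   (`aboveground`, `belowground`): mean tissue dry biomass, g.
#' @param biomass_cv Coefficient of variation of tissue biomass
#'   (lognormal).
#' @param c_content,n_content Element mass fractions per role and
#'   tissue, same shape as `biomass_g`.
#' @param uptake_ug Named list (`C13`, `N15`) of named vectors
#'   (`orchid`, `pine`): mean tracer micrograms assimilated by each
#'   role when it carries that label.
#' @param uptake_cv Coefficient of variation of tracer uptake
#'   (lognormal; uptake is multiplicative and positive).
#' @param phi Named transfer fractions in `[0, 1)`:
#'   `C_orchid_to_pine`, `C_pine_to_orchid`, `N_orchid_to_pine`,
#'   `N_pine_to_orchid`.
#' @param donor_alloc_above Fraction of the donor's retained tracer in
#'   its aboveground tissue.
#' @param recipient_alloc_above Fraction of received tracer allocated
#'   aboveground (default 0.4: root-biased retention, but some tracer
#'   reaches the shoot).
#' @param baseline_delta Natural-abundance baselines, permil
#'   (`C13`, `N15`).
#' @param analytical_sd_permil Measurement noise sd in permil (0
#'   disables noise).
#' @param seed Default seed used by [simulate_experiment()] when none
#'   is passed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(orchid_species = "Cymbidium goeringii",
                              pine_species = "Pinus yunnanensis",
                              n_labelled = 4,
                              n_control = 4,
                              biomass_g = list(
                                orchid = c(aboveground = 0.7, belowground = 0.5),
                                pine = c(aboveground = 1.5, belowground = 1.0)
                              ),
                              biomass_cv = 0.2,
                              c_content = list(
                                orchid = c(aboveground = 0.45, belowground = 0.42),
                                pine = c(aboveground = 0.48, belowground = 0.50)
                              ),
                              n_content = list(
                                orchid = c(aboveground = 0.022, belowground = 0.018),
                                pine = c(aboveground = 0.012, belowground = 0.010)
                              ),
                              uptake_ug = list(
                                C13 = c(orchid = 1000, pine = 12000),
                                N15 = c(orchid = 400, pine = 300)
                              ),
                              uptake_cv = 0.3,
                              phi = c(C_orchid_to_pine = 0.016,
                                      C_pine_to_orchid = 0.030,
                                      N_orchid_to_pine = 0.0053,
                                      N_pine_to_orchid = 0.0068),
                              donor_alloc_above = 0.7,
                              recipient_alloc_above = 0.4,
                              baseline_delta = c(C13 = -27, N15 = 0),
                              analytical_sd_permil = 0.15,
                              seed = 1L) {
  cfg <- list(
    orchid_species = orchid_species, pine_species = pine_species,
    n_labelled = as.integer(n_labelled), n_control = as.integer(n_control),
    biomass_g = biomass_g, biomass_cv = biomass_cv,
    c_content = c_content, n_content = n_content,
    uptake_ug = uptake_ug, uptake_cv = uptake_cv,
    phi = phi[.PHI_NAMES],
    donor_alloc_above = donor_alloc_above,
    recipient_alloc_above = recipient_alloc_above,
    baseline_delta = baseline_delta[c("C13", "N15")],
    analytical_sd_permil = analytical_sd_permil,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_config <- function(cfg) {
  if (anyNA(cfg$phi) || length(cfg$phi) != 4L) {
    stop("phi must name all four transfer fractions: ",
         paste(.PHI_NAMES, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$phi < 0 | cfg$phi >= 1)) {
    stop("transfer fractions phi must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$biomass_cv < 0 || cfg$uptake_cv < 0) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  if (cfg$n_labelled < 1L || cfg$n_control < 1L) {
    stop("n_labelled and n_control must be >= 1", call. = FALSE)
  }
  if (cfg$analytical_sd_permil < 0) {
    stop("analytical_sd_permil must be >= 0", call. = FALSE)
  }
  for (a in c(cfg$donor_alloc_above, cfg$recipient_alloc_above)) {
    if (a < 0 || a > 1) stop("allocation fractions must lie in [0, 1]",
                             call. = FALSE)
  }
  invisible(cfg)
}

# lognormal draw parameterized by arithmetic mean and CV; degenerate at
# the mean when cv = 0
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.baseline_af <- function(cfg) {
  c(C13 = delta_to_atom_fraction(cfg$baseline_delta[["C13"]], "C13"),
    N15 = delta_to_atom_fraction(cfg$baseline_delta[["N15"]], "N15"))
}

# measurement noise applied in instrument (permil) space
.add_noise <- function(af, sd_permil, element) {
  if (sd_permil == 0) return(af)
  d <- atom_fraction_to_delta(af, element)
  delta_to_atom_fraction(d + stats::rnorm(length(af), 0, sd_permil), element)
}

#' Simulate one dual-labelling microcosm experiment
#'
#' Generates the tidy measurement table for `2 * n_labelled` labelled
#' microcosms (both labelling orientations) plus `n_control` controls,
#' together with the per-microcosm ground truth. Deterministic under a
#' fixed seed. Tracer is conserved exactly before measurement noise:
#' donor-retained plus recipient-received tracer equals the drawn
#' uptake, per microcosm and element.
#'
#' @param config A [simulation_config()].
#' @param seed Seed override; defaults to `config$seed`.
#' @return A `sim_experiment` list: `measurements` (measurement-schema
#'   tibble), `ground_truth` (one row per labelled microcosm x element:
#'   drawn uptake, transferred micrograms, true percent transferred =
#'   100 phi), and `config`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  validate_config(config)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  baseline <- .baseline_af(config)
  roles <- c("orchid", "pine")
  species_of <- c(orchid = config$orchid_species, pine = config$pine_species)

  microcosms <- rbind(
    data.frame(microcosm_id = sprintf("A%d", seq_len(config$n_labelled)),
               treatment = "labelled", label_13C = "orchid",
               label_15N = "pine"),
    data.frame(microcosm_id = sprintf("B%d", seq_len(config$n_labelled)),
               treatment = "labelled", label_13C = "pine",
               label_15N = "orchid"),
    data.frame(microcosm_id = sprintf("CTRL%d", seq_len(config$n_control)),
               treatment = "control", label_13C = "none",
               label_15N = "none")
  )

  tissues <- c("aboveground", "belowground")
  n_mc <- nrow(microcosms)
  # one row per microcosm x role x tissue, microcosm-major
  grid <- data.frame(
    idx_mc = rep(seq_len(n_mc), each = 4L),
    plant_role = rep(rep(roles, each = 2L), times = n_mc),
    tissue = rep(tissues, times = 2L * n_mc)
  )
  lookup <- function(param) {
    mapply(function(role, tis) param[[role]][[tis]],
           grid$plant_role, grid$tissue, USE.NAMES = FALSE)
  }
  biomass <- .rlnorm_mean_cv(nrow(grid), 1, config$biomass_cv) *
    lookup(config$biomass_g)
  c_content <- lookup(config$c_content)
  n_content <- lookup(config$n_content)

  lab <- microcosms$treatment == "labelled"
  excess <- list(C13 = numeric(nrow(grid)), N15 = numeric(nrow(grid)))
  truth <- list()
  for (element in c("C13", "N15")) {
    donor_of_mc <- if (element == "C13") microcosms$label_13C else
      microcosms$label_15N
    uptake_mc <- rep(NA_real_, n_mc)
    uptake_mc[lab] <- .rlnorm_mean_cv(sum(lab), 1, config$uptake_cv) *
      config$uptake_ug[[element]][donor_of_mc[lab]]
    el <- substr(element, 1, 1)
    phi_mc <- rep(NA_real_, n_mc)
    phi_mc[lab] <- config$phi[sprintf(
      "%s_%s_to_%s", el, donor_of_mc[lab],
      ifelse(donor_of_mc[lab] == "orchid", "pine", "orchid"))]
    transferred_mc <- phi_mc * uptake_mc
    retained_mc <- (1 - phi_mc) * uptake_mc

    is_donor <- grid$plant_role == donor_of_mc[grid$idx_mc]
    row_lab <- lab[grid$idx_mc]
    alloc_above <- ifelse(is_donor, config$donor_alloc_above,
                          config$recipient_alloc_above)
    alloc <- ifelse(grid$tissue == "aboveground", alloc_above,
                    1 - alloc_above)
    plant_mass <- ifelse(is_donor, retained_mc[grid$idx_mc],
                         transferred_mc[grid$idx_mc])
    mass_ug <- ifelse(row_lab, alloc * plant_mass, 0)
    content <- if (element == "C13") c_content else n_content
    excess[[element]] <- mass_ug / 1e6 / (content * biomass)

    truth[[element]] <- tibble::tibble(
      microcosm_id = microcosms$microcosm_id[lab],
      element = element,
      donor_role = donor_of_mc[lab],
      recipient_role = ifelse(donor_of_mc[lab] == "orchid", "pine",
                              "orchid"),
      uptake_ug = uptake_mc[lab],
      transferred_ug = transferred_mc[lab],
      retained_ug = retained_mc[lab],
      phi = phi_mc[lab],
      percent_transferred = 100 * phi_mc[lab]
    )
  }

  af_13C <- baseline[["C13"]] + excess$C13
  af_15N <- baseline[["N15"]] + excess$N15
  if (any(af_13C >= 1) || any(af_15N >= 1)) {
    stop("configuration error: tracer load implies atom fraction >= 1",
         call. = FALSE)
  }
  af_13C <- .add_noise(af_13C, config$analytical_sd_permil, "C13")
  af_15N <- .add_noise(af_15N, config$analytical_sd_permil, "N15")

  measurements <- tibble::tibble(
    microcosm_id = microcosms$microcosm_id[grid$idx_mc],
    treatment = microcosms$treatment[grid$idx_mc],
    species = unname(species_of[grid$plant_role]),
    plant_role = grid$plant_role,
    tissue = grid$tissue,
    biomass_g = biomass,
    c_content_pct = 100 * c_content,
    n_content_pct = 100 * n_content,
    label_13C = microcosms$label_13C[grid$idx_mc],
    label_15N = microcosms$label_15N[grid$idx_mc],
    af_13C = af_13C,
    af_15N = af_15N,
    atom_pct_13C = 100 * af_13C,
    atom_pct_15N = 100 * af_15N,
    c_content = c_content,
    n_content = n_content
  )
  ground_truth <- dplyr::arrange(dplyr::bind_rows(truth),
                                 .data$microcosm_id, .data$element)
  structure(
    list(measurements = measurements, ground_truth = ground_truth,
         config = config),
    class = "sim_experiment"
  )
}

#' Expected transfer pattern implied by a configuration
#'
#' Derives, per element, the pattern the generator encodes: mean
#' directional fluxes are `phi * mean uptake`; a direction with
#' `phi = 0` carries no flux; when both directions flow, the net is
#' called negligible when it is under 10% of the larger flux.
#'
#' @param config A [simulation_config()].
#' @return A tibble with `element`, `pattern`, `net_direction`, and the
#'   two mean fluxes (micrograms).
#' @export
expected_patterns <- function(config) {
  validate_config(config)
  out <- lapply(c("C13", "N15"), function(element) {
    el <- substr(element, 1, 1)
    f_o2p <- config$phi[[paste0(el, "_orchid_to_pine")]] *
      config$uptake_ug[[element]][["orchid"]]
    f_p2o <- config$phi[[paste0(el, "_pine_to_orchid")]] *
      config$uptake_ug[[element]][["pine"]]
    if (f_o2p == 0 && f_p2o == 0) {
      pattern <- "none"; dir <- "none"
    } else if (f_o2p == 0 || f_p2o == 0) {
      pattern <- "unidirectional"
      dir <- if (f_o2p > 0) "orchid_to_pine" else "pine_to_orchid"
    } else if (abs(f_o2p - f_p2o) <= 0.1 * max(f_o2p, f_p2o)) {
      pattern <- "bidirectional_no_net"; dir <- "none"
    } else {
      pattern <- "bidirectional_net"
      dir <- if (f_o2p > f_p2o) "orchid_to_pine" else "pine_to_orchid"
    }
    tibble::tibble(element = element, pattern = pattern,
                   net_direction = dir,
                   flux_orchid_to_pine_ug = f_o2p,
                   flux_pine_to_orchid_ug = f_p2o)
  })
  dplyr::bind_rows(out)
}

#' Named scenario configurations spanning the observed pattern space
#'
#' Three fully parameterized configurations whose ground-truth transfer
#' patterns cover the qualitative outcomes a dual-labelling microcosm
#' study can produce, named after the orchid taxa they emulate:
#'
#' * `"goeringii-like"` -- strictly unidirectional exchange: carbon
#'   flows pine -> orchid only, nitrogen orchid -> pine only.
#' * `"serratum-like"` -- bidirectional exchange of both elements with
#'   a net carbon flux toward the orchid and a net nitrogen flux toward
#'   the pine.
#' * `"faberi-like"` -- bidirectional exchange with a net carbon flux
#'   toward the orchid but no resolvable net nitrogen flux.
#'
#' All three share the default plant parameters and carry a net carbon
#' flux from pine to orchid, the signature of mixotrophic orchids
#' drawing on their fungal network.
#'
#' @param seed Seed stored in each configuration.
#' @return A named list of [simulation_config()] objects.
#' @export
transfer_scenarios <- function(seed = 1L) {
  list(
    "goeringii-like" = simulation_config(
      orchid_species = "Cymbidium goeringii",
      phi = c(C_orchid_to_pine = 0, C_pine_to_orchid = 0.014,
              N_orchid_to_pine = 0.0030, N_pine_to_orchid = 0),
      seed = seed
    ),
    "serratum-like" = simulation_config(
      orchid_species = "Cymbidium goeringii var. serratum",
      phi = c(C_orchid_to_pine = 0.027, C_pine_to_orchid = 0.014,
              N_orchid_to_pine = 0.090, N_pine_to_orchid = 0.0025),
      seed = seed
    ),
    "faberi-like" = simulation_config(
      orchid_species = "Cymbidium faberi",
      phi = c(C_orchid_to_pine = 0.016, C_pine_to_orchid = 0.030,
              N_orchid_to_pine = 0.0053, N_pine_to_orchid = 0.0068),
      seed = seed
    )
  )
}
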