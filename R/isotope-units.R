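# Isotope composition arithmetic.
#
# Everything downstream works in ATOM FRACTION (dimensionless, [0,1]).
# Delta notation (permil) and atom percent exist only at I/O boundaries:
# the micrograms-from-grams factor in the mass balance is only
# dimensionally coherent when enrichment and element content are proper
# fractions.

# Heavy/light isotope ratios of the international reference materials.
# 13C/12C of Vienna Pee Dee Belemnite; 15N/14N of atmospheric N2.
.REFERENCE_RATIOS <- c(C13 = 0.0111802, N15 = 0.0036765)

#' International isotope reference standard
#'
#' Returns the reference standard used to anchor delta-notation values for
#' one element: Vienna Pee Dee Belemnite (VPDB) for carbon-13, atmospheric
#' N2 (AIR) for nitrogen-15.
#'
#' @param element `"C13"` or `"N15"`.
#' @return A list with `element`, `name`, and `reference_ratio`
#'   (the dimensionless heavy/light isotope ratio of the standard).
#' @examples
#' isotope_standard("C13")$reference_ratio
#' @export
isotope_standard <- function(element = c("C13", "N15")) {
  element <- match.arg(element)
  list(
    element = element,
    name = if (element == "C13") "VPDB" else "AIR",
    reference_ratio = unname(.REFERENCE_RATIOS[element])
  )
}

.resolve_ratio <- function(standard) {
  if (is.character(standard)) standard <- isotope_standard(standard)
  r <- standard$reference_ratio
  stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  r
}

#' Convert delta notation (permil) to atom fraction
#'
#' delta values express the sample's heavy/light isotope ratio R relative
#' to a reference standard: delta = (R/R_std - 1) * 1000. The atom
#' fraction of the heavy isotope is R/(1+R).
#'
#' @param delta_permil Numeric vector of delta values in permil. Must be
#'   >= -1000 (a delta below -1000 permil would imply a negative isotope
#'   ratio).
#' @param standard An element code (`"C13"`, `"N15"`) or the result of
#'   [isotope_standard()].
#' @return Atom fraction(s) in `[0, 1)`, strictly increasing in
#'   `delta_permil`.
#' @examples
#' delta_to_atom_fraction(0, "C13")    # natural VPDB operating point
#' delta_to_atom_fraction(-27, "C13")  # typical C3 plant tissue
#' @export
delta_to_atom_fraction <- function(delta_permil, standard) {
  r_std <- .resolve_ratio(standard)
  bad <- !is.na(delta_permil) & delta_permil < -1000
  if (any(bad)) {
    stop("invalid isotope composition: delta below -1000 permil implies a ",
         "negative isotope ratio (got ", min(delta_permil[bad]), ")",
         call. = FALSE)
  }
  r <- r_std * (1 + delta_permil / 1000)
  r / (1 + r)
}

#' Convert atom fraction to delta notation (permil)
#'
#' Exact inverse of [delta_to_atom_fraction()].
#'
#' @param atom_fraction Numeric vector in `[0, 1)`.
#' @inheritParams delta_to_atom_fraction
#' @return Delta values in permil.
#' @export
atom_fraction_to_delta <- function(atom_fraction, standard) {
  r_std <- .resolve_ratio(standard)
  bad <- !is.na(atom_fraction) & (atom_fraction >= 1 | atom_fraction < 0)
  if (any(bad)) {
    stop("invalid isotope composition: atom fraction must lie in [0, 1)",
         call. = FALSE)
  }
  r <- atom_fraction / (1 - atom_fraction)
  (r / r_std - 1) * 1000
}

#' Atom-percent excess of a labelled sample over its control baseline
#'
#' The tracer signal: the difference between a labelled sample's heavy-
#' isotope abundance and the abundance measured in unlabelled control
#' material of the same species and tissue. Computed and returned in atom
#' FRACTION units; multiply by 100 for atom percent.
#'
#' Negative excess (labelled below control, possible through measurement
#' noise) is retained, not clipped -- clipping would bias replicate means
#' upward -- and flagged `"below_zero"` so downstream detection logic can
#' decide significance.
#'
#' @param labelled,control Atom fractions in `[0, 1]` (vectors recycle).
#' @param element `"C13"` or `"N15"`, attached to the output for pairing
#'   safety. If both `labelled` and `control` carry an `"element"`
#'   attribute they must agree.
#' @return A tibble with columns `element`, `ape` (atom-fraction excess)
#'   and `flag` (`"ok"` or `"below_zero"`).
#' @examples
#' atom_percent_excess(0.0135, 0.0110, "N15")
#' @export
atom_percent_excess <- function(labelled, control, element = c("C13", "N15")) {
  element <- match.arg(element)
  el_l <- attr(labelled, "element")
  el_c <- attr(control, "element")
  for (el in c(el_l, el_c)) {
    if (!is.null(el) && !identical(el, element)) {
      stop("element mismatch: cannot pair a ", el,
           " composition in an ", element, " excess", call. = FALSE)
    }
  }
  stopifnot(all(labelled >= 0 & labelled <= 1, na.rm = TRUE),
            all(control >= 0 & control <= 1, na.rm = TRUE))
  ape <- as.numeric(labelled) - as.numeric(control)
  tibble::tibble(
    element = element,
    ape = ape,
    flag = ifelse(ape < 0, "below_zero", "ok")
  )
}

# Analytical (IRMS) precision quoted in permil, expressed as an
# atom-fraction standard deviation at a given operating composition.
# Central difference of the delta->atom-fraction map; the map is almost
# linear over +/- 1 permil so this is exact for practical purposes.
analytical_sd_atom_fraction <- function(sd_permil, at_atom_fraction, element) {
  d0 <- atom_fraction_to_delta(at_atom_fraction, element)
  (delta_to_atom_fraction(d0 + sd_permil, element) -
      delta_to_atom_fraction(d0 - sd_permil, element)) / 2
}
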