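# shared test helpers

# a quiet pipeline run: pre-check / detection warnings are inspected
# explicitly where they matter
quantify_quietly <- function(...) suppressWarnings(quantify_transfer(...))

# hand-built two-microcosm dataset (one labelled, orientation given; two
# controls) with round numbers so every mass is hand-checkable
tiny_dataset <- function(label_13C = "orchid",
                         label_15N = setdiff(c("orchid", "pine"), label_13C)) {
  plant <- function(mc, treatment, role, af13, af15, l13, l15) {
    tibble::tibble(
      microcosm_id = mc, treatment = treatment,
      species = if (role == "orchid") "Cymbidium goeringii" else
        "Pinus yunnanensis",
      plant_role = role,
      tissue = c("aboveground", "belowground"),
      biomass_g = c(1, 0.5),
      c_content_pct = 45, n_content_pct = 2,
      label_13C = l13, label_15N = l15,
      af_13C = af13, af_15N = af15
    )
  }
  ctrl <- dplyr::bind_rows(
    plant("CTRL1", "control", "orchid", 0.011, 0.0036, "none", "none"),
    plant("CTRL1", "control", "pine", 0.011, 0.0036, "none", "none"),
    plant("CTRL2", "control", "orchid", 0.011, 0.0036, "none", "none"),
    plant("CTRL2", "control", "pine", 0.011, 0.0036, "none", "none")
  )
  orchid_13 <- if (label_13C == "orchid") 0.013 else 0.0112
  pine_13 <- if (label_13C == "pine") 0.013 else 0.0112
  orchid_15 <- if (label_15N == "orchid") 0.0046 else 0.0037
  pine_15 <- if (label_15N == "pine") 0.0046 else 0.0037
  lab <- dplyr::bind_rows(
    plant("M1", "labelled", "orchid", orchid_13, orchid_15,
          label_13C, label_15N),
    plant("M1", "labelled", "pine", pine_13, pine_15, label_13C, label_15N)
  )
  dplyr::bind_rows(lab, ctrl)
}
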