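# tracer mass balance: tissue masses, plant pools, pool construction

test_that("tissue tracer mass follows excess x content x biomass x 1e6", {
  expect_equal(tissue_tracer_mass(0.01, 0.02, 1), 200)
  expect_equal(tissue_tracer_mass(0, 0.3, 5), 0)
  expect_equal(tissue_tracer_mass(0.005, 0.45, 2), 4500)
})

test_that("tissue tracer mass is linear in every argument", {
  set.seed(21)
  for (i in 1:25) {
    ape <- runif(1, -0.001, 0.02)
    ct <- runif(1, 0.005, 0.6)
    bm <- runif(1, 0.1, 5)
    base <- tissue_tracer_mass(ape, ct, bm)
    expect_equal(tissue_tracer_mass(2 * ape, ct, bm), 2 * base)
    expect_equal(tissue_tracer_mass(ape, ct, 2 * bm), 2 * base)
    # percent-notation inputs divided by 100 agree with fraction inputs
    expect_equal(tissue_tracer_mass((100 * ape) / 100, (100 * ct) / 100, bm),
                 base)
  }
})

test_that("tissue tracer mass validates its domain", {
  expect_error(tissue_tracer_mass(0.01, 0.02, 0), "biomass")
  expect_error(tissue_tracer_mass(0.01, 0.02, -1), "biomass")
  expect_error(tissue_tracer_mass(0.01, 0, 1), "element_content")
  expect_error(tissue_tracer_mass(0.01, 1.2, 1), "element_content")
})

test_that("plant pools sum tissues, keep the breakdown, propagate flags", {
  p <- plant_pool(c(aboveground = 150, belowground = 50))
  expect_equal(p$mass_ug, 200)
  expect_equal(p$breakdown[["aboveground"]], 150)
  expect_identical(p$flag, "ok")

  expect_equal(plant_pool(c(aboveground = 42))$mass_ug, 42)

  f <- plant_pool(c(aboveground = 120, belowground = -5),
                  flags = c("ok", "below_zero"))
  expect_equal(f$mass_ug, 115)
  expect_identical(f$flag, "below_zero")

  # permutation invariance
  a <- plant_pool(c(aboveground = 1.5, belowground = 2.5))
  b <- plant_pool(c(belowground = 2.5, aboveground = 1.5))
  expect_equal(a$mass_ug, b$mass_ug)

  expect_error(plant_pool(c(aboveground = 1, aboveground = 2)), "duplicate")
})

test_that("build_pools assigns donor and recipient pools by label orientation", {
  m <- tiny_dataset(label_13C = "orchid")
  pools <- build_pools(m)
  expect_equal(nrow(pools), 4L)

  get <- function(el, role) pools[pools$element == el &
                                    pools$plant_role == role, ]
  # 13C-labelled orchid: donor for carbon, recipient for nitrogen
  expect_identical(get("C13", "orchid")$pool_kind, "assimilated_by_label")
  expect_identical(get("C13", "pine")$pool_kind, "received_via_network")
  expect_identical(get("N15", "pine")$pool_kind, "assimilated_by_label")
  expect_identical(get("N15", "orchid")$pool_kind, "received_via_network")

  # hand arithmetic: APE 0.002 (13C donor), content 0.45,
  # biomass 1 + 0.5 g -> (0.002*0.45*1 + 0.002*0.45*0.5) * 1e6
  expect_equal(get("C13", "orchid")$mass_ug,
               0.002 * 0.45 * 1.5 * 1e6, tolerance = 1e-9)
  # recipient pine 13C: APE 0.0002 over 1.5 g at 45% C
  expect_equal(get("C13", "pine")$mass_ug,
               0.0002 * 0.45 * 1.5 * 1e6, tolerance = 1e-9)
  # 15N donor pine: APE 0.001, content 0.02
  expect_equal(get("N15", "pine")$mass_ug,
               0.001 * 0.02 * 1.5 * 1e6, tolerance = 1e-9)
  # tissue breakdown sums to the pool
  expect_equal(pools$mass_ug,
               pools$mass_aboveground_ug + pools$mass_belowground_ug)
})

test_that("swapping the labelling orientation swaps the roles", {
  # enumeration over both reciprocal orientations
  for (donor13 in c("orchid", "pine")) {
    pools <- build_pools(tiny_dataset(label_13C = donor13))
    donor15 <- setdiff(c("orchid", "pine"), donor13)
    expect_identical(
      pools$pool_kind[pools$element == "C13" & pools$plant_role == donor13],
      "assimilated_by_label")
    expect_identical(
      pools$pool_kind[pools$element == "N15" & pools$plant_role == donor15],
      "assimilated_by_label")
  }
})

test_that("control-only data yield no pools; missing controls are named", {
  m <- tiny_dataset()
  ctrl_only <- m[m$treatment == "control", ]
  pools <- build_pools(ctrl_only)
  expect_equal(nrow(pools), 0L)

  no_orchid_ctrl <- m[!(m$treatment == "control" &
                          m$plant_role == "orchid"), ]
  expect_error(build_pools(no_orchid_ctrl), "Cymbidium goeringii")
})

test_that("schema violations are reported with row context", {
  m <- tiny_dataset()
  m$biomass_g[3] <- -1
  expect_error(validate_measurements(m), "row")
  m2 <- tiny_dataset()
  m2$tissue[2] <- "stem"
  expect_error(validate_measurements(m2), "tissue")
  m3 <- tiny_dataset()[, setdiff(names(tiny_dataset()), "species")]
  expect_error(validate_measurements(m3), "species")
})
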