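# synthetic microcosm generator: conservation, determinism, fixtures

test_that("tracer is conserved before measurement noise", {
  sim <- simulate_experiment(simulation_config(seed = 41))
  gt <- sim$ground_truth
  expect_equal(gt$transferred_ug + gt$retained_ug, gt$uptake_ug,
               tolerance = 1e-12)
  expect_equal(gt$percent_transferred, 100 * gt$phi)
})

test_that("control microcosms scatter around the natural-abundance baseline", {
  cfg <- simulation_config(n_labelled = 1, n_control = 200, seed = 42)
  sim <- simulate_experiment(cfg)
  ctrl <- sim$measurements[sim$measurements$treatment == "control", ]
  for (el in c("C13", "N15")) {
    base <- delta_to_atom_fraction(cfg$baseline_delta[[el]], el)
    dev <- ctrl[[paste0("af_", substr(el, 2, 3), substr(el, 1, 1))]] - base
    expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  }
})

test_that("identical seeds give byte-identical datasets and fixtures", {
  cfg <- simulation_config(seed = 7)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$ground_truth, s2$ground_truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(s1, d1)
  write_fixtures(s2, d2)
  for (f in c("measurements.csv", "ground_truth.csv", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("fixtures round trip and differ only in draws across seeds", {
  sim <- simulate_experiment(simulation_config(seed = 8))
  d <- withr::local_tempdir()
  write_fixtures(sim, d)
  back <- read_measurements(file.path(d, "measurements.csv"))
  expect_equal(as.data.frame(back[names(sim$measurements)]),
               as.data.frame(sim$measurements))

  other <- simulate_experiment(simulation_config(seed = 9))
  expect_identical(names(other$measurements), names(sim$measurements))
  expect_identical(vapply(other$measurements, class, character(1)),
                   vapply(sim$measurements, class, character(1)))
  expect_false(identical(other$measurements$af_13C,
                         sim$measurements$af_13C))
})

test_that("configuration validation rejects impossible setups", {
  expect_error(simulation_config(phi = c(C_orchid_to_pine = 1.2,
                                         C_pine_to_orchid = 0,
                                         N_orchid_to_pine = 0,
                                         N_pine_to_orchid = 0)),
               "phi")
  expect_error(simulation_config(phi = c(C_orchid_to_pine = 0.1)), "phi")
  expect_error(simulation_config(uptake_cv = -1), "variation")
  expect_error(simulation_config(n_labelled = 0), "n_labelled")
  # a tracer load that would push atom fraction past 1
  huge <- simulation_config(uptake_ug = list(C13 = c(orchid = 5e9, pine = 1e4),
                                             N15 = c(orchid = 400, pine = 300)),
                            analytical_sd_permil = 0, seed = 1)
  expect_error(simulate_experiment(huge), "atom fraction")
})

test_that("scenario set encodes the three nitrogen patterns and universal net C", {
  scen <- transfer_scenarios()
  expect_named(scen, c("goeringii-like", "serratum-like", "faberi-like"))
  pats <- lapply(scen, expected_patterns)

  g <- pats[["goeringii-like"]]
  expect_identical(g$pattern[g$element == "N15"], "unidirectional")
  expect_identical(g$net_direction[g$element == "N15"], "orchid_to_pine")
  expect_identical(g$pattern[g$element == "C13"], "unidirectional")

  s <- pats[["serratum-like"]]
  expect_identical(s$pattern[s$element == "N15"], "bidirectional_net")
  expect_identical(s$net_direction[s$element == "N15"], "orchid_to_pine")
  expect_identical(s$pattern[s$element == "C13"], "bidirectional_net")

  f <- pats[["faberi-like"]]
  expect_identical(f$pattern[f$element == "N15"], "bidirectional_no_net")
  expect_identical(f$pattern[f$element == "C13"], "bidirectional_net")

  # carbon always flows net pine -> orchid
  for (p in pats) {
    expect_identical(p$net_direction[p$element == "C13"], "pine_to_orchid")
  }
})
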