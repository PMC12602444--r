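# directional ratios, detection, bootstrap net transfer, pattern calls

test_that("percent transferred is the displayed-ratio with correct bounds", {
  expect_equal(percent_transferred(10, 190), 5)
  expect_equal(percent_transferred(0, 100), 0)
  expect_equal(percent_transferred(50, 0), 100)
  expect_equal(percent_transferred(-3, 100), 0)  # floored negative
  expect_error(percent_transferred(0, 0), "undefined ratio")
  expect_error(percent_transferred(10, -1), "non-negative")
})

test_that("percent transferred is monotone in each argument", {
  set.seed(31)
  for (i in 1:20) {
    tr <- runif(1, 0.1, 50)
    as_ <- runif(1, 0.1, 500)
    eps <- runif(1, 0.01, 1)
    expect_gt(percent_transferred(tr + eps, as_), percent_transferred(tr, as_))
    expect_lt(percent_transferred(tr, as_ + eps), percent_transferred(tr, as_))
  }
})

test_that("detection compares weighted excess against the larger threshold", {
  # zero excess never detected at a positive threshold
  d0 <- detect_transfer(0, control_sd = 1e-6)
  expect_false(d0$detected)
  expect_equal(d0$threshold, 2e-6)

  # far above threshold
  expect_true(detect_transfer(2e-5, control_sd = 1e-6)$detected)

  # exactly at the threshold: strict inequality, not detected
  expect_false(detect_transfer(2e-6, control_sd = 1e-6)$detected)

  # analytical-precision branch dominates when controls are quiet
  da <- detect_transfer(1e-5, control_sd = 0, control_af = 0.0111,
                        analytical_sd_permil = 0.15, element = "C13")
  expect_gt(da$threshold, 0)

  # biomass weighting
  dw <- detect_transfer(c(1e-4, 0), weights = c(3, 1), control_sd = 1e-6)
  expect_equal(dw$ape_bw, 7.5e-5)

  expect_error(detect_transfer(1e-5), "neither is available")
})

test_that("net transfer bootstrap: point estimate, CI behaviour, symmetry", {
  x <- c(10, 11, 9, 10)
  z <- c(0, 0, 0, 0)
  nt <- net_transfer(x, z, n_boot = 4000, seed = 42)
  expect_equal(nt$estimate_ug, 10)
  expect_true(nt$ci[1] > 0)      # excludes zero
  expect_true(nt$net_present)

  same <- net_transfer(x, x, n_boot = 4000, seed = 42)
  expect_identical(same$estimate_ug, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  expect_identical(same$ci[1], -same$ci[2])
})

test_that("net transfer is exactly antisymmetric under argument swap", {
  set.seed(32)
  for (i in 1:5) {
    a <- rlnorm(4, 3, 0.3)
    b <- rlnorm(4, 2, 0.3)
    f_ab <- net_transfer(a, b, n_boot = 2000, seed = 100 + i)
    f_ba <- net_transfer(b, a, n_boot = 2000, seed = 100 + i)
    expect_identical(f_ab$estimate_ug, -f_ba$estimate_ug)
    expect_identical(f_ab$ci, -rev(f_ba$ci))
    expect_identical(f_ab$net_present, f_ba$net_present)
  }
})

test_that("net transfer degrades gracefully on tiny or silly inputs", {
  one <- net_transfer(5, c(1, 2), seed = 1)
  expect_identical(one$flag, "ci_unavailable")
  expect_true(all(is.na(one$ci)))
  expect_warning(net_transfer(c(1, 2), c(3, 4), n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("pattern classification is exhaustive and deterministic", {
  fake_net <- function(est, lo, hi) {
    list(estimate_ug = est, ci = c(lo, hi), conf = 0.95,
         net_present = lo > 0 || hi < 0, n = c(4L, 4L), flag = "ok")
  }
  net_pos <- fake_net(5, 2, 8)      # excludes zero, a -> b
  net_neg <- fake_net(-5, -8, -2)   # excludes zero, b -> a
  net_span <- fake_net(0.3, -1, 2)  # spans zero

  expect_identical(classify_pattern(FALSE, FALSE)$pattern, "none")
  expect_identical(classify_pattern(FALSE, FALSE)$net_direction, "none")

  uni_ab <- classify_pattern(TRUE, FALSE, net_pos)
  expect_identical(uni_ab$pattern, "unidirectional")
  expect_identical(uni_ab$net_direction, "orchid_to_pine")
  uni_ba <- classify_pattern(FALSE, TRUE, net_neg)
  expect_identical(uni_ba$net_direction, "pine_to_orchid")

  for (net in list(net_pos, net_neg, net_span)) {
    out <- classify_pattern(TRUE, TRUE, net)
    if (net$net_present) {
      expect_identical(out$pattern, "bidirectional_net")
      expect_identical(out$net_direction,
                       if (net$estimate_ug > 0) "orchid_to_pine"
                       else "pine_to_orchid")
    } else {
      expect_identical(out$pattern, "bidirectional_no_net")
      expect_identical(out$net_direction, "none")
    }
  }
  expect_error(classify_pattern(TRUE, TRUE), "net_transfer")
})

test_that("group comparison runs the ANOVA battery with letters", {
  # the constant group makes residuals non-normal; the pre-check is
  # expected to warn and the ANOVA to run regardless
  expect_warning(
    res <- compare_groups(c(0, 0, 0, 0, 100, 101, 99, 100),
                          rep(c("a", "b"), each = 4)),
    "Shapiro")
  expect_lt(res$p_value, 0.05)
  expect_false(res$letters[["a"]] == res$letters[["b"]])
  expect_true(all(res$tukey$p_adj <= 1))

  # a group duplicated under two names shares a letter
  y <- c(1, 2, 1.5, 1, 2, 1.5, 30, 31, 29)
  g <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  dup <- suppressWarnings(compare_groups(y, g))
  expect_identical(dup$letters[["a"]], dup$letters[["b"]])
  expect_false(dup$letters[["a"]] == dup$letters[["c"]])

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
  expect_error(compare_groups(1:4, rep("a", 4)), "two groups")
})

test_that("under the null all groups usually share a letter", {
  set.seed(33)
  trials <- 40
  shared <- logical(trials)
  for (i in seq_len(trials)) {
    y <- rnorm(15)
    g <- rep(c("g1", "g2", "g3"), each = 5)
    res <- suppressWarnings(compare_groups(y, g))
    shared[i] <- length(unique(res$letters)) == 1L
  }
  expect_gte(mean(shared), 0.9)
})
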