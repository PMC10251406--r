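bicarb <- substrate_spec("bicarbonate")

test_that("depth normalization maps any transect onto [0, 1] affinely", {
  p <- normalize_depth(depth_profile(c(0, 4500, 9000), c(0, 0, 0)))
  expect_equal(p$normalized_depth, c(0, 0.5, 1))
  p2 <- normalize_depth(depth_profile(c(100, 5100), c(0, 0)))
  expect_equal(p2$normalized_depth, c(0, 1))
  # affine invariance: a * depth + b yields the same grid
  d <- c(30, 250, 800, 4100, 8800)
  g1 <- normalize_depth(depth_profile(d, rep(0, 5)))$normalized_depth
  g2 <- normalize_depth(depth_profile(3 * d + 500, rep(0, 5)))$normalized_depth
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_error(normalize_depth(depth_profile(5, 0)), "degenerate profile")
})

test_that("replacement profiles equal per-spot scalar mass balances", {
  z <- c(0, 1000, 2500, 5000, 9000)
  delta <- c(900, 400, 150, 20, -10)
  prof <- depth_profile(z, delta, treatment = "bicarbonate")
  rp <- replacement_profile(prof, control = -20, substrate = bicarb)
  manual <- vapply(delta, function(dd)
    percent_replacement(delta_to_atom_fraction(dd),
                        delta_to_atom_fraction(-20), 0.5), numeric(1))
  expect_equal(rp$percent_replacement, manual, tolerance = 1e-12)

  flat <- replacement_profile(depth_profile(z, rep(-20, 5)), -20, bicarb)
  expect_equal(flat$percent_replacement, rep(0, 5), tolerance = 1e-12)

  two <- replacement_profile(
    depth_profile(c(0, 100), c(atom_fraction_to_delta(0.5), -20)), -20, bicarb)
  expect_equal(two$percent_replacement, c(100, 0), tolerance = 1e-9)
})

test_that("a depth-varying control profile is interpolated onto the sample grid", {
  smp <- depth_profile(c(0, 500, 1000), c(100, 100, 100))
  ctl <- depth_profile(c(0, 1000), c(-30, -10))
  rp <- replacement_profile(smp, ctl, bicarb)
  expected_ctrl <- c(-30, -20, -10)
  manual <- vapply(seq_len(3), function(i)
    percent_replacement(delta_to_atom_fraction(100),
                        delta_to_atom_fraction(expected_ctrl[i]), 0.5),
    numeric(1))
  expect_equal(rp$percent_replacement, manual, tolerance = 1e-12)
  expect_error(replacement_profile(smp, depth_profile(10, 5), bicarb),
               ">= 2 spots")
})

test_that("negative spot replacements are flagged, not clipped", {
  prof <- depth_profile(c(0, 100, 200), c(-120, -20, 300))
  rp <- replacement_profile(prof, -20, bicarb)
  expect_lt(rp$percent_replacement[1], -0.1)
  expect_equal(rp$flag_negative, c(TRUE, FALSE, FALSE))
})

test_that("mean replacement is the depth-weighted trapezoid of the profile", {
  mk <- function(z, u) structure(
    list(profile_id = "m", normalized_depth = z, percent_replacement = u,
         flag_negative = rep(FALSE, length(z))),
    class = "replacement_profile")
  expect_equal(mean_replacement(mk(c(0, 0.3, 1), rep(2.46, 3))), 2.46)
  expect_equal(mean_replacement(mk(seq(0, 1, 0.25), 10 * seq(0, 1, 0.25))), 5)
  set.seed(42)
  z <- sort(c(0, runif(18), 1)); u <- rnorm(20, 3, 1.5)
  expect_equal(mean_replacement(mk(z, u)), riemann_mean(z, u, 1e5),
               tolerance = 1e-6)
  # unweighted spot mean for comparison with spot-count summaries
  expect_equal(mean_replacement(mk(c(0, 0.9, 1), c(0, 0, 6)), method = "spot"), 2)
})

test_that("photic partitioning conserves the integral and matches oracles", {
  mk <- function(z, u) structure(
    list(profile_id = "m", normalized_depth = z, percent_replacement = u,
         flag_negative = rep(FALSE, length(z))),
    class = "replacement_profile")
  uni <- partition_at_boundary(mk(c(0, 1), c(3, 3)), 0.1)
  expect_equal(uni$fraction_below, 0.9, tolerance = 1e-12)
  expect_equal(uni$fraction_below + uni$fraction_above, 1, tolerance = 1e-9)

  surf <- partition_at_boundary(mk(c(0, 0.049, 0.05, 1), c(10, 10, 0, 0)), 0.1)
  expect_equal(surf$fraction_below, 0, tolerance = 1e-12)

  set.seed(7)
  z <- sort(c(0, runif(25), 1)); u <- abs(rnorm(27, 2, 1))
  part <- partition_at_boundary(mk(z, u), 0.37)
  xm <- (seq_len(1e5) - 0.5) / 1e5
  ym <- approx(z, u, xout = xm, rule = 2)$y
  expect_equal(part$fraction_below, sum(ym[xm > 0.37]) / sum(ym),
               tolerance = 1e-4)
  expect_equal(part$fraction_below + part$fraction_above, 1, tolerance = 1e-9)

  # moving the boundary deeper never increases the below fraction
  fb <- vapply(seq(0.05, 0.95, 0.05), function(b)
    partition_at_boundary(mk(z, u), b)$fraction_below, numeric(1))
  expect_true(all(diff(fb) <= 1e-12))

  neg <- partition_at_boundary(mk(c(0, 1), c(-1, -1)), 0.5)
  expect_true(neg$flagged)
  expect_true(is.na(neg$fraction_below))
})

test_that("the photic boundary is found by interpolating the irradiance profile", {
  z <- seq(0, 1, 0.001)
  expect_equal(boundary_from_irradiance(z, 100 * exp(-z / 0.1), 10),
               0.1 * log(10), tolerance = 1e-4)
  expect_equal(boundary_from_irradiance(c(0, 0.5), c(8, 1), 10), 0)
  expect_equal(boundary_from_irradiance(c(0, 0.2, 0.3, 1), c(50, 12, 8, 1), 10),
               0.25, tolerance = 1e-12)
  expect_error(boundary_from_irradiance(c(0, 1), c(100, 50), 10), "no boundary")
  expect_warning(b <- boundary_from_irradiance(c(0, 0.2, 0.4, 0.6),
                                               c(100, 5, 20, 2), 10),
                 "monotone")
  expect_lt(b, 0.21)
})

test_that("diel loss is the relative decrease from the earlier timepoint", {
  expect_equal(diel_loss(1.0, 0.56), 44)
  expect_equal(diel_loss(2.0, 2.0), 0)
  expect_equal(diel_loss(1.0, 1.2), -20)  # net gain
  expect_error(diel_loss(0, 1), "undefined loss")
})

test_that("replicate profiles are averaged per-profile, not pooled by spot", {
  mk <- function(z, u) structure(
    list(profile_id = "m", treatment = "bicarbonate", timepoint = 24,
         normalized_depth = z, percent_replacement = u,
         flag_negative = rep(FALSE, length(z))),
    class = "replacement_profile")
  # one short profile at 4%, one long profile at 2%: profile-first mean is 3
  rps <- list(mk(c(0, 1), c(4, 4)), mk(seq(0, 1, 0.1), rep(2, 11)))
  s <- summarize_profiles(rps, boundary = 0.5)
  expect_equal(s$mean_replacement_pct, 3)
  expect_equal(s$sd_replacement_pct, sd(c(4, 2)))
  expect_equal(s$fraction_below, 0.5, tolerance = 1e-9)
})
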