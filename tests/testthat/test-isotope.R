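test_that("delta/ratio/atom-fraction conversions match direct arithmetic", {
  expect_identical(delta_to_ratio(0), 0.0112372)
  expect_equal(delta_to_ratio(1000), 2 * 0.0112372, tolerance = 1e-15)
  # in-house fishing-line standard
  expect_equal(delta_to_ratio(-27.71), (1 - 0.02771) * 0.0112372,
               tolerance = 1e-15)
  expect_equal(delta_to_atom_fraction(0), 0.0112372 / 1.0112372,
               tolerance = 1e-15)
  # 24 h light bicarbonate bulk enrichment
  expect_equal(delta_to_atom_fraction(187.3), oracle_af(187.3),
               tolerance = 1e-15)
  expect_equal(ratio_to_delta(0.0112372), 0)
  expect_equal(ratio_to_delta(0.0224744), 1000, tolerance = 1e-12)
  # a 50 atom% pool: R = 1, delta = (1/R_VPDB - 1) * 1000
  expect_equal(atom_fraction_to_delta(0.5), (1 / 0.0112372 - 1) * 1000,
               tolerance = 1e-12)
  # delta -> -1000 as the pool empties of 13C
  expect_lt(atom_fraction_to_delta(1e-12), -999.999)
})

test_that("conversion round-trips are exact over the full enrichment range", {
  deltas <- c(-900, -50, 0, 187.3, 500, 5000, 50000)
  expect_equal(ratio_to_delta(delta_to_ratio(deltas)), deltas,
               tolerance = 1e-12)
  expect_equal(atom_fraction_to_delta(delta_to_atom_fraction(deltas)), deltas,
               tolerance = 1e-12)
  f <- c(1e-6, 0.0111, 0.25, 0.5, 0.99)
  expect_equal(delta_to_atom_fraction(atom_fraction_to_delta(f)), f,
               tolerance = 1e-12)
})

test_that("domain violations raise informative errors", {
  expect_error(delta_to_ratio(-1000), "invalid measurement")
  expect_error(ratio_to_delta(0), "invalid ratio")
  expect_error(ratio_to_delta(-1), "invalid ratio")
  expect_error(atom_fraction_to_delta(0), "atom fraction")
  expect_error(atom_fraction_to_delta(1), "atom fraction")
  expect_error(iso_constants(f13_natural = 0.05))
})

test_that("two-point correction reproduces identity, offset and fitted lines", {
  usgs <- data.frame(standard_id = c("USGS40", "USGS41"),
                     certified_delta = c(-26.39, 37.63),
                     measured_delta = c(-26.39, 37.63))
  expect_equal(as.numeric(two_point_correction(usgs, -10)), -10,
               tolerance = 1e-12)

  offset <- data.frame(certified_delta = c(-26.39, 37.63),
                       measured_delta = c(-27.39, 36.63))
  expect_equal(as.numeric(two_point_correction(offset, 0)), 1.0,
               tolerance = 1e-12)

  # >2 standards: closed-form least squares oracle
  pairs <- data.frame(certified_delta = c(-26.39, 0, 37.63),
                      measured_delta = c(-27.1, -0.4, 36.2))
  mx <- mean(pairs$measured_delta); my <- mean(pairs$certified_delta)
  a <- sum((pairs$measured_delta - mx) * (pairs$certified_delta - my)) /
    sum((pairs$measured_delta - mx)^2)
  b <- my - a * mx
  corr <- two_point_correction(pairs, 12.3)
  expect_equal(as.numeric(corr), a * 12.3 + b, tolerance = 1e-10)
  expect_equal(attr(corr, "slope"), a, tolerance = 1e-10)

  degenerate <- data.frame(certified_delta = c(5, 5), measured_delta = c(4, 6))
  expect_error(two_point_correction(degenerate, 0), "degenerate calibration")
})

test_that("effective substrate atom fraction mixes added and background pools", {
  bic <- substrate_spec("bicarbonate")
  expect_identical(effective_substrate_atom_fraction(bic), 0.5)

  diluted <- substrate_spec("bicarbonate", background_conc = 2.25,
                            background_delta = 0)
  expect_equal(effective_substrate_atom_fraction(diluted),
               (0.5 + oracle_af(0)) / 2, tolerance = 1e-12)

  swamped <- substrate_spec("bicarbonate", background_conc = 1e12,
                            background_delta = 0)
  expect_equal(effective_substrate_atom_fraction(swamped), oracle_af(0),
               tolerance = 1e-8)

  broken <- substrate_spec("bicarbonate", background_conc = 1)
  expect_error(effective_substrate_atom_fraction(broken), "background_delta")
})

test_that("percent replacement is the two-pool mass balance", {
  f_ctl <- oracle_af(-20)
  expect_equal(percent_replacement(f_ctl, f_ctl, 0.5), 0)
  expect_equal(percent_replacement(0.5, f_ctl, 0.5), 100)
  # bulk 24 h bicarbonate sample against an unlabeled control
  f_s <- oracle_af(187.3)
  expect_equal(percent_replacement(f_s, f_ctl, 0.5),
               100 * (f_s - f_ctl) / (0.5 - f_ctl), tolerance = 1e-12)
  expect_equal(round(percent_replacement(f_s, f_ctl, 0.5), 3), 0.465)
  expect_error(percent_replacement(0.3, 0.2, 0.2), "degenerate end-members")
})

test_that("replacement is linear in the sample atom fraction and inverts mixing", {
  f_ctl <- oracle_af(-15); f_sub <- 0.5
  f1 <- 0.015; f2 <- 0.21
  for (alpha in c(0, 0.25, 0.6, 1)) {
    lhs <- percent_replacement(alpha * f1 + (1 - alpha) * f2, f_ctl, f_sub)
    rhs <- alpha * percent_replacement(f1, f_ctl, f_sub) +
      (1 - alpha) * percent_replacement(f2, f_ctl, f_sub)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # planted mixing fractions are recovered exactly
  for (x in c(0.001, 0.0246, 0.5, 0.99)) {
    f_mix <- x * f_sub + (1 - x) * f_ctl
    expect_equal(percent_replacement(f_mix, f_ctl, f_sub), 100 * x,
                 tolerance = 1e-10)
  }
  # strictly increasing in sample delta
  deltas <- seq(-20, 2000, length.out = 25)
  repl <- percent_replacement(oracle_af(deltas), f_ctl, f_sub)
  expect_true(all(diff(repl) > 0))
})
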