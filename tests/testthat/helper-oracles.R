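# Independent oracles, coded from first principles and kept free of any
# package internals so they can arbitrate the implementation.

R_VPDB <- 0.0112372

oracle_ratio <- function(delta) (delta / 1000 + 1) * R_VPDB
oracle_delta <- function(ratio) (ratio / R_VPDB - 1) * 1000
oracle_af <- function(delta) {
  r <- oracle_ratio(delta)
  r / (1 + r)
}
oracle_af_to_delta <- function(f) oracle_delta(f / (1 - f))

# Brute-force Riemann mean of the piecewise-linear interpolant of (x, y)
# over [0, 1] at n subdivisions (midpoint rule).
riemann_mean <- function(x, y, n = 1e5) {
  xm <- (seq_len(n) - 0.5) / n
  mean(stats::approx(x, y, xout = xm, rule = 2)$y)
}

# Independently coded SIPPER filter predicate (row-by-row, explicit ifs).
brute_force_labeled <- function(records, cfg = matSIP::filter_config()) {
  out <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- TRUE
    if (is.na(r$fit_score_labeled) || r$fit_score_labeled > cfg$max_fit_score_labeled) ok <- FALSE
    if (ok && (is.na(r$i_score) || r$i_score > cfg$max_i_score)) ok <- FALSE
    if (ok && (is.na(r$sum_of_ratios) || r$sum_of_ratios < cfg$min_sum_of_ratios)) ok <- FALSE
    if (ok && (is.na(r$contig_score) || r$contig_score < cfg$min_contig_score)) ok <- FALSE
    if (ok && (is.na(r$percent_incorporation) ||
               r$percent_incorporation < cfg$min_percent_incorporation)) ok <- FALSE
    if (ok && (is.na(r$percent_peptide) ||
               r$percent_peptide < cfg$min_percent_peptide)) ok <- FALSE
    out[i] <- ok
  }
  out
}

# Forward binomial natural-abundance convolution by its sampling definition:
# a molecule with j labeled carbons gains i - j further heavy carbons among
# the remaining n - j with probability f each.
oracle_na_convolve <- function(true_mid, f) {
  n <- length(true_mid) - 1
  obs <- numeric(n + 1)
  for (j in 0:n) for (i in j:n)
    obs[i + 1] <- obs[i + 1] +
      true_mid[j + 1] * choose(n - j, i - j) * f^(i - j) * (1 - f)^(n - i)
  obs
}
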