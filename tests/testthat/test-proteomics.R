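boundary_record <- data.frame(
  peptide_id = "p1", protein_id = "pr1", taxon_bin = "cyanobacterial",
  timepoint = 4, incubation = "bicarbonate", spectral_count = 1,
  fit_score_labeled = 0.8, i_score = 0.6, sum_of_ratios = 0,
  contig_score = 0, percent_incorporation = 0.5, percent_peptide = 0.5)

random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    peptide_id = sprintf("p%d", 1:n),
    protein_id = sprintf("pr%d", sample(ceiling(n / 3), n, replace = TRUE)),
    taxon_bin = sample(c("cyanobacterial", "non_cyanobacterial"), n, TRUE),
    timepoint = sample(c(4, 6, 8), n, TRUE),
    incubation = sample(c("bicarbonate", "acetate", "glucose"), n, TRUE),
    spectral_count = 1 + rpois(n, 2),
    # scores straddle every cutoff so both outcomes are exercised
    fit_score_labeled = runif(n, 0, 1.6),
    i_score = runif(n, 0, 1.2),
    sum_of_ratios = runif(n, -1, 3),
    contig_score = runif(n, -1, 3),
    percent_incorporation = runif(n, 0, 2),
    percent_peptide = runif(n, 0, 2))
}

test_that("score filtering honors every cutoff with equality passing", {
  out <- apply_sipper_filters(boundary_record)
  expect_true(out$labeled)
  tweak <- boundary_record; tweak$fit_score_labeled <- 0.81
  expect_false(apply_sipper_filters(tweak)$labeled)
  tweak <- boundary_record; tweak$percent_peptide <- 0.49
  expect_false(apply_sipper_filters(tweak)$labeled)
})

test_that("filter flags are identical to a brute-force predicate", {
  rec <- rbind(random_records(1000, 21),
               boundary_record[rep(1, 5), ])
  out <- apply_sipper_filters(rec)
  expect_identical(out$labeled, brute_force_labeled(rec))
  expect_gt(sum(out$labeled), 0)
  expect_gt(sum(!out$labeled), 0)
  # idempotence
  expect_identical(apply_sipper_filters(out)$labeled, out$labeled)
})

test_that("loosening any single cutoff never decreases the labeled count", {
  rec <- random_records(600, 8)
  base <- sum(apply_sipper_filters(rec)$labeled)
  looser <- list(
    filter_config(max_fit_score_labeled = 1.2),
    filter_config(max_i_score = 1),
    filter_config(min_sum_of_ratios = -0.5),
    filter_config(min_contig_score = -0.5),
    filter_config(min_percent_incorporation = 0.2),
    filter_config(min_percent_peptide = 0.2))
  for (cfg in looser)
    expect_gte(sum(apply_sipper_filters(rec, cfg)$labeled), base)
})

test_that("records with missing scores are excluded, schema errors are named", {
  rec <- random_records(10, 3)
  rec$i_score[4] <- NA
  out <- apply_sipper_filters(rec)
  expect_false(out$labeled[4])
  expect_equal(attr(out, "n_excluded_missing_scores"), 1)
  expect_error(apply_sipper_filters(rec[, -7]), "fit_score_labeled")
  empty <- rec[0, ]
  expect_warning(out0 <- apply_sipper_filters(empty), "empty")
  expect_equal(nrow(out0), 0)
})

test_that("protein rollup counts a protein labeled if any peptide is", {
  rec <- data.frame(
    peptide_id = c("a", "b", "c"), protein_id = c("P1", "P1", "P2"),
    taxon_bin = "cyanobacterial", timepoint = 4, incubation = "bicarbonate",
    spectral_count = c(4, 1, 2), labeled = c(TRUE, FALSE, FALSE))
  s <- summarize_labeled_proteins(rec)
  expect_equal(s$n_labeled_proteins, 1)
  expect_equal(s$n_total_proteins, 2)
  expect_equal(s$relative_abundance, 0.5)
  sw <- summarize_labeled_proteins(rec, weight_by_spectra = TRUE)
  expect_equal(sw$weighted_labeled_peptide_fraction, 4 / 7)

  none <- rec; none$labeled <- FALSE
  expect_equal(summarize_labeled_proteins(none)$relative_abundance, 0)
})

test_that("taxon-bin rollups conserve the per-column labeled totals", {
  rec <- apply_sipper_filters(random_records(900, 13))
  # make protein ids unique per bin so bins partition the proteins
  rec$protein_id <- paste(rec$protein_id, rec$taxon_bin, sep = "_")
  total <- summarize_labeled_proteins(rec, level = "protein")
  by_bin <- summarize_labeled_proteins(rec, level = "taxon_bin")
  agg <- aggregate(cbind(n_labeled_proteins, n_total_proteins) ~
                     timepoint + incubation, by_bin, sum)
  m <- merge(total, agg, by = c("timepoint", "incubation"))
  expect_equal(m$n_labeled_proteins.x, m$n_labeled_proteins.y)
  expect_equal(m$n_total_proteins.x, m$n_total_proteins.y)
})

test_that("pathway matrix is sqrt of per-column relative abundance", {
  rec <- data.frame(
    peptide_id = sprintf("p%d", 1:4),
    protein_id = c("P1", "P2", "P3", "P4"),
    taxon_bin = "cyanobacterial", timepoint = 4, incubation = "bicarbonate",
    spectral_count = 1,
    labeled = c(TRUE, FALSE, FALSE, FALSE))
  kegg <- data.frame(protein_id = c("P1", "P1", "P2"),
                     pathway_id = c("ko00010", "ko00020", "ko00010"))
  pm <- pathway_matrix(rec, kegg)
  # P1 labeled, in two pathways; 4 proteins in the column -> raw 0.25 each
  expect_equal(unname(pm$raw_abundance["ko00010", 1]), 0.25)
  expect_equal(unname(pm$raw_abundance["ko00020", 1]), 0.25)
  expect_equal(unname(pm$sqrt_abundance["ko00010", 1]), 0.5)
  expect_equal(pm$sqrt_abundance, sqrt(pm$raw_abundance))

  # no labeled proteins -> all-zero column
  rec0 <- rec; rec0$labeled <- FALSE
  pm0 <- pathway_matrix(rec0, kegg)
  expect_true(all(pm0$sqrt_abundance == 0))

  # unmapped labeled proteins land in the unassigned row
  rec2 <- rec; rec2$labeled <- c(FALSE, FALSE, FALSE, TRUE)
  pm2 <- pathway_matrix(rec2, kegg)
  expect_equal(unname(pm2$raw_abundance["unassigned", 1]), 0.25)
})
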