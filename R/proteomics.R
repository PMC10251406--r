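#' SIPPER score filter configuration
#'
#' Cutoffs applied to per-peptide isotope-envelope scores to call a peptide
#' isotopically labeled. Defaults are the tight-filtering cutoffs tuned for a
#' false-positive rate near 5%: Fit Score Labeled <= 0.8, I Score <= 0.6,
#' Sum of Ratios >= 0, Contig Score >= 0, Percent Incorporation >= 0.5,
#' Percent Peptide >= 0.5. Boundary equality passes on every cutoff.
#'
#' @param max_fit_score_labeled,max_i_score Upper cutoffs.
#' @param min_sum_of_ratios,min_contig_score,min_percent_incorporation,min_percent_peptide
#'   Lower cutoffs.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_fit_score_labeled = 0.8,
                          max_i_score = 0.6,
                          min_sum_of_ratios = 0,
                          min_contig_score = 0,
                          min_percent_incorporation = 0.5,
                          min_percent_peptide = 0.5) {
  cfg <- list(max_fit_score_labeled = max_fit_score_labeled,
              max_i_score = max_i_score,
              min_sum_of_ratios = min_sum_of_ratios,
              min_contig_score = min_contig_score,
              min_percent_incorporation = min_percent_incorporation,
              min_percent_peptide = min_percent_peptide)
  stopifnot(all(vapply(cfg, is.finite, logical(1))))
  structure(cfg, class = "filter_config")
}

sipper_score_cols <- c("fit_score_labeled", "i_score", "sum_of_ratios",
                       "contig_score", "percent_incorporation",
                       "percent_peptide")

#' Flag labeled peptides by SIPPER score filtering
#'
#' A peptide is labeled iff it satisfies all six cutoffs simultaneously.
#' Records with any missing score are excluded (flagged unlabeled) and
#' counted in the `n_excluded_missing_scores` attribute.
#'
#' @param records data.frame of peptide records with the six score columns
#'   (`fit_score_labeled`, `i_score`, `sum_of_ratios`, `contig_score`,
#'   `percent_incorporation`, `percent_peptide`).
#' @param cfg A [filter_config()].
#' @return `records` with a logical `labeled` column appended.
#' @export
apply_sipper_filters <- function(records, cfg = filter_config()) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(sipper_score_cols, names(records))
  if (length(miss))
    stop("peptide table missing score column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0) {
    warning("empty peptide table")
    records$labeled <- logical(0)
    return(records)
  }
  complete <- stats::complete.cases(records[sipper_score_cols])
  lab <- complete &
    records$fit_score_labeled <= cfg$max_fit_score_labeled &
    records$i_score <= cfg$max_i_score &
    records$sum_of_ratios >= cfg$min_sum_of_ratios &
    records$contig_score >= cfg$min_contig_score &
    records$percent_incorporation >= cfg$min_percent_incorporation &
    records$percent_peptide >= cfg$min_percent_peptide
  lab[is.na(lab)] <- FALSE
  records$labeled <- lab
  structure(records, n_excluded_missing_scores = sum(!complete))
}

#' Labeled-protein counts and relative abundance
#'
#' Rolls labeled/unlabeled peptides up to proteins: a protein is labeled if
#' at least one of its peptides passes the filters. Relative abundance is
#' labeled proteins divided by total observed proteins within each
#' (timepoint, incubation) column — or each (taxon_bin, timepoint,
#' incubation) cell when `level = "taxon_bin"`. With
#' `weight_by_spectra = TRUE` the peptide-level labeled/unlabeled
#' distribution is additionally reported with each peptide weighted by its
#' spectral count.
#'
#' @param records Output of [apply_sipper_filters()]; needs `protein_id`,
#'   `timepoint`, `incubation`, `labeled`, plus `taxon_bin` for the taxon
#'   level and `spectral_count` for weighting.
#' @param level "protein" (per column) or "taxon_bin" (per bin within column).
#' @param weight_by_spectra Also compute the spectral-count-weighted labeled
#'   peptide fraction.
#' @param denominator "column" (default: totals per timepoint x incubation)
#'   or "global" (one denominator across the whole table).
#' @return data.frame with labeled counts, total proteins, and
#'   `relative_abundance` per group.
#' @export
summarize_labeled_proteins <- function(records,
                                       level = c("protein", "taxon_bin"),
                                       weight_by_spectra = FALSE,
                                       denominator = c("column", "global")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  stopifnot(all(c("protein_id", "timepoint", "incubation", "labeled") %in%
                  names(records)))
  if (level == "taxon_bin") stopifnot("taxon_bin" %in% names(records))
  keys <- c(if (level == "taxon_bin") "taxon_bin", "timepoint", "incubation")
  grp <- interaction(records[keys], drop = TRUE)
  global_total <- length(unique(records$protein_id))
  rows <- lapply(split(records, grp), function(s) {
    prot_lab <- tapply(s$labeled, s$protein_id, any)
    n_total <- if (denominator == "global") global_total else length(prot_lab)
    out <- data.frame(s[1, keys, drop = FALSE],
                      n_labeled_proteins = sum(prot_lab),
                      n_total_proteins = n_total,
                      relative_abundance = sum(prot_lab) / n_total,
                      row.names = NULL)
    if (weight_by_spectra) {
      stopifnot("spectral_count" %in% names(s))
      out$weighted_labeled_peptide_fraction <-
        sum(s$spectral_count[s$labeled]) / sum(s$spectral_count)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$incubation, out$timepoint), , drop = FALSE]
}

#' KEGG pathway matrix of labeled-protein relative abundance
#'
#' Builds the matrix behind a pathway heatmap: rows are KEGG pathways,
#' columns are (taxon_bin, timepoint, incubation) triples, and each value is
#' the square root of the labeled-protein relative abundance — labeled
#' proteins assigned to the pathway divided by all proteins observed in that
#' column. A protein mapped to k pathways contributes to all k rows; proteins
#' absent from the map fall in an "unassigned" row. Columns with no labeled
#' proteins are all zero.
#'
#' @param records Output of [apply_sipper_filters()] with `taxon_bin`.
#' @param kegg_map data.frame mapping `protein_id` to `pathway_id` (one row
#'   per assignment; proteins may appear multiple times).
#' @return A list of class `pathway_matrix`: `sqrt_abundance` (the
#'   transformed matrix), `raw_abundance`, and `columns` (the column
#'   metadata).
#' @export
pathway_matrix <- function(records, kegg_map) {
  stopifnot(all(c("protein_id", "taxon_bin", "timepoint", "incubation",
                  "labeled") %in% names(records)),
            all(c("protein_id", "pathway_id") %in% names(kegg_map)))
  cols_meta <- unique(records[c("taxon_bin", "timepoint", "incubation")])
  cols_meta <- cols_meta[order(cols_meta$incubation, cols_meta$timepoint,
                               cols_meta$taxon_bin), , drop = FALSE]
  rownames(cols_meta) <- NULL
  col_id <- function(df) paste(df$taxon_bin, df$timepoint, df$incubation,
                               sep = "|")
  kegg_map <- unique(kegg_map[c("protein_id", "pathway_id")])
  pathways <- sort(unique(kegg_map$pathway_id))
  rows <- c(pathways, "unassigned")
  M <- matrix(0, length(rows), nrow(cols_meta),
              dimnames = list(rows, col_id(cols_meta)))
  rec_col <- col_id(records)
  for (j in seq_len(nrow(cols_meta))) {
    s <- records[rec_col == col_id(cols_meta[j, ]), ]
    total <- length(unique(s$protein_id))
    if (total == 0) next
    lab_prot <- unique(s$protein_id[s$labeled])
    if (length(lab_prot) == 0) next
    pw <- kegg_map$pathway_id[kegg_map$protein_id %in% lab_prot]
    n_unassigned <- sum(!(lab_prot %in% kegg_map$protein_id))
    cnt <- table(factor(pw, levels = pathways))
    M[pathways, j] <- as.numeric(cnt) / total
    M["unassigned", j] <- n_unassigned / total
  }
  structure(list(sqrt_abundance = sqrt(M), raw_abundance = M,
                 columns = cols_meta),
            class = "pathway_matrix")
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("Pathway matrix: %d pathways x %d columns (sqrt-transformed)\n",
              nrow(x$sqrt_abundance), ncol(x$sqrt_abundance)))
  invisible(x)
}
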