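# Read a CSV and fail loudly, naming any missing required column.
read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s (%s): missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read a LA-IRMS spot table
#'
#' @param path CSV with columns `profile_id`, `treatment`, `timepoint_h`,
#'   `depth_um`, `delta_c13_permil`.
#' @return data.frame.
#' @export
read_spot_table <- function(path) {
  read_checked_csv(path, c("profile_id", "treatment", "timepoint_h",
                           "depth_um", "delta_c13_permil"), "spot table")
}

#' Read a bulk EA-IRMS measurement table
#'
#' @param path CSV with columns `sample_id`, `treatment`, `timepoint_h`,
#'   `delta_c13_permil`; `sd_permil` and `n` are carried when present.
#' @return data.frame.
#' @export
read_measurement_table <- function(path) {
  read_checked_csv(path, c("sample_id", "treatment", "timepoint_h",
                           "delta_c13_permil"), "measurement table")
}

#' Read an acid-wash pre/post table
#'
#' @param path CSV with columns `sample_id`, `treatment`, `timepoint_h`,
#'   `delta_pre`, `delta_post`; optional `delta_supernatant`,
#'   `carbon_fraction_removed`, `sd_pre`, `sd_post`.
#' @return data.frame.
#' @export
read_acid_wash_table <- function(path) {
  read_checked_csv(path, c("sample_id", "treatment", "timepoint_h",
                           "delta_pre", "delta_post"), "acid-wash table")
}

#' Read a GC-MS fragment intensity table
#'
#' @param path CSV with columns `metabolite`, `timepoint`, `incubation`,
#'   `replicate`, `mz_offset`, `intensity`.
#' @return data.frame.
#' @export
read_intensity_table <- function(path) {
  read_checked_csv(path, c("metabolite", "timepoint", "incubation",
                           "replicate", "mz_offset", "intensity"),
                   "intensity table")
}

#' Read a SIPPER peptide score table
#'
#' @param path CSV with columns `peptide_id`, `protein_id`, `taxon_bin`,
#'   `timepoint`, `incubation`, `spectral_count` and the six SIPPER score
#'   columns.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  read_checked_csv(path, c("peptide_id", "protein_id", "taxon_bin",
                           "timepoint", "incubation", "spectral_count",
                           sipper_score_cols), "peptide table")
}

#' Read a protein-to-pathway (or protein-to-taxon) mapping table
#'
#' @param path Tab- or comma-separated file with a `protein_id` column and
#'   one further id column (`pathway_id` or `taxon_bin`).
#' @param value_col Name of the second required column.
#' @return data.frame.
#' @export
read_mapping_table <- function(path, value_col = "pathway_id") {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("protein_id", value_col), names(df))
  if (length(miss))
    stop(sprintf("mapping table (%s): missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Split a spot table into depth profiles
#'
#' @param tbl A spot table ([read_spot_table()] or [emit_spot_tables()]).
#' @return Named list of normalized [depth_profile()] objects, one per
#'   `profile_id`.
#' @export
spot_table_to_profiles <- function(tbl) {
  req <- c("profile_id", "depth_um", "delta_c13_permil")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    stop("spot table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(tbl, tbl$profile_id), function(s)
    normalize_depth(depth_profile(
      s$depth_um, s$delta_c13_permil, profile_id = s$profile_id[1],
      treatment = if ("treatment" %in% names(s)) s$treatment[1] else NA,
      timepoint = if ("timepoint_h" %in% names(s)) s$timepoint_h[1] else NA)))
}
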