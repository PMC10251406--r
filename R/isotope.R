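#' Isotope constants
#'
#' Bundles the reference constants used throughout the package: the
#' \eqn{^{13}C/^{12}C} ratio of the VPDB standard and the natural
#' \eqn{^{13}C} atom fraction used by the mass-isotopomer routines.
#'
#' @param r_vpdb 13C/12C ratio of the Vienna Pee Dee Belemnite standard.
#'   Fixed at 0.0112372; changing it is only sensible for sensitivity checks.
#' @param f13_natural Natural 13C atom fraction, used as the default
#'   isotopic composition of unlabeled carbon. The default is the atom
#'   fraction at delta = 0 vs VPDB, r_vpdb / (1 + r_vpdb).
#' @return An object of class `iso_constants`.
#' @examples
#' iso_constants()
#' @export
iso_constants <- function(r_vpdb = 0.0112372, f13_natural = r_vpdb / (1 + r_vpdb)) {
  stopifnot(r_vpdb > 0, f13_natural > 0, f13_natural < 0.02)
  structure(list(r_vpdb = r_vpdb, f13_natural = f13_natural),
            class = "iso_constants")
}

#' @export
print.iso_constants <- function(x, ...) {
  cat("Isotope constants: R_VPDB =", format(x$r_vpdb, digits = 7),
      "; natural 13C atom fraction =", format(x$f13_natural, digits = 7), "\n")
  invisible(x)
}

#' Convert delta notation to an isotope ratio
#'
#' delta values are per-mil deviations of the sample 13C/12C ratio from the
#' VPDB standard ratio: R = (delta/1000 + 1) * R_VPDB.
#'
#' @param delta delta-13C in permil vs VPDB. Vectorized.
#' @param constants An [iso_constants()] object.
#' @return 13C/12C ratio(s), dimensionless.
#' @export
delta_to_ratio <- function(delta, constants = iso_constants()) {
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("invalid measurement: delta must be finite and > -1000 permil", call. = FALSE)
  (delta / 1000 + 1) * constants$r_vpdb
}

#' Convert an isotope ratio to delta notation
#'
#' @param ratio 13C/12C ratio(s), must be > 0.
#' @inheritParams delta_to_ratio
#' @return delta-13C in permil vs VPDB.
#' @export
ratio_to_delta <- function(ratio, constants = iso_constants()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("invalid ratio: must be finite and > 0", call. = FALSE)
  (ratio / constants$r_vpdb - 1) * 1000
}

#' Convert delta notation to 13C atom fraction
#'
#' The atom fraction F = 13C/(13C + 12C) = R/(1+R) is the correct mixing
#' coordinate for highly enriched material, where delta-space mixing is
#' strongly non-linear.
#'
#' @inheritParams delta_to_ratio
#' @return 13C atom fraction(s) in (0, 1).
#' @export
delta_to_atom_fraction <- function(delta, constants = iso_constants()) {
  r <- delta_to_ratio(delta, constants)
  r / (1 + r)
}

#' Convert a 13C atom fraction to delta notation
#'
#' @param f 13C atom fraction(s), strictly inside (0, 1).
#' @inheritParams delta_to_ratio
#' @return delta-13C in permil vs VPDB.
#' @export
atom_fraction_to_delta <- function(f, constants = iso_constants()) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("atom fraction must lie strictly inside (0, 1)", call. = FALSE)
  ratio_to_delta(f / (1 - f), constants)
}

#' Two-point (or multi-point) delta calibration
#'
#' Fits corrected = a * measured + b through calibration standards (exact for
#' two points, ordinary least squares for more) and applies the line to raw
#' measured values. Standards such as USGS 40 and USGS 41 (certified -26.39
#' and +37.63 permil) anchor an EA-IRMS run.
#'
#' @param pairs data.frame with columns `certified_delta` and `measured_delta`
#'   (a `standard_id` column is carried along if present).
#' @param raw Raw measured delta value(s) to correct. Vectorized.
#' @return Corrected delta value(s); the fitted line is attached as
#'   attributes `slope` and `intercept`.
#' @export
two_point_correction <- function(pairs, raw) {
  stopifnot(is.data.frame(pairs),
            all(c("certified_delta", "measured_delta") %in% names(pairs)))
  if (nrow(pairs) < 2 || length(unique(pairs$certified_delta)) < 2)
    stop("degenerate calibration: need >= 2 pairs with distinct certified values",
         call. = FALSE)
  if (length(unique(pairs$measured_delta)) < 2)
    stop("degenerate calibration: measured values are all identical", call. = FALSE)
  fit <- stats::lm(certified_delta ~ measured_delta, data = pairs)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  structure(a * raw + b, slope = a, intercept = b)
}

#' Specify a labeled substrate (mixing-model end-member)
#'
#' Describes the labeled substrate added to an incubation, optionally diluted
#' by an unlabeled background pool of the same chemical species (e.g., ambient
#' lake-water DIC for bicarbonate additions).
#'
#' @param name Substrate name; "bicarbonate", "acetate" and "glucose" carry
#'   default enrichments (0.50, 0.99, 0.99 atom fraction 13C), other names
#'   require `label_atom_fraction`.
#' @param added_conc Added concentration, mM. Defaults per substrate:
#'   bicarbonate 2.25, glucose 5, acetate 2.2.
#' @param label_atom_fraction 13C atom fraction of the added substrate, in
#'   \[0, 1\].
#' @param background_conc Concentration (mM) of the same species already
#'   present (default 0: no dilution).
#' @param background_delta delta-13C (permil) of the background pool; required
#'   when `background_conc > 0`.
#' @return An object of class `substrate_spec`.
#' @examples
#' substrate_spec("bicarbonate")
#' substrate_spec("acetate")
#' @export
substrate_spec <- function(name,
                           added_conc = NULL,
                           label_atom_fraction = NULL,
                           background_conc = 0,
                           background_delta = NULL) {
  defaults <- list(
    bicarbonate = list(conc = 2.25, f = 0.50),
    acetate     = list(conc = 2.2,  f = 0.99),
    glucose     = list(conc = 5,    f = 0.99)
  )
  d <- defaults[[name]]
  if (is.null(added_conc)) added_conc <- if (!is.null(d)) d$conc else
    stop("added_conc required for user-defined substrate", call. = FALSE)
  if (is.null(label_atom_fraction)) label_atom_fraction <- if (!is.null(d)) d$f else
    stop("label_atom_fraction required for user-defined substrate", call. = FALSE)
  stopifnot(added_conc > 0, label_atom_fraction >= 0, label_atom_fraction <= 1,
            background_conc >= 0)
  structure(list(name = name, added_conc = added_conc,
                 label_atom_fraction = label_atom_fraction,
                 background_conc = background_conc,
                 background_delta = background_delta),
            class = "substrate_spec")
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf("Substrate '%s': %.3g mM at %.3g atom%% 13C",
              x$name, x$added_conc, 100 * x$label_atom_fraction))
  if (x$background_conc > 0)
    cat(sprintf(" + %.3g mM background at %.4g permil",
                x$background_conc, x$background_delta))
  cat("\n")
  invisible(x)
}

#' Effective 13C atom fraction of the substrate pool
#'
#' Concentration-weighted mean atom fraction of the added labeled substrate
#' and any unlabeled background pool of the same species. With no background
#' this is simply the label enrichment.
#'
#' @param spec A [substrate_spec()].
#' @inheritParams delta_to_ratio
#' @return 13C atom fraction of the effective substrate end-member.
#' @export
effective_substrate_atom_fraction <- function(spec, constants = iso_constants()) {
  stopifnot(inherits(spec, "substrate_spec"))
  if (spec$background_conc == 0) return(spec$label_atom_fraction)
  if (is.null(spec$background_delta))
    stop("config error: background_delta required when background_conc > 0",
         call. = FALSE)
  f_bg <- delta_to_atom_fraction(spec$background_delta, constants)
  (spec$added_conc * spec$label_atom_fraction + spec$background_conc * f_bg) /
    (spec$added_conc + spec$background_conc)
}

#' Percent carbon replacement by a labeled substrate
#'
#' Two-pool isotope mass balance in atom-fraction space: the percentage of
#' biomass carbon derived from the labeled substrate is
#' 100 * (F_sample - F_control) / (F_substrate - F_control).
#' Values may be slightly negative under measurement noise; they are returned
#' unclipped so that downstream integrals remain unbiased.
#'
#' @param f_sample 13C atom fraction of the labeled sample. Vectorized.
#' @param f_control 13C atom fraction of the unlabeled control biomass.
#' @param f_substrate Effective 13C atom fraction of the substrate end-member.
#' @return Percent replacement (may exceed \[0, 100\] under noise).
#' @export
percent_replacement <- function(f_sample, f_control, f_substrate) {
  stopifnot(all(f_sample > 0 & f_sample < 1),
            f_control > 0, f_control < 1,
            f_substrate > 0, f_substrate < 1)
  if (abs(f_substrate - f_control) < .Machine$double.eps * 10)
    stop("degenerate end-members: substrate and control atom fractions are equal",
         call. = FALSE)
  100 * (f_sample - f_control) / (f_substrate - f_control)
}
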