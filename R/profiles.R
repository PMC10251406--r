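#' Construct a LA-IRMS depth profile
#'
#' One laser-ablation transect through the mat: ordered spot measurements of
#' delta-13C at increasing depth below the upper (illuminated) surface.
#'
#' @param depth_um Spot depths in micrometres, positive downward from the
#'   upper mat surface. Must be non-negative and strictly increasing after
#'   sorting; spots are sorted internally.
#' @param delta_c13 delta-13C (permil vs VPDB), parallel to `depth_um`.
#' @param profile_id,treatment Identifiers carried into outputs.
#' @param timepoint Hours since incubation start.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depth_um, delta_c13, profile_id = "p1",
                          treatment = NA_character_, timepoint = NA_real_) {
  stopifnot(length(depth_um) == length(delta_c13), all(depth_um >= 0))
  o <- order(depth_um)
  depth_um <- depth_um[o]; delta_c13 <- delta_c13[o]
  if (anyDuplicated(depth_um))
    stop("duplicate spot depths in profile ", profile_id, call. = FALSE)
  structure(list(profile_id = profile_id, treatment = treatment,
                 timepoint = timepoint, depth_um = depth_um,
                 delta_c13 = delta_c13, normalized_depth = NULL),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile '%s' (%s, t = %s h): %d spots, %.0f-%.0f um\n",
              x$profile_id, x$treatment, format(x$timepoint),
              length(x$depth_um), min(x$depth_um), max(x$depth_um)))
  invisible(x)
}

#' Normalize profile depths to the unit interval
#'
#' Affine map of absolute depths onto \[0, 1\]: 0 at the shallowest spot of
#' the profile, 1 at the deepest. Profiles of different absolute thickness
#' thereby become comparable on a common relative-depth axis.
#'
#' @param profile A [depth_profile()] with at least 2 spots.
#' @return The profile with `normalized_depth` filled in.
#' @export
normalize_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  d <- profile$depth_um
  if (length(d) < 2 || max(d) == min(d))
    stop("degenerate profile: need >= 2 spots at distinct depths", call. = FALSE)
  profile$normalized_depth <- (d - min(d)) / (max(d) - min(d))
  profile
}

#' Per-spot percent replacement along a depth profile
#'
#' Converts each spot's delta-13C to an atom fraction and applies the
#' two-pool mass balance against a control and substrate end-member.
#' The control may be a scalar delta (permil) or another depth profile,
#' which is normalized and linearly interpolated onto the sample grid.
#'
#' @param profile A [depth_profile()]; normalized on the fly if needed.
#' @param control A scalar control delta-13C (permil) or a [depth_profile()].
#' @param substrate A [substrate_spec()].
#' @param constants An [iso_constants()].
#' @param negative_tolerance Spot replacements below this value (percent) are
#'   flagged as suspect; they are never clipped.
#' @return An object of class `replacement_profile`: normalized depth grid,
#'   percent replacement per spot, and negative-value flags.
#' @export
replacement_profile <- function(profile, control, substrate,
                                constants = iso_constants(),
                                negative_tolerance = -0.1) {
  stopifnot(inherits(profile, "depth_profile"))
  if (is.null(profile$normalized_depth)) profile <- normalize_depth(profile)
  f_sub <- effective_substrate_atom_fraction(substrate, constants)
  if (inherits(control, "depth_profile")) {
    if (length(control$depth_um) < 2)
      stop("control profile needs >= 2 spots for interpolation", call. = FALSE)
    if (is.null(control$normalized_depth)) control <- normalize_depth(control)
    ctrl_delta <- stats::approx(control$normalized_depth, control$delta_c13,
                                xout = profile$normalized_depth, rule = 2)$y
  } else {
    stopifnot(is.numeric(control), length(control) == 1)
    ctrl_delta <- rep(control, length(profile$depth_um))
  }
  f_sample <- delta_to_atom_fraction(profile$delta_c13, constants)
  f_control <- delta_to_atom_fraction(ctrl_delta, constants)
  pct <- 100 * (f_sample - f_control) / (f_sub - f_control)
  structure(list(profile_id = profile$profile_id, treatment = profile$treatment,
                 timepoint = profile$timepoint,
                 normalized_depth = profile$normalized_depth,
                 percent_replacement = pct,
                 flag_negative = pct < negative_tolerance),
            class = "replacement_profile")
}

#' @export
print.replacement_profile <- function(x, ...) {
  cat(sprintf(
    "Replacement profile '%s': %d spots, mean %.3g%%, %d flagged negative\n",
    x$profile_id, length(x$percent_replacement),
    mean(x$percent_replacement), sum(x$flag_negative)))
  invisible(x)
}

# Trapezoidal integral over an ordered (x, y) grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Depth-averaged percent replacement of a profile
#'
#' The depth-weighted mean is the trapezoidal integral of the replacement
#' profile over the normalized depth axis (total span 1), which weights spots
#' by the depth interval they represent; the unweighted spot mean is offered
#' for comparison with spot-count-based summaries.
#'
#' @param rp A [replacement_profile()] with >= 2 points.
#' @param method "integrated" (default, depth-weighted trapezoid) or "spot"
#'   (plain mean over spots).
#' @return Mean percent replacement (scalar).
#' @export
mean_replacement <- function(rp, method = c("integrated", "spot")) {
  stopifnot(inherits(rp, "replacement_profile"),
            length(rp$percent_replacement) >= 2)
  method <- match.arg(method)
  z <- rp$normalized_depth; u <- rp$percent_replacement
  if (method == "spot") return(mean(u))
  trapz(z, u) / (max(z) - min(z))
}

#' Partition a replacement profile across a boundary depth
#'
#' Splits the depth-integrated tracer inventory of a replacement profile at a
#' normalized boundary depth (typically the photic boundary), using
#' trapezoidal quadrature with linear interpolation of the profile at the
#' boundary crossing.
#'
#' @param rp A [replacement_profile()].
#' @param boundary Normalized boundary depth, strictly inside (0, 1).
#' @return A list of class `photic_partition`: `boundary`, `fraction_below`,
#'   `fraction_above` (summing to 1), `total_integral`, and `flagged` (TRUE
#'   when the total integral is non-positive, in which case fractions are NA
#'   for clearly negative totals and best-effort otherwise).
#' @export
partition_at_boundary <- function(rp, boundary) {
  stopifnot(inherits(rp, "replacement_profile"), boundary > 0, boundary < 1)
  z <- rp$normalized_depth; u <- rp$percent_replacement
  zz <- sort(unique(c(z, boundary)))
  uu <- stats::approx(z, u, xout = zz, rule = 2)$y
  total <- trapz(zz, uu)
  below <- trapz(zz[zz >= boundary], uu[zz >= boundary])
  flagged <- total <= 0
  fb <- if (flagged) NA_real_ else below / total
  structure(list(boundary = boundary, fraction_below = fb,
                 fraction_above = if (is.na(fb)) NA_real_ else 1 - fb,
                 total_integral = total, flagged = flagged),
            class = "photic_partition")
}

#' @export
print.photic_partition <- function(x, ...) {
  cat(sprintf("Photic partition at z = %.3f: %.1f%% below, %.1f%% above%s\n",
              x$boundary, 100 * x$fraction_below, 100 * x$fraction_above,
              if (x$flagged) " [FLAGGED: non-positive total]" else ""))
  invisible(x)
}

#' Photic boundary depth from an irradiance profile
#'
#' Finds the shallowest normalized depth at which scalar irradiance falls to
#' or below a threshold (default 10 umol photons PAR m-2 s-1), by linear
#' interpolation between the bracketing tabulated points.
#'
#' @param depth Normalized depths, increasing.
#' @param irradiance Scalar irradiance (umol photons m-2 s-1) at each depth;
#'   expected monotone non-increasing. A non-monotone profile triggers a
#'   warning and the first crossing is used.
#' @param threshold Irradiance threshold defining the boundary.
#' @return Normalized boundary depth.
#' @export
boundary_from_irradiance <- function(depth, irradiance, threshold = 10) {
  stopifnot(length(depth) == length(irradiance), length(depth) >= 1,
            !is.unsorted(depth, strictly = TRUE))
  if (any(diff(irradiance) > 0))
    warning("irradiance profile is not monotone non-increasing; ",
            "using first downward crossing")
  if (irradiance[1] <= threshold) return(0)  # surface already below threshold
  below <- which(irradiance <= threshold)
  if (length(below) == 0)
    stop("no boundary: irradiance never reaches the threshold", call. = FALSE)
  i <- below[1]
  # linear interpolation between (i-1, i)
  d0 <- depth[i - 1]; d1 <- depth[i]
  I0 <- irradiance[i - 1]; I1 <- irradiance[i]
  d0 + (I0 - threshold) / (I0 - I1) * (d1 - d0)
}

#' Diel loss of previously incorporated tracer carbon
#'
#' Percent of the tracer carbon held at an earlier timepoint that was lost by
#' a later timepoint: 100 * (earlier - later) / earlier. Negative values mean
#' net gain and are returned as-is.
#'
#' @param uptake_earlier Mean percent replacement at the earlier timepoint
#'   (must be > 0).
#' @param uptake_later Mean percent replacement at the later timepoint.
#' @return Percent of earlier-held tracer lost.
#' @export
diel_loss <- function(uptake_earlier, uptake_later) {
  if (any(uptake_earlier <= 0))
    stop("undefined loss: earlier uptake must be > 0", call. = FALSE)
  100 * (uptake_earlier - uptake_later) / uptake_earlier
}

#' Summarize replicate replacement profiles
#'
#' Per-profile statistics are computed first and then averaged across
#' profiles (replicate transects have unequal spot counts, so pooling spots
#' would overweight the longer profiles).
#'
#' @param rps List of [replacement_profile()] objects (replicates of one
#'   treatment x timepoint).
#' @param boundary Optional normalized photic boundary; when given, the
#'   across-profile mean partition is included.
#' @return data.frame with one row: mean/sd of the depth-integrated mean
#'   replacement and (optionally) mean fraction below the boundary.
#' @export
summarize_profiles <- function(rps, boundary = NULL) {
  stopifnot(length(rps) >= 1)
  m <- vapply(rps, mean_replacement, numeric(1))
  out <- data.frame(n_profiles = length(rps),
                    mean_replacement_pct = mean(m),
                    sd_replacement_pct = stats::sd(m))
  if (!is.null(boundary)) {
    fb <- vapply(rps, function(r) partition_at_boundary(r, boundary)$fraction_below,
                 numeric(1))
    out$boundary <- boundary
    out$fraction_below <- mean(fb, na.rm = TRUE)
    out$fraction_above <- 1 - out$fraction_below
  }
  out
}
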