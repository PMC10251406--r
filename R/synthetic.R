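# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic diel-mat simulation
#'
#' Describes a forward model of tracer uptake in a stratified phototrophic
#' mat over a diel cycle: photoautotrophic uptake follows light with
#' saturating kinetics and decays with depth through irradiance attenuation;
#' heterotrophic uptake of organic substrates is depth-uniform; a first-order
#' fraction of incorporated tracer is lost in darkness (fermentation /
#' respiration of fresh photosynthate).
#'
#' @param n_depth Depth grid points over the normalized mat thickness \[0, 1\].
#' @param dt Euler time step, hours; must be <= 0.1 for stability.
#' @param t_end Simulation length, hours.
#' @param start_hour Local solar hour at incubation start (default 11.5,
#'   i.e., 11:30).
#' @param light_on,light_off Local hours bounding the daylight window.
#' @param I0_max Midday surface scalar irradiance, umol photons m-2 s-1; the
#'   diel course is a half-sine over the daylight window.
#' @param attenuation_length Normalized-depth e-folding length of irradiance
#'   (and hence of photoautotrophic uptake) in the mat.
#' @param k_p Photoautotrophic uptake coefficient, percent replacement per
#'   hour at light saturation (applies to bicarbonate).
#' @param k_h Heterotrophic uptake coefficient, percent per hour,
#'   depth-uniform (applies to acetate and glucose).
#' @param k_loss First-order nighttime loss rate of incorporated tracer,
#'   per hour; active only when surface irradiance is zero.
#' @param K_I Irradiance half-saturation constant, umol photons m-2 s-1.
#' @param noise_sd Gaussian measurement noise added to emitted spot
#'   delta-13C values, permil.
#' @param substrate A [substrate_spec()].
#' @param control_delta delta-13C (permil) of unlabeled control biomass.
#' @param sample_times Hours since start at which tables are emitted
#'   (default eight timepoints spanning dusk, night, dawn, and the second
#'   midday).
#' @param thickness_um Absolute mat thickness, micrometres.
#' @param seed Integer seed; recorded in all outputs.
#' @return A list of class `mat_sim_params`.
#' @export
mat_sim_params <- function(n_depth = 41,
                           dt = 0.05,
                           t_end = 24,
                           start_hour = 11.5,
                           light_on = 6,
                           light_off = 20,
                           I0_max = 1500,
                           attenuation_length = 0.115,
                           k_p = 0.77,
                           k_h = 0.13,
                           k_loss = 0.058,
                           K_I = 50,
                           noise_sd = 2,
                           substrate = substrate_spec("bicarbonate"),
                           control_delta = -20,
                           sample_times = c(1/3, 2, 6, 8.5, 13, 18.5, 21, 24),
                           thickness_um = 9000,
                           seed = 1L) {
  stopifnot(attenuation_length > 0, k_p >= 0, k_h >= 0, k_loss >= 0,
            K_I > 0, n_depth >= 2, t_end > 0, thickness_um > 0)
  if (dt > 0.1)
    stop("stability error: explicit Euler requires dt <= 0.1 h", call. = FALSE)
  structure(as.list(environment()), class = "mat_sim_params")
}

# Diel surface irradiance: half-sine over the daylight window, 0 at night.
surface_irradiance <- function(t, p) {
  h <- (p$start_hour + t) %% 24
  lit <- h >= p$light_on & h < p$light_off
  out <- numeric(length(t))
  out[lit] <- p$I0_max *
    sin(pi * (h[lit] - p$light_on) / (p$light_off - p$light_on))
  out
}

#' Simulate the true percent-replacement field of a diel mat
#'
#' Integrates, by explicit Euler, the uptake/loss balance
#' dU/dt = k_p I(z,t)/(I(z,t)+K_I) (bicarbonate) + k_h (organics)
#'       - k_loss U (in darkness),
#' with I(z,t) = I0(t) exp(-z / lambda), on the depth x time grid of `p`.
#' U is the true percent of biomass carbon replaced by substrate-derived
#' carbon and is non-negative throughout.
#'
#' @param p A [mat_sim_params()].
#' @return A list of class `replacement_field`: `depth` (normalized grid),
#'   `time` (hours), `U` (depth x time matrix, percent), and `params`.
#' @export
simulate_replacement_field <- function(p) {
  stopifnot(inherits(p, "mat_sim_params"))
  z <- seq(0, 1, length.out = p$n_depth)
  times <- seq(0, p$t_end, by = p$dt)
  autotrophic <- p$substrate$name == "bicarbonate"
  U <- matrix(0, length(z), length(times))
  atten <- exp(-z / p$attenuation_length)
  for (k in seq_len(length(times) - 1)) {
    I0 <- surface_irradiance(times[k], p)
    Iz <- I0 * atten
    dU <- if (autotrophic) p$k_p * Iz / (Iz + p$K_I) else rep(p$k_h, length(z))
    if (I0 == 0) dU <- dU - p$k_loss * U[, k]
    U[, k + 1] <- pmax(U[, k] + p$dt * dU, 0)
  }
  structure(list(depth = z, time = times, U = U, params = p),
            class = "replacement_field")
}

#' Construct a replacement field from a closed-form profile
#'
#' Plants a known truth directly, bypassing the ODE: `U(z, t)` is
#' `amplitude(t) * shape(z)`. Used to validate the profile pipeline against
#' analytic results (e.g., exponential attenuation with a known
#' below-boundary fraction).
#'
#' @param shape Function of normalized depth giving the profile shape.
#' @param amplitude Scalar or vector of per-timepoint amplitudes (percent).
#' @param times Timepoints (hours) of the field.
#' @param p A [mat_sim_params()] providing grid and emission settings.
#' @return A `replacement_field`.
#' @export
planted_field <- function(shape, amplitude, times, p = mat_sim_params()) {
  z <- seq(0, 1, length.out = p$n_depth)
  amplitude <- rep_len(amplitude, length(times))
  U <- outer(shape(z), rep(1, length(times))) *
    matrix(amplitude, length(z), length(times), byrow = TRUE)
  structure(list(depth = z, time = times, U = U, params = p),
            class = "replacement_field")
}

#' Emit synthetic LA-IRMS spot tables from a replacement field
#'
#' Samples the field at the requested timepoints and emits triplicate (by
#' default) depth profiles of delta-13C spots with Gaussian measurement
#' noise. Replicate profiles are jittered in spot count and in start/end
#' offset, emulating transects of unequal length. The true field value at
#' each spot is carried in a `truth_percent` column.
#'
#' @param field A `replacement_field`.
#' @param timepoints Hours at which to emit profiles (nearest grid time is
#'   used); defaults to the params' `sample_times` within range.
#' @param n_profiles Replicate profiles per timepoint.
#' @param n_spots_base Typical spot count per profile (jittered by replicate).
#' @param constants An [iso_constants()].
#' @return data.frame with columns `profile_id`, `treatment`, `timepoint_h`,
#'   `depth_um`, `delta_c13_permil`, `truth_percent`; attributes `seed` and
#'   `control_delta` record the generating conditions.
#' @export
emit_spot_tables <- function(field, timepoints = NULL, n_profiles = 3,
                             n_spots_base = 32,
                             constants = iso_constants()) {
  stopifnot(inherits(field, "replacement_field"))
  p <- field$params
  if (is.null(timepoints))
    timepoints <- p$sample_times[p$sample_times <= max(field$time)]
  f_sub <- effective_substrate_atom_fraction(p$substrate, constants)
  f_ctl <- delta_to_atom_fraction(p$control_delta, constants)
  with_seed(p$seed, {
    rows <- list()
    for (tp in timepoints) {
      k <- which.min(abs(field$time - tp))
      for (r in seq_len(n_profiles)) {
        n_spots <- n_spots_base + sample(-4:4, 1)
        start <- stats::runif(1, 0, 0.01)
        end <- stats::runif(1, 0.99, 1)
        z <- seq(start, end, length.out = n_spots)
        u_true <- stats::approx(field$depth, field$U[, k], xout = z)$y
        f_sample <- f_ctl + (u_true / 100) * (f_sub - f_ctl)
        delta <- atom_fraction_to_delta(f_sample, constants) +
          stats::rnorm(n_spots, 0, p$noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          profile_id = sprintf("%s_t%g_r%d", p$substrate$name, tp, r),
          treatment = p$substrate$name,
          timepoint_h = tp,
          depth_um = z * p$thickness_um,
          delta_c13_permil = delta,
          truth_percent = u_true)
      }
    }
    out <- do.call(rbind, rows)
    structure(out, seed = p$seed, control_delta = p$control_delta)
  })
}

#' Emit the irradiance depth profile of a simulated mat
#'
#' Tabulates midday scalar irradiance I(z) = I0_max exp(-z / lambda) on the
#' field's depth grid, for photic-boundary determination.
#'
#' @param p A [mat_sim_params()].
#' @return data.frame with columns `normalized_depth`, `irradiance`.
#' @export
emit_irradiance_table <- function(p) {
  z <- seq(0, 1, length.out = p$n_depth)
  data.frame(normalized_depth = z,
             irradiance = p$I0_max * exp(-z / p$attenuation_length))
}

#' Emit synthetic GC-MS fragment intensity tables
#'
#' For every (metabolite, timepoint, incubation) cell of the truth table,
#' draws replicate intensity vectors proportional to the mixture
#' x * Binomial(n, p_label) + (1 - x) * Binomial(n, f13_natural), with
#' multiplicative log-normal noise. Unlabeled control replicates (x = 0) are
#' added automatically for every metabolite x timepoint.
#'
#' @param truth data.frame with columns `metabolite`, `timepoint`,
#'   `incubation`, `x` (labeled-population fraction in \[0, 1\]).
#' @param fragments Named list of [fragment_spec()] keyed by metabolite;
#'   defaults to [default_fragments()].
#' @param p_label 13C atom fraction of the labeled population.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates per cell.
#' @param base_intensity Total ion count scale.
#' @param f13_natural Natural 13C atom fraction.
#' @param control_incubation Name given to the control rows.
#' @param seed Integer seed.
#' @return data.frame with columns `metabolite`, `timepoint`, `incubation`,
#'   `replicate`, `mz_offset`, `intensity`; the truth table is attached as
#'   attribute `truth`.
#' @export
emit_mid_tables <- function(truth, fragments = default_fragments(),
                            p_label = 0.99, noise_cv = 0.01,
                            n_replicates = 3, base_intensity = 1e6,
                            f13_natural = iso_constants()$f13_natural,
                            control_incubation = "control",
                            seed = 1L) {
  stopifnot(all(c("metabolite", "timepoint", "incubation", "x") %in%
                  names(truth)),
            all(truth$x >= 0 & truth$x <= 1))
  ctrl <- unique(truth[c("metabolite", "timepoint")])
  ctrl$incubation <- control_incubation
  ctrl$x <- 0
  cells <- rbind(truth[c("metabolite", "timepoint", "incubation", "x")], ctrl)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(cells))) {
      met <- cells$metabolite[i]
      spec <- fragments[[met]]
      if (is.null(spec)) stop("no fragment spec for metabolite ", met,
                              call. = FALSE)
      n <- spec$n_carbons
      mu <- cells$x[i] * natural_abundance_mid(n, p_label) +
        (1 - cells$x[i]) * natural_abundance_mid(n, f13_natural)
      for (r in seq_len(n_replicates)) {
        noise <- exp(stats::rnorm(n + 1, 0, noise_cv))
        rows[[length(rows) + 1]] <- data.frame(
          metabolite = met, timepoint = cells$timepoint[i],
          incubation = cells$incubation[i], replicate = r,
          mz_offset = 0:n,
          intensity = base_intensity * mu * noise)
      }
    }
    structure(do.call(rbind, rows), truth = cells, seed = seed)
  })
}

#' Default fragment specifications for the six tracked metabolites
#'
#' Carbon counts are the full carbon backbones: glucose 6, sucrose 12,
#' trehalose 12, glucosylglycerol 9, 3-hydroxybutanoate 4,
#' 3-hydroxypentanoate 5.
#'
#' @return Named list of [fragment_spec()].
#' @export
default_fragments <- function() {
  list(
    glucose = fragment_spec("glucose", 6),
    sucrose = fragment_spec("sucrose", 12),
    trehalose = fragment_spec("trehalose", 12),
    glucosylglycerol = fragment_spec("glucosylglycerol", 9),
    `3-hydroxybutanoate` = fragment_spec("3-hydroxybutanoate", 4),
    `3-hydroxypentanoate` = fragment_spec("3-hydroxypentanoate", 5)
  )
}

#' Emit synthetic SIPPER peptide score tables
#'
#' For each (taxon_bin, timepoint, incubation) cell, simulates `n_proteins`
#' proteins, marks each labeled with the cell's planted probability, and
#' emits peptides whose scores deterministically pass all six filter cutoffs
#' (labeled proteins get at least one passing peptide) or fail at least one
#' (all peptides of unlabeled proteins violate one randomly chosen
#' criterion).
#'
#' @param n_proteins Proteins per cell.
#' @param fractions data.frame with columns `taxon_bin`, `timepoint`,
#'   `incubation`, `labeled_fraction`.
#' @param peptides_per_protein Mean peptides observed per protein (>= 1).
#' @param cfg The [filter_config()] the labeled peptides are drawn to pass.
#' @param seed Integer seed.
#' @return data.frame of peptide records; the per-cell planted and realized
#'   labeled fractions are attached as attribute `truth`.
#' @export
emit_peptide_tables <- function(n_proteins, fractions,
                                peptides_per_protein = 3,
                                cfg = filter_config(), seed = 1L) {
  stopifnot(all(c("taxon_bin", "timepoint", "incubation",
                  "labeled_fraction") %in% names(fractions)),
            all(fractions$labeled_fraction >= 0 &
                  fractions$labeled_fraction <= 1))
  draw_passing <- function(k) data.frame(
    fit_score_labeled = stats::runif(k, 0, cfg$max_fit_score_labeled),
    i_score = stats::runif(k, 0, cfg$max_i_score),
    sum_of_ratios = cfg$min_sum_of_ratios + stats::rexp(k, 2),
    contig_score = cfg$min_contig_score + stats::rexp(k, 2),
    percent_incorporation = stats::runif(k, cfg$min_percent_incorporation, 30),
    percent_peptide = stats::runif(k, cfg$min_percent_peptide, 100))
  # make each row fail exactly one randomly chosen criterion
  violate_one <- function(scores) {
    n <- nrow(scores)
    if (n == 0) return(scores)
    fail <- sample.int(6, n, replace = TRUE)
    i <- fail == 1
    scores$fit_score_labeled[i] <- cfg$max_fit_score_labeled +
      stats::runif(sum(i), 0.01, 1)
    i <- fail == 2
    scores$i_score[i] <- cfg$max_i_score + stats::runif(sum(i), 0.01, 1)
    i <- fail == 3
    scores$sum_of_ratios[i] <- cfg$min_sum_of_ratios -
      stats::runif(sum(i), 0.01, 1)
    i <- fail == 4
    scores$contig_score[i] <- cfg$min_contig_score -
      stats::runif(sum(i), 0.01, 1)
    i <- fail == 5
    scores$percent_incorporation[i] <- cfg$min_percent_incorporation -
      stats::runif(sum(i), 0.01, 0.4)
    i <- fail == 6
    scores$percent_peptide[i] <- cfg$min_percent_peptide -
      stats::runif(sum(i), 0.01, 0.4)
    scores
  }
  with_seed(seed, {
    rows <- list(); truth <- list()
    for (i in seq_len(nrow(fractions))) {
      bin <- fractions$taxon_bin[i]; tp <- fractions$timepoint[i]
      inc <- fractions$incubation[i]; q <- fractions$labeled_fraction[i]
      prot_labeled <- stats::runif(n_proteins) < q
      k <- pmax(1L, stats::rpois(n_proteins, peptides_per_protein))
      # labeled proteins carry >= 1 passing peptide; the rest of their
      # peptides, and all peptides of unlabeled proteins, fail one cutoff
      n_pass <- ifelse(prot_labeled, pmax(1L, stats::rbinom(n_proteins, k, 0.5)), 0L)
      prot_idx <- rep.int(seq_len(n_proteins), k)
      within_pep <- sequence(k)
      pass <- within_pep <= n_pass[prot_idx]
      sc <- draw_passing(length(prot_idx))
      sc[!pass, ] <- violate_one(sc[!pass, , drop = FALSE])
      pid <- sprintf("%s_%s_t%s_prot%04d", inc, bin, format(tp),
                     seq_len(n_proteins))
      rows[[length(rows) + 1]] <- data.frame(
        peptide_id = sprintf("%s_pep%d", pid[prot_idx], within_pep),
        protein_id = pid[prot_idx], taxon_bin = bin, timepoint = tp,
        incubation = inc,
        spectral_count = 1L + stats::rpois(length(prot_idx), 2), sc)
      truth[[i]] <- data.frame(taxon_bin = bin, timepoint = tp,
                               incubation = inc, planted_fraction = q,
                               realized_fraction = mean(prot_labeled))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, truth = do.call(rbind, truth), seed = seed)
  })
}
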