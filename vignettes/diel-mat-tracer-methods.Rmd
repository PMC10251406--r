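---
title: "Quantifying 13C tracer movement in a stratified microbial mat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 13C tracer movement in a stratified microbial mat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matSIP)
```

## The measurement problem

Benthic phototrophic mats are stratified ecosystems in which photoautotrophs
(dominantly cyanobacteria) fix inorganic carbon in a thin illuminated surface
layer, while heterotrophs throughout the profile consume organic carbon. A
standard way to resolve who takes up what, where, and when is a stable
isotope tracer experiment: incubate mat sections with a ^13^C-labeled
substrate (bicarbonate, acetate, or glucose), sample over a full
light--dark (diel) cycle, and measure ^13^C enrichment in bulk biomass
(EA-IRMS), in 50-µm spots down depth transects (LA-IRMS), in metabolite
fragments (GC-MS mass isotopomer distributions), and in peptides
(SIP proteomics). `matSIP` implements the quantitative chain from those raw
tables to interpretable quantities — percent carbon replacement, photic-zone
partitioning, diel gain/loss, metabolite labeling calls, and labeled-protein
summaries — together with a synthetic generator that produces every input
with known ground truth.

## Isotope arithmetic and the mixing model

All isotope content is handled in standard delta notation against VPDB
($R_\mathrm{std} = 0.0112372$):

$$\delta^{13}\mathrm{C} = \left(\frac{R_\mathrm{sample}}{R_\mathrm{std}} - 1\right) \times 1000\ \text{‰},
\qquad R = {}^{13}\mathrm{C}/{}^{12}\mathrm{C}.$$

Mixing calculations are done in **atom-fraction** space,
$F = R/(1+R)$, never in delta space. At natural abundance the two are
nearly proportional, but the substrates here are 50–99 atom% ^13^C; delta
values of such pools run to tens of thousands of permil and mix
non-linearly, while atom fractions obey an exact linear two-pool carbon
balance. The percent of biomass carbon replaced by substrate-derived carbon
is

$$\mathrm{repl} = 100 \times \frac{F_\mathrm{sample} - F_\mathrm{control}}{F_\mathrm{substrate} - F_\mathrm{control}},$$

implemented in `percent_replacement()`. This is exactly linear in
$F_\mathrm{sample}$ and inverts a planted mixing fraction to machine
precision, which the test suite exploits.

Three choices deserve mention:

* **Calibration order.** `two_point_correction()` fits
  $\delta_\mathrm{corrected} = a\,\delta_\mathrm{measured} + b$ through
  certified standards (e.g., USGS 40/41 at −26.39 and +37.63 ‰; least
  squares when more than two standards are supplied) and is applied to raw
  deltas *before* any mixing arithmetic.
* **Substrate end-member.** The default end-members are the added-substrate
  enrichments (bicarbonate 0.50, acetate and glucose 0.99 atom fraction).
  For bicarbonate incubations the ambient dissolved inorganic carbon pool
  dilutes the effective end-member; because the ambient DIC concentration
  is generally not known precisely, dilution is off by default and exposed
  through `substrate_spec(background_conc =, background_delta =)` with a
  concentration-weighted mean in `effective_substrate_atom_fraction()`.
  Users should treat reported replacement percentages for bicarbonate as
  conditional on this choice and run a sensitivity check when ambient DIC
  is appreciable.
* **Negative replacements** arise from measurement noise when a sample sits
  slightly below the control. They are reported unclipped (clipping biases
  depth integrals upward) and flagged below a configurable tolerance
  (default −0.1%).
* **Control choice.** Either a time-matched unlabeled incubation or a t0
  baseline can serve as $F_\mathrm{control}$; both are supported (scalar or
  profile), and the choice is the caller's.

## Depth profiles and photic partitioning

LA-IRMS transects have unequal absolute lengths, so each profile's depths
are affinely normalized to $[0, 1]$ (0 = illuminated surface, 1 = bottom)
by `normalize_depth()`. Profile summaries use trapezoidal quadrature on the
normalized grid — spot spacing is coarse (~200–300 µm) and irregular, so
spline smoothing is deliberately avoided. The depth-weighted mean
replacement is the trapezoid integral over the unit span;
`partition_at_boundary()` splits the same integral at a normalized boundary
depth, with the profile linearly interpolated at the crossing, so that
`fraction_below + fraction_above = 1` holds identically whenever the total
integral is positive. Profiles whose total integral is non-positive (pure
noise around zero) are flagged rather than producing meaningless fractions.

The photic boundary itself comes from a scalar-irradiance depth profile:
`boundary_from_irradiance()` returns the shallowest depth at which
irradiance falls to a threshold (default 10 µmol photons PAR m^−2^ s^−1^),
interpolating linearly between tabulated points. No default boundary depth
is hard-coded; when no irradiance profile exists the boundary must be given
explicitly.

Replicate (typically triplicate) profiles are combined by computing
per-profile statistics first and then averaging across profiles
(`summarize_profiles()`). Pooling spots would overweight longer transects.
Whether "average % replacement" should be the depth-integrated or the
plain spot mean is ambiguous in general; both are computed
(`mean_replacement(method =)`) and the integrated form is the default and
the one used in partitioning.

Diel accounting is the relative change between timepoints:
`diel_loss(u_earlier, u_later)` = $100 (u_e - u_l)/u_e$, with negative
values meaning net gain, reported as-is.

## Acid-wash three-pool balance

Mild acid removes carbonate minerals and part of the EPS matrix. With the
carbon fraction removed $f$ known, the removed pool's composition follows
exactly from
$F_\mathrm{pre} = f F_\mathrm{removed} + (1-f) F_\mathrm{post}$
(`removed_pool_atom_fraction()`; rejected as ill-conditioned below
$f = 0.01$). The balance is on **carbon atoms**: $f$ must be the fraction
of sample *carbon* removed, not of sample mass — a frequent source of error
since experiments typically report only the delta shift. When $f$ is
unknown, `classify_removed_pool()` still classifies the removed pool as
having carried more tracer than the residue (bulk enrichment drops on
washing), less (it rises), or indistinguishable, using a
$z \sqrt{sd_\mathrm{pre}^2 + sd_\mathrm{post}^2}$ tolerance (default
$z = 2$) or an absolute 0.5 ‰ when uncertainties are absent. A supernatant
delta, when measured, is interpreted as the organic (EPS) component of the
removed pool, since carbonate carbon leaves as CO~2~.

## Metabolite mass isotopomer distributions

Fragment ion intensities $M{+}0 \dots M{+}n$ are normalized to a mass
isotopomer distribution (MID), corrected for natural ^13^C abundance, and
compared against unlabeled controls. The correction model is binomial: a
molecule already carrying $j$ labeled carbons distributes its remaining
$n-j$ carbons as $\mathrm{Binomial}(n-j, f_{13})$, giving a lower-triangular
convolution matrix solved by back-substitution. Only carbon is corrected;
Si/O/N/H isotopes of TMS derivatives are ignored, and `n_carbons` counts
labeled-backbone carbons only. This matches fragment-level manual practice
but means absolute M+1 fractions of heavy derivatives should not be
over-interpreted. Small negative artifacts from noise are floored at zero
and the MID renormalized, with the floored mass recorded.

Enrichment is summarized as molar percent excess,
$100\,[\sum_i i\,m_i^\mathrm{sample} - \sum_i i\,m_i^\mathrm{control}]/n$,
which is linear in the fraction of molecules drawn from a labeled
population. The three-level labeling call (`call_label()`) is **explicit
configuration**: "+" when the excess clears
$\max(0.5\%,\ 3\,sd_\mathrm{control})$, "−" when it fails
$\max(0.1\%,\ 1\,sd_\mathrm{control})$, "+/−" between. Manual curation in
the field has not published a numeric criterion, so these defaults are
declared, not inferred from any study. Controls are the same-timepoint
unlabeled incubations, falling back to pooled controls with a warning.
`fit_labeled_population()` additionally estimates, by constrained least
squares, the fraction of molecules drawn from a binomially labeled
population at a given enrichment, putting the qualitative diel pattern on
a continuous scale.

## SIP proteomics

The package consumes per-peptide isotope-envelope scores (SIPPER-style) and
applies the six tight-filtering cutoffs — Fit Score Labeled ≤ 0.8,
I Score ≤ 0.6, Sum of Ratios ≥ 0, Contig Score ≥ 0, Percent
Incorporation ≥ 0.5, Percent Peptide ≥ 0.5 — with boundary equality
passing. Envelope extraction and score computation are out of scope.
A protein is labeled when any of its peptides passes; relative abundance is
labeled over total observed proteins per (timepoint × incubation) column
(a global-denominator mode exists but is non-default). Spectral-count
weighting of the labeled/unlabeled peptide distribution is available
separately (`weight_by_spectra = TRUE`) because counting proteins and
weighting peptide distributions answer different questions and cannot be
merged into one number. Peptides shared by proteins in both taxon bins
count in both; pathway rollups intentionally count multi-pathway proteins
once per pathway, and the heatmap-ready matrix stores
$\sqrt{\text{relative abundance}}$ to compress the dynamic range.

## The synthetic diel mat

`simulate_replacement_field()` integrates, by explicit Euler
($\Delta t \le 0.1$ h),

$$\frac{\partial U}{\partial t} =
k_p \frac{I(z,t)}{I(z,t) + K_I}\,[\text{bicarbonate}]
+ k_h\,[\text{organic}]
- k_\mathrm{loss}\, U\,[I_0(t) = 0],
\qquad I(z,t) = I_0(t)\, e^{-z/\lambda},$$

where $U(z,t)$ is true percent replacement. Defaults describe the study
conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| start hour | 11:30 | incubation start at late morning |
| daylight window | 06:00–20:00 | summer diel cycle; half-sine irradiance course |
| sampling timepoints | 8, spanning 0.33–24 h | dusk (8.5 h), night, dawn (18.5 h), second noon (24 h) |
| $I_{0,\max}$ | 1500 µmol photons m^−2^ s^−1^ | midday full sun |
| $\lambda$ | 0.115 (normalized depth) | light (and hence photoautotrophy) confined to roughly the top millimetre of a ~1 cm mat |
| $K_I$ | 50 µmol photons m^−2^ s^−1^ | plausible saturation constant; any positive value works for the closed-form tests |
| $k_\mathrm{loss}$ | 0.058 h^−1^ | ~44% loss of incorporated tracer over the 10 h dark window, $1 - e^{-0.058 \times 10}$ |
| $k_p$ | 0.77 % h^−1^ | puts the 24 h depth-mean bicarbonate replacement near 2.5% |
| $k_h$ | 0.13 % h^−1^ | puts organic-substrate replacement in the same few-percent range |
| noise | 2 ‰ (Gaussian, per spot) | typical LA-IRMS spot repeatability |

Emitted spot tables are triplicate profiles of unequal spot count with
small start/end offsets, inverted from $U$ through the same atom-fraction
mass balance the analysis uses, so at zero noise the pipeline recovers the
field exactly. MID tables draw intensities from
$x\,\mathrm{Binomial}(n, 0.99) + (1-x)\,\mathrm{Binomial}(n, f_{13})$ with
1% multiplicative log-normal noise; peptide tables plant per-cell
labeled-protein fractions, drawing labeled peptides to pass all six cutoffs
and unlabeled ones to fail exactly one, chosen at random. All generators
run on a private seeded RNG stream and are byte-deterministic given
parameters and seed.

### What the generator does *not* emulate

The forward model has **no vertical transport**: fixed carbon stays where
it was fixed. In real mats, freshly fixed carbon is exported below the
photic boundary via metabolites, EPS, and necromass — that export is
precisely the scientific signal such experiments look for. Consequently the
reference scenario's below-photic fraction for bicarbonate is small
(a few percent), not the tens of percent a real mat can show; recovering a
*planted* exponential profile, not reproducing field partitioning, is what
the spatial tests demonstrate. Likewise, heterotrophic uptake runs
day and night in the model, so organic-substrate scenarios show net
overnight *gain* where field data can show modest loss; the diel-loss
closed form is exercised on the bicarbonate scenario, where darkness stops
uptake entirely. The generator also omits chromatographic artifacts,
derivative-element isotopes, residual-substrate carryover, and any
taxon-resolved metabolism. Passing tests therefore validate the
*estimators*, not the realism of any particular mat.

## Numerical choices

* Trapezoidal quadrature everywhere on normalized grids; verified against
  10^5^-subdivision Riemann sums.
* The natural-abundance correction solves a lower-triangular system by
  back-substitution (exact, $O(n^2)$); flooring of noise-induced negatives
  happens *after* the solve and is logged via the `floored_mass` attribute.
* Explicit Euler with $\Delta t \le 0.1$ h (enforced); the nighttime decay
  branch matches $e^{-k_\mathrm{loss}\Delta t}$ to <0.5% at
  $\Delta t = 0.01$ h.
* `fit_labeled_population()` clamps its closed-form least-squares estimate
  to $[0,1]$ and warns when the labeled enrichment is within 0.01 of
  natural abundance (ill-conditioned design).
* Degenerate inputs fail loudly and specifically: all-equal depths,
  identical end-members, all-identical calibration standards, all-zero
  intensity vectors, removal fractions below 0.01.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at deliberately modest sizes: 41-point depth grids (201 for the planted
exponential-recovery check), 0.05 h time steps (0.01 h for closed-form
checks), triplicate profiles of ~30 spots, 3 replicate MIDs per cell over
54 metabolite × timepoint × substrate cells, and 1 000 proteins per
taxon-bin × timepoint × incubation cell (2 000 per incubation column) with
~3 peptides per protein. These sizes make every statistical tolerance in
the tests meaningful while keeping a full run in seconds.

## Known limitations

* Absolute removed-pool compositions require a carbon-based removal
  fraction, which bulk delta measurements alone cannot supply.
* The labeling-call thresholds are package defaults, not community
  standards; report them alongside any call matrix.
* Percent replacement for bicarbonate is conditional on the DIC end-member
  choice (see above).
* The pipeline treats profiles as one-dimensional; lateral heterogeneity
  and image registration are out of scope.
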