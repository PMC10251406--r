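# matSIP

Quantification of ¹³C stable-isotope tracer incorporation in stratified
phototrophic microbial mats over a diel (24 h) light–dark cycle.

Mat ecosystems fix inorganic carbon photoautotrophically in a thin
illuminated surface layer and redistribute that carbon — via metabolites,
EPS and necromass — to heterotrophs throughout the profile. Tracer
incubations with ¹³C-bicarbonate, -acetate or -glucose, read out by bulk
EA-IRMS, spatially resolved LA-IRMS depth transects, GC-MS metabolite mass
isotopomer distributions (MIDs) and SIP proteomics, measure who takes up
which carbon, where, and when. `matSIP` implements the full quantitative
chain from those tables to interpretable results, plus a synthetic diel-mat
generator with known ground truth so every estimator is testable without
field data.

## The core model

All mixing arithmetic runs in ¹³C atom-fraction space, `F = R/(1+R)` with
`R = (δ/1000 + 1) × R_VPDB` (`R_VPDB = 0.0112372`), because delta-space
mixing is badly non-linear at 50–99 atom% end-members. The central
estimator is the two-pool isotope mass balance

```
% replacement = 100 × (F_sample − F_control) / (F_substrate − F_control)
```

applied per bulk sample or per 50-µm laser-ablation spot. Around it:

- **Spatial analysis** — affine depth normalization to [0, 1], trapezoidal
  depth integration, photic/aphotic partitioning at an irradiance-derived
  boundary (≤ 10 µmol photons PAR m⁻² s⁻¹), and diel gain/loss accounting.
- **Acid-wash balance** — exact inversion of the three-pool mixture to
  recover the composition of the acid-removed (carbonate + EPS) pool, and a
  tolerance-based enrichment classification when the removed carbon
  fraction is unknown.
- **Metabolite MIDs** — binomial natural-abundance correction (triangular
  solve), molar percent excess over same-timepoint unlabeled controls, a
  configurable three-level labeling call (`+`, `+/−`, `−`), and a
  constrained least-squares labeled-population fraction.
- **SIP proteomics** — the six SIPPER tight-filter cutoffs
  (Fit Score Labeled ≤ 0.8, I Score ≤ 0.6, Sum of Ratios ≥ 0,
  Contig Score ≥ 0, Percent Incorporation ≥ 0.5, Percent Peptide ≥ 0.5,
  equality passing), protein- and taxon-bin rollups, and a √-transformed
  KEGG-pathway relative-abundance matrix.
- **Synthetic diel mat** — explicit-Euler forward model
  `dU/dt = k_p·I/(I+K_I)` (bicarbonate) `+ k_h` (organics)
  `− k_loss·U` (darkness), with `I(z,t) = I₀(t)·exp(−z/λ)`, emitting all
  four input table families with truth sidecars.

See `vignettes/diel-mat-tracer-methods.Rmd` for assumptions, parameter
rationale, and what the synthetic data do and do not emulate.

## Worked example

A bulk 24 h ¹³C-bicarbonate sample at δ¹³C = 187.3 ‰ against a −20 ‰
control and a 50 atom% substrate:

```r
library(matSIP)
f_s <- delta_to_atom_fraction(187.3)
f_c <- delta_to_atom_fraction(-20)
round(percent_replacement(f_s, f_c, 0.5), 3)
#> [1] 0.465
```

i.e. 0.465% of the biomass carbon derives from the added bicarbonate.

The full pipeline on the reference synthetic scenario:

```r
dir <- file.path(tempdir(), "demo")
cfg <- reference_scenario(dir, seed = 1)   # writes all input tables + truth
res <- run_pipeline(cfg, quiet = TRUE)

subset(res$profile_summary,
       treatment == "bicarbonate" & timepoint_h %in% c(8.5, 18.5, 24),
       select = c(timepoint_h, mean_replacement_pct, sd_replacement_pct,
                  fraction_below))
#>  timepoint_h mean_replacement_pct sd_replacement_pct fraction_below
#>          8.5                 2.20            0.02268         0.0443
#>         18.5                 1.23            0.00708         0.0447
#>         24.0                 2.50            0.00449         0.0414
```

Depth-averaged replacement climbs to 2.20% by dusk (8.5 h), drops to 1.23%
overnight — `diel_loss(2.20, 1.23)` ≈ 44.2%, the generator's
`1 − exp(−k_loss·10 h)` — and rebounds to 2.50% by the second noon. With
photoautotrophy confined near the surface and no transport in the forward
model, only ~4% of the tracer inventory sits below the photic boundary.

```r
subset(res$mid_calls, metabolite == "trehalose" & incubation == "bicarbonate")
#>   incubation metabolite timepoint excess_pct call
#>  bicarbonate  trehalose         4    29.7118    +
#>  bicarbonate  trehalose         6     0.0117    -
#>  bicarbonate  trehalose         8     0.0048    -

subset(res$labeled_proteins, timepoint == 8)
#>  timepoint  incubation n_labeled_proteins n_total_proteins relative_abundance
#>          8     acetate                 30             2000             0.0150
#>          8 bicarbonate                130             2000             0.0650
#>          8     glucose                103             2000             0.0515
```

The trehalose row recovers the planted diel pattern (labeled at dusk, label
turned over by dawn); the labeled-protein fractions recover the planted
5.6 / 1.5 / 5.9% within binomial sampling error at 2 000 proteins per
incubation.

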