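---
title: "Methods: ensemble modelling of the scbR/scbA butyrolactone switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble modelling of the scbR/scbA butyrolactone switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblcircuit)
```

## The model

The γ-butyrolactone (GBL) switch of *Streptomyces coelicolor* is modelled
as a deterministic mass-action reaction network in two compartments (cell
and culture medium). Eighteen species are tracked: the full-length
*scbR* and *scbA* transcripts `r` and `a` and their sense–antisense duplex
`ra`; ScbR monomer `R`, homodimer `R2` and ScbA protein `A`; intracellular
and extracellular butyrolactone `C`/`Ce` (nM); the SCB-deactivated
repressor complex `C2R2`; the hypothetical ScbA–ScbR complex `AR`; and the
operator occupancy states of O_R, O_A (free, one dimer, two dimers) and of
the hypothetical activator operator O_A′ (free, AR-bound). The full
configuration (scenario H) comprises 41 reactions governed by 51
parameters; the eight scenarios A–H switch the antisense (AS), ScbA–ScbR
complex (RA) and ScbR-as-activator (R_act) mechanisms on and off while
transcriptional interference (TI) is structural and always present.

Key modelling assumptions:

* **Elementary mass action everywhere.** Two ScbR dimers bind each
  operator sequentially with dissociation constants (K_d1, K_d7) for O_R
  and (K_d2, K_d8) for O_A; partial occupancy already represses (residual
  transcription factors `f_rep1`, `f_rep2` ≤ 1), full occupancy represses
  further. SCB binding to the dimer is collapsed into one
  second-order-in-C step with 2:1 stoichiometry (`C2R2`), the fewest extra
  species that honour the complex's composition.
* **Transcriptional interference.** Convergent RNA polymerases across the
  53-bp promoter overlap abort one another. The probability that an
  initiation at gene *i* escapes interference is
  `1 / (1 + aspect_i * f_j / k_elong)`, where `f_j` is the opposing
  promoter's occupancy-modulated initiation frequency, `aspect_i` a
  per-promoter geometry factor and `k_elong` the RNAP clearance rate of
  the shared region. This one-coupling form captures the defining
  properties — mutual, monotone in the opposing firing rate, vanishing for
  `aspect → 0` — and is isolated in `interference_escape()` so an
  alternative occlusion model can be swapped in. Truncated abortive
  transcripts are not tracked; interference only reduces full-length mRNA
  production, which is the observable.
* **Activation folds.** The R_act and RA hypotheses add surplus
  transcription channels for *scbA* proportional to `(f_Ract − 1)` (when
  one dimer occupies O_A) and `(f_RA − 1)` (when AR occupies O_A′). The
  neutral value 1 disables the channel exactly, which is what makes
  scenario-nesting equivalences (D ≡ A at `f_Ract = 1`) hold bitwise;
  sampled folds below 1 are treated as neutral rather than as repression.
* **Growth coupling.** The population follows the closed-form
  six-parameter Baranyi–Roberts model (carrying capacity `K`, inoculum
  `N0`, maximum specific growth rate `mu_max`, curvatures `v` and `m`, lag
  `lambda`). Every intracellular species is diluted at
  `mu(t) = (dN/dt)/N`; operator states gain a DNA-duplication term
  `+mu(t)·O` so gene copies per cell stay constant at one; the medium pool
  `Ce` integrates the per-cell export flux scaled by `N(t)·V_cell/V_env`.
  Growth parameters are fitted to data, not sampled, and sit outside the
  51-parameter kinetic count.
* **Units.** Intracellular molecular species are in molecules/cell, GBL
  pools in nM; the conversion (≈1.66 nM per molecule/cell at the fixed
  1 fL cell volume) is applied inside the compiled stoichiometry, so rate
  constants carry the units stated in `parameter_catalogue()`.

## Parameters and priors

The 51 parameters split into 44 *sampled*, 5 *fixed* structural constants
(compartment volumes, operator copy numbers) and 2 *derived* entries:
`k_FR = chi · k_FA`, so the heterogeneity factor χ (the *scbR*/*scbA*
promoter-strength ratio) is itself a sampled quantity, and `d_Ce = d_C`,
since internal and external SCBs degrade at the same rate. Each sampled
parameter has an independent log-normal prior specified as a median plus a
95% plausible range (`prior_from_range()`); correlations between
parameters are not modelled. The shipped table (`default_priors()`) is a
reconstructed default spanning literature-plausible ranges for
actinomycete gene expression — e.g. mRNA turnover 0.02–0.5 /min, ScbA
degradation 10⁻³–10⁻¹ /min, GBL synthesis 10⁻³–10 /min, χ 0.1–10 — wide
enough (typically two decades) that enrichment analyses can resolve
preferred regions. Every entry can be replaced via a plain-text prior
table (`read_priors()`).

## Simulation and scoring

Ensembles are drawn once per study (`sample_ensemble()`, bitwise
reproducible by seed) and the identical parameter sets are integrated
under every scenario over 60 h (3600 min) with deSolve's implicit BDF
solver at `rtol 1e-6`, `atol 1e-9`. A single full-meta-model stoichiometry
matrix is compiled for all scenarios, with mechanism flags zeroing
disabled rates: this guarantees that scenario equivalences (e.g. scenario
C with duplex rate 0 versus scenario A) hold to the last bit, and that
disabled-mechanism species are structural zeros. Solver failures and
non-physical excursions are recorded as member status — never raised — so
that downstream scoring can assign them zero likelihood; transient
negative values within −10⁻⁶ of zero are clipped.

Each member's **total log-likelihood** sums Gaussian log-densities over
all transcript target points plus one activation-threshold term, with
normalisation constants included so TLL is an absolute, comparable
quantity. Transcript profiles are compared after scaling each observable
to a maximum of 1 (configurable), which bridges simulated copy numbers and
intensity-scale target data without introducing per-member nuisance
scales. The activation threshold is extracted as the intracellular GBL
concentration at the last upward crossing of 50% unrepressed O_A — an
operational definition of the switch point, isolated in
`activation_threshold()` and documented as a design choice. The pass
criterion is strict: `TLL > −140` by default. On the synthetic study's
normalised scale this threshold admits members whose profiles track the
targets to roughly 2.5 target standard deviations per point on average;
mechanistically distant members fall thousands of log units below it, so
pass counts are small and sharply discriminating. Scenario comparison uses
the per-scenario pass counts (parametric robustness) and the
ensemble-average likelihood computed by overflow-safe log-sum-exp
(`predictive_density()`).

## Enrichment statistics

For a selected member subset (typically `TLL > threshold`),
`ks_enrichment()` runs one two-sample Kolmogorov–Smirnov test per sampled
parameter against the full ensemble, flagging significance at α/44
(strict Bonferroni). `bin_enrichment()` divides each parameter's sampled
range into 20 log-spaced bins (log-spacing matches the log-normal priors;
the count is configurable), takes expected bin probabilities from the
*empirical* full-ensemble distribution — so the test is exact under the
null even at finite n — computes `log2(observed/expected)` ratios and a
two-tailed binomial test per bin, and applies Benjamini–Hochberg control
at FDR 0.05 across each parameter's bins (Bonferroni available). Bins
with zero expected mass are merged leftwards. Growth parameters, being
fitted rather than sampled, are compared by two-sample K–S between the
initially assigned fit vectors and those of the selected members,
Bonferroni-corrected over the 6 parameters.

## The synthetic study

`synthetic_study()` generates every input the pipeline needs with known
ground truth: (a) *scbR*/*scbA* transcript targets sampled hourly over
60 h with multiplicative log-normal noise (default sd 0.1) and
uncertainties `noise_sd · value` floored at 5% of the profile maximum;
(b) 11 growth observations with 5% multiplicative noise, matching the
sparse sampling typical of such experiments; (c) the true activation
threshold with 10% uncertainty. The generating scenario is C
(TI + antisense), the configuration the analysis singles out.

The shipped true parameter set was selected from prior-predictive draws
for exhibiting the reference phenotype and then frozen: per-cell GBL
accumulates as growth dilution wanes, de-represses the operators near the
exponential-to-stationary transition (~20–22 h against a 10 h lag),
*scbA* bursts and then declines as re-synthesised ScbR floods the system.
It is a genuinely excitable trajectory, not a steady-state artefact. The
*scbR* profile shares the burst and decline but additionally shows an
early transient that is inherent to starting all species at zero with
free operators; the qualitative shape checks in the tests therefore
target the *scbA* profile. What the generator deliberately does *not*
emulate: microarray platform effects beyond multiplicative noise and a
scale factor, biomass-to-cell-count calibration, death phase, and any
correlation structure between parameters. Passing recovery tests
therefore demonstrate that the pipeline identifies a known generating
mechanism under its own noise model — not that the circuit's real
parameters are identifiable from the reference experiment.

## Numerical choices and test problem sizes

* Output grids default to hourly (61 points); the adaptive solver's
  accuracy is independent of the output grid, and the target generator
  always resolves the de-repression crossing on an internal hourly grid
  even when asked for sparser observation times.
* Growth fitting runs 40 multi-start Levenberg–Marquardt fits on
  log-transformed parameters with residuals on log₁₀ cell counts
  (multiplicative error); all fits within 5% of the best SSE form the
  confidence set from which per-member growth vectors are resampled.
  Degenerate inputs (no growth signal, fewer than 7 points) are rejected.
* The recovery acceptance test uses a 500-member ensemble with the truth
  injected, scored under scenarios C and D; the acceptance script runs
  200 members across all eight scenarios. These sizes give stable
  qualitative results (the true member ranks first by a wide margin;
  random-selection enrichment stays null) while keeping a full run in the
  minutes range on a single CPU. Scaling `n_members` up only sharpens the
  comparisons.
* SBML export is not provided; the JSON network dump
  (`network_to_json()`) carries species, stoichiometry, deparsed rate
  laws and the growth-coupling terms for external cross-validation.

## Known limitations

The literal supplementary rate-law tables of the reference analysis are
not reproduced here; the network is a faithful mass-action reconstruction
of the documented mechanisms with the reaction and parameter counts
enforced as structural constraints (41/51/44). The interference coupling
and the activation-threshold extraction rule are contract-level stand-ins,
each isolated behind a single function. Stochastic (SSA) simulation,
spatial/filament structure, explicit precursor metabolism and posterior
sampling are out of scope; the prior predictive check deliberately stops
short of Bayesian updating.
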