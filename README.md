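# gblcircuit

Ensemble modelling of the γ-butyrolactone (GBL) signalling circuit of
*Streptomyces coelicolor*.

## The scientific problem

Antibiotic production in *S. coelicolor* is switched on by diffusible
γ-butyrolactones (SCBs). The switch is implemented by just two divergently
encoded genes whose promoters overlap by 53 bp: *scbR*, a TetR-family
repressor, and *scbA*, the SCB synthase. The ScbR homodimer (R₂) represses
both genes by binding their operators (two dimers can bind each operator);
SCBs bind and deactivate R₂ (as a C₂·R₂ complex), closing a
positive-feedback loop. Because the mechanistic wiring is not fully
established, several hypotheses coexist:

* **TI** — transcriptional interference between the convergent overlapping
  promoters (structural: always present),
* **AS** — antisense interaction: the complementary transcripts form a
  fast-degrading sense–antisense duplex,
* **RA** — a ScbA–ScbR complex that sequesters the repressor and activates
  *scbA* via a hypothetical O_A′ operator,
* **R_act** — ScbR as a dual repressor/activator.

`gblcircuit` builds a unified meta-model (two compartments, 41 reactions,
51 parameters in the full configuration) in which these mechanisms can be
toggled, giving eight scenarios A–H (A = TI; B = TI+RA; C = TI+AS;
D = TI+R_act; E = TI+RA+AS; F = TI+RA+R_act; G = TI+AS+R_act; H = all).
Cellular growth enters through a six-parameter Baranyi–Roberts model
N(t): every intracellular species is diluted at the instantaneous specific
growth rate μ(t) = (dN/dt)/N, operators are replicated at the same rate,
and exported signal accumulates in the medium in proportion to N(t).

Rather than fitting a single parameter set, the package performs a **prior
predictive check**: for each of the 44 sampled parameters a log-normal
prior is elicited (median + 95% plausible range); thousands of parameter
sets are drawn and the *same* sets are simulated under every scenario over
60 h. Each member is scored by a **total log-likelihood (TLL)** — the sum
of independent Gaussian log-densities of the simulated *scbR*/*scbA*
transcript profiles and the GBL activation threshold against target
features — and a member "accommodates the data" when TLL > −140 (strict).
Scenario plausibility is compared by the number of passing members
(parametric robustness) and by the ensemble-average likelihood (predictive
density). Finally, **parameter enrichment** asks which parameter regions
are over-represented among high-TLL members: two-sample Kolmogorov–Smirnov
tests per sampled parameter with a strict Bonferroni correction (α/44),
bin-wise two-tailed binomial tests with Benjamini–Hochberg FDR control at
0.05, and two-sample K–S tests (Bonferroni α/6) for the six growth
parameters.

Because the reference transcriptomics and biomass series are not bundled,
the package ships a first-class synthetic-data generator
(`synthetic_study()`) with a known ground truth whose scenario-C dynamics
reproduce the canonical phenotype — transcripts repressed through the lag
phase, a burst near the exponential-to-stationary transition, and a
decline afterwards — so that every stage, including end-to-end parameter
recovery, is testable.

## Worked example

```r
library(gblcircuit)

build_network("H")
#> <scb_network scenario H: 41 reactions, 51 parameters, 18 species>

study <- synthetic_study(seed = 1)
#> <synthetic_study: scenario C truth, 61 transcript times, 11 growth points (seed 1)>

sim <- simulate_member(study$true_params, "C", study$true_growth)
a <- sim$trajectory[, "a"]
max(a)                                   # 4.1 molecules/cell ...
sim$times[which.max(a)] / 60             # ... peaking at 22 h
activation_threshold(sim)                # 590 nM

ens    <- sample_ensemble(default_priors(), 100, seed = 1)
simset <- run_ensemble(ens, c("C", "D"), study$true_growth,
                       extra_members = list(truth = study$true_params))
scores <- score_ensemble(simset, study$targets, threshold = -140)
rank_and_count(scores)$counts
#> C D
#> 1 0
```

The *scbA* transcript of the ground truth peaks at 22 h — after the 10 h
lag, near the growth transition — and declines to 0.20 molecules/cell by
60 h; the de-repression of its operator happens at an intracellular GBL
concentration of 590 nM. Scoring a 100-member ensemble plus the injected
truth under scenarios C and D, the true member attains TLL 259.1 and rank
1 of 101 in its generating scenario, one scenario-C member passes the
TLL > −140 criterion while scenario D has none — the antisense-containing
scenario accommodates the synthetic data better, mirroring the analysis
this package automates. `run_pipeline(run_config(...))` performs the whole
chain (sample → simulate → score → enrich) and writes scores, pass counts,
predictive densities, enrichment tables and a manifest to a run directory;
`inst/scripts/gblcircuit-cli.R` wraps it for the shell.

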