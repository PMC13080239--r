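# cardiocap

Proteome-constrained kinetic analysis of cardiac energy metabolism.

`cardiocap` is for researchers who profile the heart proteome across
experimental groups (diet models, genetic obesity models, heart-failure
models) and want to translate protein abundance changes into *functional*
energetic readouts. It ships a reduced kinetic model of cardiac central
metabolism — the catabolism of glucose, lactate, free fatty acids, ketone
bodies and branched-chain amino acids down to ATP — and instantiates it
per animal by scaling reaction Vmax values with the sample-to-control
ratio of the corresponding enzyme abundances.

## The model in brief

Internal metabolite dynamics follow mass balances over Michaelis–Menten
style lumped reactions with clamped plasma boundary species,

dC/dt = S v(C),

with conserved ATP+ADP and NAD+NADH pools and an ATP demand modeled by
the hyperbolic load law

v_ATP = load · ATP / (ATP + Km),  Km = 0.5 mM.

Per sample and plasma profile the package computes:

* **substrate utilization capacities** — the maximal steady-state uptake
  flux of each fuel class as its plasma level is titrated to
  supraphysiological concentrations,
* **maximal ATP production capacity** — the plateau of ATP production
  under a stepwise-increased load, and the **ATP/O2 ratio** there,
* **substrate contribution shares** along the load ramp (ATP-equivalents
  per fuel, from net uptake fluxes × stoichiometric yields),
* **whole-heart capacities** (per-gram × heart mass).

A statistics layer covers volcano classification (significant at FC < 0.5
or FC > 2, p < 0.05), z-score hierarchical clustering, PCA with a
deterministic sign convention, group tests gated by a Kolmogorov–Smirnov
normality check (t-test vs rank-sum), per-protein capacity marker
regression, pathway intensity shares (collagen/inflammation panels), and
a significance-masked Pearson correlation ledger. A synthetic three-group
cohort generator with planted ground truth makes the whole pipeline
testable end-to-end.

## Worked example

```r
library(cardiocap)

model  <- build_reference_model()
fasted <- plasma_profile_builtin("fasted")

scan <- atp_load_scan(model, fasted)
scan
#> <load scan> profile=fasted, 19 loads, plateau=TRUE
#>   max ATP production 45.99 mM/min, ATP/O2 5.332

round(mean(scan$scan$share_ffa), 3)
#> [1] 0.79
```

Under overnight-fasted plasma conditions the healthy reference heart
produces at most ~46 mM ATP/min per g — 4.6x its resting demand of
10 mM/min, a normal metabolic reserve — and fatty acids carry ~79% of
ATP production averaged across the whole demand ramp. Switching to the
postprandial profile drops the fatty-acid share at maximal load to ~51%,
with glucose and lactate taking over:

```r
post <- atp_load_scan(model, plasma_profile_builtin("postprandial"))
round(tail(post$scan[, c("load_rel", "share_ffa", "share_glucose", "share_lactate")], 1), 3)
#>    load_rel share_ffa share_glucose share_lactate
#> 18    4.441     0.511         0.171          0.27
```

A per-sample analysis starts from an abundance matrix and metadata:

```r
coh  <- generate_cohort(cohort_config(seed = 1))    # or read_abundance()/read_metadata()
inst <- instantiate_cohort(model, read_mapping(), coh$matrix, "control")
atp_load_scan(inst[["diet_01"]], fasted)$max_atp    # this animal's capacity
run_pipeline(coh$matrix, coh$metadata, control_group = "control",
             outdir = "results")                    # full TSV report bundle
```

A thin command-line driver with `simulate-data` and `run` subcommands is
installed at `inst/scripts/cardiocap-cli.R`.

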