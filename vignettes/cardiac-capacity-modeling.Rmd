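---
title: "Proteome-constrained modeling of cardiac energy metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-constrained modeling of cardiac energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The heart covers an enormous ATP turnover almost entirely by oxidative
metabolism, drawing flexibly on glucose, lactate, free fatty acids (NEFA),
ketone bodies and branched-chain amino acids (BCAAs). Quantitative
proteomics measures how the abundance of the enzymes and transporters of
these pathways shifts between experimental groups — but abundance tables
alone do not say what the changes *do* to the heart's energetic
capability. `cardiocap` closes that gap: it instantiates a kinetic model
of cardiac central energy metabolism for each animal from its protein
abundances, and computes functional readouts — substrate utilization
capacities, maximal ATP production capacity, and the ATP/O2 ratio — under
defined plasma nutrient profiles. A statistics layer reproduces the
analyses such studies report (volcano classification, z-score clustering,
PCA, group tests with a normality gate, marker regression, pathway shares,
and a significance-masked correlation ledger), and a synthetic cohort
generator provides ground-truth data for end-to-end validation.

## The reduced kinetic network

The shipped model (`build_reference_model()`) is a deliberately reduced
network: one lumped reaction per pathway segment rather than a
full-resolution reconstruction. It contains 17 metabolites (9 clamped
plasma species including oxygen, 8 internal) and 15 reactions:

* glucose transport + hexokinase (`glut`, insulin-stimulated),
* lumped glycolysis G6P -> 2 pyruvate (`glyc`),
* reversible monocarboxylate transport + lactate dehydrogenase (`ldh`),
* pyruvate dehydrogenase (`pdh`),
* fatty-acid uptake, activation and complete beta-oxidation of a C16
  chain (`fao`),
* ketolysis of beta-hydroxybutyrate and acetoacetate (`ket_bhb`,
  `ket_acac`),
* BCAA carrier transport (`val_t`, `leu_t`, `ile_t`) and lumped BCAA
  oxidation (`bcaa_ox`),
* the citric acid cycle per acetyl-CoA (`tca`),
* the respiratory chain with ATP synthesis at a uniform P/O of 2.5
  (`resp`), and
* a hyperbolic ATP demand `v_ATP = load * ATP / (ATP + Km)` (`atp_demand`).

Two moiety pools are conserved exactly: ATP + ADP (8 mM) and NAD + NADH
(1 mM). Redox is carried by a single NAD(H) pool; FADH2-derived reducing
equivalents are folded in as 0.6 NADH-equivalents, which makes the ATP
yields computed from the stoichiometry land at textbook values (glucose
32, C16 fatty acid 106, lactate 15, beta-hydroxybutyrate 21.5,
acetoacetate 19 ATP per molecule). These yields are *derived* from the
stoichiometric matrix at model build (`model$atp_yield`), never
hard-coded, so any edit to the shipped YAML propagates consistently.

### Regulation

Substrate competition needs feedback to be stable and realistic. The
model carries four regulatory mechanisms:

* **Acetyl-CoA inhibition** of pyruvate dehydrogenase and of the supply
  pathways (beta-oxidation, ketolysis, BCAA oxidation). This is the
  lumped analogue of the acetyl-CoA/CoA and NADH feedbacks of the
  glucose–fatty acid (Randle) cycle, and it is what makes fatty acids
  crowd out glucose oxidation when NEFA availability is high.
* **G6P inhibition** of the lumped glucose uptake step (hexokinase
  product inhibition), preventing unbounded hexose phosphate
  accumulation at rest.
* **Trans-inhibition** of the BCAA carrier by the intracellular BCAA
  pool.
* **Insulin** as a single multiplier `1 + a_ins * I / (I + K_ins)` on
  glucose-transport vmax, with `a_ins = 1`, `K_ins = 200 pM`.
  Catecholamines are accepted by every interface but act as a no-op
  multiplier in the reduced network: their plasma level is identical in
  both built-in states, so no behavior of interest depends on them.

ADP availability closes the loop on the demand side: at rest ADP is low
(~20 uM free), throttling the respiratory chain and the TCA cycle
(respiratory control); rising demand lowers ATP, raises ADP, and
accelerates oxidation.

## Plasma profiles and capacities

Two built-in profiles represent the physiological extremes
(`plasma_profile_builtin()`): an overnight-fasted state (glucose 5.8 mM,
NEFA 0.5 mM, lactate 0.8 mM, Val/Leu/Ile 0.2/0.15/0.06 mM, bhb/acac
0.08/0.04 mM, insulin 100 pM) and a postprandial state (glucose 7.8 mM,
NEFA 0.1 mM, lactate 2.0 mM, Val/Leu/Ile 0.4/0.4/0.2 mM, no ketones,
insulin 600 pM); catecholamines are 0.75 nM in both.

**ATP production capacity** (`atp_load_scan()`): the load parameter of
the hyperbolic demand law is ramped multiplicatively (default: from 10%
of the resting demand, step 1.25, at most 60 steps) with a steady-state
solve at each load, until the relative production gain over one step
falls below 1e-3. The plateau production is the maximal ATP production
capacity; O2 consumption at the plateau gives the ATP/O2 ratio. Loads are
reported both absolutely (mM/min) and in multiples of the resting demand
(`load_rest = 10 mM/min per g`, the model's calibration constant).

**Substrate contributions** (`substrate_contributions()`): each fuel's
ATP-equivalent contribution is its net uptake flux times its
stoichiometric yield. Glycolytic and oxidative glucose ATP are both
attributed to glucose; net lactate *export* therefore appears as a
negative lactate contribution (the model's resting fasted state exports
some glycolytically produced lactate and switches to net uptake at high
load — the behavior expected of a healthy heart). By linearity of the
steady-state balance, contributions sum exactly to total production.

**Substrate utilization capacity** (`substrate_capacity()`): one
substrate class is titrated to supraphysiological levels (geometric grid,
12 points, up to 50x the base concentration; 0-10 mM linear when the base
is zero) with all other plasma species fixed and an ancillary ATP demand
of 10x resting applied, so that uptake rather than demand limits. Ketone
bodies are titrated jointly at a fixed 2:1 bhb:acac ratio, the three
BCAAs jointly in their base-profile proportions — matching how such
capacities are reported as single "ketone bodies" and "bcaa" numbers.
The capacity is the maximal steady-state uptake flux over the grid.

**Whole-heart scaling** (`whole_heart_capacity()`) multiplies a per-gram
capacity by the heart mass (mg -> g), so hypertrophy can offset a
per-gram deficit.

### Calibration of the reference model

The kinetic constants of a lumped network cannot be measured directly;
they were calibrated once, against three published behaviors of healthy
control hearts, and then frozen in the shipped YAML:

1. under fasted conditions fatty acids contribute about 80% of ATP
   production across the whole load ramp (the model gives 79.0% on
   average),
2. postprandially the fatty-acid share at maximal load drops to about
   50% (model: 51.1%), with lactate and glucose taking over, and
3. the maximal fasted ATP production capacity exceeds the resting demand
   3–4-fold (model: 4.6-fold).

Km values are plausible literature-scale affinities (e.g. glucose
transport Km 8 mM, fatty-acid uptake Km 0.4 mM, respiratory-chain ADP
Km 50 uM); only vmax values were tuned. `scripts/acceptance.R` recomputes
these three behaviors from scratch.

## Numerical choices

Steady states are found by stiff integration (`deSolve::lsoda`, relative
tolerance 1e-8) to a 60-minute horizon with an explicit residual test
(`tol_ss = 1e-6` mM/min on max |dC/dt|), followed by a damped Newton
polish with a finite-difference Jacobian that pushes the residual to
~1e-10 so that flux attributions are clean. One member of each conserved
pool is eliminated from the state vector (its concentration follows from
the pool total), which keeps the Jacobian non-singular. Along
continuations (load ramps, titrations) each solve is warm-started from
the previous state and Newton is tried first, falling back to integration
when it fails; results are identical, only faster. Non-convergence is
always flagged, never silent: a failed ramp step reports the previous
plateau with a warning, a failed titration point is skipped. Negative
concentration excursions are clipped at zero and warned about beyond
-1e-9. A production *decrease* past the plateau (ATP collapse under
excessive demand) ends the ramp and is not recorded, keeping the reported
ramp non-decreasing.

## Proteome instantiation

A sample's model is the reference model with each mapped reaction's vmax
multiplied by `agg(sample intensities) / agg(control-reference
intensities)` over the reaction's protein set (`instantiate()`). Choices
and rationale:

* **Geometric mean** aggregation by default — symmetric in log space and
  robust to a single dominant subunit; `minimum` (most limiting subunit)
  and `sum` are selectable alternatives.
* **Reference = control-group mean** per protein, missing values
  ignored; proteins never observed in controls are flagged and excluded.
* **Missing data fall back to scale 1** (the reference), not to an
  imputation: in label-free proteomics "not detected" does not mean
  "absent", and a neutral fallback is the conservative choice. Every
  fallback is counted (`n_missing`) and logged.
* **Scale clipping** to [0.01, 100] with a warning guards the solver
  against artefactual ratios.
* **No normalization** is applied here; intensities are assumed
  comparably scaled across samples (true for the synthetic generator;
  real data should be normalized upstream).

The shipped protein-to-reaction mapping
(`inst/extdata/mapping/cardiac_reduced_v1_mapping.tsv`) is a curated
assignment of marker enzymes and transporters (e.g. Slc2a4/Hk2 for
glucose entry, Cpt1b/Acadvl/Hadha for beta-oxidation, respiratory complex
subunits for OXPHOS) to the reduced network's lumped reactions. It is a
small, auditable stand-in for a full-proteome assignment, not a
reconstruction of any particular study's mapping.

## The statistics layer

* `volcano()`: fold change is mean(B)/mean(A) on the linear scale;
  p-values from a two-sided Welch t-test on log2 intensities (a standard,
  variance-robust choice for label-free data). A protein is *down* iff
  FC < 0.5 and p < 0.05, *up* iff FC > 2 and p < 0.05. Raw p-values by
  default — regulated-fraction summaries are conventionally reported on
  raw p — with a Benjamini-Hochberg toggle.
* `compare_groups()`: one-sample Kolmogorov-Smirnov normality gate per
  group; Student t-test if both pass, otherwise the two-sample Wilcoxon
  rank-sum test. (The unpaired design admits no signed-rank test; the
  rank-sum test is the unpaired reading of that convention.)
* `marker_regression()` / `score_capacity_regression()`: per-protein OLS
  of a capacity on abundance (or a pathway score on capacities), slope,
  R^2, p, and significant-marker counts at raw p < 0.05.
* `pathway_score()`: a protein set's share of total intensity per sample
  (collagen and inflammation panels ship in `inst/extdata/protein_sets/`).
* `correlation_ledger()`: pairwise Pearson r with two-sided p over
  pairwise-complete observations, significance mask at alpha = 0.05, and
  a signed -1/0/+1 export.
* `zscore_cluster()` / `pca()`: features are z-scored exactly (mean 0,
  sd 1); clustering is average-linkage on Euclidean distance with the
  deterministic input-order tie-break; PCA fixes each component's sign so
  its largest-magnitude loading is positive, making runs bit-reproducible.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline consumes: a
control group (n = 4), a diet-stressed group (n = 5) and a genetically
obese group (n = 5); 2470 proteins of which ~300 are metabolic;
log-normal intensities (baseline log-normal across proteins,
multiplicative noise of 0.25 log2 units within groups). The diet plan
down-regulates OXPHOS/TCA proteins and raises the inflammation panel; the
obese plan up-regulates fatty-acid handling and collagens and
down-regulates carbohydrate transport; regulated fractions of the
metabolic subset default to 7.4%/34.6% (up/down, diet) and 10.7%/22.8%
(obese). Plasma panels shift triglycerides and Leu/Ile up and ketones
down in the obese group only; heart mass falls under diet stress and
rises with obesity; ejection fraction is a linear function of a latent
oxidative-capacity score (the geometric mean of the planted OXPHOS/TCA
scales) minus a fibrosis penalty in the obese group, plus noise — a toy
coupling for testing regressions, not a physiological claim. Everything
is reproducible from a single seed, and `generate_null()` removes every
group effect for type-I-error calibration.

Planted fold changes default to 0.4 (down) and 2.5 (up). Values exactly
at the volcano thresholds (0.5/2.0) would be unrecoverable in principle —
estimated fold changes scatter symmetrically around the true value, so
half of the planted proteins would fall on the wrong side — which would
make ground-truth recovery tests meaningless; the threshold logic itself
is instead exercised with constructed borderline cases in the test suite.

What the generator does *not* emulate: peptide-level measurement error,
intensity-dependent missingness, batch effects, isoenzyme switching, or
any real covariance between pathways beyond the planted plans. Passing
recovery tests therefore demonstrates the pipeline's correctness on data
satisfying its assumptions, not robustness to every artefact of real
label-free proteomics.

## Problem sizes and determinism

The test suite and the acceptance script run on desk-scale problems: load
ramps of ~20 steps, titration grids of 3-12 points, synthetic cohorts of
9-14 samples with 400 proteins, and 2000-replicate null calibrations for
the statistical layer; the full-size generator (2470 proteins) is the
default for interactive use. All statistics are deterministic given input
and seed; re-running a pipeline with the same configuration reproduces
every table bit-identically (checked in the test suite).

## Known limitations

* The network is lumped: no glycogen or triacylglycerol store dynamics,
  no malonyl-CoA axis, no Ca2+ or catecholamine signaling, no
  electrophysiology or mechanics.
* Oxygen is clamped (no delivery limitation); this matches the absence
  of hypoxia markers in the setting the model is designed for, but makes
  the model unsuitable for ischemia questions.
* A uniform P/O of 2.5 slightly flattens substrate differences in
  ATP/O2; the 0.6 NADH-equivalent convention for FADH2 compensates at
  the yield level.
* Vmax calibration targets whole-network behaviors, so individual lumped
  constants should not be interpreted as measured enzyme kinetics.
* The insulin multiplier with the fixed constants (a_ins = 1, K_ins =
  200 pM) raises fasted -> postprandial transport capacity by ~31%; the
  postprandial shift in the fuel mix is carried jointly by insulin,
  substrate availability and the acetyl-CoA feedback, not by insulin
  alone.
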