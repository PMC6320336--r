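---
title: "Methods: egg-composition analysis with eggomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg-composition analysis with eggomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggomics)
```

This vignette documents the statistical machinery of `eggomics`, the
assumptions behind each stage, the defaults and why they are what they
are, and the places where the design was genuinely open and a choice had
to be made.

## The data and their structure

The package targets clutch-sequence egg studies: each egg is one
biological unit nested in a female (clutch), sampled at a known laying
position, with compartment weights, a replicate-level label-free protein
intensity table per compartment (albumen, yolk), gravimetric yolk lipids
and HPLC carotenoid concentrations. Measurements are batched (MS and HPLC
separately) and run in 1–3 technical replicates. The dependence structure
is therefore two-layered — eggs within females, replicates within eggs —
with batch as a crossed nuisance factor.

## Quantitation model

Label-free intensity is proportional to abundance only within a run, so
intensities are first divided by the run's total MS signal. Identification
requires a positive intensity in at least two technical replicates of a
sample, a guard against one-off spectral matches; quantitation requires
identification in at least half of the samples of at least one biological
group (female age classes by default), so a protein expressed in only one
biological condition is retained.

Missing values in MS data are missing-not-at-random: detection probability
falls with abundance. Accordingly, missing normalised intensities are
replaced by draws from a uniform distribution bounded by the run's minimum
and 1% quantile — an explicitly *low-abundance* imputation. Numerical
conventions: the 1% quantile uses linear interpolation between order
statistics (R's default type 7; the bound contract is insensitive to this
choice); "positive" means strictly > 0, with zeros treated as
not-detected; each run consumes a private random stream derived from the
master seed and the run's rank in sorted key order, so editing one run
never perturbs draws elsewhere.

One consequence of imputing *after* normalising is that a run's values sum
to slightly more than one. Since the concentration step interprets them as
shares of the compartment's measured total protein, `eggomics` rescales
each run's values to exact proportions before multiplying by total protein
(mg) and dividing by compartment weight (g). The adjustment is below 2% at
realistic missingness and restores exact mass conservation:
per-run summed concentrations equal total protein concentration to
floating-point accuracy.

Technical replicates are collapsed to per-sample abundances by a linear
mixed model `concentration ~ 0 + sample + (1 | batch)` per protein, which
absorbs additive batch shifts; with a single batch this is identical to
the replicate mean, which is also the fallback if a fit fails.

## Standardised mixed models

All inference runs through Gaussian linear mixed models fitted by REML
(lme4) with female identity as random intercept and laying order as random
slope; protein and carotenoid models add the MS/HPLC batch as a further
random intercept. Responses are transformed first (average-rank for
protein concentrations, whose heavy tails otherwise dominate the fit; log
for carotenoids) and then standardised by **two** standard deviations.
Continuous predictors are 2-SD-standardised as well, binary predictors are
coded 0/1 (yearling/female/within-pair = 0); on this scale a binary
contrast and a 2-SD change of a continuous predictor are directly
comparable effect sizes. Inference is Wald — z = estimate/SE with normal
95% CIs — matching the asymptotic reporting convention for standardised
effects; no degrees-of-freedom correction is applied.

Open choices, and how they were resolved:

* **Rank-then-standardise order.** Standardising before ranking would be a
  no-op (ranks are invariant to monotone maps); ranking then standardising
  is the only order in which both steps matter, so that is the order used.
* **First-egg (paternity) models.** With one egg per female the female
  random intercept is unidentifiable; those models drop it (falling back
  to an ordinary linear model if no batch term remains). This is the
  fixed-effects limit of the same model, not a different estimand.
* **Singular random slopes.** If the random-slope fit is singular the
  model is refitted without the slope and flagged
  (`glance()$dropped_slope`). With a true slope variance of zero the fixed
  effects are unchanged to numerical accuracy, which the test suite
  checks.

Within each model, p-values get a single-step max-|z| correction: the
adjusted p of a term is the probability that the largest |z| among the
model's terms exceeds the observed one under their joint normal with the
fitted correlation, evaluated by Monte Carlo (10⁵ draws, fixed internal
seed, floored at the raw p). Across models, Benjamini–Hochberg FDR is
applied per term within an analysis family, and only when the family holds
at least five models; the FDR-significant set is always a subset of the
raw-significant set. Three interactions are tested a priori — female age ×
laying order, female age × clutch size, embryo sex × laying order — each
added singly to the main-effects model.

Variance partitions come from intercept-only fits with female as random
intercept: between% = 100·σ²_female/(σ²_female+σ²_residual).

## Affinity propagation

Clustering uses affinity propagation implemented directly from its message
updates: responsibilities
r(i,k) ← s(i,k) − max_{k′≠k}[a(i,k′)+s(i,k′)] and availabilities
a(i,k) ← min{0, r(k,k) + Σ_{i′∉{i,k}} max(0, r(i′,k))}
(diagonal: Σ_{i′≠k} max(0, r(i′,k))), damped with λ = 0.9, at most 1000
iterations, declared converged when the exemplar set is stable for 100.
Similarity is the Pearson correlation between log-transformed
concentration profiles; the shared exemplar preference is the q-quantile
of the off-diagonal similarities with q = 0 (the minimum), which
deliberately under-splits. Numerical choices: symmetric tie-breaking noise
of relative magnitude 10⁻¹² (seeded) is added, as exact ties can otherwise
oscillate; after convergence each cluster's exemplar is refined to the
member maximising within-cluster similarity, the canonical final step.
Albumen and yolk proteomes are clustered separately, since the two
compartments are provisioned by different maternal tissues.

Egg-level clustering uses the protein-cluster concentration sums (computed
per replicate, then averaged per sample), yolk lipids, total carotenoids
and egg weight. The similarity metric for eggs is not dictated by the
protein stage; Pearson correlation on 2-SD-standardised features was
chosen for consistency, with negative squared Euclidean distance available
(`metric = "neg_sq_euclidean"`). Features are standardised before
correlating — without this, the largest-scale feature would dominate.

Because affinity propagation is a heuristic for an NP-hard exemplar
selection problem, the package ships an exhaustive exemplar-subset search
(`ap_exhaustive()`, n ≤ 14) used in the tests: on hundreds of random small
instances the message-passing solution lands within 1% of the optimum in
well over 90% of cases, and where it falls short the reference
implementations converge to the same local solution.

## Enrichment and categorical association

Functional enrichment of protein clusters is a Monte-Carlo permutation
test: proteins are repeatedly reassigned at random to the fixed
cluster-size partition (10,000 cycles by default) and a cluster is
declared enriched for a term when its observed count of member proteins
carrying the term strictly exceeds the null 95% quantile. Multi-function
proteins count toward every term they carry. The add-one-corrected
empirical p is reported alongside; no multiplicity control is applied
across the cluster × term grid, a deliberate mirror of the quantile rule
(flagged in the output so downstream users can adjust if they wish).

Egg clusters are tested against categorised predictors with the functional
chi-square, FC = Σᵢⱼ(nᵢⱼ−nᵢ./c)²/(nᵢ./c) − Σⱼ(n.ⱼ−n/c)²/(n/c) on
(r−1)(c−1) df — a *directional* statistic that asks whether the column
variable is a noisy function of the row variable, so transposing the table
changes it. The asymptotic p is the headline; an exact permutation p
conditioning on both margins (equivalent to permuting column labels across
observations, sampled with `r2dtable`) is reported alongside and agrees to
within 0.02 on moderately sized tables. Categorisation follows fixed
schemes: laying order early = {1,3}, middle = {5,7}, late = {9,11,13};
clutch size small = 8–10, average = 11–12, large = 13–15; lay date in
half-open 4-day bins [4k, 4(k+1)) from the season start. The clutch-size
bins do not cover a 7-egg clutch even though the species lays 7–15; rather
than silently extending the scheme, `categorize()` errors on uncovered
values and accepts explicit replacement bins.

Fisher's exact test (two-sided, probability-ordering rule) handles the
2×2 paternity-by-position table; the test suite validates it against a
direct hypergeometric enumeration.

## What the synthetic generator emulates — and what it does not

`simulate_study()` reproduces the sampling design and the marginal
statistics of a wild blue tit clutch study: 39 clutches with eggs 1 and 9,
ten of them fully sampled at every second position (114 eggs; the fully
sampled clutch sizes default to a fixed multiset — 3×11, 3×12, 2×9, 2×10 —
whose odd positions contribute exactly the 36 extra eggs, making the
default dataset exactly study-sized); clutch sizes 9–15 for the
partially sampled clutches (they must contain a 9th egg); egg weight
1.16 ± 0.11 g with an 80% between-female variance share, a ±0.006 g/egg
laying-order trend of opposite sign in yearlings and adults, and a 0.094 g
adult–yearling difference at the first egg; extra-pair paternity only at
laying position 1 with probability 13/37 (≈ 12% of all assigned eggs),
with ~6 eggs left unassigned; a 12-day laying window; fair embryo sex;
1–3 technical replicates and randomised-block batch assignment; log-normal
intensities spanning ~6 orders of magnitude with logistic-in-log-intensity
missingness calibrated to 15% overall (the study only brackets this rate,
so it is an exposed parameter); carotenoids log-normal at panel means/CVs
(lutein 22.1 µg/g CV 89% … β-zeacarotene detected in 67% of eggs), driven
by one shared latent factor with species-specific loadings (0.95 for
lutein down to 0.6 for the minor carotenes) so their correlations are
positive but heterogeneous and single-factor clustering is stable; lipids
222.1 mg/g with a 20% between-female share; both declining with laying
order.

It does **not** emulate: peptide-level evidence or spectra, shared peptide
ambiguity, correlated protein co-regulation beyond the modelled fixed
effects, non-additive batch effects, heteroscedastic replicate noise, or
measurement error in compartment weights. Tests passing on this generator
therefore certify the pipeline's statistical contracts (filters, bounds,
calibration, recovery), not the behaviour of any particular real
proteome.

## Problem sizes and reproducibility

The test suite and the acceptance script deliberately run at sizes where
the statistical claims are sharp but cheap: 50 simulated datasets for the
variance-partition recovery (mean between-female share ≈ 75–80% at a
configured 0.80 — the small downward drift is the within-clutch
laying-order trend, which an intercept-only model books as residual), 200
datasets for effect recovery (mean estimate within ±0.05 of the planted
0.5, CI coverage 0.90–0.98), 1000 null fits for the 5% false-positive
check, 500 null datasets × 63 cluster-term pairs for the enrichment
type-I rate, and 100 random instances for the clustering optimality check.
Every stochastic component takes an explicit integer seed; pipeline
sub-seeds derive from one master seed by fixed offsets, and no code path
reads wall-clock entropy, so identical configurations give byte-identical
outputs.

## Known limitations

* Wald inference is asymptotic; with 39 females, CIs on variance
  components are wide and the between-female share is estimated with
  ~5-point SD at study size.
* The single-step correction conditions on the fitted correlation of the
  estimates, ignoring its own estimation error.
* Affinity propagation can converge to near-optimal rather than optimal
  partitions (by design of the heuristic), and the cluster count at q = 0
  is a conservative lower bound, not an estimate of "true" cluster number.
* The enrichment null preserves cluster sizes but not any spatial or
  abundance structure among proteins; enrichment against an
  abundance-matched null would require a different permutation scheme.
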