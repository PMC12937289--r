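---
title: "Feed evaluation methods: difference-method energy, marker-ratio digestibility, and composition-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedval)
library(dplyr)
library(tidyr)
```

`feedval` implements the biometric core of a classical swine feed-evaluation
study: estimating the digestible energy (DE) and metabolizable energy (ME) of
a protein ingredient by the difference (substitution) method, estimating the
standardized ileal digestibility (SID) of its amino acids with an
indigestible marker, summarizing batch-to-batch composition variability, and
regressing nutritional value on chemical composition to obtain prediction
equations. The package ships the printed tables of a ten-sample enzymolytic
soybean meal (ESBM) evaluation as fixtures, and a synthetic trial generator
so that every estimator can be validated by parameter recovery.

## The energy model

A total-collection metabolism trial measures, for each pig-period
observation, the feed intake $F$ (kg DM) and the gross energy (GE) of
intake, feces and urine over a 5-day window. Diet energies follow directly:

$$DE_d = \frac{GE_i - GE_f}{F}, \qquad ME_d = \frac{GE_i - GE_f - GE_u}{F}.$$

The test ingredient cannot be fed alone; it replaces a fraction $x$ (default
0.30) of the energy-supplying portion of a corn-basal diet. That portion is
97% of the basal diet (the remaining 3% — minerals, salt, premix — supplies
no energy), so the basal contribution is first corrected,
$DE_{dc} = DE_d / 0.97$, and the ingredient energy is recovered by
subtraction:

$$DE_{ing} = \frac{DE_d^{test} - DE_{dc}(1 - x)}{x}.$$

The relation is affine in the test-diet energy with slope $1/x$, which is
why measurement error on the diet is amplified about three-fold on the
ingredient — the reason the trial runs six replicate pigs per diet.

Two unit conventions interact here. The substitution fraction $x$ applies on
the as-fed formulation basis (29.10% ESBM within the 97% energy-supplying
portion, i.e. $x = 29.10/97.00 = 0.30$), so `estimate_ingredient_energy()`
computes per-observation diet energies on the DM basis (the balance
formula's natural basis), converts them to as-fed with the analyzed diet dry
matter, performs the difference step there, and finally expresses ingredient
energies on the ingredient's own dry matter. The package never clips a
negative digestibility; it warns and propagates the value.

The basal diet's corrected energy is estimated as the mean over all
basal-diet observations (a per-period option was considered and rejected:
with six basal observations spread over three periods, the overall mean
halves the variance of the correction and the crossover design blocks
period effects by construction). A useful internal consistency check —
implemented as `difference_method_consistency()` — back-solves the basal
energy from every (test diet, ingredient) pair; on the packaged reference
table all ten rows agree within 0.015 MJ/kg.

## The digestibility model

Ileal digesta cannot be collected quantitatively, so an indigestible marker
(TiO~2~ at 0.20% of the diet) converts concentrations into flows. For an
amino acid with concentration $AA_2$ in the diet and $AA_1$ in digesta (both
per kg DM), and marker concentrations $IM_2$, $IM_1$:

$$AID = \left[1 - \frac{AA_1}{AA_2}\cdot\frac{IM_2}{IM_1}\right]\times 100.$$

The ratio form makes AID invariant to any common rescaling of one sample's
concentrations — no flow measurement enters. Apparent digestibility
conflates feed-derived and endogenous amino acids; the basal endogenous loss
$IAA$ (g/kg DM intake), measured on a nitrogen-free diet via
$IAA = AA_3 (IM_4/IM_3)$, corrects it:

$$SID = AID + \frac{IAA}{AA_2}\times 100.$$

SID can legitimately exceed 100% — proline does in the reference data,
because the nitrogen-free diet itself stimulates endogenous proline
secretion beyond the basal level. The package never clips SID.

Diet amino-acid profiles are supplied the way analyzed diet tables print
them (as-fed percent plus a dry-matter row) and converted internally to
g/kg DM, the basis on which both the marker ratio and the endogenous
correction are defined.

The packaged endogenous-loss table is used verbatim by default
(`iaa_scale_factor = 1`). Its magnitudes are large relative to basal losses
reported for growing pigs elsewhere (e.g. lysine 5.09 g/kg DMI where
0.3–0.6 is typical), and several entries would imply negative undigested
flows if combined with the packaged SID values as literal truth. The factor
is therefore exposed rather than silently corrected: estimation uses the
table as given, and the question is documented rather than resolved.

## Composition summaries and prediction equations

Batch variability is summarized per analyte as mean, range and coefficient
of variation. The CV uses the population standard deviation (denominator
$n$), because only that convention reproduces the reference survey's
printed CVs (crude protein: 10.54 with $n$, 11.11 with $n-1$). The sample
convention is available via an argument.

Prediction equations regress a nutritional response (ingredient DE/ME, or
the SID of an amino acid) on DM-basis composition. Fits are ordinary least
squares with the diagnostics feed tables report: $R^2$, RMSE on residual
degrees of freedom $n - k - 1$, and the overall F-test p-value. Selection
is exhaustive best-subset up to `max_terms` predictors (default 2), ranked
by $R^2$ then RMSE — with at most a dozen candidates and two terms this is
a few dozen fits, and it implements "maximize $R^2$, minimize RMSE"
literally. A conventional forward-stepwise selector with entry/stay
thresholds of 0.15 is provided for fidelity to legacy stepwise software.
No multiple-testing adjustment is applied anywhere in the correlation or
selection machinery, matching standard practice in this literature; treat
the p-values as descriptive.

The regression unit is the ten ingredient-level means, not the sixty
pig-level observations: the reference equations are exactly reproducible on
that basis and pig-level data are not printed. One numerical convention
matters: the reproduction path carries DM-converted analytes at 2 decimals,
the precision at which analyzed-composition tables are reported. At full
precision the single-predictor DE equation's intercept comes out 21.703;
on the 2-decimal table it is 21.707 and every printed diagnostic of the
reference equations — including the tryptophan equation for total-AA SID
(intercept 31.04, slope 88.45, RMSE 6.40) — reproduces exactly at printed
precision. Package functions themselves never round internally.

```{r table11}
comp_dm <- convert_basis(feedval_fixture("table6"), "dry_matter") |>
  mutate(across(where(is.numeric) & !dm, ~ round(.x, 2)))
energy <- feedval_fixture("table9") |>
  filter(item == "ingredient", basis == "dry_matter",
         measure != "me_de_ratio") |>
  pivot_wider(id_cols = sample, names_from = measure, values_from = value) |>
  rename(ingredient_id = sample)
fit_prediction_equation(inner_join(comp_dm, energy, by = "ingredient_id"),
                        "de", "ash")
```

Two star conventions are supported for correlation tables, because the
energy and digestibility literatures annotate differently: `"p05_p01"`
(`*` for $0.01 \le p < 0.05$, `**` for $p < 0.01$) and `"p10_p05"`
(`**` for $p < 0.05$, `*` for the $0.05 \le p < 0.10$ tendency band).

## What the synthetic study emulates

`synthetic_truth()` plus the two simulators generate complete synthetic
versions of both experiments:

* **Designs.** `generate_design()` builds the replicated 11-diet × 3-period
  (22 pigs) and 10-diet × 6-period (10 pigs) incomplete Latin squares by a
  cyclic Youden construction, randomized by seeded label shuffles. The
  combinatorial invariants (no pig repeats a diet; every diet reaches six
  replicates) hold for every seed; no attempt is made to mimic any
  particular legacy randomizer.
* **Balance records.** Feed intake is 4% of initial body weight (default
  36.47 kg) per day over a 5-day window. True diet energies are composed
  forward from the ingredient truth by the exact inverse of the difference
  method, and fecal/urinary outputs follow from the energy balance.
* **Digesta records.** True AID is derived from true SID and the endogenous
  table; undigested flow plus a fixed digesta-flow fraction (0.30 kg
  digesta DM per kg DM intake — within the range implied by typical ileal
  DM digestibilities; its value cancels from the marker-ratio estimator and
  only sets concentration scale) fixes digesta concentrations.
* **Noise.** Multiplicative lognormal with unit mean, parameterized by CV:
  2% on energy outputs, 5% on digesta concentrations by default. Unit-mean
  correction keeps the estimators unbiased; zero CV switches noise off
  exactly, so zero-noise simulations invert the estimators to machine
  precision — the round-trip property the test suite pins at $10^{-9}$.

The simulator's default truth is seeded from the packaged reference tables
(composition, as-fed ingredient energies, SID of the five first-limiting
amino acids), so synthetic trials resemble the original study. Two defaults
are deliberately synthetic rather than copied: the basal diet's own energy
is back-solved from the reference treatment means (it is not printed
anywhere), and the simulator's endogenous-loss table is the packaged one
scaled by 0.1, which brings basal losses to the magnitude reported for
growing pigs in the wider literature and keeps every implied true AID in a
physiological range. Both are overridable.

What the generator does **not** emulate: pig, period or carryover effects
(optional in principle, off by design — the reference analysis blocks on
them, and the estimators here average over the balanced design), assay
failures, marker recovery drift, or any growth/gut physiology. Passing
recovery tests therefore demonstrates correctness of the estimation
arithmetic under the stated error model, not robustness to the full
messiness of animal data.

```{r recovery}
truth <- synthetic_truth()
plan <- generate_design(22, 11, 3, 6,
                        diet_ids = c("basal", paste0("esbm", 1:10)),
                        seed = 42)
rec <- simulate_balance_trial(truth, plan, noise_model(2, 2, 0, seed = 42))
est <- estimate_ingredient_energy(
  rec, truth$diet_nutrients,
  ingredient_dm = select(truth$ingredients, diet_id = ingredient_id, dm))
est_means <- est |>
  group_by(ingredient_id = diet_id) |>
  summarise(de_asfed = mean(de_ingredient_asfed))
recovery_report(est_means, select(truth$ingredients, ingredient_id, de_asfed))
```

## Degenerate inputs and numerical choices

* Division guards: zero feed intake, zero diet amino-acid concentration and
  zero marker concentration raise typed errors (`feedval_invalid_record`,
  `feedval_undefined_digestibility`, `feedval_marker_recovery_error`).
* Negative computed digestibility (fecal GE above intake, digesta
  amino-acid enrichment above the marker prediction) warns and propagates;
  nothing is floored or clipped.
* Best-subset ties are broken by fewer terms, then lexicographic term
  names, making selection fully deterministic.
* The treatment-table SEM is the pooled residual SD divided by the square
  root of the per-diet replicate count. Mixed-model letter groupings are
  out of scope; the package reports means and SEM only.
* Simulation problem sizes used in the package's own validation: the two
  study-sized designs (66 and 60 cells), 100-seed design-invariant sweeps,
  and 1000-seed recovery runs at 2% noise for the bias and
  error-propagation checks.

## Known limitations

* Correlations and equations are fitted on $n = 10$ ingredient means;
  with two-term models this leaves seven residual degrees of freedom, and
  the selection explores dozens of subsets without multiplicity control.
  The equations are descriptive summaries of this sample, not validated
  predictors.
* The endogenous-loss table's unit question (above) propagates into any
  SID computed from raw digesta records with `iaa_scale_factor = 1`.
* Per-observation apparent digestibilities cannot be checked against the
  reference study (raw pig data are unpublished); they are validated by
  simulator recovery instead.
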