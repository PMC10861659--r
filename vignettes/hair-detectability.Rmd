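---
title: "Modelling and screening the hair detectability of doping agents"
author: "trichoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and screening the hair detectability of doping agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichoScreen)
```

## The problem

Doping control relies mostly on urine and blood, which read out hours to
days of drug exposure. Hair grows at roughly one centimetre per month
and archives circulating drugs for months, so knowing *which* prohibited
substances deposit into hair — and how strongly — determines whether
hair can complement routine testing. The quantity at the centre of this
package is the **hair incorporation degree**

$$ \mathrm{degree} \;=\; \frac{C_\mathrm{hair}\ (\mathrm{pg/mg})}
   {\mathrm{AUC}_\mathrm{plasma}\ (\mathrm{ng\cdot h/mL})}, $$

the hair concentration at harvest divided by the plasma exposure that
produced it. It is only defined when the substance is detected in
*both* matrices; a censored hair value or an incalculable AUC yields
"incalculable", never zero.

The package implements three linked layers:

1. a **synthetic study generator** reproducing the statistical structure
   of a repeated oral-dose rat study across plasma, urine, faeces and
   hair, including an LC–MS-like measurement model;
2. a **semi-quantitation and PK layer** (matrix-matched calibration,
   S/N-based LOD, trapezoidal AUC, detection windows, dose linearity,
   incorporation degrees);
3. a **QSAR screening layer**: molecular descriptors, a variance
   filter, a random-forest hair-detectability classifier with a
   range-based applicability domain, and scored screening of substance
   lists.

## The embedded panel

The 17-compound model panel spans anabolic agents (S1), beta-2 agonists
(S3), hormone and metabolic modulators (S4) and diuretics/masking
agents (S5). Its hair/plasma labels encode the study outcome: 14 of 17
hair-positive, 10 detectable in both hair and plasma (the degree is
calculable only for those 10). Per-substance urine/faeces statuses were
never reported as text, so the fixture stores them as `NA` rather than
inventing figure-derived values.

```{r panel}
panel <- modelPanel()
c(hair = sum(panel$hair), both = sum(panel$hair & panel$plasma))
```

Gavage vehicles follow a logP threshold: below 3.25 the drug dissolves
in DMSO, otherwise in corn oil (the mixture's final diluent, which also
takes the exact boundary value). The fixture's logP values come from
the Open Babel predictor applied to the embedded structures.

## The disposition model

The generator is deliberately minimal: a one-compartment model with
first-order absorption, dose superposition over 7 daily gavages, and
apparent volume $V/F$:

$$ C(t) = \sum_{t_i \le t} \frac{D\,k_a}{(V/F)(k_a-k_e)}
   \left(e^{-k_e(t-t_i)} - e^{-k_a(t-t_i)}\right). $$

No compartmental model is fitted to data anywhere in the package; the
model exists only to *generate* realistic curves. Per-substance presets
give short (elimination half-life of a few hours, detectable about 12 h
post-dose), intermediate (letrozole-like) and long (clenbuterol- and
GW1516-like, detectable for weeks) plasma windows.

Key parameters (`PKParameters`):

| parameter | units | default | role |
|---|---|---|---|
| `ka` | 1/h | 1.2 | absorption rate (must exceed `ke`) |
| `ke` | 1/h | 0.25 (0.02–0.08 for long/medium presets) | elimination rate |
| `vOverF` | L/kg | 2 | apparent volume, sets the concentration scale |
| `fAbs` | – | 0.6 | absorbed fraction (mass balance) |
| `fUrine`, `fFaeces` | – | 0.3, 0.3 | fractions of the absorbed dose excreted |
| `incorporationCoeff` | (pg/mg)/(ng·h/mL) | per-substance | generating analogue of the degree |
| `bsvSigma` | – | 0.2 | between-animal lognormal SD |

**Excretion** uses an instantaneous-absorption approximation (valid for
$k_a \gg k_e$): the absorbed amount decays mono-exponentially and each
matrix receives its fixed fraction of the interval's elimination;
faeces additionally receives the unabsorbed dose fraction with a
one-day transit lag. Over an infinite horizon the books close:
urine + faeces = dose × (fAbs·(fUrine+fFaeces) + (1−fAbs)), which the
test suite verifies against numerical quadrature to 0.5%. Excreted
amounts become concentrations through fixed 24-h collection constants
(20 mL urine, 10 g faeces per rat-day).

**Hair deposition.** The harvest-day hair concentration is
`incorporationCoeff × AUC × exp(σZ − σ²/2)`. Two choices here were
genuinely open and deserve their rationale:

* *Mean-one between-animal variability.* The lognormal perturbation is
  centred so that its expectation is exactly 1. The incorporation
  coefficient is defined as the population **mean** degree (that is how
  reported group means are used to parameterize the generator), so the
  variability model must preserve the mean; an uncentred lognormal
  would silently inflate every recovered mean by $e^{\sigma^2/2}$.
* *Exposure basis.* The deposition is keyed to the day-7 AUC(0–12 h)
  of the animal's noise-free curve evaluated **by the trapezoidal rule
  on the design sampling grid** — the same estimator the downstream
  analysis applies to measured data. Reported mean degrees are
  themselves hair/trapezoid-AUC ratios, so defining the coefficient
  against the same functional keeps generator and estimator consistent;
  an exact analytic basis (`hairAucBasis = "day7_analytic"`) is exposed
  for sensitivity checks.

Between-animal variability also scales apparent clearance (through
`vOverF`); because the degree divides hair by the same animal's AUC,
clearance variability cancels from the degree — which is also why
pooling animals across dose groups is legitimate under a linear model
(the test suite asserts exact dose-invariance of noise-free degrees).

## The measurement model

Measurement operates at the internal-standard response-ratio level:

```
response = slope × concentration × (1 + CV·Z) + Normal(0, blankSD)
```

Study samples carry a 20% proportional CV (biological extracts:
extraction and matrix variability included). Calibrators are spiked
standards in pooled blank matrix and carry a smaller 5% CV; one
15-level curve (0.01–500, geometric spacing) is run per analytical
sequence and the fitted curve uses the **mean response ratio per level
across the five sequences** — this is why `CalibrationCurve` stores
mean responses. Blanks (six per analyte × matrix) supply the noise
estimate for the S/N ≥ 3 LOD rule: the LOD is the lowest calibrator
whose mean response reaches three blank SDs, with an `Inf` sentinel
when nothing qualifies.

Calibration is **unweighted** ordinary least squares; over a
four-decade range with proportional noise a 1/x² weighting would
normally be preferred and is available (`weighting = "1/x2"`), but the
default follows the unweighted convention of the semi-quantitation
method being emulated. Curves with r² < 0.99 are *flagged*, not
discarded — the 0.99 figure is treated as an observed quality level,
not a hard acceptance gate. Concentrations outside the linear range are
estimated by extrapolation and flagged; negative back-calculations
clamp to zero with the censored flag. Censoring is idempotent: a record
censored at measurement time can never be un-censored by
re-quantification.

## Numerical choices

* **AUC** is the linear trapezoid over the sampled grid with censored
  points contributing zero; no log-trapezoid, no extrapolation to
  infinity — the degree convention uses the observed day-7 AUC(0–12 h)
  only. On the design grid the trapezoid sits within 5% of the closed
  form and converges under refinement (tested).
* **Boundary contracts** are inclusive: a value exactly at the top
  calibrator is not extrapolated; a descriptor exactly at an AD
  boundary is in-domain; a screening score of exactly 0.9 is *not*
  high-confidence (the cut is strict).
* **Degenerate inputs**: `ka = ke` is rejected (the caller perturbs),
  single-point series are rejected for AUC, a single degree reports an
  undefined SEM, constant dose statistics return an undefined
  correlation, and the empty panel yields empty tables throughout.
* **Ties in the vehicle rule**: logP exactly 3.25 maps to corn oil.

## The QSAR layer

Descriptors are restricted to the families known to drive hair
incorporation — lipophilicity, ionization, and mass: Open Babel logP,
TPSA, H-bond donors/acceptors, molecular weight, molar refractivity,
SMARTS-counted ionizable groups (carboxylic acids, sulfonamides,
phenols, basic amines) and a net charge-at-pH-7.4 proxy (basic minus
acidic counts; no pKa engine is shipped). External descriptor CSVs
bypass computation bit-exactly for parity studies.

The `removeUseless` filter drops constant numeric features and
categorical features whose distinct-value percentage exceeds 99% of the
rows (identifier-like columns); it is idempotent and order-preserving.

The classifier is a 500-tree random forest with √p features per split
under the fixed seed 20240115 — sized for stability on a 17-row
training table. The score is the fraction of trees voting positive (no
probability calibration); `detectable` means score ≥ 0.5 and the 0.9
high-confidence threshold is strict. Cross-validation is **stratified**
tenfold: with only 3 negatives in 17 rows, unstratified folds would
regularly contain no negative at all. The applicability domain is the
per-feature min/max box of the training set, boundaries inclusive;
out-of-domain substances carry no score and are excluded from the
detectable/undetectable counts.

```{r qsar}
desc <- removeUseless(buildDescriptorTable(panel))
model <- trainModel(desc, setNames(panel$hair_label, panel$name))
trainingAccuracy(model)
```

## What the generator does and does not emulate

The generator reproduces: dose-proportional plasma kinetics with
realistic sampling, interval excretion with mass balance, AUC-coupled
hair deposition with between-animal spread, response-ratio measurement
with proportional and blank noise, LOD censoring, and matrix-matched
calibration structure. Passing recovery tests therefore show the
*pipeline* is unbiased and correctly propagates censoring — they do
**not** validate the disposition model against real rats. Real data
additionally contain metabolism (parent loss to metabolites, which is
why parent drugs vanish from urine), nonlinear kinetics, melanin- and
pH-dependent hair binding, cosmetic-treatment losses, and
matrix-specific recovery differences, none of which are modelled. The
reported rat concentrations themselves are not deposited and are not
reproduced; recovery is demonstrated on synthetic data only.

## Problem sizes

The shipped tests simulate single-substance studies of 30 treated
animals (three dose groups of ten, the pooled n the degree summaries
quote), 100 seeded replicates per recovery setting, 200 replicate
calibration curves, and the full 17-substance panel for screening and
smoke tests — sizes chosen to keep each property estimable with
comfortable Monte-Carlo error while the whole suite runs in a few
minutes.

## Known limitations

* The degree-recovery distribution has an irreducible seed-level spread
  set by the between-animal σ and the hair measurement CV over 30
  animals, plus the shared calibration-slope error of the hair and
  plasma curves; pooled means recover generating coefficients to a few
  percent on average, with single-study spread around 6–7%.
* Urine/faeces detection labels for individual panel substances are
  unknown (`NA`) by design; only simulated grids populate them.
* The segmental human-hair fixture carries only the handful of
  text-reported values; it supports report logic, not inference.
* Descriptor values depend on the Open Babel backend; an external
  descriptor table is the supported route to tool-parity studies.
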