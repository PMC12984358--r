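---
title: "Models and methods behind migrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind migrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrisk)
```

`migrisk` turns a migration survey — concentrations of polymer
antioxidants measured in food simulants or edible oil after contact with
tableware — into a health-risk assessment. This vignette records the
models, the conventions, the numerical choices, and the places where the
design was genuinely open, so that a user can audit every number the
package produces.

## The data and its two awkward properties

A migration survey is a `sample x analyte x medium` table of
concentrations in mg/kg (we use the standard 1 L simulant = 1 kg food
equivalence throughout, and mg/kg as the single internal unit — the
10^-3 mg/kg scaling seen in printed tables is treated purely as display
formatting, because a mixed-unit core is how silent thousand-fold errors
happen). Two properties dominate how such data must be handled:

**Left-censoring.** Many cells are non-detects (below the limit of
detection). Censoring metadata (LOD, LOQ) is stored per row, not per
analyte, because detection limits genuinely differ across media. Summary
statistics depend strongly on what you do with non-detects, and published
tables routinely mix two conventions without saying so: whole-survey
tables substitute ND -> 0 and average over all n, while prose about "the
average migration of the detected analyte" divides by the number of
detections only. `summarize_migration()` therefore refuses to guess: the
convention is a required argument (`nd_as_zero` / `detected_only`, with
the survey-table and detected-only presets also reachable as
`table2_style` / `table3_style`). The detection rate is reported
identically under both. A mostly-censored group under `nd_as_zero` has
median 0, which report layers may render as "ND".

**Strong right skew.** Group standard deviations far exceeding the means
are typical; the synthetic generator consequently models positive
concentrations as lognormal (see below).

## Deterministic frameworks

The EU single-point method assumes an adult eating 1 kg of packaged food
per day:

EDI = M × fc / BW,  fc = 1 kg/day.

The default body weight is 60.95 kg. This is a deliberate choice: the EU
convention is nominally a 60 kg adult, but the worked results this package
reproduces use 60.95 kg, and `exposure_constants(bw = 60)` restores the
plain convention with one argument.

The FDA method weights migration by what fraction of the diet actually
contacts the packaging (consumption factor CF) and by food type
(f_T over aqueous / acidic / alcoholic / fatty, summing to 1):

⟨M⟩ = Σ f_T(class) × M(simulant of class),  EDI = ⟨M⟩ × fc × CF / BW,
fc = 3 kg/day,

with the fixed class-to-simulant mapping aqueous → 10% ethanol,
alcoholic → 50% ethanol, fatty → 95% ethanol, acidic → 3% acetic acid. CF
and f_T are regulatory constants that depend on the packaging category;
the package ships an *illustrative* weights file
(`inst/extdata/fda_weights_example.yaml`, using the well-known general
polymer f_T split 0.49/0.16/0.01/0.34) but deliberately has no hidden
defaults — fabricating regulatory constants would be worse than requiring
the user to supply them. A simulant absent from the data but carrying
nonzero f_T is treated as zero migration with a warning, which makes ⟨M⟩
a lower bound in that case.

Risk is described by the margin of exposure, MOE = NOAEL / EDI. The NOAEL
is resolved per analyte by a fallback chain: a database NOAEL, else a
database RfD, else the threshold of toxicological concern (TTC) surrogate
from the Cramer structural class (I/II/III = 0.03/0.009/0.0015 mg/kg
bw/day). The target margin is 100 for database values but 1 for
TTC-derived ones: the TTC thresholds already embed inter-/intraspecies
uncertainty factors, so demanding another factor of 100 would
double-count conservatism. MOE values are rounded to integers only at the
report layer; risk-class comparisons always use the unrounded value.

Worst-case screening uses each analyte's maximum observed migration, so
the deterministic outputs are upper-bound estimates, not typical consumer
exposure. Compliance screening against specific migration limits resolves
each analyte's SML as specific limit, else recommended limit, else the
60 mg/kg default, and passes a group whose maximum is at or below the
limit (boundary inclusive).

## Probabilistic framework

The Monte Carlo model is

EDI = C × fc × F_abs × EF × ED / (LT × BW),  LT = ED × 365,

so the exposure duration ED cancels algebraically: EDI = C × fc × F_abs ×
EF / (365 × BW). The engine implements the cancelled form. That makes a
stated invariant exactly true — two models differing only in the ED
distribution produce bit-identical profiles — and we additionally draw
each parameter from its own seeded substream (base seed plus a fixed
per-parameter offset), so changing one distribution never perturbs the
draws of another. An `ed` distribution may still be supplied; it is
sampled and recorded, nothing more.

The absorption fraction comes from the octanol/water partition
coefficient:

F_abs = 1 / (1.11×10⁻⁸ × Kow + 0.41 / Kow + 1.01),  Kow = 10^log Kow,

clamped to (0, 1]. The function is unimodal with a maximum of about 0.990
near log Kow 3.78 and falls toward zero for both very hydrophilic and
very lipophilic compounds. This grouping of the three denominator terms
is the only reading of the model that yields a bounded fraction in
(0, 1], which is what an absorption fraction must be; it is nevertheless
kept as a single swappable component (`f_abs()`, or a fixed `fabs`
argument) because it is known to overestimate absorption for
high-molecular-weight antioxidants such as Irganox 1010. The hazard
quotient is HQ = EDI / RfD, elementwise across the whole profile, so the
HQ profile is exactly the EDI profile divided by the RfD — at
RfD = 1 mg/kg bw/day the two are numerically identical.

Distribution specifications support point, uniform, triangular, normal,
lognormal (parameterised by `meanlog`/`sdlog` on the natural-log scale)
and empirical (resampling) families, each with optional truncation.
Numerical choices, fixed and tested:

- **Truncation by rejection**, with a 1000-round cap; an (almost)
  zero-mass truncation region raises an error rather than looping.
  Body-weight draws are always truncated positive — a non-positive BW
  must never reach the denominator.
- **Percentiles by linear interpolation of order statistics** (R's
  quantile type 7). Commercial risk packages do not document their exact
  quantile rule, so exact reproduction of third-party percentile tables
  is not claimed; with 10,000 iterations the difference between standard
  definitions is far below sampling noise anyway.
- **Seeds are mandatory.** Every simulation takes an explicit integer
  seed and reproduces its profile bit for bit.
- The default iteration count is 10,000, the conventional size for this
  kind of dietary simulation; at that size profile means across
  independent seeds vary by well under three standard errors of the mean
  (property-tested for a lognormal C).

The per-analyte dietary concentration C can be a fitted parametric
distribution or the empirical distribution of the measured values
(non-detects as zero); whether a survey's original probabilistic
assessment resampled data or fitted a distribution is usually unstated,
so both are supported and the choice is the user's. The shipped
`exposure_example.yaml` parameter file is explicitly non-authoritative:
exposure-parameter distributions are population- and scenario-specific
inputs, not package constants. Exposure frequency EF is interpreted in
days/year (consistent with LT in days); this, too, is config-driven
rather than hard-coded.

## Method-validation arithmetic

The QC module implements the standard validation quantities around an
LC-MS/MS migration method: ordinary least-squares calibration (R² defined
as 1 − SSres/SStot, identical to the squared correlation whenever the
slope is nonzero, and 0 for a flat fit); the matrix effect
ME = (matrix slope / solvent slope − 1) × 100 with the weak/moderate/
strong classification cut at |ME| = 20 and 50 — the boundaries themselves
are assigned to the *milder* class, a convention the source descriptions
of this statistic leave open, fixed here and tested; recovery as the
replicate-mean ratio; RSD with the n−1 standard deviation; and LOD/LOQ
censoring with the LOD boundary counted as detected (inclusive lower
bound). Instrument-level determination of LOD/LOQ from signal-to-noise is
out of scope: the limits are inputs.

## The synthetic-data generator

`generator_config()` / `simulate_migration()` emulate the features of
real migration surveys that the analysis code must survive:

- class-stratified detection (Bernoulli per class x analyte; e.g. fiber
  products all-ND, starch products carrying the most analytes);
- lognormal positive concentrations (`mean_log`, `sd_log`);
- cross-analyte correlation via one shared standard-normal factor per
  cluster: log C = mean_log + sd_log·(√ρ·z_shared + √(1−ρ)·z_own), which
  induces pairwise log-scale correlation exactly ρ between cluster
  members;
- re-censoring of generated values below the LOD, so no emitted
  quantified value ever sits below its own detection limit.

`recover_parameters()` closes the loop with moment estimates (detection
rate; detected-only log mean/sd; pairwise Pearson r of log values over
jointly detected pairs), and the test suite requires recovery within
three standard errors at n = 10,000 samples. The bundled
`tableware_generator_config()` encodes an approximate survey: 10 PLA, 15
starch and 14 fiber samples, ten antioxidants, class detection
probabilities and nd-as-zero class means typical of a biodegradable
tableware survey in 95% ethanol, a five-analyte co-migration cluster
(Irganox 1310, Antioxidant JX-35, Irgafos 168, Irganox 1010, 2,4-DTBP;
ρ = 0.7, matching the 0.60–0.85 correlations such surveys report),
`sd_log = 1.2` for the heavy right skew, and `mean_log` moment-matched so
that detect_prob × E[positive] equals the class mean. These are marginal
targets only: the generator makes no claim of sample-level fidelity to
any real survey, and passing tests on synthetic data demonstrate the
*pipeline's* correctness, not that real tableware behaves this way. In
particular the generator does not model migration kinetics (temperature/
time/medium effects are labels on the rows, not mechanisms), measurement
error, or between-replicate variance.

## Worked problem sizes

The test suite and the acceptance script run: desk-scale reconstructions
of survey summary numbers (n = 8–39 samples); Monte Carlo property checks
and identities at the full 10,000 iterations; and parameter recovery on
one synthetic class of 10,000 samples x 3 analytes. These sizes make the
statistical tolerances (3 SE bands, CLT bounds) meaningful while keeping
a full run in seconds.

## Known limitations

- CF/f_T values, exposure-parameter distributions and per-analyte
  log Kow / NOAEL values are *inputs*; the shipped examples are
  documented stand-ins and the registry marks its log Kow values as
  placeholders. Conclusions drawn from the example configs are
  illustrations, not assessments.
- The worst-case deterministic screen (max migration, daily lifelong
  consumption) intentionally overestimates exposure for short-contact
  disposable tableware.
- No mixture/cumulative risk, no age-stratified populations, no
  variance-based sensitivity analysis (Sobol/Morris) — the single-analyte
  HQ and MOE are the endpoints.
- The F_abs model is empirical and likely optimistic for very large
  molecules; swap it out where compound-specific absorption data exist.
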