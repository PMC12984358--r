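# migrisk

Migration-to-exposure risk assessment for polymer antioxidants in
food-contact tableware.

Antioxidants such as Irganox 1010, Irganox 1076 and Irgafos 168 are blended
into polymers (including biodegradable PLA-, starch- and fiber-based
tableware) to prevent oxidative degradation. They are not covalently bound,
so they migrate into food — most readily into fatty foods and their
regulatory simulants (95% ethanol, edible oil). `migrisk` takes a table of
left-censored migration concentrations plus an analyte registry and answers
the questions a safety assessor asks of such a survey:

- **Descriptive layer** — group summaries (mean, SD, median, max, detection
  rate) under an *explicit* non-detect convention (ND→0 or detected-only),
  pooled means, composition shares, Pearson co-migration screens, and
  compliance screening against specific migration limits (SMLs).
- **Deterministic exposure** — the EU single-point framework,
  EDI = M·fc/BW (fc = 1 kg/day, BW = 60.95 kg by default), and the FDA
  framework, EDI = ⟨M⟩·fc·CF/BW with fc = 3 kg/day and the food-type
  weighted migration ⟨M⟩ = Σ f_T·M(simulant); risk is described by the
  margin of exposure MOE = NOAEL/EDI against a target of 100 for
  database NOAELs and 1 for NOAELs taken from the threshold of
  toxicological concern (TTC: Cramer class I/II/III =
  0.03/0.009/0.0015 mg/kg bw/day).
- **Probabilistic exposure** — a seeded Monte Carlo engine for
  EDI = C·fc·F_abs·EF·ED/(LT·BW) with LT = ED·365 (so ED cancels
  analytically), a gastrointestinal absorption fraction
  F_abs = 1/(1.11·10⁻⁸·Kow + 0.41/Kow + 1.01) derived from log Kow, and
  HQ = EDI/RfD; profiles report the mean, max and P5–P99 percentiles.
- **Synthetic data** — a generator for class-stratified, left-censored,
  lognormal, cluster-correlated migration surveys, so the whole pipeline is
  testable end-to-end with known ground truth.
- **Method validation arithmetic** — calibration fits, matrix effect,
  recovery, RSD and LOD/LOQ censoring.

Internals are base R; results come back as plain data frames, and the Monte
Carlo simulation as a classed model object with `print`, `summary`,
`quantile`, `plot` and `as.data.frame` methods.

## Worked example

Eight representative tableware samples migrated into soybean oil, six
antioxidants monitored (bundled data set):

```r
library(migrisk)

reg <- read_registry(system.file("extdata", "antioxidants.yaml",
                                 package = "migrisk"))
oil <- read_measurements(system.file("extdata", "soybean_oil_migration.csv",
                                     package = "migrisk"), reg)

s <- summarize_migration(oil, convention = "detected_only")
s[s$analyte_id == "irganox_1010",
  c("analyte_id", "n", "n_detected", "mean", "max", "detection_rate")]
#>     analyte_id n n_detected      mean    max detection_rate
#> 4 irganox_1010 8          7 0.3431429 0.6037           87.5
```

Irganox 1010 was detected in 7 of 8 samples (87.5 %) with a detected-only
mean of 0.343 mg/kg and a worst case of 0.604 mg/kg — well below its
default SML of 60 mg/kg (`sml_screen(s, reg)` reports a margin of
59.4 mg/kg), but the dominant contributor to total migration.

Deterministic worst-case risk for its degradation product 2,4-DTBP in 95 %
ethanol (max migration 0.3708 mg/kg, TTC class I):

```r
res <- moe(noael = ttc_rfd("I"), edi = edi_eu(0.3708), noael_source = "ttc")
c(edi = edi_eu(0.3708), moe = res$moe_report, class = res$risk_class)
#>                  edi                  moe                class
#> "0.0060836751435603"                  "5"                "low"
```

An MOE of 5 against the TTC target margin of 1: low risk, but the smallest
margin in the survey. A probabilistic view of the same exposure:

```r
m <- mc_exposure(
  c_spec  = dist_spec("empirical",
                      values = ifelse(oil$censored, 0,
                                      oil$concentration_mg_per_kg)[
                        oil$analyte_id == "irganox_1010"]),
  fc_spec = dist_spec("triangular", min = 0.5, mode = 1, max = 2),
  ef_spec = dist_spec("point", value = 350),
  bw_spec = dist_spec("normal", mean = 60.95, sd = 10,
                      truncation = c(40, 120)),
  log_kow = 4.9, rfd = 0.009, n_iter = 10000, seed = 1)
m
#> Monte Carlo exposure simulation (10000 iterations, seed 1)
#>   F_abs = 0.9892, RfD = 0.009 mg/kg bw/day
#>   EDI in mg/kg bw/day; HQ unitless:
#>        mean p5      p50     p75     p90     p95     p99     max
#> edi 0.00559  0 0.005161 0.00811 0.01139 0.01354 0.01724 0.02563
#> hq  0.62110  0 0.573500 0.90120 1.26500 1.50500 1.91500 2.84700
#>   HQ >= 1 from the P90 percentile upward
```

Read: under these (illustrative) exposure parameter distributions the
hazard quotient stays below 1 for a median consumer but exceeds 1 from the
90th percentile upward — the classic pattern where a deterministic screen
says "low risk" while the probabilistic tail flags high-exposure consumers.

`run_pipeline()` chains all stages (summaries → SML screen → EU → FDA →
Monte Carlo) and writes a delimited-text report bundle plus a JSON manifest
recording seed and conventions, reproducible file-for-file.

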