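# cardiomiR

Plasma miRNA screening, cardiac energetics and survival analysis for
myocardial-infarction cohorts.

## What it does

Heart failure after myocardial infarction (MI) needs non-invasive
markers. This package implements, end to end, a clinical study design
that profiles plasma miRNA on single-channel microarrays in four groups
of 10 patients — NHF (normal cardiac function, control), AMNHF (acute MI
without heart failure), AMHF (acute MI with heart failure) and OMHF
(heart failure after an old MI) — and asks which miRNAs separate each
case group from control, how severe the heart failure is, and whether
target-gene expression predicts survival. It is aimed at analysts who
want the published screening protocol as tested, reusable code.

Three analysis stages, plus a simulator:

* **Preprocessing and differential screen** — technical-replicate
  averaging, an inclusive intensity floor at 50 fluorescence units (a
  miRNA must reach 50 in *every* sample), per-sample median
  normalization; then, per miRNA, data-driven test selection
  (Shapiro–Wilk + Brown–Forsythe choosing Student's *t* / Welch's *t* /
  ANOVA / Welch ANOVA), linear fold change FC = mean(case)/mean(NHF),
  volcano coordinates (FC, −log₁₀ p), the strict significance rule
  (FC > 1.5 or FC < 1/1.5, **and** p < .05), and top-5 ranking tables
  per direction.
* **Cardiac energetics** — per-patient indices from echocardiography:
  LVEF = (LVEDV − LVESV)/LVEDV × 100; cube-formula ventricular mass
  LVM = 0.8 × 1.4 × [(LVIDd + IVS + PWTs)³ − LVIDd³] + 0.6; body
  surface area BSA = 0.0061·height + 0.0128·weight − 0.1529; the mass
  index LVM/BSA; circumferential end-systolic wall stress
  cESS = SBP·a²(1 + b²/c²)/(b² − a²) with a = LVIDs/2, b = a + PWTs,
  c = a + PWTs/2; and myocardial energy expenditure
  MEE = cESS × LVET × LVSV × HR × 4.3×10⁻⁷, the heart-failure-degree
  index.
* **Survival** — median split on target-gene expression, hand-written
  Kaplan–Meier product-limit curves per stratum, a two-group log-rank
  test and median overall survival.
* **Synthetic cohorts** — `simulateExpression()` plants the 30
  published (miRNA, comparison, fold-change) effects — miR-320 and
  miR-204 down-regulated in every comparison — into log-normal-noise
  intensity matrices with known ground truth; companion generators
  produce echo records, survival records and cell-viability (OD)
  trajectories. Every stage is testable without any data download.

## Worked example

```r
library(cardiomiR)

sim <- simulateExpression(SimConfig(seed = 1))   # 4 x 10 patients, noise CV 0.15
pre <- preprocess(sim$experiment)                # floor 50 + median normalization
#> filterFloor: 309 of 325 miRNAs at or above 50 in all samples
res <- screenMirnas(pre, control = "NHF", case = "AMNHF")
topTable(res)$down[, c("mirna", "fold_change", "p_value")]
#>            mirna fold_change  p_value
#> 1 hsa-miR-20b-3p       0.524 4.91e-09
#> 2 hsa-miR-299-5p       0.344 1.06e-08
#> 3 hsa-miR-767-5p       0.568 5.80e-07
#> 4    hsa-miR-204       0.696 4.23e-05
#> 5    hsa-miR-320       0.738 5.30e-04
```

All five recovered down-regulated miRNAs are the planted ones; the
estimated fold changes scatter around their planted values (miR-320 was
planted at 0.765, miR-204 at 0.643) because each group has only 10
patients. With `noiseCV = 0` the screen returns the planted tables
verbatim. The survival stage, on a cohort with a planted hazard ratio
of 3 against high expressors:

```r
sv <- survivalByExpression(
  simulateSurvival(n = 30, hazard_ratio = 3, censor_rate = 0.2, seed = 1))
sv$logrank$p_value   # 0.000506 — high-expression stratum dies faster
sv$median_os         # high 1.93 vs low 11.7 follow-up units
```

`runPipeline(outdir, config = SimConfig(seed = 1))` chains every stage
(three screens, energetics, survival) and writes all tables plus a JSON
manifest; the same seed reproduces every output byte-for-byte.

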