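# mcrscreen

Screening-level cumulative risk assessment for chemical mixtures in
drinking-water sources.

Environmental surveys routinely find dozens of chemicals in a single
ground-water sample. Risk managers then face a triage question: does the
combined toxicity of the mixture warrant a full cumulative risk assessment
(CRA), or is one chemical so dominant that a chemical-by-chemical review is
enough? `mcrscreen` implements the standard tier-0 screening arithmetic for
that question, for toxicologists and exposure scientists working with
sample-by-analyte monitoring tables.

## The statistics

For each chemical *i* in a sample, the **hazard quotient** normalises the
dose by the chemical's permitted dose (PD — an RfD, PAD, MRL, TDI, or
MCL-derived value):

```
HQ_i = dose_i / PD_i,    dose_i = C_i × IR × f_abs / BW
```

with water concentration `C_i` (mg/L), intake rate `IR` (2 L/day by
default), absorption fraction `f_abs` (1) and body weight `BW` (60 kg).
Under dose additivity the mixture's cumulative exposure is the **hazard
index** `HI = Σ HQ_i`, the largest single contribution is `MHQ = max HQ_i`,
and the **maximum cumulative ratio** is

```
MCR = HI / MHQ,    1 ≤ MCR ≤ n.
```

`MCR` near 1 means one chemical carries the mixture's predicted toxicity;
an MCR of 5 means a single-chemical assessment would miss
`1 − 1/MCR = 80%` of the HI. Because monitoring data are heavily censored,
every quantity is computed under two non-detect treatments: **case 1**
(ND = 0) and **case 2** (ND = DL/√2, the usual substitution for lognormal
data).

Around that core the package provides the full screening pipeline: a
packaged permitted-dose registry (115 ground-water contaminants with
provenance, metabolite→parent fallback, and an RfC→oral conversion for
chloromethane), mean-HQ data-reduction rules (drop samples missing any
top-k chemical or with fewer than 5 detects), HI-centile subgroup
summaries, Wilcoxon comparisons, Kendall trend tests (per-mixture and on
grouped medians), and a calibrated synthetic ground-water cohort generator
for testing everything end to end.

## Worked example

```r
library(mcrscreen)

# a mixture summarised by its six leading mean HQs
mix <- evaluate_mixture(c(Arsenic = 0.362, Fluoride = 0.217, Uranium = 0.098,
                          Lead = 0.059, Lithium = 0.040, Strontium = 0.040))
mix$hi   # 0.816
mix$mcr  # 2.254
missed_fraction(mix$mcr)  # 0.556: a single-chemical review misses 56% of the HI

# a full synthetic cohort, screened and analysed
cfg     <- groundwater_config(n_samples = 618, seed = 42)
cohort  <- simulate_cohort(cfg)
reg     <- config_pd_registry(cfg)
analysis <- run_full_analysis(cohort, reg)
analysis
```

```
== MCR cohort screening analysis ==
Samples: 618 in -> 565 retained (53 missing top-3 chemicals, 0 with < 5 detects)
case1: HI 0.088-19.6 (mean 0.878); MCR 1.02-6.38 (mean 2.35); HI >= 1 in 23.5% of mixtures
  Kendall tau(HI, MCR) = -0.4105 (p = 3.26e-48)
case2: HI 0.33-19.7 (mean 1.05); MCR 1.03-7.23 (mean 3.14); HI >= 1 in 32.2% of mixtures
  Kendall tau(HI, MCR) = -0.5873 (p = 9.09e-97)
Top contributors to mean HI:
  1. arsenic_analogue  mean HQ 0.380  cumulative 36%
  ...
  6. strontium_analogue  mean HQ 0.041  cumulative 78%
```

Reading this: about a quarter to a third of the simulated wells exceed the
protective level (HI ≥ 1) depending on the censoring treatment; six
analytes carry ~78% of the cohort's mean HI; and MCR falls as HI rises
(negative Kendall τ), i.e. the most toxic mixtures are the ones dominated
by a single chemical — the ones least in need of a full CRA.
`tidy(analysis)` returns the HI-centile subgroup table (typical mixtures
at the median have mean MCR ≈ 2.7–3.2, upper-bound mixtures ≈ 1.2),
`glance(analysis)` a one-row-per-case summary, and `autoplot()` the MCR-HI
scatter. `run_simulate()` / `run_screen()` / `run_analyze()` (or
`inst/exec/mcrtool.R`) drive the same pipeline over CSV files.

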