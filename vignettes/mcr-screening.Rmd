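---
title: "Screening chemical mixtures with the maximum cumulative ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chemical mixtures with the maximum cumulative ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrscreen)
```

## The screening model

Cumulative risk assessments are expensive; the maximum cumulative ratio
(MCR) is a cheap triage statistic for deciding when one is needed. For a
water sample containing chemicals $i = 1, \dots, n$, each chemical's
exposure is normalised by its permitted dose $PD_i$ — the chronic daily
dose below which non-carcinogenic effects are not expected:

$$HQ_i = \frac{C_i \cdot IR \cdot f_{abs}}{BW \cdot PD_i}, \qquad
HI = \sum_i HQ_i, \qquad MCR = \frac{HI}{\max_i HQ_i}.$$

Under dose additivity $MCR$ is bounded by 1 and the number of components
with a nonzero HQ. It measures how much of the cumulative hazard a
single-chemical assessment would capture: the missed share is $1 - 1/MCR$
(80% at MCR 5, 20% at MCR 1.25), and MCR below 2 means one compound alone
provides the majority of the HI.

The screening assumptions are deliberately conservative and fixed by
`exposure_assumptions()`: 2 L/day of untreated source water, 100% oral
absorption, 60 kg body weight. They are screening conventions, not
estimates of actual exposure; samples taken before treatment overstate
what people drink. Dose additivity itself is a tier-0 assumption that a
later assessment tier would revisit chemical class by chemical class.

## Permitted doses

The packaged registry (`default_pd_registry()`) carries 115 ground-water
contaminants: for each, the PD in mg/kg/day, an integer source code
recording provenance, and the basis (RfD, PAD, MRL, MCL-derived, TDI).
Three choices deserve comment.

* **Route extrapolation.** Chloromethane has an inhalation reference
  concentration (0.09 mg/m³) but no oral RfD; `rfc_to_oral_pd()` converts
  it assuming 20 m³/day breathed, 40% lung clearance and 60 kg body
  weight, giving 0.012 mg/kg/day (tabulated rounded to 0.01). The
  function returns the unrounded value; rounding is presentation.
* **Metabolites.** Degradates without their own PD are assumed to carry
  the parent compound's toxicity; `lookup_pd()` falls back through the
  packaged metabolite→parent map. A metabolite with its own tabulated PD
  (e.g. the aldicarb sulfoxide entry) uses it directly — the printed value
  takes precedence over the inheritance rule.
* **Plausibility flags.** Two tabulated values (fluoride 60, natural
  uranium 30 mg/kg/day) are orders of magnitude above the corresponding
  authoritative reference values. The registry reproduces them verbatim —
  faithfulness first — but reports everything above a configurable
  ceiling (default 10 mg/kg/day) through a warning channel rather than
  silently "correcting" anything. Absence of a PD is a modelled outcome,
  not an error: such analytes simply contribute nothing to HI, which is
  defensible because in the motivating survey they are either essential
  elements or occur in under 2% of samples.

## Censored observations

Ground-water panels are dominated by non-detects. Every statistic is
therefore computed twice: **case 1** treats NDs as absent (concentration
0) and **case 2** substitutes $DL/\sqrt{2}$, the standard imputation for
lognormally distributed concentrations (and less biased than $DL/2$ for
such data). Case 2 dominates case 1 elementwise by construction, so the
pair brackets the influence of the censored mass. Under case 2 a
non-detect lacking a recorded detection limit cannot be imputed; it is
dropped with a warning. A detected concentration reported below its DL is
used as reported. Mixture size $n$ is case-dependent: the number of
detects under case 1 (only detects carry exposure) and the number of
analytes under case 2.

## Data reduction

Because no sample is assayed for every analyte, samples missing a known
major contributor would bias the MCR distribution. `mcrscreen` first ranks
chemicals by their mean HQ across mixtures
(`rank_chemicals_by_mean_hq()`, computed under case 2 so censored analytes
still count), then `apply_exclusion_criteria()` drops samples for which
any of the top-*k* chemicals was unmeasured (*k* = 3 by default; *k* = 6
gives a stricter subset) and afterwards any sample with fewer than 5
detected components, logging which rule removed each sample. Two open
conventions had to be fixed:

* The ranking that *defines* the top-*k* set is computed on the full
  input cohort — the exclusion needs a ranking before any reduction
  exists — while the reported top-contributor table is recomputed on the
  final retained set, which is the set the published style of summary
  describes.
* The mean HQ averages over the samples in which the chemical was
  measured, not over all samples; the alternative denominator is exposed
  as `over = "all"`. Measured-only avoids penalising sparsely assayed
  chemicals, at the cost of favouring analytes from small panels.

## Cohort statistics

`run_full_analysis()` assembles the screening report: overall HI/MCR
summaries, the split at HI = 1 (a mixture exactly at the threshold counts
as "above"; the convention is arbitrary but fixed and documented),
HI-centile subgroups, Kendall trend tests and Wilcoxon comparisons.

**Centile convention.** The centile of the rank-$r$ mixture out of $N$ is
$100\,r/N$, and a band $(low, high]$ is half-open; ties in HI are ordered
by sample id so membership is deterministic. With $N = 618$ the 49–51st
band holds 12–13 mixtures under this convention; analyses using a
different (unstated) convention report 11. No convention we tried
reproduces exactly 11, so tests assert a band rather than exact
membership.

**Trend tests.** `kendall_trend()` is Kendall's $\tau_b$ (tie-corrected;
HI, MCR and count data are full of ties) with a two-sided p-value, exact
for small tie-free inputs. When one variable is constant $\tau_b$ is
undefined; the package reports $\tau = 0$, $p = 1$ as the no-trend
convention. `grouped_median_trend()` first groups mixtures by size, drops
groups with fewer than 5 members so each median is stable, and tests the
(size, median) pairs. `wilcoxon_compare()` is the unpaired two-sided
rank-sum test (exact for small tie-free samples, normal approximation
with tie correction otherwise), with a `paired` option for per-sample
case-1-vs-case-2 comparisons; the unpaired form is the default because
the subgroup comparisons it serves have unequal sizes. No
multiple-testing correction is applied; p-values are reported raw.

## The synthetic cohort generator

The pipeline is exercised against synthetic cohorts
(`groundwater_config()` + `simulate_cohort()`) that emulate the structure
of a national ground-water survey without using any survey values. Per
sample and analyte: panel membership is Bernoulli(`panel_prob`) —
optionally drawn per method block, since surveys assay analytes in method
groups — presence is Bernoulli(`occurrence_prob`), a present analyte's
concentration is lognormal(`log_gm`, `log_gsd`), and detection is a hard
threshold at the detection limit (no measurement-error model; the
simplest mechanism producing realistic censoring rates).

The default panel has 110 analytes: six dominant inorganic-like analytes
and three background archetypes (22 trace-element-like, 30
pesticide-like, 52 VOC-like). Calibration was done once, coarsely, and
frozen:

* the six dominant meanlogs were solved (by root-finding on the closed
  form of the expected case-2 concentration, imputation included) so
  their mean case-2 HQs hit 0.362, 0.217, 0.098, 0.059, 0.040, 0.040 —
  the dominance pattern in which six chemicals carry roughly three
  quarters of the cohort mean HI;
* background detection limits, permitted doses and occurrence rates were
  tuned so a sample averages about 16 detects against 82 non-detects on a
  ~98-analyte panel, and so that roughly a quarter (case 1) to a third
  (case 2) of mixtures reach HI > 1.

With those frozen constants a 618-sample cohort reproduces the field's
qualitative laws: MCR declines as HI rises in both cases (τ < 0), the
high-HI centile bands have mean MCR near 1 while the median band sits near
2.5–3, and case 2 exceeds case 1 in HI for every sample. What passing
these tests does **not** show: the generator has no spatial correlation
between wells, no correlated co-occurrence of chemicals beyond the shared
dominance structure, no seasonality, and per-analyte detection limits are
stand-ins — so agreement on real survey data, where such structure
exists, is not guaranteed, and the generator's concentrations must never
be mistaken for measured values.

## Numerical choices and degenerate inputs

* Units are fixed: mg/L for water, mg/kg/day for doses; µg/L inputs must
  be converted at the I/O boundary.
* An all-zero HQ vector (possible under case 1) has HI = 0 and an
  undefined MCR, reported as `NA` and excluded from MCR summaries with a
  logged count — never coerced to 1.
* Ties in the maximum HQ leave HI and MCR unchanged; the reported top
  chemical is the alphabetically first among the tied, for determinism.
* `simulate_cohort()` restores the caller's RNG state, so cohorts are
  pure functions of their seed.
* Problem sizes in the test-suite simulations (cohorts of 40–618 samples,
  10⁴ random mixtures for the bound checks) were chosen as the smallest
  sizes at which the stochastic bands are stable across seeds.

## Limitations

Tier-0 screening only: no dose-additivity refinements, no interaction or
relative-potency models, no carcinogenic endpoints, no treatment
modelling, single exposure route. The centile-membership and
mean-HQ-denominator conventions above are choices among defensible
alternatives; both are configurable where they matter.
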