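---
title: "Actual and normative PHC costing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actual and normative PHC costing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(phccostgap)
library(dplyr)
```

`phccostgap` estimates, for a three-level primary health care (PHC) network
— dispensaries, health centers, and primary (sub-county) hospitals — the
actual recurrent cost of service delivery, the normative cost of delivering
the full service package at universal coverage, and the per-capita resource
gap between them, together with one-way sensitivity analysis. This vignette
is the package's account of the methods: the model in each stage, the
parameters that matter, the design choices made where the design was open,
and what the synthetic-data validation does and does not demonstrate.

## Actual costs

### Cost allocation by weighted service volume

Each sampled facility contributes one facility-year of recurrent cost in
four categories — clinical labor, drugs, medical supplies, and other
indirect costs, all in USD/year — and two service volumes, outpatient (OP)
visits and inpatient (IP) bed-days. Capital and above-facility costs are out
of scope. To compare and allocate across facilities that mix outpatient and
inpatient care, bed-days are converted to outpatient-visit equivalents with
WHO-CHOICE relative cost weights: an inpatient day is weighted 432 cost
units at every level, an outpatient visit 126 in hospitals, 111 in health
centers, and 90 in dispensaries. The weighted volume is

$$W = \mathrm{OP} + \mathrm{IP} \cdot \frac{432}{w_{\text{level}}},$$

the unit cost is total cost divided by $W$, outpatient cost is
$\mathrm{OP}$ times the unit cost, and inpatient cost is the remainder —
so the two components always reconstruct the total exactly (the conservation
property tested on 1,000 random facilities).

*Weight orientation.* 432 is the inpatient-day weight and 126/111/90 the
outpatient-visit weight: the ratio expresses the cost of an inpatient day
relative to an outpatient visit. We confirmed this orientation numerically —
with the alternative orientation the single-hospital caseloads below would
be off by an order of magnitude.

### Caseloads and working days

Daily caseload per clinical staff is volume divided by
`clinical_staff × working_days`. The year length of a clinical roster is not
a physical constant; we default to **264 working days** (22 days × 12
months), which reproduces the reference single-hospital caseloads (3.2, 2.5,
2.8/3.0, 2.5, 1.7/2.1 services/staff/day) exactly after rounding in five of
seven sub-counties, with residual ±0.1 discrepancies attributable to
rounding upstream of the published means. It is a configuration parameter
(`phc_config(working_days_per_year = )`), not a constant.

### Overhead rates

The overhead rate per level is pooled: total indirect cost divided by total
cost, summed over all sampled facilities at the level (a ratio of sums).
The mean of per-facility ratios is a different estimator — a facility with
costs (60, 25, 5, 10) and one with (0, 0, 0, 100) pool to 0.55, while the
mean of their ratios is degenerate — and pooling is the natural estimator of
a level-wide loading factor. Published per-level percentage breakdowns are
typically means of facility ratios and are treated as reporting-only.

## Extrapolation to the facility universe

Sampled costs scale to the whole network in three steps: per level, the
capture fraction is sampled OP visits over universe OP visits (from routine
KHIS-style aggregates) and the extrapolated cost is sampled cost divided by
that fraction; levels are summed to the sub-county network total; dividing
by population gives the actual cost per capita. The national roll-up pools
all sampled facilities as one sample against national universe totals —
it does not average sub-county per-capita values.

Three deliberate choices:

* **Outpatient volumes only**, at every level, drive the capture fraction —
  even for hospitals with heavy inpatient loads. This is faithful to the
  study design the package implements; it assumes the sample is
  representative of each level's outpatient unit cost, and is a documented
  methodological caveat rather than something the package corrects.
* **Raw counts, never rounded percentages.** A printed capture percentage
  (say 69%) does not reproduce the printed extrapolated cost; the
  unrounded ratio does. Capture fractions are always computed from service
  counts.
* **Clamping.** Noisy routine data can report a universe OP total below the
  sampled total; the frame constructor warns and clamps the universe up to
  the sample, so extrapolation never shrinks sampled costs. Facilities with
  zero outpatient visits keep their costs in the totals but contribute
  nothing to capture fractions, and are flagged.

The national population used for the national per-capita is an input
(`national_rollup(..., national_population = )`), not a built-in constant.

## Normative costs

Normative costs are built bottom-up from standard treatment protocols
(STPs). Each STP lists resource lines — drugs, diagnostics, reagents
(quantity × unit cost per encounter) and clinical time (minutes per
encounter × salary per minute by cadre) — plus encounters per episode and a
need rate (incidence, prevalence, or utilization per person-year).

$$c_{\text{direct}} = e \cdot \Big( \sum_{\text{non-HR}} q_i u_i +
\frac{\sum_{\text{HR}} m_j s_j}{1 - s_{\text{nc}}} \Big)$$

with $e$ encounters per episode and $s_{\text{nc}}$ the non-clinical time
share. Key choices:

* **Non-clinical uplift is a divisor.** "30% of clinical time is
  non-clinical" means 30% of *paid* time is non-contact, so contact minutes
  gross up by $1/(1-0.30) \approx 1.43$, not by 1.3. The share is a
  parameter (`nonclinical_share`, default 0.30, valid in $[0,1)$); only
  clinical-time lines are uplifted — diagnostics and consumables are not.
* **Overhead loading is a gross-up.** With the overhead rate defined as
  indirect ÷ total, the loaded cost is $c_{\text{direct}}/(1-r)$, so the
  indirect share of the loaded cost equals $r$ exactly. The multiplicative
  alternative $c(1+r)$ is selectable (`apply_overhead(method = "markup")`)
  for sensitivity comparisons but is inconsistent with $r$'s definition.
* **Encounters multiply everything by default.** A per-line `per_episode`
  flag exempts resources issued once per episode (e.g. a confirmatory test)
  from the encounter multiplier.
* **Level shares default to uniform** over the levels offering a service;
  a share matrix can be supplied. With equal overhead rates across levels
  the shares cancel (tested).
* **Aggregation to KHIS groups** uses frequency-weighted means of member
  unit costs, with population-in-need as the frequency.

Population in need is `population × need_rate` at fixed 100% coverage — the
normative scenario is the maximum expected service volume, deliberately
aspirational. Per-capita normative cost is therefore invariant to population
size (it cancels), which is also why the population perturbation is inert
for the normative per-capita in sensitivity analysis.

The real national STP catalog behind published normative figures is not
public; the package ships the schema, a validator (`stp_catalog()`), a
small synthetic example under `inst/extdata` (files suffixed `_synthetic`),
and a catalog generator. National normative per-capita values can be
recomputed only when a catalog is supplied; they are validated here by the
generator-recovery oracle instead.

## Gap and sensitivity

`resource_gap()` returns `gap = normative − actual` per capita and the
required-investment multiple `normative/actual`, reported as e.g.
"1.6 times". One-way sensitivity (`one_way()`) perturbs, by default,
clinical labor ±20%, drugs ±30%, medical supplies ±20%, indirect costs
±30%, and population ±5% — one at a time for the tornado bars, and jointly
for best/worst scenarios. Because per-capita cost divides by population, the
worst case pairs high costs with low population (and the best case the
reverse); this pairing maximizes the scenario range. Perturbations scale
aggregate category totals deterministically — there is no Monte-Carlo layer,
matching the one-way design. Every one-way output provably lies within
[best, worst] for models monotone in each parameter, and this is asserted as
an invariant on both the actual and normative models.

## Reporting conventions

Computation is in USD throughout; KES-denominated ledgers convert once at
ingest (default 101.99 KES/USD). Reported values round half away from zero
(`round_half_up()`: 1.568 → 1.6), one decimal for per-capita values and
ratios, integers for totals; `write_results()` writes unrounded columns
alongside `_reported` companions. Base R's banker's rounding would turn
0.25 into 0.2 and disagree with the reference tables.

## The synthetic-world generator

`generate_world()` creates, per sub-county, the *entire* facility universe:
populations uniform on 90k–200k; per level, facility counts (default
20/8/2), OP volumes uniform over the observed level ranges, inpatient
bed-days for hospitals and (rarely) health centers, and dispensary inpatient
volumes zero except for a small violation rate (5%) mirroring the policy
that forbids dispensary inpatient care but is occasionally breached. Costs
are log-normal around level category means anchored to observed sampled
means (e.g. dispensary clinical labor ≈ 27,400 USD/year, hospital ≈
872,700), scaled proportionally to OP volume, with log-sd 0.5 — observed
facility cost ranges span ~20× within a level, implying heavy right skew.
Sampling is OP-volume-weighted without replacement (dispensaries 35%, health
centers 50%, hospitals 100% by default, echoing one-referral-hospital
designs). A single seed controls everything, split deterministically per
sub-county so adding a sub-county leaves the others bit-identical.

Ground truth is computed by brute-force enumeration over the full universe —
never through the pipeline under test: the true network total is the plain
sum of all facility costs, and the true normative per-capita is an
independent per-service loop using overhead rates pooled over the whole
universe.

What passing the synthetic checks shows — and does not:

* Full capture (sampling everything) reproduces the true total exactly, and
  zero cost dispersion (homogeneous unit costs) makes proportional inflation
  exact under any sample: these validate the extrapolation *algebra*.
* With dispersion 0.5, the median relative error of the extrapolated total
  over 50 seeds stays under 5%: this validates behaviour under realistic
  heterogeneity, *given* OP-proportional sampling and costs that scale with
  OP volume. Real facility samples are not drawn proportionally to volume,
  real unit costs correlate with level, remoteness, and case mix, and
  routine-data denominators have completeness artifacts the generator does
  not emulate; the synthetic results bound sampling noise, not these biases.
* Normative recovery to $10^{-9}$ is a determinism check of a composition of
  exact arithmetic, not evidence about real STP quality.

## Problem sizes and numerical notes

The test suite and the acceptance script use single-sub-county worlds
(30 universe facilities, 12 STPs) and 50-seed replicate loops — sizes chosen
so the full validation runs in well under a minute while leaving the
recovery statistics stable across seeds. Degenerate inputs are handled
explicitly: zero weighted volume with positive cost is flagged
`unallocatable` (unit cost undefined, cost retained); a level missing from a
sample errors if the universe expects it and contributes zero otherwise; an
all-zero-frequency KHIS group is an error at the operation level and an `NA`
group cost within the sub-county aggregation; overhead and non-clinical
shares are validated to $[0,1)$. Ties in tornado bar ordering preserve the
parameter order of the specification, making the ordering stable under
relabeling.

## Known limitations

Inpatient case-mix is not modelled (only bed-day totals), outpatient
case-mix decomposition is out of scope, and the extrapolation inherits the
outpatient-only representativeness assumption discussed above. Need rates
are plain inputs; the package does not extract incidence or prevalence from
burden-of-disease datasets. There is no probabilistic (distributional)
sensitivity analysis, no survey-weighted small-area estimation, and no
cross-year currency adjustment.
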