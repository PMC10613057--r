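# phccostgap

Activity-based costing of primary health care (PHC) networks: actual costs
from sampled facilities, normative costs from standard treatment protocols,
and the financial resource gap between them.

## The problem

Health ministries planning universal health coverage need two numbers per
district: what delivering PHC *actually* costs today, and what it *should*
cost to deliver the full service package with reasonable quality at 100%
coverage. The difference — the resource gap — is the financing shortfall.
`phccostgap` implements this comparison for a three-level PHC network
(dispensaries, health centers, primary/sub-county hospitals), following the
design used in Kenyan-style sub-county costing studies:

**Actual costs.** Each sampled facility reports a year of recurrent costs in
four categories (clinical labor, drugs, medical supplies, indirect). Costs
are allocated between outpatient visits and inpatient bed-days using
WHO-CHOICE relative cost weights — an inpatient day weighs 432 against an
outpatient visit at 126 (hospital), 111 (health center), or 90 (dispensary) —
so a facility's weighted volume is

```
W = OP + IP × (432 / w_level),   unit cost = total cost / W
```

Sampled costs are extrapolated to the whole facility universe by outpatient
capture: for each level, `extrapolated = sampled cost × (universe OP /
sampled OP)`; levels are summed to the network total and divided by
population for the actual cost per capita.

**Normative costs.** Each service has a standard treatment protocol (STP):
drugs/diagnostics/reagents per encounter, clinical minutes per encounter by
cadre, and encounters per episode. Clinical time is grossed up by
`1/(1 − s)` for the share `s` (default 30%) of paid time spent on necessary
non-clinical work. Direct unit costs are loaded with the level's overhead
rate `r` (indirect ÷ total cost, pooled over sampled facilities) as
`direct/(1 − r)`, multiplied by the population in need
(`population × need rate`, coverage fixed at 100%), and summed over the
catalog.

**Gap and sensitivity.** `gap = normative − actual` per capita;
`investment multiple = normative / actual`. One-way (tornado) sensitivity
perturbs clinical labor ±20%, drugs ±30%, supplies ±20%, indirect ±30%, and
population ±5%, plus combined best/worst scenarios (worst = costs high,
population low).

A synthetic-world generator (`generate_world()`) builds complete facility
universes, OP-weighted samples, and STP catalogs with brute-force ground
truth, so every stage is testable end to end without confidential data.

## Worked example

The package ships the published seven-sub-county study tables as fixtures:

```r
library(phccostgap)

fx <- paper_fixture()
network_total(fx$frames[["Garbatulla"]])
#> <phc_network_cost> Garbatulla
#> # A tibble: 3 × 7
#>   level                n sample_cost sample_op universe_op capture_fraction
#>   <chr>            <int>       <dbl>     <dbl>       <dbl>            <dbl>
#> 1 dispensary           1      269873     31794      46358.            0.686
#> 2 health_center        1      377428     33741      33741             1
#> 3 primary_hospital     1      498674      9620       9620             1
#> # ℹ 1 more variable: extrapolated_cost <dbl>
#> network total: 1,269,600 USD;  per capita: 12.7 USD (population 99,729)

resource_gap(26.6, 41.7)
#> # A tibble: 1 × 5
#>   actual_pc normative_pc gap_pc investment_multiple multiple_reported
#>       <dbl>        <dbl>  <dbl>               <dbl> <chr>
#> 1      26.6         41.7   15.1                1.57 1.6 times
```

Garbatulla's sampled dispensaries captured ~69% of the sub-county's
outpatient services, so their sampled cost is inflated accordingly; the
network costs 1,269,600 USD/year, 12.7 USD per person. Nationally, actual
spending of 26.6 USD per capita against a normative 41.7 leaves a gap of
15.1 USD per person — investment would need to rise 1.6 times.

Sensitivity, tidiers, and plots:

```r
tor <- one_way(actual_pc_model(fx$frames[["Garbatulla"]]), sensitivity_spec())
tidy(tor)      # one bar per parameter, widest output swing first
glance(tor)    # base, best_case, worst_case
autoplot(tor)  # tornado diagram
```

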