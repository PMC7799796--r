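---
title: "Methods: locating spatial accessibility gaps in care services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating spatial accessibility gaps in care services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caregap)
```

## The problem

Older adults with reduced self-sufficiency draw a state care allowance and
use it to purchase social care: long-term **residential** care (homes for
the elderly, special-regime homes, capacity in beds) or **outpatient day
care** (day-care centres and day-services centres, capacity in daily
spots). Whether those services are *usable* depends not only on capacity
but on whether a recipient can actually reach a facility — by car, or by
the regional bus and train network. `caregap` measures this at the level
of districts nested in regions, in three phases:

1. **Reachability.** For every municipality, the minimal travel time to
   the nearest municipality hosting a facility of each service class, by
   individual transport (IT; shortest paths over a road network weighted
   in minutes) and by public transport (PT; filtered timetable
   connections). Thresholding at the time budgets answers the classical
   service-area question.
2. **Coverage and gap classification.** Per district, service class and
   mode, the share of allowance recipients living within each budget, and
   a three-tier class: I good (provider present, ≥ 80 % of recipients
   within 30 min), III poor (no provider and ≤ 40 % within 60 min), II
   lowered otherwise.
3. **Ranking and association.** TOPSIS closeness scores rank districts per
   coverage group; their mean (MT c~i~) summarizes overall accessibility;
   Pearson correlations with bootstrap percentile confidence intervals
   relate demand (X1), capacities (X2, X3) and achieved accessibility
   (X4–X7 as closeness scores).

## Indicators

| Indicator | Meaning | Unit |
|---|---|---|
| X1 | allowance recipients aged 65+ per district | persons |
| X2 | residential capacity | beds |
| X3 | outpatient-clinic capacity | daily spots |
| X4a/X4b | residential coverage by IT within 30/60 min | % of X1 |
| X5a/X5b | residential coverage by PT within 30/60 min | % of X1 |
| X6a/X6b | clinic coverage by IT within 30/60 min | % of X1 |
| X7a/X7b | clinic coverage by PT within 30/60 min | % of X1 |

Coverage is the recipient-weighted share
$100 \cdot \sum X1_{d,\;\text{within band}} / \sum X1_d$. Bands are
**cumulative**: "within 60" contains "within 30", so the *b* part never
falls below the *a* part. A `ring` reading (30–60 only) was considered and
rejected as the default because the smaller weight given to the 60-minute
criterion in the ranking only makes sense when the criterion nests the
first; the classifier offers an `area` basis (municipality-count share) as
a sensitivity switch instead.

## Public-transport connections

A timetable row carries departure and arrival clock times, total travel
minutes (including transfer waits), a transfer count, a price and the
direct distance. Feasibility filters, applied before any scoring:

* travel time **strictly below 90 minutes**,
* **at most five** transfers,
* direct distance **strictly below 150 km**,
* arrival at a required arrival time — 14:00 for residential visits,
  07:00 or 08:00 for day care, on a common workday (Tuesday; Mondays and
  Fridays are distorted by weekend commuting).

Arrival matching is **exact to the minute** by default. Whether "arrival
at 7 AM" means exactly-at or at-latest-by is genuinely ambiguous from the
study design; exact matching is the stricter reading and the
`arrival_tolerance` parameter (minutes, default 0) lets users widen it
symmetrically.

Among feasible connections of one origin–destination pair, the most
suitable one minimizes a min–max-normalized weighted sum over five
attributes: travel minutes, arrival slack, departure lateness, transfers,
price. The functional form of this weighing is a design choice — only the
attribute list is fixed by the study design — so the weights are
configuration, default `0.5 / 0.1 / 0.1 / 0.2 / 0.1` with travel time
dominant, and every run's report records them. Ties break
deterministically: lowest travel time, fewest transfers, lowest price,
input order. Municipalities hosting a facility of the class reach it in 0
minutes by either mode: the model's resolution is the municipality (main
stations), not facility doors, and city public transport is out of scope.

## TOPSIS

Each coverage group (X4–X7) forms a two-criterion decision matrix over
districts (the *a* and *b* parts). The five steps: column-wise vector
normalization $r_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$; weighting
$v_{ij} = w_j r_{ij}$; ideal and base alternatives as column max/min of
$v$ (all criteria are benefit-type percentages); Euclidean distances
$d_i^+, d_i^-$; closeness $c_i = d^-/(d^-+d^+) \in [0,1]$. Weights:
0.60/0.40 for residential groups, 0.70/0.30 for clinic groups — daily
visits premium short journeys more strongly than a one-off move into
residential care. The published formulation writes the ideal/base step
over "$w_{ij}$"; the package resolves that symbol overloading to the
weighted normalized matrix $v$, the standard TOPSIS reading, since the
distance step measures rows of the same matrix against $H_j$ and $D_j$.

Numerical edge cases, chosen so batch runs survive pathological inputs:
an all-zero criterion column normalizes to zeros with a warning; if an
alternative has $d^+ = d^- = 0$ (all alternatives identical) its
closeness is 0.5 with a warning rather than an exception; districts with
zero recipients have undefined coverage and are dropped from rankings
with a message. Ranking ties break by district id.

The **MT c~i~** is the arithmetic mean of the four group closenesses.
Descriptive statistics use the sample standard deviation (N−1), sample
skewness and sample *excess* kurtosis (the bias-corrected estimators that
mainstream statistical suites print; `e1071` type 2) — the convention is
stated because skewness/kurtosis conventions differ enough across software
to matter.

## Correlation and bootstrap

Pearson's r is computed from the N−1 covariance standardized by both
sample standard deviations. Significance at α = 0.05 and 0.01 uses the
two-sided t test, $t = r\sqrt{(N-2)/(1-r^2)}$ with N−2 degrees of
freedom — the test statistic is a documented package choice (only the α
levels are fixed by the study design) and is deliberately swappable.
Confidence intervals are **percentile bootstrap**: observation *pairs*
(district rows) are resampled with replacement — resampling the two
variables independently would destroy precisely the dependence being
estimated — r is recomputed per resample, and the empirical 2.5/97.5
percentiles are reported (quantile type 7). Resamples with zero variance
in either variable are redrawn by default (`degenerate_policy`), and the
count of such redraws is attached to the result. Verbal strength labels
follow a six-interval scale on |r|: negligible (0.00–0.09), low
(0.10–0.29), moderate (0.30–0.49), substantial (0.50–0.69), very high
(0.70–0.89), near-perfect (0.90–1.00); the middle two intervals carry the
analysis, the outer four complete the scale.

## What the synthetic generator emulates

`generate_region()` stands in for administrative registers that are not
publicly deposited: a provider register (facility locations), regional
capacity networks, ministry recipient counts, and a national
commuting-connection database. Defaults describe a Czech-like national
study area and were fixed from the published aggregate facts before any
validation runs:

* **13 regions**, 3–9 districts each (the real hierarchy has 76 districts
  across 13 regions, 3–12 per region averaging 5.8; a uniform 3–9 range
  has mean 6, giving ≈ 78 districts);
* **5–12 municipalities per district** — a deliberate scale-down from the
  real ≈ 82 per district, keeping test problems tractable while
  preserving the within-district heterogeneity the classifier needs;
* recipients per municipality ~ negative binomial (mean 250, size 1.2):
  overdispersed counts yielding district totals of a few thousand,
  matching the order of magnitude of published regional totals. No
  distributional facts below district level are published, so this is a
  modelling placeholder, not a calibration;
* facility densities: Poisson with mean **10 residential** and **1.75
  clinic** facilities per district (≈ 760 and ≈ 133 facilities over 76
  districts); the low clinic rate naturally produces districts and whole
  regions without any day-care provision, which is the phenomenon the gap
  analysis exists to find;
* capacities: residential ≈ lognormal around 45 beds; clinic uniform 5–15
  daily spots;
* roads: intra-district spanning trees plus random extras, district and
  region hubs chained; edge minutes are drawn per 10 km of Euclidean
  length (default uniform 8–14 min / 10 km ≈ 43–75 km/h). Distance-free
  edge times were rejected: they would make the whole country reachable
  within an hour and erase the gaps under study;
* transit: a seeded fraction (default 0.35) of ordered municipality pairs
  within 150 km receives 1–2 connections; 80 % arrive exactly on the
  07:00/08:00/14:00 pattern and the rest carry off-pattern arrivals, long
  durations or many transfers so the filters are exercised on realistic
  input.

What it does **not** emulate: real geography or network topology, a
capital-city analogue (the study area has none by design), population
dynamics, within-municipality access, city public transport, or live
traffic. Passing tests on synthetic areas therefore demonstrate that the
*method* is implemented correctly and recovers planted truth, not that
any particular real region has a gap.

`plant_gap_scenario()` edits a district to a known class: I places a
provider in every municipality (coverage 100 % by construction); II
removes the district's providers and links every municipality to an
external host at exactly 45 minutes (all within 60, none within 30);
III removes providers and cuts the district off in the chosen mode.
Class II is built provider-absent rather than provider-present with
partial coverage because the former is feasible for every district
including single-municipality ones. Every edit lands in the dataset's
edit log so tests can assert exactly what changed.

## Problem sizes and determinism

The test suite validates shortest paths against exhaustive path
enumeration on 100 random graphs of up to 8 nodes, TOPSIS invariants on
1000 random matrices, planted-class recovery over 20 seeds × 12
combinations (240 classifications), and bootstrap coverage over 500
bivariate-normal replicates of n = 76 with 2000 resamples each — sizes
chosen to make the checks statistically meaningful while a full run stays
in the low minutes on one CPU. All randomness is seeded: the generator
restores the caller's RNG state, equal configurations reproduce
byte-identical datasets, and pipeline runs with equal seeds produce
identical output files.

## Known limitations

* PT travel time counts departure→arrival including transfer waits; any
  initial walk or wait before departure is not modelled.
* Coverage is recipient-weighted even where the verbal scale speaks of a
  district's *area*; the `area` basis (municipality-count share) is a
  proxy, not a true areal measure.
* The model has no capacity constraint: a reachable facility counts as
  access regardless of free seats; X2/X3 enter only the correlation
  phase.
* Zero-recipient districts carry a documented degenerate coverage of 0
  and are excluded from rankings; real registries rarely contain such
  districts, synthetic ones can.
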