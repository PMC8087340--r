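---
title: "Wakamola: scoring model, network propagation and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wakamola: scoring model, network propagation and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wakamola)
```

## The assessment

Wakamola is a conversational screening instrument for overweight and obesity
risk factors. A participant answers three questionnaire sections — Personal
(anthropometrics, sociodemographics, sleep, smoking, four cardiometabolic
diagnosis flags), Diet (a 51-item food-frequency questionnaire) and Activity
(the IPAQ short form's 7 items) — and shares typed invitations (home,
family, friend, work) whose redemption builds an undirected social graph.
Each completer receives four sub-scores on 0–100 and a composite
**Wakastatus**, all "higher is better".

This package implements the assessment end to end: domain types with
validation, the scoring engine, typed-graph construction with Louvain
community detection, a calibrated synthetic-cohort simulator, a
transport-agnostic dialogue engine, and a CLI. Only participants whose three
sections are present and valid are scored; everyone else is excluded and
reported, mirroring the original pilot's filtering to completers.

## The scores

**WakaBMI** is a step function of BMI $= w/h^2$ (kg/m²): 100 points for
normal weight, 75 for overweight *or* underweight, 50 / 25 / 0 for obesity
classes 1 / 2 / 3. Category intervals are half-open $[lo, hi)$ —
underweight $<18.5$, normal $[18.5, 25)$, overweight $[25, 30)$, classes
1–3 at 30, 35, 40 — because the instrument's printed "24.9 / 25" style
ranges would otherwise leave gaps such as $(24.9, 25)$ undefined.

**Wakalimentation (diet).** Every (item, frequency level) pair carries a
penalty $p \in [1, 10]$, higher meaning less healthy. With
$S = \sum_i p_i$ and $P_{\min}, P_{\max}$ the extreme totals over complete
records, the score is the affine inversion

$$\mathrm{Diet} = 100\,\frac{P_{\max} - S}{P_{\max} - P_{\min}},$$

so the healthiest possible sheet scores 100 and the least healthy 0. The
deployed instrument's per-item penalty tables are not public, so the shipped
`default_v1` table assigns penalties by item class — *daily-recommended*
foods (dairy, fruit, vegetables, cereals, olive oil) are penalised when
absent, *weekly-recommended* foods (fish, legumes, meats, nuts) are best at
moderate frequency, *occasional* foods (sweets, alcohol, fries, processed
meat) are penalised as frequency grows. The table, like the 51-item list
itself, is configuration, not code, and is explicitly provisional.

**Activity.** IPAQ short-form MET-minutes per week, with each domain's
session minutes truncated at 180 min/day per the IPAQ scoring protocol:

$$\mathrm{MET} = 8.0\,d_v \min(m_v, 180) + 4.0\,d_m \min(m_m, 180)
  + 3.3\,d_w \min(m_w, 180),$$

then linear normalisation with saturation,
$\mathrm{Activity} = 100 \min(\mathrm{MET}/3000,\ 1)$. The reference volume
3000 MET-min/week is the conventional "high activity" threshold; it is a
parameter (`activity_ref_met`), not a constant.

**Wakasocial.** The instrument defines the social score through two
ingredients — the contact count and the mean Wakastatus of those contacts.
We combine them convexly: for user $i$ with degree $d_i$ and neighbours
$N(i)$,

$$\mathrm{Social}_i = 100\left[w_{\mathrm{deg}} \min\!\left(\frac{d_i}{D_{\mathrm{ref}}}, 1\right)
  + (1 - w_{\mathrm{deg}})\,\frac{\overline{W}_{N(i)}}{100}\right],$$

with the neighbour-mean term 0 for isolated users (consistent with the
pilot's low mean social score). Defaults $w_{\mathrm{deg}} = 0.5$,
$D_{\mathrm{ref}} = 10$ contacts.

**Wakastatus** is the weighted sum of the four sub-scores; "normalised sum"
is read as equal weights $1/4$, configurable through
`wakastatus_weights`.

### The fixed point

Social depends on neighbours' Wakastatus, which depends on their Social: a
linear system. We solve it by Jacobi iteration from $\mathrm{Social} \equiv
0$, stopping when the largest componentwise change drops below
`fixedpoint_tol` ($10^{-9}$). One sweep's update operator has spectral
coefficient at most $(1 - w_{\mathrm{deg}})\,w_{\mathrm{social}}$ (0.125
under defaults), a strict contraction, so convergence is guaranteed and the
solution is independent of the starting vector — both properties are tested
(restart from 100, and agreement with 10,000 naive sweeps to $10^{-6}$).
Non-convergence within `fixedpoint_max_iter` (possible only under
pathological parameter configurations) raises an error carrying the last
residual rather than returning unconverged numbers.

## Network analysis

Relations merge into a simple undirected graph: one edge per pair, carrying
the set of relation types, because the network view draws one link per pair
while invitations carry a group label. Communities come from igraph's
Louvain implementation; we fix determinism by seeding R's RNG (default seed
0) and processing vertices in sorted-id order, and relabel community ids
contiguously from 0. Isolated nodes are singleton communities. Node colours
follow the BMI legend blue/green/yellow/red with yellow read as $[25, 30)$
since red covers $\ge 30$. Report percentages round half-up to one decimal
(so 5/74 prints 6.8 and 8/74 prints 10.8); dispersions in reports are
population SDs, noted in the report footer.

The pilot's own accounting — 12 communities, 8 with more than one member,
5 isolated users — is internally inconsistent (it implies 4 singletons),
so pilot network counts are treated as consistency checks on fixtures, not
as exact reproduction targets.

## The simulator

`pilot2019_profile()` encodes the pilot's printed statistics: $n = 74$,
BMI $\sim \mathcal{N}(21.4, 2.41^2)$ truncated to $[14, 45]$ (sampled by
inverse CDF, so exact), the 20 food-group weekly means, the activity and
sleep means, and a network of 12 planted blocks with an expected 178 edges
and 5/74 isolated users. Where the pilot prints no value (height
distributions, education mix, household size, cigarettes), the profile uses
values typical of a Spanish university cohort; they are profile fields, not
code.

Three design choices matter for parameter recovery:

* **BMI is generated directly** and weight derived as
  $\mathrm{BMI} \cdot h^2$, so the printed BMI moments are targetable
  exactly; generating weight and height independently would not be.
* **Diet amounts are continuous.** Each item draws a weekly amount from a
  scaled Beta on $[0, 16]$ (concentration 2) with mean equal to the group
  mean split over the group's items, and the frequency level is assigned by
  *stochastic rounding* onto the representative grid
  $(0, 0.5, 2, 4.5, 9, 16)$, making
  $E[\mathrm{representative} \mid \mathrm{amount}] = \mathrm{amount}$.
  Deterministic cut-point binning of integer counts onto this fixed grid is
  biased by ~25% at the dairy group's mean and cannot represent the olive
  oil group's mean of 12.72 at all; the bounded support plus stochastic
  rounding gives exactly unbiased group-mean recovery for every group. The
  deterministic cut points ($0$; $(0,1)$; $[1,3)$; $[3,7)$; $[7,14)$;
  $\ge 14$) remain available as `units_to_level()` for binning observed
  data.
* **Day counts are Binomial(7, mean/7)**: the mean is exact on the native
  0–7 support. Clipping an unbounded count distribution to $[0, 7]$ would
  bias the walking-days mean (5.80) well downward. Minutes and sitting
  hours are gamma; sleep is (effectively untruncated) normal.

The network generator deals non-isolated users into balanced blocks, keeps
within-block pairs with probability 0.9, and calibrates the between-block
probability so the expected edge count equals $n \cdot \bar d / 2$ (178
under the profile). Edge types are drawn with probabilities friend .4,
family .3, work .2, home .1. Master seed → four per-section sub-seeds, so
sections are independently reproducible and a cohort is a pure function of
(profile, seed).

**What the simulator does and does not emulate.** It reproduces the pilot's
marginal means and the existence of community structure. It does not model
self-selection of volunteers, correlations between diet, activity and BMI
within person, degree heterogeneity beyond the planted-partition model, or
zip-code geography. Passing recovery tests therefore shows the toolkit's
estimators are consistent with the published marginals — not that synthetic
cohorts are exchangeable with real ones.

## Dialogue engine

Question ids, answer types and validation bounds are engine code; only
wording lives in the per-language JSON files (Spanish, English, Catalan).
That makes translation divergence in *structure* impossible, and
`translation_check()` reports missing *texts* against the Spanish
reference; the shipped Catalan file is deliberately partial (it lacks the
About text) to keep that check honest. Sections are chosen from a menu
rather than forced linearly; completion requires Personal + Diet +
Activity. Invitations are opaque base64 tokens encoding inviter, relation
type and issue time; redemption is idempotent per (pair, type) and
self-redemption is rejected. User-facing texts speak of "status", never
"risk". Transports are a two-function contract (receive, deliver), so the
console client and scripted test transports exercise exactly the same state
machine.

## Numerical and testing choices

* Tolerances: fixed point $10^{-9}$; score-sum identity checked at
  $10^{-6}$.
* Monte-Carlo sizes: recovery checks use $n = 10{,}000$ records against a
  3-standard-error band; sweep-style properties (slope $\approx 1$ of
  recovered vs configured) use 2,000–3,000 records per point. Edge-count
  calibration is checked over 200 seeds against a 10% band. These sizes
  give stable verdicts under fixed seeds while keeping the default test run
  fast.
* The Louvain result on the two-clique fixture is compared against
  exhaustive modularity maximisation over all 115,975 partitions of its 10
  nodes.
* All randomness flows through explicit seeds; cohorts, exports and CLI
  outputs are byte-reproducible given (inputs, config, seed), and output
  directories record the seed and config hashes in `run_meta.json`.

## Known limitations

The penalty table and several profile fields are informed defaults, not the
deployed instrument's values (those were never published); scores computed
with `default_v1` are comparable within a cohort scored the same way, not
with the original deployment. The social-score functional form is one
reasonable reading of "contact count and mean status of contacts". The item
count follows the 51-question Diet section even though the instrument's
abstract summary says 50 foods; the item list is replaceable configuration
either way. Clinical interpretation of the scores is out of scope.
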