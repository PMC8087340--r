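# wakamola

An R toolkit for the **Wakamola** health assessment: a chatbot-style
screening instrument for overweight and obesity risk factors that scores
each participant's diet, physical activity, body-mass index and social
network, and combines them into a single 0–100 **Wakastatus**.

The package is aimed at public-health researchers and methodologists who
want to (a) score questionnaire data collected with a Wakamola-style
instrument, (b) analyse the resulting social network and its community
structure, and (c) generate calibrated synthetic cohorts for power
analysis, method development and teaching — the shipped `pilot2019`
profile reproduces the printed statistics of the instrument's 74-person
university pilot.

## The model

For participant $i$ who completed all three questionnaire sections:

* **WakaBMI** — a step function of $\mathrm{BMI} = w/h^2$:
  100 (normal, $[18.5, 25)$), 75 (underweight or overweight),
  50 / 25 / 0 (obesity classes 1–3 at 30, 35, 40 kg/m²).
* **Wakalimentation** — each of 51 food items answered on six frequency
  levels carries a penalty $p \in [1,10]$; with $S_i = \sum p$ and
  $P_{\min}, P_{\max}$ the best/worst possible totals,
  $\mathrm{Diet}_i = 100\,(P_{\max} - S_i)/(P_{\max} - P_{\min})$.
* **Wakactivity** — IPAQ short-form energy expenditure
  $\mathrm{MET}_i = 8\,d_v \tilde m_v + 4\,d_m \tilde m_m + 3.3\,d_w \tilde m_w$
  (minutes capped at 180/day), normalised as
  $100 \min(\mathrm{MET}_i / 3000,\, 1)$.
* **Wakasocial** — a convex mix of normalised contact count and the mean
  Wakastatus of contacts:
  $\mathrm{Social}_i = 100\,[\,w_d \min(d_i/D_{\mathrm{ref}},1) + (1-w_d)\,\overline{W}_{N(i)}/100\,]$
  with defaults $w_d = 0.5$, $D_{\mathrm{ref}} = 10$.
* **Wakastatus** — $W_i = \tfrac14(\mathrm{Diet}_i + \mathrm{Activity}_i + \mathrm{BMI}_i + \mathrm{Social}_i)$.

Because Social depends on neighbours' Wakastatus and vice versa, the last
two are defined jointly; the package solves the system by Jacobi iteration,
which is a strict contraction under any sensible parameterisation (see the
methods vignette, `vignette("wakamola-methods")`).

## Worked example

Two participants with maximal diet, activity and BMI sub-scores who are
mutual friends. Each has degree 1, so the degree term contributes
$100 \cdot 0.5 \cdot 1/10 = 5$ points of Social; solving
$S = 5 + W/2$ and $W = 75 + S/4$ gives $W = 76.25/0.875 = 87.1428\ldots$:

```r
library(wakamola)

best <- function(id) {
  items <- canonical_food_items()
  lv <- c(daily = "L5", weekly = "L3", occasional = "L0")[items$item_class]
  assessment(id,
    personal = personal_record(65, 1.75, age = 21, sleep_hours = 8),
    diet     = diet_record(stats::setNames(lv, items$item_id)),
    activity = activity_record(7, 180, 7, 180, 7, 180, 10))
}
ch <- cohort(list(best("a"), best("b")), list(relation("a", "b", "friend")))
sc <- compute_scorecards(ch)
sc[, c("user_id", "diet_score", "activity_score", "bmi_score",
       "social_score", "wakastatus")]
#>   user_id diet_score activity_score bmi_score social_score wakastatus
#> 1       a        100            100       100     48.57143   87.14286
#> 2       b        100            100       100     48.57143   87.14286
```

A full pilot-scale pipeline — simulate, score, build the network, detect
communities:

```r
ch <- generate_cohort(pilot2019_profile(), seed = 2019)
ch
#> A cohort: 74 participants (74 complete), 186 relations

sc <- compute_scorecards(ch)
head(sc[, c("user_id", "bmi", "bmi_category", "diet_score",
            "activity_score", "social_score", "wakastatus")], 3)
#>   user_id      bmi bmi_category diet_score activity_score social_score wakastatus
#> 1    u001 23.94480       normal   40.38005       94.95058     60.85275   74.04584
#> 2    u002 20.29737       normal   41.56770       33.51849     63.95678   59.76074
#> 3    u003 20.03058       normal   40.14252       72.59124     59.04866   67.94560

g <- build_graph(ch, sc)
comm <- detect_communities(g, seed = 0)
s <- network_summary(g, comm)
s[c("n_nodes", "n_edges", "n_isolated", "n_communities", "largest_community_size")]
#> $n_nodes
#> [1] 74
#> $n_edges
#> [1] 186
#> $n_isolated
#> [1] 5
#> $n_communities
#> [1] 15
#> $largest_community_size
#> [1] 12
```

The same pipeline is available from the shell:

```sh
Rscript inst/cli/wakamola.R simulate --seed 2019 --out cohort/
Rscript inst/cli/wakamola.R score    --cohort cohort/ --out scored/
Rscript inst/cli/wakamola.R network  --cohort cohort/ --scores scored/scores.csv --out net/
Rscript inst/cli/wakamola.R report   --cohort cohort/ --scores scored/scores.csv --out report/
```

Every command records its seed and the MD5 of each configuration input in
`run_meta.json`, and identical inputs produce byte-identical outputs.

## Package layout

| Path | Contents |
|---|---|
| `R/domain.R` | records, relations, assessments, cohorts, validation |
| `R/scoring.R`, `R/score-table.R` | the five scores, fixed-point solver, penalty-table and parameter config |
| `R/network.R` | graph construction, seeded Louvain communities, GraphML / JSON export |
| `R/simulate.R` | cohort generator and the `pilot2019` calibration profile |
| `R/conversation.R` | dialogue engine, es/en/ca texts, invitation tokens |
| `R/cohort-io.R`, `R/report.R`, `R/cli.R` | CSV/JSON round-tripping, descriptive reports, CLI entry points |
| `inst/extdata/` | food-item list, penalty table, scoring parameters, cohort profiles, dialogue texts |

Scoring parameters, the penalty table, the food-item list and simulation
profiles are all data files replaceable at call time (`read_config()`
accepts JSON or YAML); the defaults are documented, provisional choices —
see "Known limitations" in the methods vignette before comparing scores
across studies.
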