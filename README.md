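# triadminer

Process mining of multidisciplinary collaboration in type 2 diabetes
primary care.

Chronic diabetes follow-up is delivered by a triad of disciplines —
physician (P), nurse (N) and dietitian (D) — through periodic
cardiovascular appointments (CVPAs). `triadminer` takes the two tables an
electronic clinical record system already holds (CVPA events and HbA1c test
results) and answers two questions: *how do the disciplines organise
themselves around each patient*, and *does that organisation relate to the
patient's glycaemic evolution?* It is aimed at health-services researchers
and primary-care analysts working with appointment-level extracts.

## The method

1. **Selection funnel** — patients need ≥ 2 HbA1c results, zero
   comorbidity/complication index counts, protocol-adherent test intervals
   (≤ 12/6/3 months after a compensated / moderately decompensated / highly
   decompensated value, plus a 4-month tolerance), and a closing
   measurement 10–26 months after their first (target 18 ± 8).
2. **Discipline log** — each patient's in-window CVPAs, time-ordered,
   become a sequence over {P, N, D}.
3. **Collaborative network** — for a patient group, the directed multigraph
   G = (V, E) whose arc a→b counts consecutive-visit transitions
   (self-loops allowed). Three indices in percent: participation
   (discipline's share of all CVPAs), self-referral (share of a
   discipline's outgoing arcs returning to it) and referral (share going to
   each other discipline). The identity Σ arcs = #CVPAs − #patients holds
   on every network.
4. **Trace clustering** — agglomerative (complete linkage) on the
   normalised Levenshtein distance between discipline sequences, cut at
   0.15, so members of one cluster differ by at most 15%; clusters smaller
   than ⌈0.03 · n⌉ are pooled as outliers.
5. **Pattern classification** — a threshold-explicit decision tree maps
   each cluster's indices onto seven collaboration patterns:
   self-contained, tacit leader, shared, participatory, equitably centered,
   hierarchically centered, self-referred leader.
6. **Outcome segmentation** — each HbA1c series becomes compensated,
   improved (negative OLS slope ending < 7%), moderately decompensated or
   highly decompensated, by rules evaluated in that order.
7. **Statistics** — each (pattern, segment) subgroup proportion is tested
   against the whole-cohort proportion (two-proportion z-test, Fisher exact
   fallback for small expected counts, α = 0.05).

A synthetic ECR generator with planted patterns, trajectories, comorbidity
flags and adherence violations (`generate_cohort()`) makes every stage
testable without patient data.

## Worked example

```r
library(triadminer)

cfg <- simulation_config(n_patients = 200, seed = 42,
                         comorbidity_rate = 0.2,
                         adherence_violation_rate = 0.2,
                         single_test_rate = 0.1)
cohort <- generate_cohort(cfg)
run <- run_pipeline(cohort$encounters, cohort$measurements, cohort$patients)
print(run)
#> Patient selection funnel
#>   total                200
#>   >= min tests         170
#>   no comorbidity       143
#>   adherent             106
#>   valid study window   106
#> Trace clustering: 106 patients, 5 cluster(s), 74 outlier(s)
#> Cluster patterns:
#>   cluster_1    self-contained (leader P)
#>   cluster_2    self-contained (leader P)
#>   cluster_3    tacit leader (leader P)
#>   cluster_4    unclassified
#>   cluster_5    tacit leader (leader P)
#> Segments:
#>                    segment  n  pct
#> 1              compensated 60 56.6
#> 2                 improved 18 17.0
#> 3 moderately decompensated 18 17.0
#> 4     highly decompensated 10  9.4
#> 1 significant subgroup comparison(s) at alpha = 0.05
```

Reading the output: 200 simulated patients enter the funnel and 106 survive
its four stages. Clustering their care trajectories at 15% dissimilarity
yields five behaviour groups large enough to interpret (74 patients sit in
small groups pooled as outliers — realistic for stochastic visit
sequences). Two clusters are physician-only (*self-contained*), two show a
dominant discipline fed by the other's referrals (*tacit leader*). The
segment table counts the in-window HbA1c evolutions, and one subgroup
differs significantly from the cohort margin at α = 0.05.

Per-cluster indices, networks (GraphML/DOT) and all tables can be written
with `write_run_report(run, "out/")`; `run$networks$cluster_1$metrics`
shows, for example, `participation: P 100, N 0, D 0`.

Real extracts enter through `read_encounters()`, `read_measurements()` and
`read_patients()` (ISO-8601 dates; discipline synonyms such as
"physician"/"nurse"/"dietitian" accepted; non-CVPA appointment types
dropped).

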