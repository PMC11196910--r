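# kgdx — explainable syndrome diagnosis on clinical knowledge graphs

kgdx is for clinical-informatics researchers who need a diagnostic
classifier whose every prediction can be audited. It targets traditional
Chinese medicine (TCM) syndrome differentiation for tinnitus — assigning a
patient to one of five patterns (WFAI, LFBU, PFSI, QDSS, KED) from a set
of discrete findings (reported sounds, pulse and tongue qualities,
aggravating factors, onset/duration categories) — but the machinery is
generic: any cohort of labeled patients with binary feature profiles can
be represented and diagnosed the same way.

## The method

Patients, findings and syndromes are nodes of a heterogeneous knowledge
graph. Each finding `e` is weighted against each syndrome `s` by

```
w_if(e)      = H(Y) - H(Y | X_e)          information gain, in bits
w_sd(e, s)   = p(e present | s)           syndrome-conditional probability
combined(e,s) = w_if(e) + w_sd(e, s)
```

with `Y` the syndrome label and `X_e` presence/absence of `e`. Similarity
between a query patient `x` and a labeled candidate `y` is a weighted
common-neighbor (WCN) score over their shared findings:

```
score(x, y) = Σ_{h ∈ CN(x, y)} combined(h, s_y)
```

where `s_y` is the candidate's syndrome. The predicted syndrome is the
modal label among the top k = 20 candidates by score, and every score
decomposes into per-finding contributions — the explanation. Plain common
neighbors, Adamic-Adar and resource allocation are included as baselines,
and a stratified 5-fold cross-validation harness reports one-vs-rest
accuracy, precision, sensitivity, specificity, F1 and rank-based AUC per
syndrome. Because no such patient-level dataset is publicly deposited, a
seeded synthetic cohort generator reproduces the study conditions (class
sizes 339/307/194/270/155, ranked signature findings, shared background
findings, a deliberate QDSS/KED confusion block) so the whole pipeline is
testable end to end.

## Worked example

```r
library(kgdx)

cfg     <- default_config(seed = 42)      # 1265 patients, 5 syndromes
cohort  <- generate_cohort(cfg)
graph   <- build_graph(cohort)
weights <- compute_weight_table(cohort)

graph
#> <knowledge_graph> 1321 entities, 13387 relations
#>    patient: 1265, symptom: 51, syndrome: 5

round(weights$combined[c("Spermatorrhea", "Fine pulse", "Duration"),
                       c("KED", "QDSS")], 4)
#>                  KED   QDSS
#> Spermatorrhea 1.5241 0.6450
#> Fine pulse    1.2598 1.4065
#> Duration      0.6173 0.7748
```

The same finding carries different weight under different syndromes:
`Fine pulse` matters for both deficiency patterns, `Spermatorrhea` is
KED-specific, `Duration` is common and therefore weakly informative.

```r
query <- list(patient_id = "new-patient",
              features = c("Cicadas chirp", "Fine pulse",
                           "Soreness of loins", "Spermatorrhea",
                           "Duration", "Fatigue"))
dx <- diagnose(graph, query, weights, k = 20)
dx
#> <diagnosis_result> query new-patient -> KED (k = 20)
#>   votes: KED 20

ex <- explain(dx)
ex$breakdowns[[1]]
#>              entity     weight
#> 1     cicadas_chirp 1.14184290
#> 2          duration 0.61726923
#> 3           fatigue 0.06547221
#> 4        fine_pulse 1.25976247
#> 5 soreness_of_loins 1.47243493
#> 6     spermatorrhea 1.52407090
```

All twenty nearest labeled patients are KED, so the vote is unanimous;
the breakdown shows *why* the top neighbor scored 6.08 — the sum of the
six shared findings' combined weights, dominated by the KED-signature
findings and barely moved by the background finding `Fatigue`.

```r
report <- run_cv(cohort, cv_config(k = 20, seed = 42,
                                   methods = c("wcn", "cn")))
report
#> <cv_report> 5-fold stratified CV, methods: wcn, cn
#>   wcn  multiclass accuracy 1.0000 | per-class mean acc 1.0000, F1 1.0000, AUC 1.0000
#>   cn   multiclass accuracy 0.9992 | per-class mean acc 0.9997, F1 0.9993, AUC 1.0000
```

On this well-separated synthetic cohort both methods are near-perfect and
the weighted score dominates the unweighted count; real cohorts, with
correlated and noisier findings, sit lower.

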