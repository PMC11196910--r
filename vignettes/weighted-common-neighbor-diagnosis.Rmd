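---
title: "Weighted common-neighbor diagnosis on a clinical knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted common-neighbor diagnosis on a clinical knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgdx)
```

## The problem

Traditional Chinese medicine (TCM) assigns tinnitus patients to one of five
syndrome patterns — wind fire attacking internally (WFAI), liver fire
bearing upward (LFBU), phlegm fire stagnation internally (PFSI), Qi
deficiency of the spleen and stomach (QDSS) and kidney essence deficiency
(KED) — from a profile of discrete findings: sounds the patient reports,
pulse and tongue qualities, aggravating factors, onset and duration
categories. There is no laboratory marker; the diagnosis rests on which
findings co-occur. kgdx represents a cohort of diagnosed patients as a
heterogeneous knowledge graph (patient, symptom, syndrome and allied node
types), and diagnoses a new patient by finding the labeled patients most
similar to them, where similarity is a *weighted* count of the clinical
findings they share.

## The model

### Edge weights

Every finding (entity) `e` receives two weights relative to a syndrome `s`,
estimated from the labeled cohort:

* **Information gain** `w_if(e) = H(Y) − H(Y | X_e)` in bits, where `Y` is
  the syndrome label and `X_e` is presence/absence of `e`. This equals the
  mutual information between the finding and the diagnosis, is shared
  across syndromes, and is zero exactly when the finding is independent of
  the label. For a five-class target it is bounded by `log2 5 ≈ 2.32` bits.
* **Syndrome-conditional probability** `w_sd(e, s) = p(e present | s)`,
  the maximum-likelihood estimate from class counts (optionally
  Laplace-smoothed by `alpha`; the default `alpha = 0` keeps exact zeros,
  matching weight tables whose entries can vanish).

The edge weight used everywhere downstream is the sum
`combined(e, s) = w_if(e) + w_sd(e, s)`, bounded by `log2 5 + 1`. Base-2
logarithms are used throughout; published combined weights for this kind of
five-pattern cohort (maximum ≈ 1.44) are consistent with bits and far below
the cap, which the bundled `table2_weights.tsv` fixture checks.

### Patient similarity

For a query patient `x` and a labeled candidate `y` with syndrome `s_y`,
every common neighbor `h` (a finding adjacent to both patients) defines a
2-hop path `x – h – y`. The weighted common-neighbor (WCN) score is

```
score(x, y) = sum over h in CN(x, y) of combined(h, s_y)
```

The per-`h` terms are returned as a *breakdown*, so each score is exactly
the sum of auditable contributions — that additivity is asserted by the
test suite at 1e-9 and is what makes a diagnosis explainable.

Which weight a 2-hop path should carry is genuinely open: entity weights
are defined against a *syndrome*, and the query patient has none. We
resolve this by crediting each shared entity with its weight under the
candidate's known syndrome (`mode = "candidate-syndrome"`), which uses only
weights the model defines and keeps scores on the scale of published
example tables (≈ 0.7–0.8 per shared entity). Two alternates remain
switchable because the choice is a convention, not a theorem:
`"both-hops"` doubles each term (crediting the weight on each hop of the
path), which rescales all scores by 2 and cannot change a ranking or a
vote; `"unweighted"` drops the weights and reproduces the plain
common-neighbor count exactly.

Three classical link-prediction baselines are included for comparison:
common neighbors `|CN|`, Adamic-Adar `sum 1/log deg(h)` (natural log) and
resource allocation `sum 1/deg(h)`. The graph is undirected, so degree
stands in for outdegree.

### From ranking to diagnosis

Candidates are sorted by score, descending, with deterministic
tie-breaking: larger common-neighbor count first, then smaller patient id.
The predicted syndrome is the modal label of the top `k = 20` candidates
(`k` truncates to the candidate count when fewer are available). Vote ties
go to the label with the larger summed score, then lexicographically —
the tie rules are conventions chosen to make every result reproducible.
`class_scores()` additionally returns the normalized per-syndrome score
mass of the top k; it sums to 1, falls back to vote fractions when all
scores are zero, and provides the continuous output a ROC analysis needs,
since a bare vote has no threshold to sweep.

## Graph construction and entity alignment

Records arrive structured: one row per patient with a feature set and an
optional label. Free-text extraction is out of scope, and continuous
findings (e.g. duration) must arrive pre-binned as categorical labels,
because the model treats every finding as a discrete node. Near-duplicate
surface forms are merged by normalized Levenshtein similarity
(`1 − editdistance / max length`, computed on Unicode code points so CJK
strings compare per character; an LCS-ratio variant is available). A raw
label maps to the highest-similarity canonical label at or above the
threshold (default 0.6 — a deliberately moderate cutoff, since clinical
entity strings are short), otherwise to itself; a manual override table
wins over any automatic match and stands in for expert review in a
reproducible, auditable form. Feature nodes get ASCII slug ids derived
from sorted unique labels, so ids are stable under record reordering while
labels keep their original (possibly non-ASCII) form.

## Evaluation design

`run_cv()` performs stratified k-fold cross-validation (default 5 folds):
per-class test counts differ by at most one across folds, folds are
deterministic given a seed, and each fold rebuilds the graph and refits
the weight table *from the training records only*, so no test-label
information reaches the weights. (A `leakage_safe = FALSE` switch fits
weights once on the whole cohort, for comparison with workflows that
weight before splitting; knowledge triples are treated as global
background and are never folded.) Metrics are one-vs-rest per syndrome:
accuracy, precision, sensitivity, specificity, F1 — 0/0 ratios report 0
and are flagged — plus rank-based AUC (ties counted one half) computed
from the class-score mass. "Accuracy" is one-vs-rest accuracy per class,
the only reading consistent with reporting one accuracy per syndrome
alongside the other per-class metrics.

Inside the fold loop the scorer is a vectorized sparse-matrix formulation
of the same computation `score_all()` performs pair by pair (the test
suite asserts their equivalence); scoring a fold costs one sparse
matrix-vector product per test patient per syndrome. For Adamic-Adar and
resource allocation the fold scorer uses the training-graph degree plus
one, i.e. the degree each common neighbor would have with the query
transiently attached — the same value the per-pair functions see on a
graph that contains both endpoints.

## The synthetic cohort generator

No patient-level dataset of this kind is publicly deposited, so the
generator emulates the study conditions directly: five syndromes with
class sizes 339 / 307 / 194 / 270 / 155 (1265 patients), each syndrome
carrying ten signature findings with Bernoulli presence probabilities
spread from 0.9 down to 0.6 in order of characteristicness, fifteen
background findings shared by all classes at probabilities 0.05–0.2, and a
deliberate confusion block: the QDSS-specific aggravation/ear-emptiness
findings also appear under KED with probability 0.3, because those two
deficiency patterns are the clinically confusable pair. Every patient is
drawn with conditionally independent features given the label, and a
patient drawn empty is redrawn. All randomness flows from one seed.

Conditional independence is chosen deliberately: under it,
`w_sd` estimates exactly the generating parameter, so parameter-recovery
tests are sharp (estimates within three binomial standard errors for at
least 95% of entity–syndrome pairs at n = 5000). What the generator does
*not* emulate — symptom co-occurrence correlation, demographic covariates,
vocabulary drift and misspelling, label noise beyond the explicit
`corrupt_labels()` helper — bounds what passing tests prove: they validate
the machinery and its statistical behavior under the stated model, not
clinical performance on real records, where correlated findings and
noisier labels will lower every metric.

## Numerical choices

* `0 · log 0 = 0` in every entropy; gains are clamped at 0 to absorb
  floating-point cancellation (`-1e-17`-scale negatives).
* Probability vectors must sum to 1 within 1e-9; weight-table identities
  (`combined = w_if + w_sd`, breakdown sums) hold to 1e-9 or better.
* TSV and JSON serialization formats numbers at 17 significant digits, so
  graph and weight-table round-trips are exact.
* Degenerate inputs error early and name the offender: unknown entity ids,
  dangling relation endpoints, empty feature sets, duplicate patient ids,
  unlabeled candidates, classes smaller than the fold count. Unknown
  *query* features are the one soft case — skipped with a warning by
  default (live patients drift from the training vocabulary), strict mode
  errors instead.

## Problem sizes used by the checks

The shipped verification suite runs the full default cohort (n = 1265,
5-fold CV, k = 20), parameter recovery at n = 5000, oracle equivalence on
200 random graphs of at most 50 nodes, the gain/MI identity on 1000 random
contingency tables, and explanation audits over 100 held-out queries —
sizes chosen so every property is tested at or above the scale the method
is documented for while the whole suite stays interactive.

## Known limitations

Scores use 2-hop paths only; longer-range structure (symptom–symptom or
symptom–syndrome triples) influences nothing but the graph's connectivity.
The exact weight a published implementation assigns per path is not
recoverable from prose, so absolute scores here are comparable only within
one mode. Synthetic benchmarks overstate real-world separability, as noted
above. Drug and treatment nodes are carried as first-class entity types
but are not scored — prescription recommendation is out of scope.
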