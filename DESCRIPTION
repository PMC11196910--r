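Package: kgdx
Title: Explainable Syndrome Diagnosis on Clinical Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds heterogeneous patient-symptom-syndrome knowledge graphs
    from structured clinical records and curated knowledge triples, aligns
    near-duplicate entities by string similarity, weights symptom-syndrome
    edges by information gain plus syndrome-conditional probability, scores
    patient similarity by weighted common neighbors, and diagnoses by top-k
    vote with per-neighbor explanations. Includes baseline link-prediction
    scores (common neighbors, Adamic-Adar, resource allocation), a stratified
    cross-validation harness with one-vs-rest metrics and AUC, and a seeded
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
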