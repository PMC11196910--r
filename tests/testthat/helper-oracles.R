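# Independent brute-force oracles and small random fixtures. These are kept
# deliberately naive (explicit enumeration, joint-frequency formulas) so they
# exercise none of the package's own code paths.

# Mutual information from the joint frequency table:
# I(X;Y) = sum_{x,y} p(x,y) log2( p(x,y) / (p(x) p(y)) )
oracle_mi <- function(feature, labels) {
  joint <- table(feature, labels) / length(feature)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  as.numeric(mi)
}

# Explicit 2-hop path enumeration between two patient nodes on an edge list.
# per_path_weight(h) defines the contribution of the path a - h - b.
oracle_two_hop <- function(edges, a, b, per_path_weight) {
  nbr <- function(v) unique(c(edges$target[edges$source == v],
                              edges$source[edges$target == v]))
  cn <- intersect(nbr(a), nbr(b))
  if (!length(cn)) return(0)
  sum(vapply(cn, per_path_weight, numeric(1)))
}

oracle_degree <- function(edges, v) {
  length(unique(c(edges$target[edges$source == v],
                  edges$source[edges$target == v])))
}

# Exhaustive pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Random bipartite patient/symptom graph with labeled patients, plus a
# random positive weight table; returns the graph, the edge frame used by
# the oracles, and the table.
random_patient_graph <- function(n_patients = 8, n_symptoms = 12,
                                 n_syndromes = 3, p_edge = 0.35) {
  pats <- sprintf("p%02d", seq_len(n_patients))
  syms <- sprintf("s%02d", seq_len(n_symptoms))
  syns <- LETTERS[seq_len(n_syndromes)]
  labels <- sample(syns, n_patients, replace = TRUE)
  inc <- matrix(stats::runif(n_patients * n_symptoms) < p_edge,
                n_patients, n_symptoms)
  # every patient needs at least one symptom for realistic profiles
  for (i in which(rowSums(inc) == 0)) inc[i, sample(n_symptoms, 1)] <- TRUE
  edges <- data.frame(
    source = c(rep(pats, rowSums(inc)), pats),
    target = c(syms[unlist(apply(inc, 1, which))], labels),
    rtype = c(rep("has_feature", sum(inc)), rep("diagnosed_as", n_patients)),
    weight = NA_real_, stringsAsFactors = FALSE)
  nodes <- data.frame(
    id = c(pats, syms, syns), label = c(pats, syms, syns),
    etype = c(rep("patient", n_patients), rep("symptom", n_symptoms),
              rep("syndrome", n_syndromes)),
    aliases = "", stringsAsFactors = FALSE)
  g <- kgdx:::graph_from_frames(nodes, edges)
  combined <- matrix(stats::runif(n_symptoms * n_syndromes, 0.1, 2),
                     n_symptoms, n_syndromes,
                     dimnames = list(syms, syns))
  tab <- structure(list(entities = syms, syndromes = syns,
                        w_if = stats::setNames(rep(NA_real_, n_symptoms), syms),
                        w_sd = combined * NA, combined = combined,
                        alpha = 0, n = NA_integer_),
                   class = "weight_table")
  list(graph = g, edges = edges, table = tab, patients = pats,
       labels = stats::setNames(labels, pats))
}

# Tiny deterministic cohort: two well-separated syndromes.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("t%02d", 1:8),
    features = list(
      c("a", "b"), c("a", "b", "x"), c("a", "c"), c("b", "c"),
      c("d", "e"), c("d", "e", "x"), c("d", "f"), c("e", "f")),
    syndrome = rep(c("KED", "QDSS"), each = 4))
}
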