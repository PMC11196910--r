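test_that("weighted score closed forms: empty overlap and simple sums", {
  fx <- withr::with_seed(1, random_patient_graph(n_patients = 2,
                                                 n_symptoms = 4, p_edge = 0))
  g <- fx$graph
  # patients got one forced symptom each; make them share two entities
  g <- upsert_relation(g, relation("p01", "s01"))
  g <- upsert_relation(g, relation("p02", "s01"))
  g <- upsert_relation(g, relation("p01", "s02"))
  g <- upsert_relation(g, relation("p02", "s02"))
  tab <- fx$table
  tab$combined[] <- 0
  tab$combined["s01", ] <- 1.2
  tab$combined["s02", ] <- 0.8
  s <- wcn_score(g, "p01", "p02", tab)
  shared <- kg_common_neighbors(g, "p01", "p02", etype = "symptom")
  expect_equal(s$cn_count, length(shared))
  expect_equal(s$score, sum(tab$combined[shared, s$syndrome]))
  expect_equal(nrow(s$breakdown), s$cn_count)
  expect_equal(sum(s$breakdown$weight), s$score)
  # both-hops doubles every term; unweighted counts
  expect_equal(wcn_score(g, "p01", "p02", tab, mode = "both-hops")$score,
               2 * s$score)
  expect_equal(wcn_score(g, "p01", "p02", mode = "unweighted")$score,
               s$cn_count)
})

test_that("baseline closed forms: degree-2 Adamic-Adar and degree-4 RA", {
  g <- knowledge_graph()
  for (p in c("a", "b")) g <- upsert_entity(g, entity(p, etype = "patient"))
  g <- upsert_entity(g, entity("h"))
  g <- upsert_relation(g, relation("a", "h"))
  g <- upsert_relation(g, relation("b", "h"))
  expect_equal(common_neighbors_score(g, "a", "b"), 1)
  expect_equal(adamic_adar_score(g, "a", "b"), 1 / log(2))
  expect_equal(resource_allocation_score(g, "a", "b"), 1 / 2)
  for (p in c("c", "d")) {
    g <- upsert_entity(g, entity(p, etype = "patient"))
    g <- upsert_relation(g, relation(p, "h"))
  }
  expect_equal(resource_allocation_score(g, "a", "b"), 1 / 4)
  g2 <- knowledge_graph()
  for (p in c("a", "b")) g2 <- upsert_entity(g2, entity(p, etype = "patient"))
  expect_equal(common_neighbors_score(g2, "a", "b"), 0)
  expect_equal(adamic_adar_score(g2, "a", "b"), 0)
  expect_equal(resource_allocation_score(g2, "a", "b"), 0)
})

test_that("all four scores match the brute-force 2-hop path enumerator", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      fx <- random_patient_graph(n_patients = sample(4:10, 1),
                                 n_symptoms = sample(6:15, 1))
      pairs <- utils::combn(fx$patients, 2)
      take <- sample(ncol(pairs), min(4, ncol(pairs)))
      for (k in take) {
        a <- pairs[1, k]; b <- pairs[2, k]
        s_b <- unname(fx$labels[b])
        # oracle counts feature entities only (syndrome hops excluded)
        feat_only <- function(h) h %in% fx$table$entities
        w_of <- function(h) if (feat_only(h)) fx$table$combined[h, s_b] else 0
        expect_equal(wcn_score(fx$graph, a, b, fx$table)$score,
                     oracle_two_hop(fx$edges, a, b, w_of), tolerance = 1e-12)
        # baselines include every common neighbor (shared syndrome too)
        cnt <- function(h) 1
        aa <- function(h) 1 / log(oracle_degree(fx$edges, h))
        ra <- function(h) 1 / oracle_degree(fx$edges, h)
        expect_equal(common_neighbors_score(fx$graph, a, b),
                     oracle_two_hop(fx$edges, a, b, cnt))
        expect_equal(adamic_adar_score(fx$graph, a, b),
                     oracle_two_hop(fx$edges, a, b, aa), tolerance = 1e-12)
        expect_equal(resource_allocation_score(fx$graph, a, b),
                     oracle_two_hop(fx$edges, a, b, ra), tolerance = 1e-12)
      }
    }
  })
})

test_that("adding or removing a shared neighbor moves the score monotonically", {
  fx <- withr::with_seed(31, random_patient_graph(n_patients = 4,
                                                  n_symptoms = 8))
  g <- fx$graph
  a <- "p01"; b <- "p02"
  before <- wcn_score(g, a, b, fx$table)$score
  free <- setdiff(fx$table$entities,
                  kg_common_neighbors(g, a, b))[1]
  g2 <- upsert_relation(upsert_relation(g, relation(a, free)),
                        relation(b, free))
  after <- wcn_score(g2, a, b, fx$table)$score
  expect_gt(after, before)
  # removal restores the original score
  g3 <- g2
  keep <- !(g3$edges$source %in% c(a, b) & g3$edges$target == free)
  g3$edges <- g3$edges[keep, ]
  g3$adj[[a]] <- setdiff(g3$adj[[a]], free)
  g3$adj[[b]] <- setdiff(g3$adj[[b]], free)
  g3$adj[[free]] <- setdiff(g3$adj[[free]], c(a, b))
  expect_equal(wcn_score(g3, a, b, fx$table)$score, before)
})

test_that("unweighted mode reproduces the common-neighbor count", {
  withr::with_seed(77, {
    fx <- random_patient_graph(n_patients = 8, n_symptoms = 10)
    pairs <- utils::combn(fx$patients, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      uw <- wcn_score(fx$graph, a, b, mode = "unweighted")$score
      cn_feat <- kg_common_neighbors(fx$graph, a, b, etype = "symptom")
      expect_equal(uw, length(cn_feat))
    }
  })
})

test_that("score_all sorts by score, then cn count, then id", {
  fx <- withr::with_seed(123, random_patient_graph(n_patients = 12,
                                                   n_symptoms = 14))
  others <- setdiff(fx$patients, "p01")
  rk <- score_all(fx$graph, "p01", others, fx$table)
  df <- as.data.frame(rk)
  expect_setequal(df$candidate_id, others)
  expect_true(all(diff(df$score) <= 1e-12))
  # per-pair results and ranking agree
  for (i in seq_len(nrow(df))) {
    s <- wcn_score(fx$graph, "p01", df$candidate_id[i], fx$table)
    expect_equal(df$score[i], s$score)
    expect_equal(df$cn_count[i], s$cn_count)
  }
  # tie rule: equal scores ordered by cn desc then id asc
  ties <- list(
    structure(list(query_id = "q", candidate_id = "x2", syndrome = "A",
                   cn_count = 2, score = 1,
                   breakdown = data.frame()), class = "similarity_score"),
    structure(list(query_id = "q", candidate_id = "x1", syndrome = "A",
                   cn_count = 2, score = 1,
                   breakdown = data.frame()), class = "similarity_score"),
    structure(list(query_id = "q", candidate_id = "x3", syndrome = "A",
                   cn_count = 3, score = 1,
                   breakdown = data.frame()), class = "similarity_score"))
  srt <- kgdx:::sort_ranking(ties)
  expect_equal(vapply(srt, `[[`, character(1), "candidate_id"),
               c("x3", "x1", "x2"))
  expect_error(score_all(fx$graph, "p01", character(), fx$table),
               "empty candidate set")
})
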