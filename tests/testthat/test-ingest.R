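test_that("records round-trip through JSONL and CSV with validation", {
  dir <- withr::local_tempdir()
  jl <- file.path(dir, "r.jsonl")
  writeLines(c(
    '{"patient_id":"p1","features":["tinnitus"," fine pulse "],"syndrome":"KED"}',
    '{"patient_id":"p2","features":["tinnitus"]}',
    '{"patient_id":"p3","features":["dizziness"],"syndrome":"QDSS"}'), jl)
  recs <- read_records(jl)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$features[[1]], c("tinnitus", "fine pulse"))  # trimmed
  expect_true(is.na(recs$syndrome[2]))

  csv <- file.path(dir, "r.csv")
  writeLines(c("patient_id,features,syndrome",
               "p1,tinnitus|fine pulse,KED",
               "p2,tinnitus,"), csv)
  recs2 <- read_records(csv)
  expect_equal(recs2$features[[1]], c("tinnitus", "fine pulse"))
  expect_true(is.na(recs2$syndrome[2]))

  rt <- file.path(dir, "rt.jsonl")
  write_records(recs, rt)
  expect_equal(read_records(rt), recs)
})

test_that("ingest rejects empty features, duplicate ids and unknown labels", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "empty.jsonl")
  writeLines(c('{"patient_id":"p1","features":["a"]}',
               '{"patient_id":"p2","features":["  "]}'), f1)
  expect_error(read_records(f1), "row 2.*p2")
  f2 <- file.path(dir, "dup.jsonl")
  writeLines(rep('{"patient_id":"p1","features":["a"]}', 2), f2)
  expect_error(read_records(f2), "duplicate patient_id 'p1'")
  f3 <- file.path(dir, "syn.jsonl")
  writeLines('{"patient_id":"p1","features":["a"],"syndrome":"XYZ"}', f3)
  expect_error(read_records(f3), "unknown syndrome label 'XYZ'")
  writeLines('{"patient_id":"p1","features":["a"],"syndrome":"KED"}', f3)
  expect_silent(read_records(f3))
})

test_that("string similarity matches hand-computed edit distances", {
  expect_equal(string_similarity("abc", "abc"), 1)
  expect_equal(string_similarity("abc", "xyz"), 0)
  # one substitution over max length 4
  expect_equal(string_similarity("abcd", "abce"), 0.75)
  # symmetric
  expect_equal(string_similarity("kidney", "kidny"),
               string_similarity("kidny", "kidney"))
  # LCS ratio: LCS("abcd","abce") = 3, 2*3/8
  expect_equal(string_similarity("abcd", "abce", method = "lcs"), 0.75)
  expect_equal(string_similarity("ab", "ba", method = "lcs"), 0.5)
  # per-character comparison for multibyte strings
  expect_equal(string_similarity("肾虚", "肾虚"), 1)
  expect_equal(string_similarity("肾虚证", "肾虚"),
               1 - 1 / 3)
  expect_error(string_similarity("", "a"), "non-empty")
})

test_that("alignment maps to best candidate above threshold, overrides win", {
  canon <- c("Fine pulse", "Yellow fur", "Duration")
  map <- align_entities(c("Fine pulse", "fine pulse", "Fin pulse", "zzz"),
                        canon, threshold = 0.6)
  expect_equal(apply_alignment(map, "Fine pulse"), "Fine pulse")
  expect_equal(apply_alignment(map, "Fin pulse"), "Fine pulse")
  expect_equal(apply_alignment(map, "zzz"), "zzz")  # below threshold
  # boundary: similarity strictly below threshold stays unmapped
  m2 <- align_entities("abcf", "abcd", threshold = 0.76)
  expect_equal(apply_alignment(m2, "abcf"), "abcf")
  m3 <- align_entities("abcf", "abcd", threshold = 0.75)
  expect_equal(apply_alignment(m3, "abcf"), "abcd")
  # argmax: closer candidate wins
  m4 <- align_entities("abcde", c("abcdX", "abXXX"), threshold = 0.5)
  expect_equal(apply_alignment(m4, "abcde"), "abcdX")
  # override beats automatic match
  ov <- data.frame(raw = "Fin pulse", canonical = "Duration")
  m5 <- align_entities("Fin pulse", canon, overrides = ov)
  expect_equal(apply_alignment(m5, "Fin pulse"), "Duration")
  # idempotence: applying twice equals applying once
  raws <- c("Fine pulse", "Fin pulse", "zzz")
  once <- apply_alignment(map, raws)
  expect_equal(apply_alignment(map, once), once)
})

test_that("build_graph creates the expected nodes, edges and dedups labels", {
  recs <- tibble::tibble(
    patient_id = c("p1", "p2"),
    features = list(c("f1", "f2", "f3"), c("f1", "f4")),
    syndrome = c("KED", NA))
  g <- build_graph(recs[1, ])
  # 1 patient + 3 features + 1 syndrome = 5 entities; 3 + 1 edges
  expect_equal(entity_count(g), 5)
  expect_equal(relation_count(g), 4)
  g2 <- build_graph(recs)
  # shared feature f1 becomes a single node
  expect_equal(sum(g2$nodes$etype == "symptom"), 4)
  expect_length(kg_common_neighbors(g2, "p1", "p2"), 1)
  # every feature reachable from its patient in exactly one hop
  for (i in 1:2) {
    nb <- kg_neighbors(g2, recs$patient_id[i], etype = "symptom")
    labs <- g2$nodes$label[match(nb, g2$nodes$id)]
    expect_setequal(labs, recs$features[[i]])
  }
})

test_that("knowledge triples join the graph after alignment", {
  recs <- tibble::tibble(patient_id = "p1",
                         features = list(c("symptomA", "symptomB")),
                         syndrome = "KED")
  triples <- data.frame(source = "symptomA", rtype = "indicates",
                        target = "KED")
  g <- build_graph(recs, triples = triples)
  sa <- g$nodes$id[g$nodes$label == "symptomA"]
  expect_true("KED" %in% kg_neighbors(g, sa))
  expect_true("indicates" %in% g$edges$rtype)
})

test_that("graph construction is order-independent up to isomorphism", {
  recs <- withr::with_seed(11, {
    cfg <- default_config(class_sizes = c(KED = 10, QDSS = 10), seed = 3)
    generate_cohort(cfg)
  })
  g1 <- build_graph(recs)
  g2 <- build_graph(recs[rev(seq_len(nrow(recs))), ])
  expect_equal(entity_count(g1), entity_count(g2))
  expect_equal(relation_count(g1), relation_count(g2))
  expect_setequal(g1$nodes$id, g2$nodes$id)
  for (p in recs$patient_id[1:5])
    expect_setequal(kg_neighbors(g1, p), kg_neighbors(g2, p))
})
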