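test_that("stratified folds balance classes and partition the cohort", {
  recs <- tibble::tibble(patient_id = sprintf("p%02d", 1:10),
                         features = replicate(10, "f", simplify = FALSE),
                         syndrome = rep(c("KED", "QDSS"), each = 5))
  folds <- stratified_folds(recs, n_folds = 5, seed = 4)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test_ids")
  expect_setequal(unlist(tests), recs$patient_id)     # exhaustive
  expect_equal(anyDuplicated(unlist(tests)), 0)       # disjoint
  for (f in folds) {
    labs <- recs$syndrome[match(f$test_ids, recs$patient_id)]
    expect_equal(as.integer(table(labs)), c(1L, 1L))
    expect_setequal(c(f$train_ids, f$test_ids), recs$patient_id)
  }
  expect_equal(stratified_folds(recs, 5, seed = 4), folds)  # deterministic
  expect_error(stratified_folds(recs, n_folds = 6), "'KED'")
})

test_that("per-fold class counts stay within one of n_c / 5 at full scale", {
  recs <- generate_cohort(default_config(seed = 21))
  folds <- stratified_folds(recs, n_folds = 5, seed = 2)
  sizes <- table(recs$syndrome)
  for (f in folds) {
    labs <- recs$syndrome[match(f$test_ids, recs$patient_id)]
    cnt <- table(labs)
    for (cl in names(sizes))
      expect_lte(abs(cnt[[cl]] - sizes[[cl]] / 5), 1)
  }
})

test_that("confusion metrics match textbook arithmetic and flag 0/0", {
  perfect <- data.frame(class = "A", TP = 10, FP = 0, TN = 90, FN = 0)
  mp <- confusion_metrics(perfect)
  expect_equal(unlist(mp[1, c("accuracy", "precision", "sensitivity",
                              "specificity", "f1")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1, f1 = 1))
  m <- confusion_metrics(
    data.frame(class = "A", TP = 8, FP = 2, TN = 88, FN = 2))
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 88 / 90, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$f1, 0.8)
  deg <- confusion_metrics(
    data.frame(class = "A", TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(deg$precision, 0)
  expect_true(deg$undefined)
  expect_error(confusion_metrics(
    data.frame(class = "A", TP = -1, FP = 0, TN = 0, FN = 0)), "nonnegative")
})

test_that("rank-based AUC equals exhaustive pair counting", {
  labels <- c(rep("A", 4), rep("B", 6))
  sep <- matrix(c(10, 9, 8, 7, 1:6, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1), 10, 2,
                dimnames = list(NULL, c("A", "B")))
  auc <- one_vs_rest_auc(sep, labels)
  expect_equal(unname(auc["A"]), 1)  # perfectly separated
  flat <- matrix(1, 10, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(one_vs_rest_auc(flat, labels)), c(0.5, 0.5))
  withr::with_seed(55, {
    for (i in 1:20) {
      sc <- matrix(sample(0:5, 20, replace = TRUE), 10, 2,
                   dimnames = list(NULL, c("A", "B")))
      labs <- sample(c("A", "B"), 10, replace = TRUE)
      got <- one_vs_rest_auc(sc, labs)
      for (cl in c("A", "B"))
        expect_equal(unname(got[cl]),
                     oracle_auc(sc[, cl], labs == cl))
    }
  })
  one_class <- one_vs_rest_auc(flat, rep("A", 10))
  expect_true(is.na(one_class["B"]))
})

test_that("a cohort of per-class clones cross-validates perfectly", {
  recs <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:20),
    features = c(replicate(10, c("k1", "k2"), simplify = FALSE),
                 replicate(10, c("q1", "q2"), simplify = FALSE)),
    syndrome = rep(c("KED", "QDSS"), each = 10))
  rep1 <- run_cv(recs, cv_config(k = 3, seed = 1, n_folds = 5,
                                 methods = c("wcn", "cn")))
  expect_true(all(rep1$per_fold$accuracy == 1))
  expect_true(all(rep1$per_fold$f1 == 1))
  expect_equal(unname(rep1$overall), c(1, 1))
})

test_that("cross-validation is deterministic given the seed", {
  recs <- generate_cohort(default_config(
    class_sizes = c(KED = 30, LFBU = 30, QDSS = 30), seed = 14))
  cfg <- cv_config(k = 5, seed = 99, methods = c("wcn", "cn"))
  r1 <- run_cv(recs, cfg)
  r2 <- run_cv(recs, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("batch fold scorer agrees with per-pair scoring plus top-k vote", {
  recs <- generate_cohort(default_config(
    class_sizes = c(KED = 15, LFBU = 15, PFSI = 15), seed = 33))
  folds <- stratified_folds(recs, n_folds = 3, seed = 5)
  train <- recs[recs$patient_id %in% folds[[1]]$train_ids, ]
  test <- recs[recs$patient_id %in% folds[[1]]$test_ids, ]
  g <- build_graph(train)
  tab <- compute_weight_table(train)
  cfg <- cv_config(k = 7, seed = 5, n_folds = 3, methods = c("wcn", "cn"))
  batch <- kgdx:::score_fold(train, test, cfg)
  for (i in seq_len(nrow(test))) {
    d <- suppressWarnings(
      diagnose(g, list(patient_id = test$patient_id[i],
                       features = test$features[[i]]), tab, k = 7))
    expect_equal(batch$wcn$pred[i], d$predicted)
    cs <- batch$wcn$class_scores[i, ]
    expect_equal(cs[names(d$class_scores)], d$class_scores,
                 tolerance = 1e-9, ignore_attr = TRUE)
    du <- suppressWarnings(
      diagnose(g, list(patient_id = test$patient_id[i],
                       features = test$features[[i]]), tab, k = 7,
               mode = "unweighted"))
    expect_equal(batch$cn$pred[i], du$predicted)
  }
})

test_that("training-fold weights ignore test-fold labels entirely", {
  recs <- generate_cohort(default_config(
    class_sizes = c(KED = 20, QDSS = 20), seed = 44))
  folds <- stratified_folds(recs, n_folds = 4, seed = 6)
  train <- recs[recs$patient_id %in% folds[[1]]$train_ids, ]
  shuffled <- recs
  test_rows <- shuffled$patient_id %in% folds[[1]]$test_ids
  shuffled$syndrome[test_rows] <-
    rev(shuffled$syndrome[test_rows])
  train2 <- shuffled[shuffled$patient_id %in% folds[[1]]$train_ids, ]
  expect_identical(compute_weight_table(train),
                   compute_weight_table(train2))
})
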