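# Stratified k-fold cross-validation of graph-based diagnosis, with
# one-vs-rest confusion metrics and rank-based AUC per syndrome. Weight
# tables are fitted on the training fold only by default, so no label
# information leaks from the test fold into the edge weights.

#' Stratified cross-validation folds
#'
#' Partitions a labeled cohort into `n_folds` test sets so that per-class
#' counts differ by at most one across folds. Deterministic for a given
#' seed.
#'
#' @param records Labeled record tibble.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of length `n_folds`; each element has `train_ids` and
#'   `test_ids` (character vectors of patient ids).
#' @export
stratified_folds <- function(records, n_folds = 5, seed = 1) {
  stopifnot(n_folds >= 2)
  if (anyNA(records$syndrome))
    stop("stratified folds need fully labeled records", call. = FALSE)
  classes <- split(records$patient_id, records$syndrome)
  small <- names(classes)[lengths(classes) < n_folds]
  if (length(small))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 small[1], length(classes[[small[1]]]), n_folds),
         call. = FALSE)
  assign <- withr::with_seed(seed, {
    unlist(lapply(names(classes), function(cl) {
      ids <- classes[[cl]]
      stats::setNames(rep_len(seq_len(n_folds), length(ids)), sample(ids))
    }))
  })
  all_ids <- records$patient_id
  lapply(seq_len(n_folds), function(f) {
    test <- names(assign)[assign == f]
    list(train_ids = setdiff(all_ids, test),
         test_ids = all_ids[all_ids %in% test])
  })
}

#' One-vs-rest confusion metrics
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and `F1 = 2PR/(P+R)` from one-vs-rest counts.
#' A 0/0 ratio is reported as 0 and flagged in `undefined`.
#'
#' @param counts Data frame with columns `class`, `TP`, `FP`, `TN`, `FN`.
#' @return Tibble with one row per class: the five metrics plus an
#'   `undefined` flag.
#' @export
confusion_metrics <- function(counts) {
  with_cols <- c("class", "TP", "FP", "TN", "FN")
  stopifnot(all(with_cols %in% names(counts)))
  if (any(counts[c("TP", "FP", "TN", "FN")] < 0))
    stop("confusion counts must be nonnegative", call. = FALSE)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  precision <- safe_div(counts$TP, counts$TP + counts$FP)
  sensitivity <- safe_div(counts$TP, counts$TP + counts$FN)
  tibble::tibble(
    class = counts$class,
    accuracy = safe_div(counts$TP + counts$TN, n),
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_div(counts$TN, counts$TN + counts$FP),
    f1 = safe_div(2 * precision * sensitivity, precision + sensitivity),
    undefined = (counts$TP + counts$FP == 0) | (counts$TP + counts$FN == 0) |
      (counts$TN + counts$FP == 0))
}

#' Rank-based one-vs-rest AUC
#'
#' For each class, the probability that a randomly chosen positive patient
#' receives a higher class score than a randomly chosen negative, ties
#' counted one half (the Mann-Whitney statistic). Classes absent from the
#' labels get `NA`.
#'
#' @param score_matrix Numeric matrix, patients x classes, e.g. stacked
#'   [class_scores()] rows.
#' @param labels True syndrome per patient (length `nrow(score_matrix)`).
#' @return Named numeric vector of AUCs over `colnames(score_matrix)`.
#' @export
one_vs_rest_auc <- function(score_matrix, labels) {
  stopifnot(nrow(score_matrix) == length(labels))
  vapply(colnames(score_matrix), function(cl) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(score_matrix[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Cross-validation configuration
#'
#' @param k Vote size (default 20).
#' @param mode Weighted scoring mode, see [wcn_score()].
#' @param alpha Smoothing for [compute_weight_table()].
#' @param seed Integer seed driving fold assignment.
#' @param n_folds Number of folds.
#' @param methods Scoring methods to evaluate: any of `"wcn"` (weighted
#'   common neighbors), `"cn"`, `"aa"` (Adamic-Adar), `"ra"` (resource
#'   allocation).
#' @param leakage_safe Fit weights on the training fold only (default).
#'   `FALSE` fits once on the whole cohort before splitting.
#' @param triples Optional knowledge-triple data frame added to every
#'   training graph as global background.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(k = 20, mode = "candidate-syndrome", alpha = 0,
                      seed = 1, n_folds = 5,
                      methods = c("wcn", "cn", "aa", "ra"),
                      leakage_safe = TRUE, triples = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(k = k, mode = mode, alpha = alpha, seed = seed,
                 n_folds = n_folds, methods = methods,
                 leakage_safe = leakage_safe, triples = triples),
            class = "cv_config")
}

# Batch scorer over one training fold. Returns, per test patient and
# method, the predicted label and per-class scores, using sparse
# matrix-vector products; equivalent to per-pair score_all + top_k_vote
# (asserted in the test suite) but linear in the number of edges.
score_fold <- function(train, test, config) {
  tab <- if (is.null(config$whole_table))
    compute_weight_table(train, alpha = config$alpha) else config$whole_table
  graph <- build_graph(train, triples = config$triples)
  entities <- tab$entities   # feature labels as seen in records
  # record features are labels; translate to the graph's slug ids for
  # degree lookups, keeping the label-keyed weight matrices for scoring
  lab2id <- stats::setNames(graph$nodes$id, graph$nodes$label)
  m_train <- cohort_matrix(train, entities)
  # entity degree in the training graph, plus one for the transiently
  # attached query (so Adamic-Adar/resource-allocation match scoring the
  # query as a temporary node of the graph)
  deg <- lengths(graph$adj[lab2id[entities]]) + 1
  syndromes <- sort(unique(train$syndrome), method = "radix")
  labels <- train$syndrome
  per_method <- lapply(config$methods, function(method) {
    preds <- character(nrow(test))
    cls <- matrix(0, nrow(test), length(syndromes),
                  dimnames = list(test$patient_id, syndromes))
    for (i in seq_len(nrow(test))) {
      f <- as.numeric(entities %in% test$features[[i]])
      cn <- as.numeric(m_train %*% f)
      score <- switch(method,
        cn = cn,
        aa = as.numeric(m_train %*% (f / log(deg))),
        ra = as.numeric(m_train %*% (f / deg)),
        wcn = {
          s <- numeric(nrow(train))
          for (sy in syndromes) {
            idx <- labels == sy
            w <- f * tab$combined[entities, sy]
            if (config$mode == "both-hops") w <- 2 * w
            s[idx] <- as.numeric(m_train[idx, , drop = FALSE] %*% w)
          }
          s
        })
      ord <- order(-score, -cn, train$patient_id, method = "radix")
      top <- ord[seq_len(min(config$k, length(ord)))]
      vt <- table(labels[top])
      ss <- tapply(score[top], labels[top], sum)
      o2 <- order(-as.numeric(vt), -as.numeric(ss[names(vt)]), names(vt),
                  method = "radix")
      preds[i] <- names(vt)[o2][1]
      mass <- ss
      if (sum(mass) <= 0) mass <- vt / sum(vt)
      cls[i, names(mass)] <- as.numeric(mass) / sum(as.numeric(mass))
    }
    list(pred = preds, class_scores = cls)
  })
  stats::setNames(per_method, config$methods)
}

#' Run stratified cross-validation
#'
#' For every fold: a knowledge graph and weight table are fitted from the
#' training records only (unless `leakage_safe = FALSE` in the config),
#' every test patient is diagnosed by top-k vote under each configured
#' scoring method, and one-vs-rest confusion counts, the five confusion
#' metrics and rank-based AUC are accumulated per syndrome.
#'
#' @param records Labeled record tibble.
#' @param config A `cv_config`.
#' @return A `cv_report`: list with `per_fold` (tibble: fold, method,
#'   class, the six metrics), `summary` (mean and SD over folds per method
#'   and class), `overall` (multiclass accuracy per method), `predictions`
#'   and the `config`.
#' @export
run_cv <- function(records, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  if (anyNA(records$syndrome))
    stop("cross-validation needs a fully labeled cohort", call. = FALSE)
  folds <- stratified_folds(records, config$n_folds, config$seed)
  if (!config$leakage_safe)
    config$whole_table <- compute_weight_table(records, alpha = config$alpha)
  classes <- sort(unique(records$syndrome), method = "radix")
  per_fold <- list()
  predictions <- list()
  for (f in seq_along(folds)) {
    train <- records[records$patient_id %in% folds[[f]]$train_ids, ]
    test <- records[records$patient_id %in% folds[[f]]$test_ids, ]
    res <- score_fold(train, test, config)
    for (method in names(res)) {
      pred <- res[[method]]$pred
      truth <- test$syndrome
      counts <- data.frame(class = classes,
        TP = vapply(classes, function(cl) sum(pred == cl & truth == cl), 0),
        FP = vapply(classes, function(cl) sum(pred == cl & truth != cl), 0),
        TN = vapply(classes, function(cl) sum(pred != cl & truth != cl), 0),
        FN = vapply(classes, function(cl) sum(pred != cl & truth == cl), 0))
      met <- confusion_metrics(counts)
      met$auc <- unname(
        one_vs_rest_auc(res[[method]]$class_scores, truth)[met$class])
      met$fold <- f
      met$method <- method
      per_fold[[length(per_fold) + 1L]] <- met
      predictions[[length(predictions) + 1L]] <- tibble::tibble(
        fold = f, method = method, patient_id = test$patient_id,
        truth = truth, predicted = pred)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  predictions <- do.call(rbind, predictions)
  metric_cols <- c("accuracy", "precision", "sensitivity", "specificity",
                   "f1", "auc")
  summ <- do.call(rbind, lapply(split(per_fold,
                                      per_fold[c("method", "class")]),
    function(d) tibble::tibble(
      method = d$method[1], class = d$class[1],
      metric = metric_cols,
      mean = vapply(metric_cols, function(mc) mean(d[[mc]]), numeric(1)),
      sd = vapply(metric_cols, function(mc) stats::sd(d[[mc]]), numeric(1)))))
  rownames(summ) <- NULL
  overall <- vapply(unique(predictions$method), function(method) {
    d <- predictions[predictions$method == method, ]
    mean(d$predicted == d$truth)
  }, numeric(1))
  structure(list(per_fold = tibble::as_tibble(per_fold),
                 summary = tibble::as_tibble(summ),
                 overall = overall, predictions = predictions,
                 config = config),
            class = "cv_report")
}

#' Mean of one metric across folds and classes
#'
#' @param report A `cv_report`.
#' @param method Scoring method name.
#' @param metric One of `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `auc`.
#' @return Mean of the per-class fold means.
#' @export
cv_mean <- function(report, method, metric) {
  s <- report$summary
  mean(s$mean[s$method == method & s$metric == metric], na.rm = TRUE)
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified CV, methods: %s\n",
              x$config$n_folds, paste(x$config$methods, collapse = ", ")))
  for (m in names(x$overall))
    cat(sprintf("  %-4s multiclass accuracy %.4f | per-class mean acc %.4f, F1 %.4f, AUC %.4f\n",
                m, x$overall[m], cv_mean(x, m, "accuracy"),
                cv_mean(x, m, "f1"), cv_mean(x, m, "auc")))
  invisible(x)
}
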