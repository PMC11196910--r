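# Top-k vote over the similarity ranking: the predicted syndrome is the
# modal label among the k highest-scoring labeled patients (k = 20 by
# default), with deterministic tie-breaking. Class scores (normalized top-k
# score mass per syndrome) provide the continuous output needed for ROC
# analysis of a vote-based classifier.

#' Top-k majority vote over a similarity ranking
#'
#' Takes the top `min(k, n)` candidates of a descending-sorted ranking and
#' predicts the modal syndrome. Vote ties are broken by the larger summed
#' similarity score, then lexicographically by syndrome label, so the
#' result is deterministic.
#'
#' @param ranking A `similarity_ranking` from [score_all()] (descending).
#' @param k Number of neighbors to vote (default 20).
#' @return A `diagnosis_result`: list with `query_id`, `predicted`,
#'   `k_used`, `votes` (named integer), `class_scores` (named numeric
#'   summing to 1) and `top_list` (the top-k `similarity_score` entries).
#' @export
top_k_vote <- function(ranking, k = 20) {
  if (!length(ranking)) stop("empty ranking", call. = FALSE)
  stopifnot(k >= 1)
  top <- ranking[seq_len(min(k, length(ranking)))]
  labs <- vapply(top, `[[`, character(1), "syndrome")
  if (anyNA(labs)) stop("top-k candidates must all be labeled", call. = FALSE)
  scores <- vapply(top, `[[`, numeric(1), "score")
  votes <- sort(table(labs), decreasing = TRUE)
  score_sum <- vapply(names(votes), function(s) sum(scores[labs == s]),
                      numeric(1))
  ord <- order(-as.numeric(votes), -score_sum, names(votes), method = "radix")
  predicted <- names(votes)[ord][1]
  structure(list(query_id = top[[1]]$query_id, predicted = predicted,
                 k_used = length(top),
                 votes = stats::setNames(as.integer(votes), names(votes)),
                 class_scores = class_scores(ranking, k),
                 top_list = top),
            class = "diagnosis_result")
}

#' Normalized per-syndrome score mass in the top-k
#'
#' For each syndrome, the sum of similarity scores of top-k candidates with
#' that label, normalized to sum to 1. If every top-k score is zero the
#' vote fractions are used instead. This is the continuous class score used
#' for one-vs-rest ROC curves.
#'
#' @inheritParams top_k_vote
#' @return Named numeric vector over the syndromes present in the top-k,
#'   summing to 1.
#' @export
class_scores <- function(ranking, k = 20) {
  if (!length(ranking)) stop("empty ranking", call. = FALSE)
  top <- ranking[seq_len(min(k, length(ranking)))]
  labs <- vapply(top, `[[`, character(1), "syndrome")
  scores <- vapply(top, `[[`, numeric(1), "score")
  sums <- tapply(scores, labs, sum)
  if (sum(sums) <= 0) sums <- table(labs) / length(labs)
  out <- as.numeric(sums) / sum(as.numeric(sums))
  stats::setNames(out, names(sums))
}

#' Diagnose a query patient against a knowledge graph
#'
#' Scores the query's feature set against every labeled patient in the
#' graph by weighted common neighbors and applies the top-k vote. The query
#' is evaluated transiently: the graph is not modified. Query features
#' missing from the graph vocabulary are skipped with a warning (or an
#' error in strict mode); a query with no usable features is an error.
#'
#' @param graph A `knowledge_graph` of labeled patients.
#' @param query Either a record tibble row, or a list with `patient_id` and
#'   `features` (feature labels; aligned to graph node ids internally).
#' @param table A `weight_table` from [compute_weight_table()]; entities
#'   keyed by feature label or by graph node id both work.
#' @param k Vote size; default 20.
#' @param mode Scoring mode, see [wcn_score()].
#' @param alignment Optional `alignment_map` applied to query features.
#' @param strict Error (rather than warn) on unknown query features.
#' @return A `diagnosis_result` (see [top_k_vote()]).
#' @export
diagnose <- function(graph, query, table, k = 20,
                     mode = "candidate-syndrome", alignment = NULL,
                     strict = FALSE) {
  feats <- unique(apply_alignment(alignment, unlist(query$features)))
  qid <- as.character(query$patient_id)
  table <- table_on_graph_ids(table, graph)
  # map feature labels to graph node ids
  lab2id <- stats::setNames(graph$nodes$id, graph$nodes$label)
  ids <- ifelse(feats %in% graph$nodes$id, feats,
                unname(lab2id[feats]))
  unknown <- feats[is.na(ids)]
  if (length(unknown)) {
    msg <- sprintf("query '%s': %d unknown feature(s) skipped: %s", qid,
                   length(unknown), paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  ids <- ids[!is.na(ids)]
  if (!length(ids))
    stop(sprintf("query '%s' has no features known to the graph", qid),
         call. = FALSE)
  candidates <- kg_patients(graph, labeled_only = TRUE)
  candidates <- setdiff(candidates, qid)
  if (!length(candidates)) stop("no labeled candidate patients", call. = FALSE)
  syn <- patient_syndromes(graph, candidates)
  scores <- lapply(candidates, function(cid) {
    cn <- sort(intersect(ids, graph$adj[[cid]]), method = "radix")
    cn <- cn[graph$etype_of[cn] != "syndrome"]
    w <- switch(mode,
      `candidate-syndrome` = vapply(cn, function(h)
        lookup_weight(table, h, syn[[cid]]), numeric(1)),
      `both-hops` = 2 * vapply(cn, function(h)
        lookup_weight(table, h, syn[[cid]]), numeric(1)),
      unweighted = rep(1, length(cn)),
      stop(sprintf("unknown mode '%s'", mode), call. = FALSE))
    structure(list(query_id = qid, candidate_id = cid,
                   syndrome = syn[[cid]], cn_count = length(cn),
                   score = sum(w),
                   breakdown = data.frame(entity = cn, weight = unname(w),
                                          row.names = NULL,
                                          stringsAsFactors = FALSE)),
              class = "similarity_score")
  })
  top_k_vote(sort_ranking(scores), k)
}

#' @exportS3Method base::print
print.diagnosis_result <- function(x, ...) {
  cat(sprintf("<diagnosis_result> query %s -> %s (k = %d)\n",
              x$query_id, x$predicted, x$k_used))
  cat("  votes:",
      paste(sprintf("%s %d", names(x$votes), x$votes), collapse = ", "), "\n")
  invisible(x)
}

#' Explain a diagnosis
#'
#' Produces the audit trail of a top-k vote: (i) the ranked neighbor table
#' (patient id, common-neighbor count, similarity score, syndrome) and
#' (ii) the per-candidate shared-entity breakdowns whose weights sum to
#' each reported score.
#'
#' @param result A `diagnosis_result` from [diagnose()].
#' @return A `diagnosis_explanation`: list with `query_id`, `predicted`,
#'   `top_table` (data frame) and `breakdowns` (named list of data frames).
#' @export
explain <- function(result) {
  stopifnot(inherits(result, "diagnosis_result"))
  top_table <- as.data.frame(structure(result$top_list,
                                       class = "similarity_ranking"))
  breakdowns <- stats::setNames(lapply(result$top_list, `[[`, "breakdown"),
                                top_table$candidate_id)
  structure(list(query_id = result$query_id, predicted = result$predicted,
                 votes = result$votes, top_table = top_table,
                 breakdowns = breakdowns),
            class = "diagnosis_explanation")
}

#' @exportS3Method base::print
print.diagnosis_explanation <- function(x, max_breakdowns = 3, ...) {
  cat(sprintf("Diagnosis for %s: %s\n\n", x$query_id, x$predicted))
  cat("Top neighbors (patient id / common neighbors / score / syndrome):\n")
  print(x$top_table, row.names = FALSE)
  shown <- utils::head(names(x$breakdowns), max_breakdowns)
  for (cid in shown) {
    b <- x$breakdowns[[cid]]
    cat(sprintf("\nShared entities with %s (sum %.4f):\n  %s\n", cid,
                sum(b$weight),
                paste(sprintf("%s (%.4f)", b$entity, b$weight),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Render an explanation to Markdown
#'
#' @param x A `diagnosis_explanation`.
#' @param path Optional file to write.
#' @return Character vector of Markdown lines (invisibly when `path` given).
#' @export
format_explanation_md <- function(x, path = NULL) {
  stopifnot(inherits(x, "diagnosis_explanation"))
  lines <- c(sprintf("# Diagnosis: %s -> %s", x$query_id, x$predicted), "",
             "| Patient ID | Neighbors | Neighbors score | Syndrome |",
             "|---|---|---|---|",
             sprintf("| %s | %d | %.2f | %s |", x$top_table$candidate_id,
                     as.integer(x$top_table$cn_count), x$top_table$score,
                     x$top_table$syndrome),
             "")
  for (cid in names(x$breakdowns)) {
    b <- x$breakdowns[[cid]]
    lines <- c(lines, sprintf("**%s**: %s", cid,
                              paste(sprintf("%s (%.4f)", b$entity, b$weight),
                                    collapse = ", ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = FALSE)
    return(invisible(lines))
  }
  lines
}
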