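# Patient-patient similarity by weighted common neighbors: every 2-hop path
# query -> shared entity h -> candidate contributes the combined edge weight
# of h under the candidate's syndrome. Plain common-neighbor count,
# Adamic-Adar and resource allocation are kept as unweighted baselines.

#' Weighted common-neighbor similarity between two patients
#'
#' Scores the 2-hop paths between a query patient and a labeled candidate.
#' In the default `"candidate-syndrome"` mode each common neighbor `h`
#' contributes the combined weight of `h` under the candidate's syndrome
#' `s_y`; `"both-hops"` credits that weight on each of the two hops
#' (doubling every term); `"unweighted"` reduces to the common-neighbor
#' count. The returned breakdown lists every shared entity with its
#' contribution, so the score is fully auditable.
#'
#' @param graph A `knowledge_graph`.
#' @param query_id Patient id of the query (need not be labeled).
#' @param candidate_id Patient id of a labeled candidate.
#' @param table A `weight_table` whose entities are graph node ids (not
#'   needed in `"unweighted"` mode).
#' @param mode `"candidate-syndrome"`, `"both-hops"` or `"unweighted"`.
#' @return A `similarity_score`: list with `query_id`, `candidate_id`,
#'   `syndrome`, `cn_count`, `score` and a `breakdown` data frame
#'   (`entity`, `weight`).
#' @export
wcn_score <- function(graph, query_id, candidate_id, table = NULL,
                      mode = c("candidate-syndrome", "both-hops",
                               "unweighted")) {
  mode <- match.arg(mode)
  s_y <- unname(patient_syndromes(graph, candidate_id))
  if (mode != "unweighted" && is.na(s_y))
    stop(sprintf("candidate '%s' has no syndrome label", candidate_id),
         call. = FALSE)
  cn <- kg_common_neighbors(graph, query_id, candidate_id)
  cn <- sort(cn[graph$etype_of[cn] != "syndrome"], method = "radix")
  w <- switch(mode,
    `candidate-syndrome` = vapply(cn, function(h)
      lookup_weight(table, h, s_y), numeric(1)),
    `both-hops` = 2 * vapply(cn, function(h)
      lookup_weight(table, h, s_y), numeric(1)),
    unweighted = rep(1, length(cn)))
  structure(list(query_id = query_id, candidate_id = candidate_id,
                 syndrome = s_y, cn_count = length(cn), score = sum(w),
                 breakdown = data.frame(entity = cn, weight = unname(w),
                                        row.names = NULL,
                                        stringsAsFactors = FALSE)),
            class = "similarity_score")
}

#' @exportS3Method base::print
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %s ~ %s [%s]: %d common neighbors, score %.4f\n",
              x$query_id, x$candidate_id,
              if (is.na(x$syndrome)) "?" else x$syndrome,
              x$cn_count, x$score))
  invisible(x)
}

#' Baseline link-prediction scores
#'
#' `common_neighbors_score` counts the shared neighbors of two nodes.
#' `adamic_adar_score` sums `1 / log(deg(h))` over shared neighbors `h`
#' (natural log; the graph is undirected so degree stands in for outdegree).
#' `resource_allocation_score` sums `1 / deg(h)`.
#'
#' @param graph A `knowledge_graph`.
#' @param a,b Distinct node ids.
#' @return A single numeric score.
#' @export
common_neighbors_score <- function(graph, a, b) {
  length(kg_common_neighbors(graph, a, b))
}

#' @rdname common_neighbors_score
#' @export
adamic_adar_score <- function(graph, a, b) {
  cn <- kg_common_neighbors(graph, a, b)
  if (!length(cn)) return(0)
  deg <- lengths(graph$adj[cn])
  sum(1 / log(deg))
}

#' @rdname common_neighbors_score
#' @export
resource_allocation_score <- function(graph, a, b) {
  cn <- kg_common_neighbors(graph, a, b)
  if (!length(cn)) return(0)
  sum(1 / lengths(graph$adj[cn]))
}

#' Score a query patient against a set of candidates
#'
#' Computes [wcn_score()] for every candidate and returns the list sorted
#' in descending score order, ties broken by common-neighbor count
#' (descending) then candidate id (ascending), so rankings are
#' deterministic.
#'
#' @inheritParams wcn_score
#' @param candidate_ids Character vector of labeled patient ids.
#' @return A `similarity_ranking`: list of `similarity_score`, sorted.
#' @export
score_all <- function(graph, query_id, candidate_ids, table = NULL,
                      mode = "candidate-syndrome") {
  if (!length(candidate_ids))
    stop("empty candidate set", call. = FALSE)
  scores <- lapply(candidate_ids, function(cid)
    wcn_score(graph, query_id, cid, table, mode))
  sort_ranking(scores)
}

sort_ranking <- function(scores) {
  ord <- order(-vapply(scores, `[[`, numeric(1), "score"),
               -vapply(scores, `[[`, numeric(1), "cn_count"),
               vapply(scores, `[[`, character(1), "candidate_id"),
               method = "radix")
  structure(scores[ord], class = "similarity_ranking")
}

#' Turn a ranking into a data frame
#'
#' Columns mirror an explanation table: candidate id, neighbor count,
#' score, syndrome.
#'
#' @param x A `similarity_ranking`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as.data.frame.similarity_ranking <- function(x, ...) {
  data.frame(
    candidate_id = vapply(x, `[[`, character(1), "candidate_id"),
    cn_count = vapply(x, `[[`, numeric(1), "cn_count"),
    score = vapply(x, `[[`, numeric(1), "score"),
    syndrome = vapply(x, function(s)
      if (is.na(s$syndrome)) NA_character_ else s$syndrome, character(1)),
    stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.similarity_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<similarity_ranking> %d candidates\n", length(x)))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}
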