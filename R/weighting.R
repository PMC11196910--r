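# Edge weights for symptom -> syndrome relations: an information-gain term
# w_if shared by all syndromes (how much knowing the symptom's presence
# reduces uncertainty about the diagnostic pattern, in bits) plus a
# syndrome-conditional probability term w_sd = p(symptom | syndrome).
# The combined weight w_if + w_sd is what the similarity scorer consumes.

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of a label distribution
#'
#' `H = -sum p_j log2 p_j` in bits, with `0 * log 0 = 0`.
#'
#' @param p Numeric probability vector summing to 1 (within 1e-9).
#' @return Entropy in bits, between 0 and `log2(length(p))`.
#' @export
#' @examples
#' shannon_entropy(rep(1/5, 5))   # log2(5) = 2.3219...
#' shannon_entropy(c(1, 0, 0))    # 0
shannon_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
  pp <- p[p > 0]
  -sum(pp * log2(pp))
}

#' Conditional entropy H(Y | X)
#'
#' `H(Y|X) = sum_x p(x) H(Y | X = x)` over the empirical joint distribution
#' of a discrete feature and the syndrome labels.
#'
#' @param feature Discrete vector (logical presence/absence, or any factor).
#' @param labels Syndrome label vector of the same length.
#' @return Conditional entropy in bits; between 0 and `H(Y)`.
#' @export
conditional_entropy <- function(feature, labels) {
  if (length(feature) != length(labels))
    stop(sprintf("length mismatch: feature has %d values, labels %d",
                 length(feature), length(labels)), call. = FALSE)
  tab <- table(feature, labels)
  n <- sum(tab)
  px <- rowSums(tab) / n
  hy_given_x <- apply(tab, 1, entropy_from_counts)
  sum(px * hy_given_x)
}

#' Information gain of a feature for the syndrome label
#'
#' `Gain(Y, X) = H(Y) - H(Y|X)`, the mutual information between a feature's
#' presence and the diagnostic pattern, in bits. This is the per-entity
#' weight `w_if`.
#'
#' @inheritParams conditional_entropy
#' @return Gain in bits; between 0 and `H(Y)` (up to rounding).
#' @export
information_gain <- function(feature, labels) {
  hy <- entropy_from_counts(table(labels))
  g <- hy - conditional_entropy(feature, labels)
  max(g, 0)  # clamp -0 from floating-point cancellation
}

#' Syndrome-conditional symptom probabilities
#'
#' `w_sd(e, s) = (count(e present & syndrome s) + alpha) /
#' (count(syndrome s) + 2 alpha)`, the maximum-likelihood (or
#' Laplace-smoothed) estimate of `p(symptom | syndrome)` from a labeled
#' cohort.
#'
#' @param records Labeled record tibble (no `NA` syndromes).
#' @param alpha Smoothing pseudo-count; default 0 (plain ML estimate, which
#'   can produce exact zeros).
#' @return Matrix entities x syndromes of probabilities in \[0, 1\].
#' @export
syndrome_conditional_prob <- function(records, alpha = 0) {
  m <- cohort_matrix(records)
  if (anyNA(records$syndrome))
    stop("all records must be labeled; unlabeled patient: ",
         records$patient_id[which(is.na(records$syndrome))[1]], call. = FALSE)
  n_s <- table(records$syndrome)
  if (any(n_s == 0))
    stop("syndrome with zero patients: ", names(n_s)[n_s == 0][1],
         call. = FALSE)
  # counts[e, s] = number of syndrome-s patients presenting entity e
  counts <- t(rowsum(as.matrix(m), records$syndrome))
  sweep(counts + alpha, 2, as.numeric(n_s[colnames(counts)]) + 2 * alpha, "/")
}

# Binary patient x entity incidence matrix (sparse) from a record tibble.
cohort_matrix <- function(records, entities = NULL) {
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  if (is.null(entities))
    entities <- sort(unique(unlist(records$features)), method = "radix")
  j <- match(unlist(records$features), entities)
  i <- rep(seq_len(nrow(records)), lengths(records$features))
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(nrow(records), length(entities)),
                            dimnames = list(records$patient_id, entities))
  m
}

#' Compute the full weight table from a labeled cohort
#'
#' For every entity appearing in the cohort and every syndrome: the
#' information-gain weight `w_if` (entity-wide), the conditional probability
#' `w_sd`, and the combined edge weight `w_if + w_sd`.
#'
#' @inheritParams syndrome_conditional_prob
#' @return A `weight_table`: list with `entities`, `syndromes`, `w_if`
#'   (named numeric), `w_sd` and `combined` (entity x syndrome matrices),
#'   `alpha` and the cohort size `n`.
#' @export
compute_weight_table <- function(records, alpha = 0) {
  m <- cohort_matrix(records)
  if (anyNA(records$syndrome))
    stop("all records must be labeled", call. = FALSE)
  labels <- records$syndrome
  n <- nrow(m)
  n_s <- table(labels)
  hy <- entropy_from_counts(n_s)
  # per-entity 2 x k contingency via one matrix product
  pres <- t(rowsum(as.matrix(m), labels))          # entities x syndromes
  abs_ <- sweep(-pres, 2, as.numeric(n_s[colnames(pres)]), "+")
  n_pres <- rowSums(pres)
  h_pres <- apply(pres, 1, entropy_from_counts)
  h_abs <- apply(abs_, 1, entropy_from_counts)
  h_cond <- (n_pres * h_pres + (n - n_pres) * h_abs) / n
  w_if <- pmax(hy - h_cond, 0)
  w_sd <- sweep(pres + alpha, 2,
                as.numeric(n_s[colnames(pres)]) + 2 * alpha, "/")
  structure(list(entities = rownames(pres), syndromes = colnames(pres),
                 w_if = w_if, w_sd = w_sd,
                 combined = w_if + w_sd, alpha = alpha, n = n),
            class = "weight_table")
}

#' Look up a combined edge weight
#'
#' @param table A `weight_table` (from [compute_weight_table()] or
#'   [load_weight_table()]).
#' @param entity Entity label.
#' @param syndrome Syndrome label.
#' @return The combined weight `w_if + w_sd` for the pair.
#' @export
lookup_weight <- function(table, entity, syndrome) {
  stopifnot(inherits(table, "weight_table"))
  if (!entity %in% rownames(table$combined) ||
      !syndrome %in% colnames(table$combined))
    stop(sprintf("no weight for entity '%s' under syndrome '%s'",
                 entity, syndrome), call. = FALSE)
  v <- table$combined[entity, syndrome]
  if (is.na(v))
    stop(sprintf("no weight for entity '%s' under syndrome '%s'",
                 entity, syndrome), call. = FALSE)
  v
}

#' @exportS3Method base::print
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d entities x %d syndromes (alpha = %g, n = %s)\n",
              length(x$entities), length(x$syndromes), x$alpha,
              if (is.na(x$n)) "?" else x$n))
  invisible(x)
}

# Re-key a weight table from feature labels to the node ids of a graph
# (build_graph stores ASCII slug ids with the original label on the node).
# Entities already keyed by a graph id, or absent from the graph, pass
# through unchanged.
table_on_graph_ids <- function(table, graph) {
  stopifnot(inherits(table, "weight_table"))
  lab2id <- stats::setNames(graph$nodes$id, graph$nodes$label)
  rn <- table$entities
  new <- ifelse(rn %in% graph$nodes$id, rn,
                ifelse(rn %in% names(lab2id), unname(lab2id[rn]), rn))
  if (anyDuplicated(new)) return(table)  # ambiguous; keep label keys
  table$entities <- new
  names(table$w_if) <- new
  rownames(table$w_sd) <- new
  rownames(table$combined) <- new
  table
}

#' Write / read a weight table as TSV
#'
#' Long format with columns `entity  syndrome  w_if  w_sd  combined`.
#' Tables transcribed from published combined weights may omit `w_if` and
#' `w_sd`; such tables support [lookup_weight()] but not decomposition.
#'
#' @param table A `weight_table`.
#' @param path TSV file.
#' @return `path` (write) or a `weight_table` (load).
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "weight_table"))
  long <- expand.grid(entity = table$entities, syndrome = table$syndromes,
                      stringsAsFactors = FALSE)
  fmt <- function(m) format(m[cbind(long$entity, long$syndrome)],
                            digits = 17, trim = TRUE, scientific = FALSE)
  long$w_if <- format(table$w_if[long$entity], digits = 17, trim = TRUE,
                      scientific = FALSE)
  long$w_sd <- fmt(table$w_sd)
  long$combined <- fmt(table$combined)
  write_tsv_utf8(long, path)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
load_weight_table <- function(path) {
  df <- read_tsv_checked(path, c("entity", "syndrome", "combined"))
  entities <- sort(unique(df$entity), method = "radix")
  syndromes <- sort(unique(df$syndrome), method = "radix")
  mk <- function(col) {
    m <- matrix(NA_real_, length(entities), length(syndromes),
                dimnames = list(entities, syndromes))
    if (!is.null(df[[col]]))
      m[cbind(df$entity, df$syndrome)] <- suppressWarnings(as.numeric(df[[col]]))
    m
  }
  w_if <- mk("w_if")
  w_if_vec <- apply(w_if, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) r[1] else NA_real_
  })
  structure(list(entities = entities, syndromes = syndromes,
                 w_if = w_if_vec, w_sd = mk("w_sd"), combined = mk("combined"),
                 alpha = NA_real_, n = NA_integer_),
            class = "weight_table")
}
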