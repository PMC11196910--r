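# Structured-record ingest and heterogeneous knowledge fusion: read patient
# rows and curated triples, merge near-duplicate entity names by string
# similarity, and assemble the fused patient-symptom-syndrome graph.
# Free-text NLP extraction is out of scope: records arrive structured, and
# continuous findings arrive pre-binned as categorical labels.

#' Read structured patient records
#'
#' Accepts JSONL (one object per line with keys `patient_id`, `features`,
#' optional `syndrome`) or CSV (columns `patient_id`, `features` with
#' `|`-joined labels, optional `syndrome`). Feature strings are trimmed;
#' blank features are dropped. A row left with no features, a duplicate
#' patient id, or a syndrome outside `vocabulary` is an error.
#'
#' @param path Input file.
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (by file extension).
#' @param vocabulary Allowed syndrome labels (default the five tinnitus
#'   patterns in [SYNDROMES]).
#' @return A tibble with columns `patient_id` (character), `features`
#'   (list of character vectors) and `syndrome` (character, `NA` for
#'   unlabeled query patients).
#' @export
read_records <- function(path, format = c("auto", "jsonl", "csv"),
                         vocabulary = SYNDROMES) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "%s: line %d: invalid JSON (%s)", path, i,
                      conditionMessage(e)), call. = FALSE))
      if (is.null(x$patient_id) || is.null(x$features))
        stop(sprintf("%s: line %d: needs 'patient_id' and 'features'",
                     path, i), call. = FALSE)
      list(patient_id = as.character(x$patient_id),
           features = as.character(unlist(x$features)),
           syndrome = if (is.null(x$syndrome)) NA_character_
                      else as.character(x$syndrome))
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    miss <- setdiff(c("patient_id", "features"), names(df))
    if (length(miss))
      stop(sprintf("%s: missing required column '%s'", path, miss[1]),
           call. = FALSE)
    if (is.null(df$syndrome)) df$syndrome <- NA_character_
    rows <- lapply(seq_len(nrow(df)), function(i)
      list(patient_id = as.character(df$patient_id[i]),
           features = strsplit(df$features[i], "|", fixed = TRUE)[[1]],
           syndrome = if (is.na(df$syndrome[i]) || !nzchar(df$syndrome[i]))
                        NA_character_ else df$syndrome[i]))
  }
  recs <- tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    features = lapply(rows, function(r) {
      f <- trimws(r$features)
      unique(f[nzchar(f)])
    }),
    syndrome = vapply(rows, `[[`, character(1), "syndrome"))
  validate_records(recs, vocabulary, path)
}

validate_records <- function(recs, vocabulary = SYNDROMES, where = "records") {
  empty <- which(lengths(recs$features) == 0L)
  if (length(empty))
    stop(sprintf("%s: row %d (patient '%s') has no features", where,
                 empty[1], recs$patient_id[empty[1]]), call. = FALSE)
  dup <- recs$patient_id[duplicated(recs$patient_id)]
  if (length(dup))
    stop(sprintf("%s: duplicate patient_id '%s'", where, dup[1]),
         call. = FALSE)
  bad <- stats::na.omit(setdiff(unique(recs$syndrome), vocabulary))
  if (length(bad))
    stop(sprintf("%s: unknown syndrome label '%s'", where, bad[1]),
         call. = FALSE)
  recs
}

#' Write records as JSONL
#'
#' @param records Record tibble as produced by [read_records()] or
#'   [generate_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(patient_id = records$patient_id[i],
                features = records$features[[i]])
    if (!is.na(records$syndrome[i])) obj$syndrome <- records$syndrome[i]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' String similarity for entity alignment
#'
#' Character-level similarity in \[0, 1\], computed on Unicode code points so
#' CJK strings are compared per character. `"levenshtein"` (default) is
#' `1 - editdistance / max(nchar)`; `"lcs"` is the longest-common-subsequence
#' ratio `2 * LCS / (nchar(a) + nchar(b))`.
#'
#' @param a,b Non-empty strings (either may be a vector; they are recycled).
#' @param method `"levenshtein"` or `"lcs"`.
#' @return Numeric similarity in \[0, 1\], symmetric, 1 for identical strings.
#' @export
#' @examples
#' string_similarity("abcd", "abce")           # 0.75
#' string_similarity("abc", "xyz")             # 0
string_similarity <- function(a, b, method = c("levenshtein", "lcs")) {
  method <- match.arg(method)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("string_similarity requires non-empty strings", call. = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  la <- nchar(a, type = "chars"); lb <- nchar(b, type = "chars")
  if (method == "levenshtein") {
    d <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b)
    unname(1 - d / pmax(la, lb))
  } else {
    # substitution cost 2 makes edit distance equal la + lb - 2 * LCS
    d2 <- mapply(function(x, y)
      utils::adist(x, y, costs = list(ins = 1, del = 1, sub = 2))[1, 1], a, b)
    unname(1 - d2 / (la + lb))
  }
}

#' Align raw entity labels to a canonical vocabulary
#'
#' Each raw label maps to its highest-similarity canonical label when that
#' similarity reaches `threshold`, otherwise it maps to itself. Canonical
#' labels always map to themselves. Explicit overrides win over automatic
#' matches. The threshold default follows common practice for short clinical
#' entity strings, where a moderate cutoff avoids both missed merges and
#' false ones.
#'
#' @param labels Character vector of raw labels to align.
#' @param canonical Character vector: the canonical vocabulary.
#' @param threshold Similarity cutoff in (0, 1\]; default 0.6.
#' @param overrides Optional two-column data frame (`raw`, `canonical`) of
#'   manual decisions, or a path to a TSV with those columns.
#' @param method Passed to [string_similarity()].
#' @return An `alignment_map`: a tibble with columns `raw`, `canonical`,
#'   `similarity`, `source` (`identity` / `auto` / `override` /
#'   `unmatched`). Apply it with [apply_alignment()].
#' @export
align_entities <- function(labels, canonical, threshold = 0.6,
                           overrides = NULL,
                           method = c("levenshtein", "lcs")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold <= 1)
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- read_tsv_checked(overrides, c("raw", "canonical"))
  labels <- unique(labels)
  canonical <- unique(canonical)
  map <- tibble::tibble(raw = labels, canonical = labels,
                        similarity = NA_real_, source = "unmatched")
  is_canon <- labels %in% canonical
  map$source[is_canon] <- "identity"
  map$similarity[is_canon] <- 1
  todo <- which(!is_canon)
  if (length(todo) && length(canonical)) {
    for (i in todo) {
      sims <- string_similarity(map$raw[i], canonical, method = method)
      j <- which.max(sims)
      if (sims[j] >= threshold) {
        map$canonical[i] <- canonical[j]
        map$similarity[i] <- sims[j]
        map$source[i] <- "auto"
      }
    }
  }
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      k <- match(overrides$raw[i], map$raw)
      if (is.na(k)) {
        map <- rbind(map, tibble::tibble(raw = overrides$raw[i],
                                         canonical = overrides$canonical[i],
                                         similarity = NA_real_,
                                         source = "override"))
      } else {
        map$canonical[k] <- overrides$canonical[i]
        map$similarity[k] <- NA_real_
        map$source[k] <- "override"
      }
    }
  }
  class(map) <- c("alignment_map", class(map))
  map
}

#' Apply an alignment map to labels
#'
#' Labels absent from the map pass through unchanged, so applying a map is
#' idempotent.
#'
#' @param map An `alignment_map` from [align_entities()].
#' @param labels Character vector.
#' @return Character vector of canonical labels.
#' @export
apply_alignment <- function(map, labels) {
  if (is.null(map)) return(labels)
  i <- match(labels, map$raw)
  out <- ifelse(is.na(i), labels, map$canonical[i])
  as.character(out)
}

#' Read curated knowledge triples
#'
#' TSV with header `source  rtype  target`, one (entity, relation, entity)
#' triple per row.
#'
#' @param path TSV file.
#' @return Data frame with columns `source`, `rtype`, `target`.
#' @export
read_triples <- function(path) {
  read_tsv_checked(path, c("source", "rtype", "target"))
}

# ASCII-safe slug ids with a label map; built over sorted unique labels so
# ids do not depend on record order. Non-ASCII labels (the source vocabulary
# is Chinese) fall back to stable indexed ids.
make_id_map <- function(labels, prefix = "e") {
  labels <- sort(unique(labels), method = "radix")
  slug <- tolower(labels)
  slug <- gsub("[^a-z0-9]+", "_", slug)
  slug <- gsub("^_+|_+$", "", slug)
  need_fallback <- !nzchar(slug)
  slug[need_fallback] <- sprintf("%s%04d", prefix, which(need_fallback))
  dup <- duplicated(slug)
  while (any(dup)) {   # disambiguate colliding slugs deterministically
    slug[dup] <- paste0(slug[dup], "_", cumsum(dup)[dup])
    dup <- duplicated(slug)
  }
  stats::setNames(slug, labels)
}

#' Assemble the fused knowledge graph
#'
#' One patient node per record, one patient-feature edge per present
#' feature, one patient-syndrome edge when the record is labeled, and one
#' edge per curated knowledge triple. Feature and triple labels are passed
#' through `alignment` first, so near-duplicate surface forms share a single
#' node. Feature entity ids are ASCII-safe slugs of the canonical label.
#'
#' @param records Record tibble (see [read_records()]).
#' @param triples Optional data frame of knowledge triples
#'   (`source`, `rtype`, `target`), labels in the post-alignment vocabulary.
#' @param alignment Optional `alignment_map` from [align_entities()].
#' @param feature_etype Entity type assigned to record features
#'   (default `"symptom"`).
#' @param attribute_labels Optional character vector of feature labels to
#'   type as `attribute` instead.
#' @return A `knowledge_graph`.
#' @export
build_graph <- function(records, triples = NULL, alignment = NULL,
                        feature_etype = "symptom",
                        attribute_labels = character()) {
  if (!nrow(records)) stop("no records to build from", call. = FALSE)
  validate_records(records, vocabulary = unique(stats::na.omit(records$syndrome)))
  feats <- lapply(records$features, function(f)
    unique(apply_alignment(alignment, f)))
  feat_labels <- unique(unlist(feats))
  syn_labels <- unique(stats::na.omit(records$syndrome))
  if (!is.null(triples) && nrow(triples)) {
    triples$source <- apply_alignment(alignment, triples$source)
    triples$target <- apply_alignment(alignment, triples$target)
    extra <- setdiff(unique(c(triples$source, triples$target)),
                     c(feat_labels, syn_labels, records$patient_id))
    feat_labels <- c(feat_labels, extra)
  }
  feat_labels <- setdiff(feat_labels, syn_labels)
  id_of <- make_id_map(feat_labels)
  # syndrome and patient nodes keep their given identifiers as ids
  id_of <- c(id_of, stats::setNames(syn_labels, syn_labels),
             stats::setNames(records$patient_id, records$patient_id))

  etype <- rep(feature_etype, length(feat_labels))
  etype[feat_labels %in% attribute_labels] <- "attribute"
  nodes <- data.frame(
    id = c(unname(id_of[feat_labels]), syn_labels, records$patient_id),
    label = c(feat_labels, syn_labels, records$patient_id),
    etype = c(etype, rep("syndrome", length(syn_labels)),
              rep("patient", nrow(records))),
    aliases = "", stringsAsFactors = FALSE)

  pf <- data.frame(
    source = rep(records$patient_id, lengths(feats)),
    target = unname(id_of[unlist(feats)]),
    rtype = "has_feature", weight = NA_real_, stringsAsFactors = FALSE)
  labeled <- !is.na(records$syndrome)
  ps <- data.frame(source = records$patient_id[labeled],
                   target = records$syndrome[labeled],
                   rtype = "diagnosed_as", weight = NA_real_,
                   stringsAsFactors = FALSE)
  edges <- rbind(pf, ps)
  if (!is.null(triples) && nrow(triples)) {
    tr <- data.frame(source = unname(id_of[triples$source]),
                     target = unname(id_of[triples$target]),
                     rtype = triples$rtype, weight = NA_real_,
                     stringsAsFactors = FALSE)
    edges <- rbind(edges, tr)
  }
  edges <- edges[!duplicated(edges[c("source", "target", "rtype")]), ]
  graph_from_frames(nodes, edges)
}

#' Patient ids present in a graph
#'
#' @param graph A `knowledge_graph`.
#' @param labeled_only Keep only patients with a syndrome edge.
#' @return Character vector of patient node ids.
#' @export
kg_patients <- function(graph, labeled_only = FALSE) {
  ids <- graph$nodes$id[graph$nodes$etype == "patient"]
  if (labeled_only)
    ids <- ids[!is.na(patient_syndromes(graph, ids))]
  ids
}

# Syndrome label per patient id (NA when unlabeled), via diagnosed_as edges.
patient_syndromes <- function(graph, ids) {
  syn <- graph$edges[graph$edges$rtype == "diagnosed_as", , drop = FALSE]
  lab <- stats::setNames(syn$target, syn$source)
  out <- lab[ids]
  names(out) <- ids
  out
}
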