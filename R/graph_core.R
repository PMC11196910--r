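# Typed heterogeneous graph: patients, symptoms, syndromes and allied
# clinical concepts as nodes; undirected adjacency for neighbor queries,
# directed rtype retained for serialization.

#' Entity types recognised by a knowledge graph
#'
#' The closed vocabulary of node types: clinical findings (`symptom`),
#' diagnostic patterns (`syndrome`), plus `patient`, `disease`, `drug`,
#' `treatment` and demographic/history `attribute` nodes.
#'
#' @export
ENTITY_TYPES <- c("patient", "symptom", "syndrome", "disease", "drug",
                  "treatment", "attribute")

#' The five tinnitus syndrome labels
#'
#' Wind fire attacking internally (WFAI), liver fire bearing upward (LFBU),
#' phlegm fire stagnation internally (PFSI), Qi deficiency of the spleen and
#' stomach (QDSS) and kidney essence deficiency (KED).
#'
#' @export
SYNDROMES <- c("KED", "LFBU", "PFSI", "QDSS", "WFAI")

#' Create an empty knowledge graph
#'
#' A `knowledge_graph` holds typed entities and typed, optionally weighted
#' relations. Adjacency is undirected for neighbor and similarity queries;
#' the relation type string keeps its semantic direction for serialization.
#'
#' @return An empty object of class `knowledge_graph`.
#' @seealso [upsert_entity()], [upsert_relation()], [kg_neighbors()]
#' @export
#' @examples
#' g <- knowledge_graph()
#' g <- upsert_entity(g, entity("p1", etype = "patient"))
#' g <- upsert_entity(g, entity("tinnitus", etype = "symptom"))
#' g <- upsert_relation(g, relation("p1", "tinnitus", "has_symptom"))
#' kg_neighbors(g, "p1")
knowledge_graph <- function() {
  structure(
    list(
      nodes = data.frame(id = character(), label = character(),
                         etype = character(), stringsAsFactors = FALSE),
      aliases = list(),
      edges = data.frame(source = character(), target = character(),
                         rtype = character(), weight = numeric(),
                         stringsAsFactors = FALSE),
      adj = list(),
      etype_of = character()
    ),
    class = "knowledge_graph"
  )
}

#' Construct an entity
#'
#' @param id Unique identifier (ASCII-safe slug recommended; labels carry the
#'   display form, which may be non-ASCII).
#' @param label Display name; defaults to `id`.
#' @param etype One of [ENTITY_TYPES].
#' @param aliases Character vector of alternative surface forms.
#' @return A list of class `kg_entity`.
#' @export
entity <- function(id, label = id, etype = "symptom", aliases = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("entity id must be a non-empty string", call. = FALSE)
  if (!etype %in% ENTITY_TYPES)
    stop(sprintf("invalid etype '%s'; must be one of %s", etype,
                 paste(ENTITY_TYPES, collapse = ", ")), call. = FALSE)
  structure(list(id = id, label = label, etype = etype,
                 aliases = unique(as.character(aliases))),
            class = "kg_entity")
}

#' Construct a relation
#'
#' @param source,target Entity ids; both must exist in the graph at upsert.
#' @param rtype Relation type label.
#' @param weight Nonnegative weight, or `NA` when unweighted.
#' @return A list of class `kg_relation`.
#' @export
relation <- function(source, target, rtype = "related_to", weight = NA_real_) {
  if (!is.na(weight) && weight < 0)
    stop("relation weight must be nonnegative", call. = FALSE)
  structure(list(source = source, target = target, rtype = rtype,
                 weight = as.numeric(weight)),
            class = "kg_relation")
}

#' Add or update an entity
#'
#' Re-upserting an existing id merges aliases and refreshes the label; it
#' never duplicates the node. The entity type of an existing node cannot be
#' changed.
#'
#' @param graph A `knowledge_graph`.
#' @param ent A `kg_entity` (see [entity()]).
#' @return The updated graph.
#' @export
upsert_entity <- function(graph, ent) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (!inherits(ent, "kg_entity")) stop("not a kg_entity", call. = FALSE)
  i <- match(ent$id, graph$nodes$id)
  if (is.na(i)) {
    graph$nodes[nrow(graph$nodes) + 1L, ] <- list(ent$id, ent$label, ent$etype)
    graph$aliases[[ent$id]] <- ent$aliases
    graph$adj[[ent$id]] <- character()
    graph$etype_of[[ent$id]] <- ent$etype
  } else {
    if (graph$nodes$etype[i] != ent$etype)
      stop(sprintf("entity '%s' already present with etype '%s'",
                   ent$id, graph$nodes$etype[i]), call. = FALSE)
    graph$nodes$label[i] <- ent$label
    graph$aliases[[ent$id]] <- unique(c(graph$aliases[[ent$id]], ent$aliases))
  }
  graph
}

#' Add or update a relation
#'
#' A duplicate (source, target, rtype) triple overwrites the stored weight
#' rather than duplicating the edge.
#'
#' @param graph A `knowledge_graph`.
#' @param rel A `kg_relation` (see [relation()]).
#' @return The updated graph.
#' @export
upsert_relation <- function(graph, rel) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (!inherits(rel, "kg_relation")) stop("not a kg_relation", call. = FALSE)
  for (end in c(rel$source, rel$target))
    if (!end %in% graph$nodes$id)
      stop(sprintf("relation endpoint '%s' not in graph", end), call. = FALSE)
  hit <- which(graph$edges$source == rel$source &
               graph$edges$target == rel$target &
               graph$edges$rtype == rel$rtype)
  if (length(hit)) {
    graph$edges$weight[hit] <- rel$weight
  } else {
    graph$edges[nrow(graph$edges) + 1L, ] <-
      list(rel$source, rel$target, rel$rtype, rel$weight)
    graph$adj[[rel$source]] <- union(graph$adj[[rel$source]], rel$target)
    graph$adj[[rel$target]] <- union(graph$adj[[rel$target]], rel$source)
  }
  graph
}

#' Neighbors of an entity
#'
#' Adjacency is undirected: `b` is a neighbor of `a` whenever either
#' direction of the relation was stored.
#'
#' @param graph A `knowledge_graph`.
#' @param id Entity id; must exist.
#' @param etype Optional entity-type filter (one of [ENTITY_TYPES]).
#' @return Character vector of adjacent entity ids.
#' @export
kg_neighbors <- function(graph, id, etype = NULL) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (!id %in% graph$nodes$id)
    stop(sprintf("unknown entity id '%s'", id), call. = FALSE)
  nb <- graph$adj[[id]]
  if (is.null(nb)) nb <- character()
  if (!is.null(etype)) nb <- nb[graph$etype_of[nb] %in% etype]
  nb
}

#' Common neighbors of two entities
#'
#' The shared adjacent nodes of a pair — for two patients, the symptom and
#' attribute entities they both present. Symmetric in its arguments.
#'
#' @param graph A `knowledge_graph`.
#' @param a,b Distinct entity ids.
#' @param etype Optional entity-type filter.
#' @return Character vector of shared neighbor ids.
#' @export
kg_common_neighbors <- function(graph, a, b, etype = NULL) {
  if (identical(a, b))
    stop("common neighbors of a node with itself are undefined", call. = FALSE)
  intersect(kg_neighbors(graph, a, etype), kg_neighbors(graph, b, etype))
}

#' Degree of an entity
#' @param graph A `knowledge_graph`.
#' @param id Entity id.
#' @return Integer number of neighbors.
#' @export
kg_degree <- function(graph, id) length(kg_neighbors(graph, id))

#' Entity and relation counts
#' @param graph A `knowledge_graph`.
#' @return Integer count.
#' @export
entity_count <- function(graph) nrow(graph$nodes)

#' @rdname entity_count
#' @export
relation_count <- function(graph) nrow(graph$edges)

#' @exportS3Method base::print
print.knowledge_graph <- function(x, ...) {
  tab <- table(x$nodes$etype)
  cat(sprintf("<knowledge_graph> %d entities, %d relations\n",
              nrow(x$nodes), nrow(x$edges)))
  if (length(tab))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

#' Save / load a knowledge graph
#'
#' Three on-disk formats: a node/edge TSV pair (`path` is used as a prefix,
#' producing `<path>.nodes.tsv` and `<path>.edges.tsv`), a single JSON file,
#' and GraphML for interchange with visualization tools. TSV and JSON
#' round-trip entities, relations, etypes and weights exactly.
#'
#' @param graph A `knowledge_graph`.
#' @param path Output path (prefix for `format = "tsv"`).
#' @param format One of `"tsv"`, `"json"`, `"graphml"`.
#' @return `save_graph` returns `path` invisibly; `load_graph` returns the
#'   reconstructed `knowledge_graph`.
#' @export
save_graph <- function(graph, path, format = c("tsv", "json", "graphml")) {
  stopifnot(inherits(graph, "knowledge_graph"))
  format <- match.arg(format)
  nodes <- graph$nodes
  nodes$aliases <- vapply(graph$aliases[nodes$id],
                          function(a) paste(a, collapse = "|"), character(1))
  edges <- graph$edges
  switch(format,
    tsv = {
      write_tsv_utf8(nodes, paste0(path, ".nodes.tsv"))
      edges$weight <- ifelse(is.na(edges$weight), "",
                             format(edges$weight, digits = 17, trim = TRUE,
                                    scientific = FALSE))
      write_tsv_utf8(edges, paste0(path, ".edges.tsv"))
    },
    json = {
      jsonlite::write_json(
        list(nodes = nodes, edges = graph$edges),
        path, dataframe = "rows", na = "null", digits = NA, pretty = TRUE)
    },
    graphml = write_graphml(nodes, graph$edges, path)
  )
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path, format = c("tsv", "json", "graphml")) {
  format <- match.arg(format)
  parsed <- switch(format,
    tsv = {
      nodes <- read_tsv_checked(paste0(path, ".nodes.tsv"),
                                c("id", "label", "etype", "aliases"))
      edges <- read_tsv_checked(paste0(path, ".edges.tsv"),
                                c("source", "target", "rtype", "weight"))
      edges$weight <- suppressWarnings(as.numeric(edges$weight))
      list(nodes = nodes, edges = edges)
    },
    json = {
      x <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (!all(c("nodes", "edges") %in% names(x)))
        stop(sprintf("malformed graph JSON '%s': need 'nodes' and 'edges'",
                     path), call. = FALSE)
      if (length(x$nodes) == 0)
        x$nodes <- data.frame(id = character(), label = character(),
                              etype = character(), aliases = character())
      if (length(x$edges) == 0)
        x$edges <- data.frame(source = character(), target = character(),
                              rtype = character(), weight = numeric())
      if (is.null(x$edges$weight)) x$edges$weight <- NA_real_
      x
    },
    graphml = read_graphml(path)
  )
  graph_from_frames(parsed$nodes, parsed$edges)
}

# Assemble a graph from node/edge frames in one pass (no per-row upserts).
graph_from_frames <- function(nodes, edges) {
  g <- knowledge_graph()
  if (anyDuplicated(nodes$id))
    stop("duplicate entity id: ", nodes$id[duplicated(nodes$id)][1],
         call. = FALSE)
  bad <- setdiff(unique(nodes$etype), ENTITY_TYPES)
  if (length(bad))
    stop(sprintf("invalid etype '%s'", bad[1]), call. = FALSE)
  alias_str <- if (is.null(nodes$aliases)) rep("", nrow(nodes)) else nodes$aliases
  alias_str[is.na(alias_str)] <- ""
  g$nodes <- data.frame(id = as.character(nodes$id),
                        label = as.character(nodes$label),
                        etype = as.character(nodes$etype),
                        stringsAsFactors = FALSE)
  g$aliases <- lapply(strsplit(alias_str, "|", fixed = TRUE),
                      function(a) a[nzchar(a)])
  names(g$aliases) <- g$nodes$id
  g$etype_of <- stats::setNames(g$nodes$etype, g$nodes$id)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    miss <- setdiff(unique(c(edges$source, edges$target)), g$nodes$id)
    if (length(miss))
      stop(sprintf("relation endpoint '%s' not in graph", miss[1]),
           call. = FALSE)
    g$edges <- data.frame(source = as.character(edges$source),
                          target = as.character(edges$target),
                          rtype = as.character(edges$rtype),
                          weight = as.numeric(edges$weight),
                          stringsAsFactors = FALSE)
    both <- data.frame(a = c(g$edges$source, g$edges$target),
                       b = c(g$edges$target, g$edges$source))
    adj <- lapply(split(both$b, both$a), unique)
    g$adj <- stats::setNames(vector("list", nrow(g$nodes)), g$nodes$id)
    g$adj[names(adj)] <- adj
    empty <- vapply(g$adj, is.null, logical(1))
    g$adj[empty] <- list(character())
  } else {
    g$adj <- stats::setNames(rep(list(character()), nrow(g$nodes)), g$nodes$id)
  }
  g
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop(sprintf("%s: line 1: empty file", path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(required_cols %in% header))
    stop(sprintf("%s: line 1: header must contain columns %s", path,
                 paste(required_cols, collapse = ", ")), call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf > length(header))
  if (length(bad))
    stop(sprintf("%s: line %d: %d fields but %d columns in header",
                 path, bad[1] + 1L, nf[bad[1]], length(header)), call. = FALSE)
  mat <- t(vapply(fields, function(f) c(f, rep("", length(header) - length(f))),
                  character(length(header))))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  if (length(body) == 0)
    df <- as.data.frame(matrix(character(), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  df
}

write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(c("d_label", "node", "label"), c("d_etype", "node", "etype"),
               c("d_aliases", "node", "aliases"), c("d_rtype", "edge", "rtype"),
               c("d_weight", "edge", "weight"))
  for (k in keys)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3],
                        attr.type = if (k[3] == "weight") "double" else "string")
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    n <- xml2::xml_add_child(gr, "node", id = nodes$id[i])
    xml2::xml_add_child(n, "data", key = "d_label", nodes$label[i])
    xml2::xml_add_child(n, "data", key = "d_etype", nodes$etype[i])
    if (nzchar(nodes$aliases[i]))
      xml2::xml_add_child(n, "data", key = "d_aliases", nodes$aliases[i])
  }
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(gr, "edge", source = edges$source[i],
                             target = edges$target[i])
    xml2::xml_add_child(e, "data", key = "d_rtype", edges$rtype[i])
    if (!is.na(edges$weight[i]))
      xml2::xml_add_child(e, "data", key = "d_weight",
                          format(edges$weight[i], digits = 17, trim = TRUE,
                                 scientific = FALSE))
  }
  xml2::write_xml(doc, path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nnodes <- xml2::xml_find_all(doc, ".//graph/node")
  nodes <- data.frame(
    id = xml2::xml_attr(nnodes, "id"),
    label = vapply(nnodes, get_data, character(1), key = "d_label"),
    etype = vapply(nnodes, get_data, character(1), key = "d_etype"),
    aliases = vapply(nnodes, get_data, character(1), key = "d_aliases"),
    stringsAsFactors = FALSE)
  nodes$aliases[is.na(nodes$aliases)] <- ""
  nodes$label[is.na(nodes$label)] <- nodes$id[is.na(nodes$label)]
  nedges <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- data.frame(
    source = xml2::xml_attr(nedges, "source"),
    target = xml2::xml_attr(nedges, "target"),
    rtype = vapply(nedges, get_data, character(1), key = "d_rtype"),
    weight = suppressWarnings(
      as.numeric(vapply(nedges, get_data, character(1), key = "d_weight"))),
    stringsAsFactors = FALSE)
  edges$rtype[is.na(edges$rtype)] <- "related_to"
  list(nodes = nodes, edges = edges)
}
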