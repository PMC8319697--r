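# Knowledge-graph assembly and export. The igraph package is the
# GraphML backend; node and edge tables are the authoritative
# representation (see KnowledgeGraph-class).

#' Assemble a knowledge graph from kept entities and aggregated relations
#'
#' One node per census entity, one edge per aggregated relation.
#' Parallel edges with different relation types (or families) between
#' the same pair are retained; same-type duplicates are merged with
#' pmid/keyword set union. Every relation endpoint must appear among
#' the entities (referential integrity), otherwise an error names the
#' offending pair.
#'
#' @param entities Census data.frame of kept entities (see
#'   [buildCensus()]); columns \code{entity_id}, \code{entity_type},
#'   \code{mention_count}, \code{example_surface} are used.
#' @param relations From [aggregateRelations()].
#' @param lexicons Optional list of [Lexicon] objects used to resolve
#'   preferred names; entities without a lexicon entry fall back to
#'   their example surface.
#' @return A [KnowledgeGraph].
#' @export
buildGraph <- function(entities, relations, lexicons = NULL) {
  prefName <- character(0)
  if (!is.null(lexicons)) {
    if (is(lexicons, "Lexicon")) lexicons <- list(lexicons)
    for (lex in lexicons) {
      e <- lexEntries(lex)
      prefName[e$canonical_id] <- e$preferred_name
    }
  }
  ids <- entities$entity_id
  name <- unname(prefName[ids])
  name[is.na(name)] <- entities$example_surface[is.na(name)]
  name[is.na(name) | !nzchar(name)] <- ids[is.na(name) | !nzchar(name)]
  nodes <- data.frame(
    id = ids, name = name, entity_type = entities$entity_type,
    mesh_id = ifelse(startsWith(ids, "MESH:"), ids, ""),
    mention_count = as.numeric(entities$mention_count),
    stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(relations)) {
    dangling <- !(relations$id_a %in% nodes$id) |
                !(relations$id_b %in% nodes$id)
    if (any(dangling)) {
      i <- which(dangling)[1]
      stop(sprintf("relation endpoint not among kept entities: %s -- %s (%s)",
                   relations$id_a[i], relations$id_b[i],
                   relations$family[i]))
    }
    edges <- data.frame(
      source = relations$id_a, target = relations$id_b,
      family = relations$family, relation_type = relations$relation_type,
      relation_keywords = relations$keywords, pmids = relations$pmids,
      confidence = relations$confidence,
      support = as.numeric(relations$support), stringsAsFactors = FALSE)
    key <- paste(edges$source, edges$target, edges$family,
                 edges$relation_type, sep = "\r")
    if (anyDuplicated(key)) {
      sp <- split(seq_len(nrow(edges)), key)
      edges <- do.call(rbind, lapply(sp, function(ix) {
        e <- edges[ix, , drop = FALSE]
        joinSet <- function(x) paste(sort(unique(unlist(
          strsplit(x[nzchar(x)], "|", fixed = TRUE)))), collapse = "|")
        data.frame(source = e$source[1], target = e$target[1],
                   family = e$family[1], relation_type = e$relation_type[1],
                   relation_keywords = joinSet(e$relation_keywords),
                   pmids = joinSet(e$pmids),
                   confidence = max(e$confidence),
                   support = sum(e$support), stringsAsFactors = FALSE)
      }))
    }
    edges <- edges[order(edges$source, edges$target, edges$family,
                         edges$relation_type), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        family = character(0), relation_type = character(0),
                        relation_keywords = character(0),
                        pmids = character(0), confidence = numeric(0),
                        support = numeric(0), stringsAsFactors = FALSE)
  }
  new("KnowledgeGraph", nodes = nodes, edges = edges)
}

#' Export a knowledge graph as GraphML
#'
#' Node ids become igraph vertex names; the display name is stored in
#' the \code{entity_name} attribute (GraphML reserves \code{name} for
#' the vertex id). Set-valued fields are already pipe-joined strings.
#' Element ordering is deterministic (sorted node/edge tables).
#'
#' @param kg A [KnowledgeGraph].
#' @param file Path.
#' @return Invisibly, \code{file}.
#' @seealso [importGraphML()]
#' @export
exportGraphML <- function(kg, file) {
  validObject(kg)
  n <- nodes(kg)
  v <- data.frame(name = n$id, entity_name = n$name,
                  entity_type = n$entity_type, mesh_id = n$mesh_id,
                  mention_count = n$mention_count, stringsAsFactors = FALSE)
  # directed serialization keeps the canonical (family-ordered)
  # endpoint order stable across the round-trip
  g <- igraph::graph_from_data_frame(edges(kg), directed = TRUE,
                                     vertices = v)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Re-import a GraphML file written by [exportGraphML()]
#' @param file Path.
#' @return A [KnowledgeGraph] with the same node and edge multisets.
#' @export
importGraphML <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = vd$name, name = vd$entity_name,
                      entity_type = vd$entity_type, mesh_id = vd$mesh_id,
                      mention_count = as.numeric(vd$mention_count),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(ed)) {
    edges <- data.frame(source = ed$from, target = ed$to,
                        family = ed$family, relation_type = ed$relation_type,
                        relation_keywords = ed$relation_keywords,
                        pmids = ed$pmids,
                        confidence = as.numeric(ed$confidence),
                        support = as.numeric(ed$support),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target, edges$family,
                         edges$relation_type), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        family = character(0), relation_type = character(0),
                        relation_keywords = character(0),
                        pmids = character(0), confidence = numeric(0),
                        support = numeric(0), stringsAsFactors = FALSE)
  }
  new("KnowledgeGraph", nodes = nodes, edges = edges)
}

neo4jNodeHeader <- function() "id:ID,name,:LABEL,mesh_id,mention_count:int"
neo4jEdgeHeader <- function()
  ":START_ID,:END_ID,:TYPE,family,relation_keywords,pmids,confidence:float,support:int"

csvQuote <- function(x) {
  needs <- grepl("[\",\n]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}

#' Export a knowledge graph as Neo4j bulk-import CSV
#'
#' Writes \code{nodes.csv} (header
#' \code{id:ID,name,:LABEL,mesh_id,mention_count:int}) and
#' \code{edges.csv} (header
#' \code{:START_ID,:END_ID,:TYPE,family,relation_keywords,pmids,confidence:float,support:int})
#' into \code{dir}, following the \code{neo4j-admin import} header
#' conventions. Fields containing commas or quotes are quoted per the
#' CSV standard.
#'
#' @param kg A [KnowledgeGraph].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
exportNeo4jCsv <- function(kg, dir) {
  validObject(kg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nodes(kg); e <- edges(kg)
  nodeFile <- file.path(dir, "nodes.csv")
  edgeFile <- file.path(dir, "edges.csv")
  nodeLines <- c(neo4jNodeHeader(),
    if (nrow(n)) paste(csvQuote(n$id), csvQuote(n$name),
                       csvQuote(n$entity_type), csvQuote(n$mesh_id),
                       format(n$mention_count, trim = TRUE,
                              scientific = FALSE), sep = ","))
  edgeLines <- c(neo4jEdgeHeader(),
    if (nrow(e)) paste(csvQuote(e$source), csvQuote(e$target),
                       csvQuote(e$relation_type), csvQuote(e$family),
                       csvQuote(e$relation_keywords), csvQuote(e$pmids),
                       format(e$confidence, trim = TRUE, scientific = FALSE),
                       format(e$support, trim = TRUE, scientific = FALSE),
                       sep = ","))
  writeLines(nodeLines, nodeFile, useBytes = FALSE)
  writeLines(edgeLines, edgeFile, useBytes = FALSE)
  invisible(c(nodes = nodeFile, edges = edgeFile))
}

#' Dump the graph as a TSV triple list
#' @param kg A [KnowledgeGraph].
#' @param file Path or connection.
#' @return Invisibly, the triples data.frame.
#' @export
exportTriples <- function(kg, file = NULL) {
  e <- edges(kg)
  triples <- data.frame(id_a = e$source, relation_type = e$relation_type,
                        id_b = e$target, stringsAsFactors = FALSE)
  if (!is.null(file)) {
    write.table(triples, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(triples)
}

#' Summary statistics of a knowledge graph
#'
#' Property count is the total number of non-empty attribute values
#' across nodes (name, entity_type, mesh_id, mention_count) and edges
#' (family, relation_type, relation_keywords, pmids, confidence,
#' support) — ids/endpoints are structural, not properties.
#'
#' @param kg A [KnowledgeGraph].
#' @return list(\code{n_nodes}, \code{n_edges}, \code{nodes_by_type},
#'   \code{edges_by_type}, \code{n_properties}).
#' @export
graphStats <- function(kg) {
  n <- nodes(kg); e <- edges(kg)
  countNonEmpty <- function(df, cols) {
    sum(vapply(cols, function(cl) {
      x <- df[[cl]]
      if (is.character(x)) sum(!is.na(x) & nzchar(x)) else sum(!is.na(x))
    }, 1L))
  }
  list(
    n_nodes = nrow(n),
    n_edges = nrow(e),
    nodes_by_type = if (nrow(n)) table(n$entity_type) else table(character(0)),
    edges_by_type = if (nrow(e)) {
      table(paste(e$family, e$relation_type, sep = ":"))
    } else table(character(0)),
    n_properties = countNonEmpty(n, c("name", "entity_type", "mesh_id",
                                      "mention_count")) +
                   countNonEmpty(e, c("family", "relation_type",
                                      "relation_keywords", "pmids",
                                      "confidence", "support")))
}
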