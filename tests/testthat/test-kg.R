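mkEntities <- function(ids, types, counts = rep(5L, length(ids))) {
  data.frame(entity_id = ids, entity_type = types,
             mention_count = counts, doc_count = rep(1L, length(ids)),
             example_surface = tolower(ids),
             example_pmid = rep("1", length(ids)),
             stringsAsFactors = FALSE)
}

mkRelations <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id_a = r[[1]], id_b = r[[2]], family = r[[3]],
               relation_type = r[[4]], n = 3L, support = 3L,
               confidence = 1, pmids = r[[5]], keywords = "kw",
               stringsAsFactors = FALSE)
  }))
}

emptyRelations <- function() {
  data.frame(id_a = character(0), id_b = character(0),
             family = character(0), relation_type = character(0),
             n = integer(0), support = integer(0), confidence = numeric(0),
             pmids = character(0), keywords = character(0),
             stringsAsFactors = FALSE)
}

test_that("graph assembly deduplicates nodes and checks integrity", {
  ents <- mkEntities(c("A", "B", "C"), c("Drug", "Disease", "Gene"))
  g0 <- buildGraph(ents, aggregateRelations(data.frame(
    pmid = character(0), sentence = integer(0), id_a = character(0),
    id_b = character(0), family = character(0), group = character(0),
    matched_keyword = character(0), relation_type = character(0),
    classifier = character(0), stringsAsFactors = FALSE)))
  expect_identical(nrow(nodes(g0)), 3L)
  expect_identical(nrow(edges(g0)), 0L)

  rel <- mkRelations(list("A", "B", "Drug-Disease", "Treatment", "p1"),
                     list("B", "C", "Disease-Gene",
                          "PositiveAssociation", "p2"))
  g <- buildGraph(ents, rel)
  expect_identical(nrow(nodes(g)), 3L)
  expect_identical(nrow(edges(g)), 2L)

  # dangling endpoint errors and names the pair
  bad <- mkRelations(list("A", "ZZZ", "Drug-Disease", "Treatment", "p"))
  expect_error(buildGraph(ents, bad), "ZZZ")

  # MESH ids populate the standard-classification field
  entsM <- mkEntities(c("MESH:D020521", "A"), c("Disease", "Drug"))
  gM <- buildGraph(entsM, emptyRelations())
  expect_identical(nodes(gM)$mesh_id[nodes(gM)$id == "MESH:D020521"],
                   "MESH:D020521")
})

test_that("parallel edges of different types are kept, same-type merged", {
  ents <- mkEntities(c("A", "B"), c("CPM", "Herb"))
  rel <- mkRelations(list("A", "B", "CPM-Herb", "EntityOrigin", "p1"),
                     list("A", "B", "CPM-Herb", "Interaction", "p2"))
  g <- buildGraph(ents, rel)
  expect_identical(nrow(edges(g)), 2L)

  dup <- mkRelations(list("A", "B", "CPM-Herb", "EntityOrigin", "p1"),
                     list("A", "B", "CPM-Herb", "EntityOrigin", "p2|p3"))
  g2 <- buildGraph(ents, dup)
  expect_identical(nrow(edges(g2)), 1L)
  expect_identical(edges(g2)$pmids, "p1|p2|p3")
  expect_identical(edges(g2)$support, 6)
})

test_that("GraphML export/import round-trips nodes, edges and attributes", {
  ents <- mkEntities(c("MESH:D1", "DB1", "GEN:1"),
                     c("Disease", "Drug", "Gene"), c(4L, 9L, 2L))
  rel <- mkRelations(list("DB1", "MESH:D1", "Drug-Disease", "Treatment",
                          "p1|p2"),
                     list("MESH:D1", "GEN:1", "Disease-Gene",
                          "PositiveAssociation", "p3"))
  g <- buildGraph(ents, rel)
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(g, f)
  g2 <- importGraphML(f)
  expect_equal(nodes(g2), nodes(g))
  expect_equal(edges(g2), edges(g))
  # stats invariant under round-trip
  expect_equal(graphStats(g2), graphStats(g))

  # empty graph round-trips too
  ge <- buildGraph(mkEntities(character(0), character(0), integer(0)),
                   emptyRelations())
  f2 <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(ge, f2)
  expect_identical(nrow(nodes(importGraphML(f2))), 0L)
})

test_that("pipe-joined set attributes are sorted", {
  ents <- mkEntities(c("A", "B"), c("Drug", "Disease"))
  rel <- mkRelations(list("A", "B", "Drug-Disease", "Treatment", "p2|p1"))
  rel$pmids <- "p2|p1"
  g <- buildGraph(ents, mkRelations(
    list("A", "B", "Drug-Disease", "Treatment", "p2"),
    list("A", "B", "Drug-Disease", "Treatment", "p1")))
  expect_identical(edges(g)$pmids, "p1|p2")
})

test_that("Neo4j bulk-import CSV uses the documented headers", {
  ents <- mkEntities(c("A,1", "B"), c("Drug", "Disease"))
  ents$example_surface <- c("has \"quote\"", "plain")
  rel <- mkRelations(list("A,1", "B", "Drug-Disease", "Treatment", "p1"))
  g <- buildGraph(ents, rel)
  dir <- withr::local_tempdir()
  exportNeo4jCsv(g, dir)
  nl <- readLines(file.path(dir, "nodes.csv"))
  el <- readLines(file.path(dir, "edges.csv"))
  expect_identical(nl[1], "id:ID,name,:LABEL,mesh_id,mention_count:int")
  expect_identical(
    el[1],
    ":START_ID,:END_ID,:TYPE,family,relation_keywords,pmids,confidence:float,support:int")
  expect_identical(length(nl) - 1L, nrow(nodes(g)))
  expect_identical(length(el) - 1L, nrow(edges(g)))
  # special characters quoted per the CSV standard
  parsed <- utils::read.csv(file.path(dir, "nodes.csv"),
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
  expect_setequal(parsed[["id:ID"]], c("A,1", "B"))
  expect_true("has \"quote\"" %in% parsed$name)
})

test_that("graph statistics count nodes, edges and properties", {
  ge <- buildGraph(mkEntities(character(0), character(0), integer(0)),
                   emptyRelations())
  st0 <- graphStats(ge)
  expect_identical(st0$n_nodes, 0L)
  expect_identical(st0$n_edges, 0L)
  expect_identical(st0$n_properties, 0L)

  ents <- mkEntities(c("A", "B", "C"), c("Drug", "Disease", "Disease"))
  rel <- mkRelations(list("A", "B", "Drug-Disease", "Treatment", "p1"))
  st <- graphStats(buildGraph(ents, rel))
  expect_identical(st$n_nodes, 3L)
  expect_identical(st$n_edges, 1L)
  expect_identical(as.integer(st$nodes_by_type[["Disease"]]), 2L)
  expect_identical(as.integer(st$edges_by_type[["Drug-Disease:Treatment"]]),
                   1L)
  # properties: 3 nodes x (name, type, count; no mesh) + 1 edge x 6
  expect_identical(st$n_properties, 3L * 3L + 6L)
})
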