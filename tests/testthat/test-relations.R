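mkCand <- function(doc, schema = defaultPairSchema()) {
  extractCooccurrence(doc, schema)
}

# a document with pre-annotated, sentence-split mentions built from
# explicit (surface, type, id) triples placed in one sentence each
relDoc <- function(pmid, sentenceEntities, extraWords = "appears with") {
  sents <- vapply(sentenceEntities, function(ents) {
    paste0(paste(vapply(ents, `[[`, "", "surface"),
                 collapse = paste0(" ", extraWords, " ")), ".")
  }, "")
  mrows <- list()
  offset <- nchar("Fixture title") + 1L
  for (si in seq_along(sentenceEntities)) {
    cursor <- offset
    ents <- sentenceEntities[[si]]
    for (k in seq_along(ents)) {
      e <- ents[[k]]
      mrows[[length(mrows) + 1L]] <- data.frame(
        start = cursor, end = cursor + nchar(e$surface),
        surface = e$surface, entity_type = e$type, norm_id = e$id,
        source = "preannotated", sentence = NA_integer_,
        stringsAsFactors = FALSE)
      cursor <- cursor + nchar(e$surface) +
        if (k < length(ents)) nchar(extraWords) + 2L else 0L
    }
    offset <- offset + nchar(sents[si]) + 1L
  }
  docFromSentences(pmid, sents, mentions = do.call(rbind, mrows))
}

ent <- function(surface, type, id) list(surface = surface, type = type,
                                        id = id)

test_that("co-occurrence candidates follow the pair schema", {
  d <- relDoc("1", list(list(ent("Aspirin", "Drug", "DB1"),
                             ent("Stroke", "Disease", "MS1"))))
  cands <- mkCand(d)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$family, "Drug-Disease")
  expect_identical(cands$a_id, "DB1")  # canonical family order
  expect_identical(cands$b_id, "MS1")

  # 2 drugs + 2 diseases in one sentence: 4 Drug-Disease candidates,
  # Drug-Drug is not an allowed family
  d2 <- relDoc("2", list(list(ent("Aspirin", "Drug", "DB1"),
                              ent("Warfarin", "Drug", "DB2"),
                              ent("Stroke", "Disease", "MS1"),
                              ent("Ischemia", "Disease", "MS2"))))
  c2 <- mkCand(d2)
  expect_identical(nrow(c2), 4L)
  expect_identical(unique(c2$family), "Drug-Disease")

  # mentions in different sentences: no candidates
  d3 <- relDoc("3", list(list(ent("Aspirin", "Drug", "DB1")),
                         list(ent("Stroke", "Disease", "MS1"))))
  expect_identical(nrow(mkCand(d3)), 0L)

  # self-pairs (same canonical id) excluded
  d4 <- relDoc("4", list(list(ent("Aspirin", "Drug", "DB1"),
                              ent("aspirin", "Drug", "DB1"),
                              ent("Stroke", "Disease", "MS1"))))
  expect_identical(nrow(mkCand(d4)), 2L)
})

test_that("keyword rules classify candidate pairs", {
  rb <- defaultRuleBook()
  classify1 <- function(sentence, typeA, typeB) {
    d <- relDoc("9", list(list(ent("Aaa", typeA, "ID:A"),
                               ent("Bbb", typeB, "ID:B"))))
    # rebuild with the requested sentence text around the two entities
    d <- docFromSentences("9", sentence,
      mentions = local({
        ft <- paste("Fixture title", sentence, sep = " ")
        hits <- lapply(c("Aaa", "Bbb"), function(s) {
          h <- regexpr(s, ft, fixed = TRUE)
          c(as.integer(h) - 1L, as.integer(h) - 1L + nchar(s))
        })
        data.frame(start = c(hits[[1]][1], hits[[2]][1]),
                   end = c(hits[[1]][2], hits[[2]][2]),
                   surface = c("Aaa", "Bbb"),
                   entity_type = c(typeA, typeB),
                   norm_id = c("ID:A", "ID:B"), source = "preannotated",
                   sentence = NA_integer_, stringsAsFactors = FALSE)
      }))
    ev <- extractRelations(list(d), rulebook = rb)
    ev[, c("relation_type", "matched_keyword")]
  }

  tr <- classify1("Aaa is treating Bbb.", "Drug", "Disease")
  expect_identical(tr$relation_type, "Treatment")
  expect_identical(tr$matched_keyword, "treating")

  ca <- classify1("Aaa can induce Bbb.", "Drug", "Disease")
  expect_identical(ca$relation_type, "Cause")

  # stemmed inflections match too
  ind <- classify1("Aaa induced Bbb.", "Drug", "Disease")
  expect_identical(ind$relation_type, "Cause")

  # no keyword from either set: family fallback with no keyword
  fb <- classify1("Aaa was measured near Bbb.", "Disease", "Gene")
  expect_identical(fb$relation_type, "Other")
  expect_true(is.na(fb$matched_keyword))
})

test_that("high-noise keywords only fire between the entity spans", {
  rb <- defaultRuleBook()
  # "and" between the two entities: Interaction
  d1 <- relDoc("1", list(list(ent("Danshen", "Herb", "H:1"),
                              ent("Warfarin", "Drug", "DB2"))),
               extraWords = "and")
  e1 <- extractRelations(list(d1), rulebook = rb)
  expect_identical(e1$relation_type, "Interaction")
  expect_identical(e1$matched_keyword, "and")

  # "and" outside the pair window must not fire; sentence then falls
  # through to EntityOrigin via "contains"
  sent <- "Salt and Danshen contains Warfarin."
  m <- local({
    ft <- paste("Fixture title", sent, sep = " ")
    surf <- c("Danshen", "Warfarin")
    do.call(rbind, lapply(seq_along(surf), function(i) {
      h <- regexpr(surf[i], ft, fixed = TRUE)
      data.frame(start = as.integer(h) - 1L,
                 end = as.integer(h) - 1L + nchar(surf[i]),
                 surface = surf[i],
                 entity_type = c("Herb", "Drug")[i],
                 norm_id = c("H:1", "DB2")[i], source = "preannotated",
                 sentence = NA_integer_, stringsAsFactors = FALSE)
    }))
  })
  d2 <- docFromSentences("2", sent, mentions = m)
  e2 <- extractRelations(list(d2), rulebook = rb)
  expect_identical(e2$relation_type, "EntityOrigin")
  expect_identical(e2$matched_keyword, "contain")
})

test_that("a family missing from the rulebook is a configuration error", {
  rb <- defaultRuleBook()
  rb@rules <- rb@rules[rb@rules$group != "assoc", ]
  rb@fallbacks <- rb@fallbacks[rb@fallbacks$group != "assoc", ]
  d <- relDoc("1", list(list(ent("Stroke", "Disease", "MS1"),
                             ent("ACE", "Gene", "G:1"))))
  expect_error(extractRelations(list(d), rulebook = rb),
               "group assoc")
})

test_that("aggregation computes majority, confidence and thresholds", {
  ev <- function(type, i) data.frame(
    pmid = as.character(i), sentence = 0L, id_a = "A", id_b = "B",
    family = "Drug-Disease", group = "tc",
    matched_keyword = if (type == "Other") NA_character_ else "kw",
    relation_type = type, classifier = "rule", stringsAsFactors = FALSE)

  # 3 Treatment evidences: one edge, confidence 1, support 3
  agg <- aggregateRelations(do.call(rbind, lapply(1:3, function(i)
    ev("Treatment", i))), minSupport = 2, confidenceThreshold = 0.5)
  expect_identical(nrow(agg), 1L)
  expect_identical(agg$confidence, 1)
  expect_identical(agg$support, 3L)
  expect_identical(agg$n, 3L)
  expect_identical(agg$pmids, "1|2|3")

  # split vote at exactly the threshold is dropped (strict >)
  tie <- rbind(ev("Treatment", 1), ev("Cause", 2))
  a2 <- aggregateRelations(tie, minSupport = 1, confidenceThreshold = 0.5)
  expect_identical(nrow(a2), 0L)
  dropped <- attr(a2, "dropped")
  expect_identical(dropped$confidence, 0.5)

  # single evidence fails min_support 2
  a3 <- aggregateRelations(ev("Treatment", 1), minSupport = 2,
                           confidenceThreshold = 0)
  expect_identical(nrow(a3), 0L)

  # fallback evidence dilutes confidence but cannot be the majority
  # while typed evidence exists
  mix <- rbind(ev("Treatment", 1), ev("Treatment", 2),
               ev("Other", 3), ev("Other", 4), ev("Other", 5))
  a4 <- aggregateRelations(mix, minSupport = 1, confidenceThreshold = 0)
  expect_identical(a4$relation_type, "Treatment")
  expect_identical(a4$confidence, 2 / 5)
  # with only fallback evidence the fallback can carry the edge
  a5 <- aggregateRelations(rbind(ev("Other", 1), ev("Other", 2)),
                           minSupport = 2, confidenceThreshold = 0.5)
  expect_identical(a5$relation_type, "Other")
})

test_that("aggregation conserves counts and is threshold-monotone", {
  set.seed(300)
  types <- c("Treatment", "Cause", "Other")
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    evs <- data.frame(
      pmid = as.character(sample(1:5, n, replace = TRUE)),
      sentence = 0L,
      id_a = sample(c("A", "C", "E"), n, replace = TRUE),
      id_b = sample(c("B", "D"), n, replace = TRUE),
      family = "Drug-Disease", group = "tc",
      matched_keyword = "kw",
      relation_type = sample(types, n, replace = TRUE),
      classifier = "rule", stringsAsFactors = FALSE)
    agg <- aggregateRelations(evs, minSupport = 1, confidenceThreshold = 0)
    both <- rbind(agg, attr(agg, "dropped"))
    # conservation: per-pair n sums to the evidence count
    expect_identical(sum(both$n), n)
    # support == count(majority) and confidence == support / n
    expect_equal(both$confidence, both$support / both$n)

    # monotonicity in both knobs
    kept <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th)
      nrow(aggregateRelations(evs, 1, th)), 1L)
    expect_false(is.unsorted(rev(kept)))
    keptS <- vapply(1:4, function(ms)
      nrow(aggregateRelations(evs, ms, 0)), 1L)
    expect_false(is.unsorted(rev(keptS)))
  }
})

test_that("plugin classifier fills keyword-less gaps, rules take precedence", {
  rb <- defaultRuleBook()
  d <- relDoc("1", list(list(ent("Aspirin", "Drug", "DB1"),
                             ent("Stroke", "Disease", "MS1"))),
              extraWords = "appears near")
  # identity plugin (echoes the fallback) changes nothing
  idPlugin <- function(sent, cand) "Other"
  evId <- extractRelations(list(d), rulebook = rb, plugin = idPlugin)
  evNo <- extractRelations(list(d), rulebook = rb)
  expect_identical(evId$relation_type, evNo$relation_type)
  expect_identical(evId$classifier, "plugin")

  # plugin label recorded on keyword-less sentences
  cPlugin <- function(sent, cand) "Cause"
  evC <- extractRelations(list(d), rulebook = rb, plugin = cPlugin)
  expect_identical(evC$relation_type, "Cause")

  # rule matched "cure": plugin never consulted, Treatment kept
  d2 <- relDoc("2", list(list(ent("Aspirin", "Drug", "DB1"),
                              ent("Stroke", "Disease", "MS1"))),
               extraWords = "will cure")
  evR <- extractRelations(list(d2), rulebook = rb, plugin = cPlugin)
  expect_identical(evR$relation_type, "Treatment")
  expect_identical(evR$classifier, "rule")

  # a type outside the family's set is a contract violation
  badPlugin <- function(sent, cand) "Interaction"
  expect_error(extractRelations(list(d), rulebook = rb,
                                plugin = badPlugin), "plugin returned")
})
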