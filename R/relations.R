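# Relation extraction cascade: sentence-level co-occurrence candidates,
# keyword-rule classification, optional plugin classifier for
# keyword-less sentences, and corpus-level confidence aggregation.

#' Extract within-sentence co-occurrence candidates
#'
#' All unordered mention pairs in the same sentence whose type pair is
#' an allowed family. Pairs are canonically ordered to the family's
#' (type_a, type_b); self-pairs (same entity id) and boundary-crossing
#' mentions are excluded.
#'
#' @param doc A tagged, sentence-split [Document].
#' @param schema A pair schema, see [defaultPairSchema()].
#' @return data.frame with one row per candidate: \code{pmid},
#'   \code{sentence}, \code{family}, \code{group}, and for each side
#'   \code{a_id}, \code{a_type}, \code{a_start}, \code{a_end},
#'   \code{a_surface} (likewise \code{b_*}).
#' @export
extractCooccurrence <- function(doc, schema = defaultPairSchema()) {
  empty <- data.frame(pmid = character(0), sentence = integer(0),
                      family = character(0), group = character(0),
                      a_id = character(0), a_type = character(0),
                      a_start = integer(0), a_end = integer(0),
                      a_surface = character(0),
                      b_id = character(0), b_type = character(0),
                      b_start = integer(0), b_end = integer(0),
                      b_surface = character(0), stringsAsFactors = FALSE)
  m <- mentions(doc)
  m <- m[!is.na(m$sentence), , drop = FALSE]
  if (nrow(m) < 2L) return(empty)
  m$eid <- entityKey(m$norm_id, m$surface)
  famKey <- paste(schema$type_a, schema$type_b)
  rows <- list()
  for (si in unique(m$sentence)) {
    ms <- m[m$sentence == si, , drop = FALSE]
    if (nrow(ms) < 2L) next
    idx <- combn(nrow(ms), 2L)
    for (c_ in seq_len(ncol(idx))) {
      i <- idx[1L, c_]; j <- idx[2L, c_]
      hit <- match(paste(ms$entity_type[i], ms$entity_type[j]), famKey)
      if (is.na(hit)) {
        hit <- match(paste(ms$entity_type[j], ms$entity_type[i]), famKey)
        if (is.na(hit)) next
        tmp <- i; i <- j; j <- tmp
      }
      if (ms$eid[i] == ms$eid[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        pmid = pmid(doc), sentence = si,
        family = schema$family[hit], group = schema$group[hit],
        a_id = ms$eid[i], a_type = ms$entity_type[i],
        a_start = ms$start[i], a_end = ms$end[i], a_surface = ms$surface[i],
        b_id = ms$eid[j], b_type = ms$entity_type[j],
        b_start = ms$start[j], b_end = ms$end[j], b_surface = ms$surface[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# precompute matchable keyword structures for one rulebook
compileRules <- function(rulebook) {
  r <- ruleTable(rulebook)
  r <- r[order(r$group, r$priority), , drop = FALSE]
  if (rulebook@mode == "stem") {
    r$kwkey <- vapply(r$keyword, stemPhrase, "")
  } else {
    r$kwkey <- vapply(r$keyword, function(k)
      paste(tolower(tokenizeWithOffsets(k)$token), collapse = " "), "")
  }
  r$kwlen <- lengths(strsplit(r$kwkey, " ", fixed = TRUE))
  r
}

# sentence token table with stems, offsets absolute into full_text
sentenceTokens <- function(doc, sentenceIndex, mode = "stem") {
  s <- sentences(doc)
  row <- sentenceIndex + 1L
  seg <- sliceText(fullText(doc), s$start[row], s$end[row])
  toks <- tokenizeWithOffsets(seg)
  toks$start <- toks$start + s$start[row]
  toks$end <- toks$end + s$start[row]
  toks$key <- if (mode == "stem") lightStem(toks$token) else tolower(toks$token)
  toks
}

#' Classify one candidate pair by keyword rules
#'
#' Walks the candidate family's relation types in priority order; the
#' first keyword found in the sentence window fixes the relation type
#' and matched keyword. Keywords flagged \code{between_only} must occur
#' strictly between the two entity spans. No hit yields the family
#' group's fallback type with no keyword.
#'
#' @param candidate One row of [extractCooccurrence()] output.
#' @param tokens Sentence token table: \code{token}, \code{start},
#'   \code{end}, \code{key} (stems in stem mode). See the internal
#'   layout produced for each sentence by [extractRelations()].
#' @param rulebook A [RuleBook].
#' @return list(\code{relation_type}, \code{matched_keyword}
#'   (\code{NA} for fallback)).
#' @export
classifyPair <- function(candidate, tokens, rulebook) {
  rules <- if (!is.null(attr(rulebook, "compiled"))) {
    attr(rulebook, "compiled")
  } else {
    compileRules(rulebook)
  }
  rules <- rules[rules$group == candidate$group, , drop = FALSE]
  if (!nrow(rules) &&
      !(candidate$group %in% rulebook@fallbacks$group)) {
    stop(sprintf("rulebook has no rules or fallback for family %s (group %s)",
                 candidate$family, candidate$group))
  }
  left_end <- min(candidate$a_end, candidate$b_end)
  right_start <- max(candidate$a_start, candidate$b_start)
  nt <- nrow(tokens)
  for (ri in seq_len(nrow(rules))) {
    klen <- rules$kwlen[ri]
    if (klen > nt) next
    kkey <- rules$kwkey[ri]
    for (i in seq_len(nt - klen + 1L)) {
      if (paste(tokens$key[i:(i + klen - 1L)], collapse = " ") != kkey) next
      if (rules$between_only[ri]) {
        if (!(tokens$start[i] >= left_end &&
              tokens$end[i + klen - 1L] <= right_start)) next
      }
      return(list(relation_type = rules$relation_type[ri],
                  matched_keyword = rules$keyword[ri]))
    }
  }
  fb <- rulebook@fallbacks
  list(relation_type = fb$relation_type[fb$group == candidate$group][1],
       matched_keyword = NA_character_)
}

#' Extract and classify relation evidence over a corpus
#'
#' Runs [extractCooccurrence()] and [classifyPair()] over every
#' document. When a \code{plugin} classifier is supplied it is consulted
#' only for candidates the rulebook left at the fallback type (no
#' keyword matched): the rule result always takes precedence when a
#' keyword was found.
#'
#' @param corpus List of tagged, sentence-split Documents.
#' @param schema See [defaultPairSchema()].
#' @param rulebook See [defaultRuleBook()].
#' @param plugin Optional \code{function(sentenceText, candidate)}
#'   returning a relation type from the candidate family's type set
#'   (see [groupTypes()]); anything else is a contract violation error.
#' @return Evidence data.frame: \code{pmid}, \code{sentence},
#'   \code{id_a}, \code{id_b}, \code{family}, \code{group},
#'   \code{matched_keyword}, \code{relation_type}, \code{classifier}
#'   (\code{"rule"} or \code{"plugin"}).
#' @export
extractRelations <- function(corpus, schema = defaultPairSchema(),
                             rulebook = defaultRuleBook(), plugin = NULL) {
  attr(rulebook, "compiled") <- compileRules(rulebook)
  rows <- list()
  for (doc in corpus) {
    cands <- extractCooccurrence(doc, schema)
    if (!nrow(cands)) next
    for (si in unique(cands$sentence)) {
      toks <- sentenceTokens(doc, si, rulebook@mode)
      sc <- cands[cands$sentence == si, , drop = FALSE]
      for (k in seq_len(nrow(sc))) {
        cand <- sc[k, , drop = FALSE]
        res <- classifyPair(cand, toks, rulebook)
        classifier <- "rule"
        if (!is.null(plugin) && is.na(res$matched_keyword)) {
          srow <- sentences(doc)[si + 1L, ]
          sentText <- sliceText(fullText(doc), srow$start, srow$end)
          ptype <- plugin(sentText, cand)
          allowed <- groupTypes(rulebook, cand$group)
          if (!(is.character(ptype) && length(ptype) == 1L &&
                ptype %in% allowed)) {
            stop(sprintf(
              "plugin returned '%s' for family %s; allowed types: %s",
              paste(ptype, collapse = ","), cand$family,
              paste(allowed, collapse = ", ")))
          }
          res$relation_type <- ptype
          classifier <- "plugin"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = cand$pmid, sentence = cand$sentence,
          id_a = cand$a_id, id_b = cand$b_id,
          family = cand$family, group = cand$group,
          matched_keyword = res$matched_keyword,
          relation_type = res$relation_type, classifier = classifier,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pmid = character(0), sentence = integer(0),
                      id_a = character(0), id_b = character(0),
                      family = character(0), group = character(0),
                      matched_keyword = character(0),
                      relation_type = character(0),
                      classifier = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate sentence-level evidence into corpus-level relations
#'
#' Evidence is grouped by (id_a, id_b, family). Within each group the
#' majority relation type is chosen among typed (non-fallback) evidence;
#' fallback evidence counts toward the denominator but can only be the
#' majority when no typed evidence exists. \code{confidence} is the
#' majority fraction over all co-occurrence sentences of the pair and
#' \code{support} the majority count. Groups are kept iff
#' \code{support >= minSupport} and \code{confidence >
#' confidenceThreshold} (strict); dropped groups are returned in the
#' \code{"dropped"} attribute.
#'
#' @param evidences From [extractRelations()].
#' @param minSupport Minimum majority count (default 2).
#' @param confidenceThreshold Strict lower bound on confidence
#'   (default 0.5).
#' @param fallbackTypes Relation types treated as fallback
#'   (default \code{"Other"}).
#' @return data.frame \code{id_a}, \code{id_b}, \code{family},
#'   \code{relation_type}, \code{n}, \code{support}, \code{confidence},
#'   \code{pmids}, \code{keywords} (pipe-joined sorted sets), with
#'   attribute \code{dropped}.
#' @export
aggregateRelations <- function(evidences, minSupport = 2L,
                               confidenceThreshold = 0.5,
                               fallbackTypes = "Other") {
  emptyOut <- data.frame(id_a = character(0), id_b = character(0),
                         family = character(0), relation_type = character(0),
                         n = integer(0), support = integer(0),
                         confidence = numeric(0), pmids = character(0),
                         keywords = character(0), stringsAsFactors = FALSE)
  if (!nrow(evidences)) {
    attr(emptyOut, "dropped") <- emptyOut
    return(emptyOut)
  }
  gkey <- paste(evidences$id_a, evidences$id_b, evidences$family,
                sep = "\r")
  groups <- split(seq_len(nrow(evidences)), gkey)
  rows <- lapply(groups, function(ix) {
    ev <- evidences[ix, , drop = FALSE]
    n <- nrow(ev)
    tab <- table(ev$relation_type)
    typed <- tab[!(names(tab) %in% fallbackTypes)]
    if (length(typed)) {
      best <- names(typed)[order(-typed, names(typed))][1]
    } else {
      best <- names(tab)[order(-tab, names(tab))][1]
    }
    support <- as.integer(tab[[best]])
    kws <- sort(unique(ev$matched_keyword[!is.na(ev$matched_keyword)]))
    data.frame(id_a = ev$id_a[1], id_b = ev$id_b[1], family = ev$family[1],
               relation_type = best, n = n, support = support,
               confidence = support / n,
               pmids = paste(sort(unique(ev$pmid)), collapse = "|"),
               keywords = paste(kws, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, rows)
  rownames(agg) <- NULL
  agg <- agg[order(agg$family, agg$id_a, agg$id_b), , drop = FALSE]
  rownames(agg) <- NULL
  keep <- agg$support >= minSupport & agg$confidence > confidenceThreshold
  out <- agg[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- agg[!keep, , drop = FALSE]
  rownames(dropped) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Write sentence-level evidence as TSV
#' @param evidences From [extractRelations()].
#' @param file Path or connection.
#' @return Invisibly, \code{evidences}.
#' @export
writeEvidence <- function(evidences, file) {
  write.table(evidences, file, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(evidences)
}
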