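# Dictionary-based NER over sentences, plus the corpus-level
# entity-frequency filter: entities mentioned fewer than
# `minEntityCount` times (default 3) are routed to a manual-review list
# and excluded from relation extraction unless whitelisted.

#' NER configuration
#'
#' @param minEntityCount Corpus-level frequency threshold; entities with
#'   fewer total mentions are routed to the review list. Must be >= 1.
#' @param caseSensitive When TRUE a dictionary hit additionally requires
#'   a case-sensitive match against one of the entry's raw surfaces
#'   (after hyphen/space unification). Default off.
#' @return A list of class \code{NerConfig}.
#' @export
nerConfig <- function(minEntityCount = 3L, caseSensitive = FALSE) {
  minEntityCount <- as.integer(minEntityCount)
  stopifnot(length(minEntityCount) == 1L, minEntityCount >= 1L,
            is.logical(caseSensitive))
  structure(list(minEntityCount = minEntityCount,
                 caseSensitive = caseSensitive),
            class = "NerConfig")
}

# key under which an entity is counted / aggregated: canonical id when
# normalized, otherwise its normalized surface under a SURF: namespace
entityKey <- function(norm_id, surface) {
  ifelse(norm_id == unnormalized(),
         paste0("SURF:", normalizeSurface(surface)), norm_id)
}

#' Tag a document against compiled lexicons
#'
#' Longest-match, non-overlapping-within-type tagging over normalized
#' token sequences, sentence by sentence. Within one entity type,
#' overlaps resolve longest-match-then-leftmost; the same span may be
#' tagged by lexicons of different types (one mention per type).
#' Pre-annotated mentions are preserved untouched; a dictionary hit
#' duplicating a pre-annotated (span, type) is not re-added.
#'
#' @param doc A sentence-split [Document].
#' @param lexicons A list of [Lexicon] objects (one or more types).
#' @param config A [nerConfig()] (only \code{caseSensitive} is used here).
#' @return The Document with added \code{source = "dictionary"} mentions.
#' @examples
#' lex <- loadLexicon("DB00945\taspirin", "Drug")
#' d <- splitSentences(Document("1", "Note", "Aspirin reduces risk."))
#' mentions(tagDocument(d, list(lex)))
#' @export
tagDocument <- function(doc, lexicons, config = nerConfig()) {
  if (!nrow(sentences(doc))) {
    stop("document must be sentence-split before tagging; see splitSentences()")
  }
  if (is(lexicons, "Lexicon")) lexicons <- list(lexicons)
  ft <- fullText(doc)
  s <- sentences(doc)
  newRows <- list()
  for (lex in lexicons) {
    map <- surfaceMap(lex)
    if (!length(map)) next
    maxTok <- lex@maxTokens
    caseRaws <- NULL
    if (isTRUE(config$caseSensitive)) {
      sr <- lexSurfaces(lex)
      caseRaws <- split(gsub("\\s+", " ", gsub("[-_]+", " ", sr$raw)),
                        paste(sr$key, sr$canonical_id))
    }
    for (si in seq_len(nrow(s))) {
      segText <- sliceText(ft, s$start[si], s$end[si])
      toks <- tokenizeWithOffsets(segText)
      nt <- nrow(toks)
      if (!nt) next
      norm <- tolower(toks$token)
      i <- 1L
      while (i <= nt) {
        matched <- FALSE
        for (len in seq.int(min(maxTok, nt - i + 1L), 1L)) {
          key <- paste(norm[i:(i + len - 1L)], collapse = " ")
          id <- map[key]
          if (!is.na(id)) {
            start <- s$start[si] + toks$start[i]
            end <- s$start[si] + toks$end[i + len - 1L]
            surface <- sliceText(ft, start, end)
            ok <- TRUE
            if (!is.null(caseRaws)) {
              cand <- caseRaws[[paste(key, id)]]
              ok <- gsub("\\s+", " ", gsub("[-_]+", " ", surface)) %in% cand
            }
            if (ok) {
              newRows[[length(newRows) + 1L]] <- data.frame(
                start = start, end = end, surface = surface,
                entity_type = entityType(lex), norm_id = unname(id),
                source = "dictionary", sentence = si - 1L,
                stringsAsFactors = FALSE)
              i <- i + len
              matched <- TRUE
              break
            }
          }
        }
        if (!matched) i <- i + 1L
      }
    }
  }
  if (!length(newRows)) return(doc)
  add <- do.call(rbind, newRows)
  old <- mentions(doc)
  if (nrow(old)) {
    dupKey <- paste(add$start, add$end, add$entity_type)
    oldKey <- paste(old$start, old$end, old$entity_type)
    add <- add[!(dupKey %in% oldKey), , drop = FALSE]
  }
  initialize(doc, mentions = normalizeMentionFrame(rbind(old, add)))
}

#' @rdname tagDocument
#' @param corpus A list of sentence-split Documents.
#' @export
tagCorpus <- function(corpus, lexicons, config = nerConfig()) {
  lapply(corpus, tagDocument, lexicons = lexicons, config = config)
}

#' Corpus-wide mention table
#'
#' Binds the mention data.frames of all documents, prefixed with a
#' \code{pmid} column — the shape [scoreNer()] consumes.
#'
#' @param corpus A list of [Document] objects.
#' @return data.frame of mentions with \code{pmid} first.
#' @export
corpusMentions <- function(corpus) {
  rows <- lapply(corpus, function(d) {
    m <- mentions(d)
    if (!nrow(m)) return(NULL)
    cbind(pmid = pmid(d), m, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(cbind(pmid = character(0), emptyMentions()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a corpus-level entity census
#'
#' Counts mentions and documents per entity (canonical id, or normalized
#' surface for unnormalized mentions). The census total equals the
#' number of mentions in the corpus (conservation).
#'
#' @param corpus A list of tagged [Document] objects.
#' @return data.frame \code{entity_id}, \code{entity_type},
#'   \code{mention_count}, \code{doc_count}, \code{example_surface},
#'   \code{example_pmid}, ordered by (count desc, id asc).
#' @export
buildCensus <- function(corpus) {
  m <- corpusMentions(corpus)
  if (!nrow(m)) {
    return(data.frame(entity_id = character(0), entity_type = character(0),
                      mention_count = integer(0), doc_count = integer(0),
                      example_surface = character(0),
                      example_pmid = character(0), stringsAsFactors = FALSE))
  }
  key <- entityKey(m$norm_id, m$surface)
  sp <- split(seq_len(nrow(m)), key)
  census <- data.frame(
    entity_id = names(sp),
    entity_type = vapply(sp, function(i) m$entity_type[i[1]], ""),
    mention_count = lengths(sp),
    doc_count = vapply(sp, function(i) length(unique(m$pmid[i])), 1L),
    example_surface = vapply(sp, function(i) m$surface[i[1]], ""),
    example_pmid = vapply(sp, function(i) m$pmid[i[1]], ""),
    stringsAsFactors = FALSE)
  census <- census[order(-census$mention_count, census$entity_id), ]
  rownames(census) <- NULL
  census
}

#' Apply the corpus-level entity-frequency filter
#'
#' Entities with \code{mention_count < minEntityCount} have all their
#' mentions routed to a review list (mirroring a manual-inspection
#' step); entities at or above the threshold are kept. A whitelist of
#' entity ids reinstates reviewed entities. Kept and reviewed mentions
#' partition the corpus mentions exactly.
#'
#' @param corpus Tagged corpus (list of Documents).
#' @param census From [buildCensus()] on this corpus.
#' @param config A [nerConfig()].
#' @param whitelist Character vector of entity ids to keep regardless of
#'   count.
#' @return List with \code{corpus} (documents restricted to kept
#'   mentions), \code{review} (per-entity data.frame: \code{entity_id},
#'   \code{surface}, \code{count}, \code{example_pmid}) and
#'   \code{reviewMentions} (the routed mention rows with pmid).
#' @export
applyFrequencyFilter <- function(corpus, census, config = nerConfig(),
                                 whitelist = character(0)) {
  lowIds <- census$entity_id[census$mention_count < config$minEntityCount]
  lowIds <- setdiff(lowIds, whitelist)
  reviewRows <- list()
  outCorpus <- lapply(corpus, function(d) {
    m <- mentions(d)
    if (!nrow(m)) return(d)
    routed <- entityKey(m$norm_id, m$surface) %in% lowIds
    if (any(routed)) {
      reviewRows[[length(reviewRows) + 1L]] <<- cbind(
        pmid = pmid(d), m[routed, , drop = FALSE],
        stringsAsFactors = FALSE)
    }
    initialize(d, mentions = normalizeMentionFrame(m[!routed, , drop = FALSE]))
  })
  reviewMentions <- if (length(reviewRows)) {
    rr <- do.call(rbind, reviewRows)
    rownames(rr) <- NULL
    rr
  } else {
    cbind(pmid = character(0), emptyMentions())
  }
  lowCensus <- census[census$entity_id %in% lowIds, , drop = FALSE]
  review <- data.frame(entity_id = lowCensus$entity_id,
                       surface = lowCensus$example_surface,
                       count = lowCensus$mention_count,
                       example_pmid = lowCensus$example_pmid,
                       stringsAsFactors = FALSE)
  rownames(review) <- NULL
  list(corpus = outCorpus, review = review, reviewMentions = reviewMentions)
}

#' Write the review list as TSV
#' @param review The \code{review} element of [applyFrequencyFilter()].
#' @param file Path or connection.
#' @return Invisibly, \code{review}.
#' @export
writeReviewList <- function(review, file) {
  write.table(review, file, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(review)
}
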