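#' Document: one abstract with sentence offsets and entity mentions
#'
#' An S4 container for a single PubTator record. \code{fullText()} is the
#' title and abstract joined by a single space; all character offsets
#' (sentence spans and mention spans) are 0-based half-open into that
#' concatenation, PubTator's native convention.
#'
#' Slots:
#' \describe{
#'   \item{pmid}{identifier string.}
#'   \item{title, abstract}{raw text.}
#'   \item{sentences}{data.frame \code{start}, \code{end}: ordered,
#'     non-overlapping spans into the full text.}
#'   \item{mentions}{data.frame \code{start}, \code{end}, \code{surface},
#'     \code{entity_type}, \code{norm_id}, \code{source},
#'     \code{sentence} (0-based containing-sentence index, \code{NA}
#'     before splitting or for boundary-crossing mentions).}
#'   \item{diagnostics}{character vector of per-document flags (e.g.
#'     mentions crossing sentence boundaries).}
#' }
#'
#' @name Document-class
#' @aliases Document
#' @exportClass Document
setClass("Document",
  representation(pmid = "character", title = "character",
                 abstract = "character", sentences = "data.frame",
                 mentions = "data.frame", diagnostics = "character"),
  prototype(pmid = NA_character_, title = "", abstract = "",
            sentences = data.frame(start = integer(0), end = integer(0)),
            mentions = data.frame(
              start = integer(0), end = integer(0), surface = character(0),
              entity_type = character(0), norm_id = character(0),
              source = character(0), sentence = integer(0),
              stringsAsFactors = FALSE),
            diagnostics = character(0)))

validDocument <- function(object) {
  msgs <- character(0)
  if (length(object@pmid) != 1L || is.na(object@pmid) ||
      !nzchar(object@pmid)) {
    msgs <- c(msgs, "pmid must be a single non-empty string")
  }
  ft <- paste(object@title, object@abstract, sep = " ")
  n <- nchar(ft)
  s <- object@sentences
  if (!all(c("start", "end") %in% names(s))) {
    msgs <- c(msgs, "sentences must have columns start, end")
  } else if (nrow(s)) {
    if (any(s$start < 0L) || any(s$end > n) || any(s$end <= s$start)) {
      msgs <- c(msgs, "sentence spans must satisfy 0 <= start < end <= nchar(full text)")
    }
    if (nrow(s) > 1L &&
        (is.unsorted(s$start) || any(s$start[-1L] < s$end[-nrow(s)]))) {
      msgs <- c(msgs, "sentence spans must be sorted and non-overlapping")
    }
  }
  m <- object@mentions
  need <- c("start", "end", "surface", "entity_type", "norm_id",
            "source", "sentence")
  if (!all(need %in% names(m))) {
    msgs <- c(msgs, paste("mentions must have columns",
                          paste(need, collapse = ", ")))
  } else if (nrow(m)) {
    if (any(m$end <= m$start) || any(m$start < 0L) || any(m$end > n)) {
      msgs <- c(msgs, "mention spans must satisfy 0 <= start < end <= nchar(full text)")
    } else {
      bad <- sliceText(ft, m$start, m$end) != m$surface
      if (any(bad)) {
        msgs <- c(msgs, sprintf(
          "mention surface mismatch at span (%d,%d) in pmid %s",
          m$start[which(bad)[1]], m$end[which(bad)[1]], object@pmid))
      }
    }
    if (!all(m$entity_type %in% entityTypes())) {
      msgs <- c(msgs, sprintf("unknown entity_type: %s",
        paste(unique(setdiff(m$entity_type, entityTypes())), collapse = ", ")))
    }
    if (any(!nzchar(m$surface))) msgs <- c(msgs, "empty mention surface")
    if (!all(m$source %in% c("preannotated", "dictionary"))) {
      msgs <- c(msgs, "mention source must be 'preannotated' or 'dictionary'")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("Document", validDocument)

#' @describeIn Document-class construct a Document; sentence and mention
#'   assignment happens later via [splitSentences()].
#' @param pmid,title,abstract record fields.
#' @param mentions optional mention data.frame (see slots).
#' @return A \code{Document}.
#' @export
Document <- function(pmid, title = "", abstract = "",
                     mentions = emptyMentions()) {
  if (!("sentence" %in% names(mentions)) && nrow(mentions) >= 0L) {
    mentions$sentence <- rep(NA_integer_, nrow(mentions))
  }
  mentions <- normalizeMentionFrame(mentions)
  new("Document", pmid = as.character(pmid), title = title,
      abstract = abstract, sentences = emptySentences(),
      mentions = mentions, diagnostics = character(0))
}

normalizeMentionFrame <- function(m) {
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  if (!nrow(m)) return(emptyMentions())
  m$start <- as.integer(m$start)
  m$end <- as.integer(m$end)
  if (is.null(m$sentence)) m$sentence <- NA_integer_
  m$sentence <- as.integer(m$sentence)
  ord <- order(m$start, m$end, m$entity_type)
  m <- m[ord, c("start", "end", "surface", "entity_type", "norm_id",
                "source", "sentence"), drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Lexicon: compiled entity dictionary for one entity type
#'
#' Maps normalized surface forms to canonical identifiers for
#' dictionary-based NER. Matching happens over normalized token
#' sequences (see [normalizeSurface()]), never raw substrings.
#'
#' Slots: \code{entityType}; \code{entries} (data.frame
#' \code{canonical_id}, \code{preferred_name}); \code{surfaces}
#' (data.frame \code{key} = normalized surface, \code{raw},
#' \code{canonical_id}, \code{origin} in \{source, variant\});
#' \code{maxTokens}, the longest surface in tokens.
#'
#' @name Lexicon-class
#' @aliases Lexicon
#' @exportClass Lexicon
setClass("Lexicon",
  representation(entityType = "character", entries = "data.frame",
                 surfaces = "data.frame", maxTokens = "integer"))

setValidity("Lexicon", function(object) {
  msgs <- character(0)
  if (!(object@entityType %in% entityTypes())) {
    msgs <- c(msgs, sprintf("entityType '%s' not in the 9-type vocabulary",
                            object@entityType))
  }
  if (anyDuplicated(object@entries$canonical_id)) {
    msgs <- c(msgs, "duplicate canonical_id")
  }
  s <- object@surfaces
  if (nrow(s)) {
    amb <- tapply(s$canonical_id, s$key, function(x) length(unique(x)))
    if (any(amb > 1L)) {
      msgs <- c(msgs, sprintf("ambiguous surface key(s): %s",
        paste(head(names(amb)[amb > 1L], 3L), collapse = ", ")))
    }
    if (any(!nzchar(s$key))) msgs <- c(msgs, "empty surface")
  }
  if (length(msgs)) msgs else TRUE
})

#' RuleBook: keyword classification rules for relation typing
#'
#' Slots: \code{rules} (data.frame \code{group}, \code{relation_type},
#' \code{priority}, \code{keyword}, \code{between_only}); \code{fallbacks}
#' (data.frame \code{group}, \code{relation_type} — the keyword-less
#' fallback type per rule group); \code{mode}, \code{"stem"} or
#' \code{"exact"} keyword matching.
#'
#' @name RuleBook-class
#' @aliases RuleBook
#' @exportClass RuleBook
setClass("RuleBook",
  representation(rules = "data.frame", fallbacks = "data.frame",
                 mode = "character"))

setValidity("RuleBook", function(object) {
  msgs <- character(0)
  if (!(object@mode %in% c("stem", "exact"))) {
    msgs <- c(msgs, "mode must be 'stem' or 'exact'")
  }
  need <- c("group", "relation_type", "priority", "keyword", "between_only")
  if (!all(need %in% names(object@rules))) {
    msgs <- c(msgs, "rules must have columns group, relation_type, priority, keyword, between_only")
  }
  if (!all(c("group", "relation_type") %in% names(object@fallbacks))) {
    msgs <- c(msgs, "fallbacks must have columns group, relation_type")
  } else if (nrow(object@rules) &&
             !all(unique(object@rules$group) %in% object@fallbacks$group)) {
    msgs <- c(msgs, "every rule group needs a fallback type")
  }
  if (length(msgs)) msgs else TRUE
})

#' KnowledgeGraph: typed entity-relation graph
#'
#' Slots: \code{nodes} (data.frame \code{id}, \code{name},
#' \code{entity_type}, \code{mesh_id}, \code{mention_count});
#' \code{edges} (data.frame \code{source}, \code{target}, \code{family},
#' \code{relation_type}, \code{relation_keywords}, \code{pmids},
#' \code{confidence}, \code{support}). Set-valued fields are
#' pipe-joined, sorted strings. Edges reference node ids; referential
#' integrity is enforced by validity.
#'
#' @name KnowledgeGraph-class
#' @aliases KnowledgeGraph
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("KnowledgeGraph", function(object) {
  msgs <- character(0)
  nn <- c("id", "name", "entity_type", "mesh_id", "mention_count")
  en <- c("source", "target", "family", "relation_type",
          "relation_keywords", "pmids", "confidence", "support")
  if (!all(nn %in% names(object@nodes))) {
    msgs <- c(msgs, paste("nodes must have columns", paste(nn, collapse = ", ")))
  } else if (anyDuplicated(object@nodes$id)) {
    msgs <- c(msgs, "node ids must be unique")
  }
  if (!all(en %in% names(object@edges))) {
    msgs <- c(msgs, paste("edges must have columns", paste(en, collapse = ", ")))
  } else if (nrow(object@edges)) {
    dangling <- !(object@edges$source %in% object@nodes$id) |
                !(object@edges$target %in% object@nodes$id)
    if (any(dangling)) {
      i <- which(dangling)[1]
      msgs <- c(msgs, sprintf("dangling edge endpoint: %s -- %s",
        object@edges$source[i], object@edges$target[i]))
    }
    if (any(!nzchar(object@edges$pmids))) {
      msgs <- c(msgs, "every edge must carry at least one pmid")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ConfusionMatrix: predicted-by-reference relation-type counts
#'
#' Rows are predicted types, columns reference types. The grand total is
#' the number of overlapped relationships (pairs found by both sides);
#' the diagonal sum is the number of correctly classified relationships.
#'
#' @name ConfusionMatrix-class
#' @aliases ConfusionMatrix
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(labels = "character", counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  msgs <- character(0)
  k <- length(object@labels)
  if (!all(dim(object@counts) == c(k, k))) {
    msgs <- c(msgs, "counts must be a square label-by-label matrix")
  }
  if (length(object@counts) && any(object@counts < 0)) {
    msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConfusionMatrix-class construct from a square count matrix
#'   (dimnames used as labels when \code{labels} is missing).
#' @param counts square numeric matrix of counts.
#' @param labels ordered label set.
#' @return A \code{ConfusionMatrix}.
#' @export
confusionMatrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(predicted = labels, reference = labels)
  new("ConfusionMatrix", labels = as.character(labels), counts = counts)
}

#' EvalReport: precision/recall/F1 against a gold standard
#'
#' @name EvalReport-class
#' @aliases EvalReport
#' @exportClass EvalReport
setClass("EvalReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 matchMode = "character"))
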