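# PubTator corpus I/O and sentence segmentation.
#
# PubTator blocks look like:
#   123|t|Title text
#   123|a|Abstract text
#   123<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>norm_id
#   (blank line)
# Offsets are 0-based half-open into "title + single space + abstract".

#' Read a PubTator-format corpus
#'
#' Parses blank-line-separated PubTator blocks into [Document] objects.
#' Annotation lines become mentions with \code{source = "preannotated"};
#' every mention span is validated against the document text.
#'
#' @param file Path, connection, or a character vector of lines.
#' @return A list of [Document] objects (empty list for empty input).
#' @seealso [writePubTator()], [splitSentences()]
#' @examples
#' lines <- c("1|t|Aspirin study", "1|a|Aspirin helps.",
#'            "1\t14\t21\tAspirin\tDrug\tDB00945", "")
#' docs <- readPubTator(lines)
#' mentions(docs[[1]])
#' @export
readPubTator <- function(file) {
  lines <- if (is.character(file) && length(file) != 1L) {
    file
  } else if (is.character(file) && !file.exists(file) &&
             grepl("\\|t\\||\\|a\\||\t|^$", file)) {
    # a single string of literal content
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  docs <- list()
  block <- character(0)
  lineNo <- 0L
  blockStart <- 1L
  flush <- function(block, at) {
    if (length(block)) parsePubTatorBlock(block, at) else NULL
  }
  for (ln in c(lines, "")) {
    lineNo <- lineNo + 1L
    if (!nzchar(trimws(ln))) {
      d <- flush(block, blockStart)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      block <- character(0)
      blockStart <- lineNo + 1L
    } else {
      block <- c(block, ln)
    }
  }
  docs
}

parsePubTatorBlock <- function(block, startLine) {
  title <- NULL; abstract <- ""; pmid <- NULL
  anns <- list()
  for (i in seq_along(block)) {
    ln <- block[i]
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      pm <- sub("\\|.*$", "", ln)
      if (is.null(pmid)) pmid <- pm
      title <- sub("^[^|]+\\|t\\|", "", ln)
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      abstract <- sub("^[^|]+\\|a\\|", "", ln)
    } else if (grepl("\t", ln, fixed = TRUE)) {
      anns[[length(anns) + 1L]] <- ln
    } else {
      stop(sprintf("line %d: malformed PubTator header line: '%s'",
                   startLine + i - 1L, ln))
    }
  }
  if (is.null(title) || is.null(pmid)) {
    stop(sprintf("line %d: PubTator block without a pmid|t|title line",
                 startLine))
  }
  m <- emptyMentions()
  if (length(anns)) {
    fields <- strsplit(unlist(anns), "\t", fixed = TRUE)
    bad <- vapply(fields, length, 1L) < 5L
    if (any(bad)) {
      stop(sprintf("line %d: annotation line needs at least 5 tab-separated fields",
                   startLine + which(grepl("\t", block, fixed = TRUE))[which(bad)[1]] - 1L))
    }
    m <- data.frame(
      start = as.integer(vapply(fields, `[`, "", 2L)),
      end = as.integer(vapply(fields, `[`, "", 3L)),
      surface = vapply(fields, `[`, "", 4L),
      entity_type = vapply(fields, `[`, "", 5L),
      norm_id = vapply(fields, function(f)
        if (length(f) >= 6L && nzchar(f[6L])) f[6L] else unnormalized(), ""),
      source = "preannotated",
      sentence = NA_integer_,
      stringsAsFactors = FALSE)
  }
  ft <- paste(title, abstract, sep = " ")
  if (nrow(m)) {
    got <- sliceText(ft, m$start, m$end)
    bad <- got != m$surface
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "pmid %s: mention span (%d,%d) slices to '%s', not '%s'",
        pmid, m$start[i], m$end[i], got[i], m$surface[i]))
    }
  }
  Document(pmid = pmid, title = title, abstract = abstract, mentions = m)
}

#' Write documents in canonical PubTator format
#'
#' Mentions are emitted sorted by (start, end, entity_type); each block
#' ends with a blank line. Documents are validated before serialization,
#' so an invalid mention span refuses to serialize.
#'
#' @param docs A list of [Document] objects (or a single Document).
#' @param file Path or connection; \code{NULL} returns the lines invisibly
#'   without writing.
#' @return Invisibly, the character vector of lines.
#' @export
writePubTator <- function(docs, file = NULL) {
  if (is(docs, "Document")) docs <- list(docs)
  out <- unlist(lapply(docs, function(d) {
    validObject(d)
    m <- normalizeMentionFrame(mentions(d))
    lines <- c(paste0(pmid(d), "|t|", d@title),
               paste0(pmid(d), "|a|", d@abstract))
    if (nrow(m)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s\t%s", pmid(d),
                                m$start, m$end, m$surface, m$entity_type,
                                m$norm_id))
    }
    c(lines, "")
  }))
  if (is.null(out)) out <- character(0)
  if (!is.null(file)) writeLines(out, file, useBytes = FALSE)
  invisible(out)
}

#' Default abbreviation guard list for the rule-based sentence splitter
#'
#' Tokens (lower-case, without the trailing period) after which a period
#' does not end a sentence.
#' @return Character vector.
#' @export
defaultAbbreviations <- function() {
  c("e.g", "i.e", "etc", "fig", "figs", "al", "vs", "cf", "ca",
    "approx", "dr", "mr", "mrs", "ms", "prof", "st", "no", "nos",
    "resp", "inc", "ltd", "wt", "spp", "sp")
}

splitTextSentences <- function(text, offset, abbreviations) {
  # returns spans (0-based half-open, absolute = local + offset) covering
  # all non-whitespace of `text`
  n <- nchar(text)
  if (!n || !nzchar(trimws(text))) return(emptySentences())
  chars <- strsplit(text, "")[[1]]
  boundaries <- integer(0)  # index (1-based) of the sentence-final char
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "?", "!")) {
      # absorb a run of terminal punctuation
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "?", "!", "\"", "'", ")")) {
        j <- j + 1L
      }
      isEnd <- FALSE
      if (j == n) {
        isEnd <- TRUE
      } else if (grepl("\\s", chars[j + 1L])) {
        k <- j + 1L
        while (k <= n && grepl("\\s", chars[k])) k <- k + 1L
        nxt <- if (k <= n) chars[k] else ""
        if (nxt == "" || grepl("[A-Z0-9\"'(\\[]", nxt)) isEnd <- TRUE
      }
      if (isEnd && ch == ".") {
        # abbreviation guard: word immediately before the period
        prev <- sub(".*?([A-Za-z.]+)$", "\\1",
                    substr(text, max(1L, i - 12L), i - 1L))
        if (tolower(prev) %in% abbreviations) isEnd <- FALSE
      }
      if (isEnd) boundaries <- c(boundaries, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(boundaries) || boundaries[length(boundaries)] < n) {
    boundaries <- c(boundaries, n)
  }
  starts <- c(1L, boundaries[-length(boundaries)] + 1L)
  spans <- mapply(function(s, e) {
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    c(s + lead, e - trail)
  }, starts, boundaries)
  keep <- spans[2L, ] >= spans[1L, ]
  data.frame(start = offset + spans[1L, keep] - 1L,
             end = offset + spans[2L, keep])
}

#' Split a document into sentences
#'
#' Applies a deterministic rule-based splitter: sentence-final
#' \code{. ? !} followed by whitespace and an upper-case letter, digit or
#' opening quote/bracket, with an abbreviation guard list. The title and
#' abstract are segmented independently (the title/abstract junction is
#' always a sentence boundary). Existing mention spans are re-checked for
#' single-sentence containment; mentions crossing a boundary keep
#' \code{sentence = NA} and are listed in \code{diagnostics()} (they are
#' excluded from relation extraction downstream).
#'
#' @param doc A [Document].
#' @param abbreviations Guard list, see [defaultAbbreviations()].
#' @param splitter Optional replacement splitter:
#'   \code{function(text, offset)} returning a data.frame of absolute
#'   \code{start}/\code{end} spans. The default is the rule-based one.
#' @return The Document with \code{sentences} filled and mention
#'   \code{sentence} indices (0-based) assigned.
#' @examples
#' d <- Document("1", "A. B.", "One sentence here.")
#' sentences(splitSentences(d))
#' @export
splitSentences <- function(doc, abbreviations = defaultAbbreviations(),
                           splitter = NULL) {
  if (is.null(splitter)) {
    splitter <- function(text, offset) {
      splitTextSentences(text, offset, abbreviations)
    }
  }
  titleSpans <- splitter(doc@title, 0L)
  absOffset <- nchar(doc@title) + 1L  # past title and the separator space
  absSpans <- splitter(doc@abstract, absOffset)
  s <- rbind(titleSpans, absSpans)
  rownames(s) <- NULL
  m <- doc@mentions
  diag <- character(0)
  if (nrow(m)) {
    m$sentence <- NA_integer_
    for (i in seq_len(nrow(m))) {
      hit <- which(s$start <= m$start[i] & m$end[i] <= s$end)
      if (length(hit) == 1L) {
        m$sentence[i] <- hit - 1L  # 0-based
      } else {
        diag <- c(diag, sprintf(
          "mention '%s' (%d,%d) crosses a sentence boundary",
          m$surface[i], m$start[i], m$end[i]))
      }
    }
  }
  initialize(doc, sentences = s, mentions = m, diagnostics = diag)
}

#' Validate a PubTator corpus file
#'
#' Reads and validates every block, then reports per-document mention and
#' sentence-containment status.
#'
#' @param file Path to a PubTator file.
#' @return Invisibly, the parsed document list.
#' @export
validatePubTator <- function(file) {
  docs <- readPubTator(file)
  docs <- lapply(docs, splitSentences)
  flagged <- sum(vapply(docs, function(d) length(diagnostics(d)), 1L))
  message(sprintf("%d document(s), %d mention(s), %d boundary-crossing mention(s)",
                  length(docs),
                  sum(vapply(docs, function(d) nrow(mentions(d)), 1L)),
                  flagged))
  invisible(docs)
}
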