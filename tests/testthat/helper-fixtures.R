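# Shared fixtures and independent oracles, all built in code.

# tiny hand-written lexicons with overlap opportunities
tinyLexicons <- function() {
  list(
    Drug = loadLexicon(c("DB00945\tAspirin",
                         "DB00682\tWarfarin"), "Drug"),
    Disease = loadLexicon(c("MESH:D020521\tStroke",
                            "MESH:D002545\tbrain ischemia",
                            "MESH:D007511\tischemia"), "Disease"),
    Gene = loadLexicon(c("GEN:ACE\tACE", "GEN:VEGF\tVEGF"), "Gene"),
    Symptom = loadLexicon("SYM:FEV\tFever", "Symptom"))
}

# words guaranteed absent from the tiny lexicons
fillerWords <- c("studied", "within", "cohort", "baseline", "measured")

# build a sentence-split document from sentence strings (title fixed)
docFromSentences <- function(pmid, sentenceStrings,
                             mentions = emptyMentionsDf()) {
  abstract <- paste(sentenceStrings, collapse = " ")
  splitSentences(Document(pmid, "Fixture title", abstract,
                          mentions = mentions))
}

emptyMentionsDf <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             entity_type = character(0), norm_id = character(0),
             source = character(0), sentence = integer(0),
             stringsAsFactors = FALSE)
}

# independent NER oracle: enumerate every in-sentence token n-gram match,
# then repeatedly select (per type) the leftmost, then longest candidate
bruteForceTag <- function(doc, lexicons) {
  ft <- fullText(doc)
  s <- sentences(doc)
  out <- list()
  for (lex in lexicons) {
    sm <- litkg:::surfaceMap(lex)
    cands <- list()
    for (si in seq_len(nrow(s))) {
      seg <- sliceText(ft, s$start[si], s$end[si])
      toks <- tokenizeWithOffsets(seg)
      nt <- nrow(toks)
      if (!nt) next
      for (i in seq_len(nt)) for (j in i:nt) {
        key <- paste(tolower(toks$token[i:j]), collapse = " ")
        if (!is.na(sm[key])) {
          cands[[length(cands) + 1L]] <- data.frame(
            start = s$start[si] + toks$start[i],
            end = s$start[si] + toks$end[j],
            norm_id = unname(sm[key]), sentence = si - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(cands)) next
    cd <- do.call(rbind, cands)
    sel <- list()
    while (nrow(cd)) {
      cd <- cd[order(cd$start, -(cd$end - cd$start)), , drop = FALSE]
      pick <- cd[1, , drop = FALSE]
      sel[[length(sel) + 1L]] <- pick
      cd <- cd[!(cd$start < pick$end & cd$end > pick$start), ,
               drop = FALSE]
    }
    sd_ <- do.call(rbind, sel)
    sd_$surface <- sliceText(ft, sd_$start, sd_$end)
    sd_$entity_type <- entityType(lex)
    sd_$source <- "dictionary"
    out[[length(out) + 1L]] <-
      sd_[, c("start", "end", "surface", "entity_type", "norm_id",
              "source", "sentence")]
  }
  if (!length(out)) return(emptyMentionsDf())
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$entity_type), , drop = FALSE]
}

# independent candidate-pair oracle: full cross product of in-sentence
# mentions filtered by the schema, unordered
bruteForceCandidates <- function(doc, schema) {
  m <- mentions(doc)
  m <- m[!is.na(m$sentence), , drop = FALSE]
  keys <- character(0)
  if (nrow(m) >= 2L) {
    m$eid <- litkg:::entityKey(m$norm_id, m$surface)
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      if (m$sentence[i] != m$sentence[j]) next
      if (m$eid[i] == m$eid[j]) next
      hit <- which((schema$type_a == m$entity_type[i] &
                    schema$type_b == m$entity_type[j]) |
                   (schema$type_a == m$entity_type[j] &
                    schema$type_b == m$entity_type[i]))
      if (!length(hit)) next
      fam <- schema$family[hit[1]]
      ids <- sort(c(m$eid[i], m$eid[j]))
      keys <- c(keys, paste(m$sentence[i], fam, ids[1], ids[2]))
    }
  }
  sort(keys)
}

# random document built from tiny-lexicon surfaces and fillers,
# pre-annotated so the candidate oracle is exercised independently of NER
randomTaggedDoc <- function(pmid, lexicons = tinyLexicons()) {
  pool <- do.call(rbind, lapply(names(lexicons), function(tp) {
    e <- lexEntries(lexicons[[tp]])
    data.frame(name = e$preferred_name, id = e$canonical_id,
               type = tp, stringsAsFactors = FALSE)
  }))
  nSent <- sample(1:4, 1L)
  sents <- character(nSent)
  mrows <- list()
  offset <- nchar("Fixture title") + 1L
  for (si in seq_len(nSent)) {
    nEnt <- sample(0:4, 1L)
    picks <- if (nEnt) pool[sample(nrow(pool), nEnt, replace = TRUE), ,
                            drop = FALSE] else pool[0, ]
    words <- character(0)
    cursor <- offset
    first <- TRUE
    addWord <- function(w) {
      words <<- c(words, w)
      cursor <<- cursor + nchar(w) + 1L
    }
    addWord("Begin")
    if (nEnt) for (k in seq_len(nEnt)) {
      nf <- sample(0:2, 1L)
      if (nf) for (f in sample(fillerWords, nf)) addWord(f)
      start <- cursor
      addWord(picks$name[k])
      mrows[[length(mrows) + 1L]] <- data.frame(
        start = start, end = start + nchar(picks$name[k]),
        surface = picks$name[k], entity_type = picks$type[k],
        norm_id = picks$id[k], source = "preannotated",
        sentence = NA_integer_, stringsAsFactors = FALSE)
    }
    sent <- paste0(paste(words, collapse = " "), ".")
    sents[si] <- sent
    offset <- offset + nchar(sent) + 1L
  }
  m <- if (length(mrows)) do.call(rbind, mrows) else emptyMentionsDf()
  docFromSentences(pmid, sents, mentions = m)
}
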