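# Seedable synthetic-corpus generator: PubTator corpora with planted
# dictionary entities and planted relation keywords, plus gold mention
# and gold relation files, so every pipeline stage is testable offline.
#
# Templates are intentionally unambiguous — one trigger keyword per
# supporting sentence — so classifier failures indicate bugs, not
# linguistic ambiguity. Entity names are pronounceable CV-syllable
# nonsense screened against the rulebook's keyword stems.

#' Configuration for the synthetic generator
#'
#' @param nDocuments Number of abstracts.
#' @param sentencesPerDoc Length-2 integer range of target abstract
#'   sentence counts.
#' @param lexiconSizes Named integer vector (names from [entityTypes()]):
#'   entries per synthetic lexicon.
#' @param plantedRelations data.frame \code{type_a}, \code{type_b},
#'   \code{relation_type}, \code{n_sentences}: each row becomes one
#'   entity pair realized in that many supporting sentences.
#' @param distractorRate Fraction of padding (non-relation) sentences
#'   per document, in [0, 1].
#' @param keywordOmissionRate Probability a supporting sentence carries
#'   a neutral verb instead of its trigger keyword, in [0, 1].
#' @param surfaceVariantRate Probability an entity occurrence is
#'   realized as an orthographic variant (hyphen/space/case), in [0, 1].
#' @param seed Integer; fixed seed implies byte-identical output.
#' @return A list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nDocuments = 20L,
                        sentencesPerDoc = c(4L, 8L),
                        lexiconSizes = c(Disease = 6L, Symptom = 4L,
                                         Chemical = 5L, Drug = 5L,
                                         CPM = 5L, Herb = 6L,
                                         Ingredient = 4L, Gene = 5L,
                                         Pathway = 3L),
                        plantedRelations = defaultPlantedRelations(),
                        distractorRate = 0.3,
                        keywordOmissionRate = 0,
                        surfaceVariantRate = 0,
                        seed = 1L) {
  stopifnot(nDocuments >= 1L, length(sentencesPerDoc) == 2L,
            all(sentencesPerDoc >= 1L),
            all(names(lexiconSizes) %in% entityTypes()),
            all(c("type_a", "type_b", "relation_type", "n_sentences")
                %in% names(plantedRelations)))
  for (r in c(distractorRate, keywordOmissionRate, surfaceVariantRate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  structure(list(nDocuments = as.integer(nDocuments),
                 sentencesPerDoc = as.integer(sentencesPerDoc),
                 lexiconSizes = lexiconSizes,
                 plantedRelations = plantedRelations,
                 distractorRate = distractorRate,
                 keywordOmissionRate = keywordOmissionRate,
                 surfaceVariantRate = surfaceVariantRate,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Default planted relations for the synthetic generator
#'
#' Ten relations spanning all three rule groups, each with 3-5
#' supporting sentences so planted entities clear the default
#' frequency threshold of 3.
#'
#' @return data.frame \code{type_a}, \code{type_b},
#'   \code{relation_type}, \code{n_sentences}.
#' @export
defaultPlantedRelations <- function() {
  data.frame(
    type_a = c("Drug", "CPM", "Herb", "Chemical", "Drug",
               "CPM", "Herb", "Ingredient", "Disease", "Symptom"),
    type_b = c("Disease", "Disease", "Disease", "Symptom", "Symptom",
               "Herb", "Drug", "Chemical", "Gene", "Disease"),
    relation_type = c("Treatment", "Treatment", "Cause", "Cause",
                      "Treatment", "EntityOrigin", "Interaction",
                      "Mechanism", "PositiveAssociation",
                      "PositiveAssociation"),
    n_sentences = c(5L, 4L, 4L, 3L, 3L, 4L, 3L, 3L, 4L, 3L),
    stringsAsFactors = FALSE)
}

# stems that generated name tokens must avoid (keyword stems plus the
# template vocabulary)
forbiddenNameStems <- function(rulebook = defaultRuleBook()) {
  kwTokens <- unlist(strsplit(ruleTable(rulebook)$keyword, " ", fixed = TRUE))
  template <- c("accompanies", "the", "cohort", "was", "monitored",
                "routine", "observation", "continued", "without",
                "incident", "synthetic", "record", "in", "study")
  unique(lightStem(c(kwTokens, template)))
}

#' Generate synthetic per-type lexicons
#'
#' Names are CV-syllable strings, unique per type (and globally) after
#' normalization; CPM and Herb names are hyphenated multi-token forms
#' (CPMs may carry a "Decoction" suffix) to exercise normalization.
#'
#' @param config A [synthConfig()].
#' @param dir Optional directory: writes \code{lexicon_<type>.tsv}.
#' @return Named list of [Lexicon] objects.
#' @export
generateLexicons <- function(config, dir = NULL) {
  forbidden <- forbiddenNameStems()
  withLocalSeed(config$seed, {
    cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "p", "r",
              "s", "t", "v", "z")
    vows <- c("a", "e", "i", "o", "u")
    syll <- function() paste0(sample(cons, 1L), sample(vows, 1L))
    word <- function(nSyl) {
      paste(vapply(seq_len(nSyl), function(i) syll(), ""), collapse = "")
    }
    cap <- function(x) {
      paste0(toupper(substr(x, 1L, 1L)), substring(x, 2L))
    }
    # every token of every accepted name is reserved globally, so no
    # name can match inside another name of any type (keeps the
    # zero-noise gold unambiguous)
    seenTokens <- character(0)
    okName <- function(name) {
      toks <- tokenizeWithOffsets(normalizeSurface(name))$token
      toks <- setdiff(toks, "decoction")
      !any(toks %in% seenTokens) &&
        !any(lightStem(toks) %in% forbidden) &&
        !any(toks %in% c("and", "between", "no"))
    }
    draw <- function(maker) {
      for (i in 1:200) {
        name <- maker()
        if (okName(name)) {
          toks <- tokenizeWithOffsets(normalizeSurface(name))$token
          seenTokens <<- c(seenTokens, setdiff(toks, "decoction"))
          return(name)
        }
      }
      stop("could not generate a unique synthetic name; enlarge syllable space")
    }
    out <- list()
    for (type in names(config$lexiconSizes)) {
      n <- config$lexiconSizes[[type]]
      names_ <- character(n)
      for (i in seq_len(n)) {
        names_[i] <- if (type == "Herb") {
          draw(function() paste(cap(word(2L)), cap(word(2L)), sep = "-"))
        } else if (type == "CPM") {
          draw(function() {
            base <- paste(cap(word(2L)), cap(word(2L)), cap(word(2L)),
                          sep = "-")
            if (runif(1) < 0.5) paste(base, "Decoction") else base
          })
        } else {
          draw(function() cap(word(sample(2:3, 1L))))
        }
      }
      ids <- sprintf("%s:%04d", toupper(substr(type, 1L, 3L)), seq_len(n))
      entries <- data.frame(canonical_id = ids, preferred_name = names_,
                            stringsAsFactors = FALSE)
      surfaceRows <- data.frame(canonical_id = ids, raw = names_,
                                origin = "source", stringsAsFactors = FALSE)
      lex <- makeLexicon(type, entries, surfaceRows)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        writeLexicon(lex, file.path(dir, paste0("lexicon_", type, ".tsv")))
      }
      out[[type]] <- lex
    }
    out
  })
}

# realize one entity occurrence, optionally as an orthographic variant
realizeSurface <- function(name, variantRate) {
  if (variantRate > 0 && runif(1) < variantRate) {
    if (grepl("-", name, fixed = TRUE)) return(gsub("-", " ", name))
    if (grepl(" ", name, fixed = TRUE)) return(gsub(" ", "-", name))
    return(toupper(name))
  }
  name
}

#' Generate a synthetic PubTator corpus with gold annotations
#'
#' Each planted relation is realized as \code{n_sentences} sentences of
#' the form \code{"<EntityA> <keyword> <EntityB>."} with the keyword
#' drawn from the rulebook set of the planted type;
#' \code{keywordOmissionRate} replaces the keyword with a neutral verb
#' (yielding fallback-type evidence) and \code{surfaceVariantRate}
#' swaps a surface for an orthographic variant. Distractor sentences
#' contain at most one entity.
#'
#' @param config A [synthConfig()].
#' @param lexicons From [generateLexicons()] with the same config.
#' @param dir Optional output directory: writes \code{corpus.pubtator}
#'   (text only), \code{gold_mentions.pubtator} (with annotation
#'   lines), \code{gold_relations.tsv} and \code{config_echo.tsv}
#'   (records the seed).
#' @param rulebook,schema Rule set the keywords are drawn from.
#' @return list(\code{corpus} — Documents without mentions,
#'   \code{gold} — the same Documents with gold mentions,
#'   \code{goldMentions} — corpus-wide mention data.frame,
#'   \code{goldRelations} — data.frame \code{id_a}, \code{id_b},
#'   \code{family}, \code{relation_type}).
#' @export
generateCorpus <- function(config, lexicons, dir = NULL,
                           rulebook = defaultRuleBook(),
                           schema = defaultPairSchema()) {
  rules <- ruleTable(rulebook)
  pr <- config$plantedRelations
  famKey <- paste(schema$type_a, schema$type_b)
  withLocalSeed(config$seed + 1L, {
    # assign distinct entities per planted relation
    used <- lapply(lexicons, function(l) integer(0))
    pickEntity <- function(type) {
      e <- lexEntries(lexicons[[type]])
      free <- setdiff(seq_len(nrow(e)), used[[type]])
      if (!length(free)) stop(sprintf(
        "lexicon for %s too small for the planted relations", type))
      i <- if (length(free) == 1L) free else sample(free, 1L)
      used[[type]] <<- c(used[[type]], i)
      e[i, ]
    }
    planted <- list()   # per relation: entities, family, keywords
    for (k in seq_len(nrow(pr))) {
      hit <- match(paste(pr$type_a[k], pr$type_b[k]), famKey)
      swapped <- FALSE
      if (is.na(hit)) {
        hit <- match(paste(pr$type_b[k], pr$type_a[k]), famKey)
        swapped <- TRUE
      }
      if (is.na(hit)) stop(sprintf("no family for planted pair %s-%s",
                                   pr$type_a[k], pr$type_b[k]))
      grp <- schema$group[hit]
      kws <- rules$keyword[rules$group == grp &
                           rules$relation_type == pr$relation_type[k]]
      if (!length(kws)) stop(sprintf(
        "planted relation type %s has no keywords in group %s",
        pr$relation_type[k], grp))
      ta <- if (swapped) pr$type_b[k] else pr$type_a[k]
      tb <- if (swapped) pr$type_a[k] else pr$type_b[k]
      planted[[k]] <- list(
        entA = pickEntity(ta), typeA = ta,
        entB = pickEntity(tb), typeB = tb,
        family = schema$family[hit], relation_type = pr$relation_type[k],
        keywords = kws, n = pr$n_sentences[k])
    }
    # realize supporting sentences: list of (text, mention local offsets)
    supportSentences <- list()
    for (k in seq_along(planted)) {
      pl <- planted[[k]]
      for (s in seq_len(pl$n)) {
        kw <- if (runif(1) < config$keywordOmissionRate) {
          "accompanies"
        } else if (length(pl$keywords) == 1L) {
          pl$keywords
        } else {
          sample(pl$keywords, 1L)
        }
        sa <- realizeSurface(pl$entA$preferred_name,
                             config$surfaceVariantRate)
        sb <- realizeSurface(pl$entB$preferred_name,
                             config$surfaceVariantRate)
        text <- paste0(sa, " ", kw, " ", sb, ".")
        m <- data.frame(
          start = c(0L, nchar(sa) + nchar(kw) + 2L),
          end = c(nchar(sa), nchar(sa) + nchar(kw) + 2L + nchar(sb)),
          surface = c(sa, sb),
          entity_type = c(pl$typeA, pl$typeB),
          norm_id = c(pl$entA$canonical_id, pl$entB$canonical_id),
          stringsAsFactors = FALSE)
        supportSentences[[length(supportSentences) + 1L]] <-
          list(text = text, mentions = m)
      }
    }
    # distribute over documents, pad with distractors
    docAssign <- if (length(supportSentences)) {
      sample(config$nDocuments, length(supportSentences), replace = TRUE)
    } else integer(0)
    allEntries <- do.call(rbind, lapply(names(lexicons), function(tp) {
      e <- lexEntries(lexicons[[tp]])
      if (!nrow(e)) return(NULL)
      cbind(e, entity_type = tp, stringsAsFactors = FALSE)
    }))
    makeDistractor <- function() {
      if (!is.null(allEntries) && nrow(allEntries) && runif(1) < 0.5) {
        i <- sample(nrow(allEntries), 1L)
        sf <- realizeSurface(allEntries$preferred_name[i],
                             config$surfaceVariantRate)
        list(text = paste0("The ", sf, " cohort was monitored."),
             mentions = data.frame(
               start = 4L, end = 4L + nchar(sf), surface = sf,
               entity_type = allEntries$entity_type[i],
               norm_id = allEntries$canonical_id[i],
               stringsAsFactors = FALSE))
      } else {
        list(text = "Routine observation continued without incident.",
             mentions = NULL)
      }
    }
    docs <- vector("list", config$nDocuments)
    goldDocs <- vector("list", config$nDocuments)
    goldMentionRows <- list()
    for (d in seq_len(config$nDocuments)) {
      sents <- supportSentences[docAssign == d]
      target <- sample(seq(config$sentencesPerDoc[1],
                           config$sentencesPerDoc[2]), 1L)
      nDis <- round(config$distractorRate * target)
      if (length(sents) + nDis == 0L) nDis <- 1L
      for (j in seq_len(nDis)) {
        sents[[length(sents) + 1L]] <- makeDistractor()
      }
      if (length(sents) > 1L) sents <- sents[sample(length(sents))]
      pm <- sprintf("9%06d", d)
      title <- sprintf("Synthetic record %s", pm)
      texts <- vapply(sents, function(s) s$text, "")
      abstract <- paste(texts, collapse = " ")
      offsets <- nchar(title) + 1L +
        c(0L, cumsum(nchar(texts) + 1L)[-length(texts)])
      mrows <- list()
      for (j in seq_along(sents)) {
        mm <- sents[[j]]$mentions
        if (is.null(mm)) next
        mm$start <- mm$start + offsets[j]
        mm$end <- mm$end + offsets[j]
        mrows[[length(mrows) + 1L]] <- mm
      }
      m <- if (length(mrows)) do.call(rbind, mrows) else NULL
      docs[[d]] <- Document(pm, title, abstract)
      if (!is.null(m)) {
        m$source <- "preannotated"
        m$sentence <- NA_integer_
        goldDocs[[d]] <- Document(pm, title, abstract, mentions = m)
        goldMentionRows[[d]] <- cbind(pmid = pm,
                                      normalizeMentionFrame(m),
                                      stringsAsFactors = FALSE)
      } else {
        goldDocs[[d]] <- docs[[d]]
      }
    }
    goldMentions <- if (length(goldMentionRows)) {
      gm <- do.call(rbind, goldMentionRows[!vapply(goldMentionRows,
                                                   is.null, TRUE)])
      rownames(gm) <- NULL
      gm
    } else {
      cbind(pmid = character(0), emptyMentions())
    }
    goldRelations <- if (length(planted)) {
      do.call(rbind, lapply(planted, function(pl) {
        data.frame(id_a = pl$entA$canonical_id,
                   id_b = pl$entB$canonical_id, family = pl$family,
                   relation_type = pl$relation_type,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(id_a = character(0), id_b = character(0),
                 family = character(0), relation_type = character(0),
                 stringsAsFactors = FALSE)
    }
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writePubTator(docs, file.path(dir, "corpus.pubtator"))
      writePubTator(goldDocs, file.path(dir, "gold_mentions.pubtator"))
      relLines <- c(sprintf("# seed=%d", config$seed),
                    "id_a\tid_b\tfamily\trelation_type",
                    sprintf("%s\t%s\t%s\t%s", goldRelations$id_a,
                            goldRelations$id_b, goldRelations$family,
                            goldRelations$relation_type))
      writeLines(relLines, file.path(dir, "gold_relations.tsv"))
      echo <- c(sprintf("seed\t%d", config$seed),
                sprintf("n_documents\t%d", config$nDocuments),
                sprintf("distractor_rate\t%g", config$distractorRate),
                sprintf("keyword_omission_rate\t%g",
                        config$keywordOmissionRate),
                sprintf("surface_variant_rate\t%g",
                        config$surfaceVariantRate))
      writeLines(echo, file.path(dir, "config_echo.tsv"))
    }
    list(corpus = docs, gold = goldDocs, goldMentions = goldMentions,
         goldRelations = goldRelations)
  })
}

#' Corrupt gold mentions into noisy predictions
#'
#' Removes each gold mention with probability \code{fnRate} and injects
#' spurious mentions (which can never match gold in either scoring
#' mode) at rate \code{fpRate} per gold mention, so expected
#' precision/recall are analytically known: E[recall] = 1 - fnRate.
#'
#' @param goldMentions Corpus-wide mention data.frame (with
#'   \code{pmid}).
#' @param fpRate,fnRate Rates in [0, 1].
#' @param seed Integer seed.
#' @return A predicted-mention data.frame of the same shape.
#' @export
corruptForEval <- function(goldMentions, fpRate = 0, fnRate = 0,
                           seed = 1L) {
  stopifnot(fpRate >= 0, fpRate <= 1, fnRate >= 0, fnRate <= 1)
  withLocalSeed(seed, {
    n <- nrow(goldMentions)
    keep <- if (n) runif(n) >= fnRate else logical(0)
    pred <- goldMentions[keep, , drop = FALSE]
    nSp <- if (n) rbinom(1L, n, fpRate) else 0L
    if (nSp > 0L) {
      pmids <- if (n) sample(goldMentions$pmid, nSp, replace = TRUE)
               else rep("1", nSp)
      sp <- data.frame(
        pmid = pmids,
        start = 1000000L + seq_len(nSp) * 10L,
        end = 1000000L + seq_len(nSp) * 10L + 7L,
        surface = "spurious",
        entity_type = sample(entityTypes(), nSp, replace = TRUE),
        norm_id = sprintf("FAKE:%06d", seq_len(nSp)),
        source = "dictionary", sentence = NA_integer_,
        stringsAsFactors = FALSE)
      sp <- sp[, intersect(names(goldMentions), names(sp)), drop = FALSE]
      pred <- rbind(pred[, names(sp), drop = FALSE], sp)
    }
    rownames(pred) <- NULL
    pred
  })
}
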