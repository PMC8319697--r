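# Entity dictionaries for dictionary-based NER.
#
# Source format, one file per entity type, UTF-8 TSV:
#   canonical_id <TAB> preferred_name <TAB> syn1|syn2|...
# (the synonym column may be absent). Matching is over normalized token
# sequences, never raw characters, so "Huang-Lian" and "huang lian"
# share one key and substring hits inside words are impossible.

#' Normalize a surface form into its matching key
#'
#' Case-folds, maps hyphens and underscores to single spaces, collapses
#' whitespace runs and strips leading/trailing whitespace. Idempotent.
#'
#' @param text Character vector.
#' @return Normalized keys, same length.
#' @examples
#' normalizeSurface("Huang-Lian")        # "huang lian"
#' normalizeSurface("  Buyang   Huanwu") # "buyang huanwu"
#' @export
normalizeSurface <- function(text) {
  x <- tolower(text)
  x <- gsub("[-_]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Expand deterministic surface variants
#'
#' Adds (never removes) orthographic variants of each surface:
#' hyphen/space alternation, and "decoction"/"tang" suffix alternation
#' when the surface ends in either token. Romanization equivalence
#' (e.g. Hwangryun vs Huanglian) is deliberately not attempted: no
#' defensible rule set exists for it.
#'
#' @param surfaces Character vector of raw surface forms.
#' @return Character vector: a superset of \code{surfaces}.
#' @examples
#' expandVariants("Huanglian-Jie-Du-Tang")
#' @export
expandVariants <- function(surfaces) {
  out <- surfaces
  for (s in surfaces) {
    if (grepl("-", s, fixed = TRUE)) out <- c(out, gsub("-", " ", s))
    if (grepl(" ", s, fixed = TRUE)) out <- c(out, gsub(" ", "-", s))
    key <- normalizeSurface(s)
    if (grepl("(^| )decoction$", key)) {
      out <- c(out, sub("decoction$", "tang", key))
    } else if (grepl("(^| )tang$", key)) {
      out <- c(out, sub("tang$", "decoction", key))
    }
  }
  unique(out)
}

# internal constructor shared by loadLexicon() and the synthetic generator
makeLexicon <- function(entityType, entries, surfaceRows) {
  # surfaceRows: data.frame(canonical_id, raw, origin)
  s <- surfaceRows
  s$key <- normalizeSurface(s$raw)
  s <- s[nzchar(s$key), , drop = FALSE]
  s <- unique(s[, c("key", "raw", "canonical_id", "origin")])
  # resolve key collisions: source forms win over generated variants;
  # variants that still collide across entries are dropped
  dupKeys <- unique(s$key[duplicated(s$key)])
  for (k in dupKeys) {
    rows <- which(s$key == k)
    ids <- unique(s$canonical_id[rows])
    if (length(ids) == 1L) next
    src <- rows[s$origin[rows] == "source"]
    if (length(unique(s$canonical_id[src])) > 1L) {
      stop(sprintf(
        "ambiguous surface '%s' in %s lexicon maps to multiple ids: %s",
        k, entityType, paste(unique(s$canonical_id[src]), collapse = ", ")))
    }
    drop <- rows[s$origin[rows] == "variant"]
    if (length(src)) {
      keepId <- s$canonical_id[src[1]]
      drop <- drop[s$canonical_id[drop] != keepId]
    } else {
      # variants only, from different entries: all dropped
    }
    if (length(drop)) s <- s[-drop, , drop = FALSE]
    s <- s[nzchar(s$key), , drop = FALSE]
  }
  rownames(s) <- NULL
  maxTok <- if (nrow(s)) {
    max(lengths(strsplit(s$key, " ", fixed = TRUE)))
  } else 0L
  new("Lexicon", entityType = entityType, entries = entries,
      surfaces = s, maxTokens = as.integer(maxTok))
}

#' Load an entity lexicon from TSV
#'
#' @param file Path, connection, or character vector of TSV lines
#'   (\code{canonical_id<TAB>preferred_name<TAB>syn1|syn2|...}).
#' @param entityType One of [entityTypes()].
#' @param expand Apply [expandVariants()] to every entry's surfaces.
#' @return A compiled [Lexicon]. Duplicate canonical ids and surfaces
#'   shared by two entries (ambiguity) are load-time errors.
#' @examples
#' lex <- loadLexicon(
#'   "CPM:001\tBuyang Huanwu Decoction\tBUYANGHUANWU DECOCTION", "CPM")
#' lexSurfaces(lex)
#' @export
loadLexicon <- function(file, entityType, expand = FALSE) {
  stopifnot(entityType %in% entityTypes())
  lines <- if (is.character(file) &&
               (length(file) != 1L || grepl("\t", file))) {
    file
  } else {
    readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(makeLexicon(entityType,
      data.frame(canonical_id = character(0), preferred_name = character(0),
                 stringsAsFactors = FALSE),
      data.frame(canonical_id = character(0), raw = character(0),
                 origin = character(0), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 2L
  if (any(short)) {
    stop(sprintf("lexicon line %d needs at least 2 tab-separated fields",
                 which(short)[1]))
  }
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate canonical_id in lexicon: %s",
                 ids[duplicated(ids)][1]))
  }
  entries <- data.frame(canonical_id = ids,
                        preferred_name = vapply(fields, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  rowsList <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    surfs <- f[2L]
    if (length(f) >= 3L && nzchar(f[3L])) {
      surfs <- c(surfs, strsplit(f[3L], "|", fixed = TRUE)[[1]])
    }
    surfs <- unique(surfs[nzchar(surfs)])
    origin <- rep("source", length(surfs))
    if (expand) {
      ex <- setdiff(expandVariants(surfs), surfs)
      surfs <- c(surfs, ex)
      origin <- c(origin, rep("variant", length(ex)))
    }
    data.frame(canonical_id = ids[i], raw = surfs, origin = origin,
               stringsAsFactors = FALSE)
  })
  makeLexicon(entityType, entries, do.call(rbind, rowsList))
}

#' Write a lexicon back to its TSV source format
#'
#' Only source surfaces are written (generated variants are
#' reconstructible).
#'
#' @param lexicon A [Lexicon].
#' @param file Path or connection.
#' @return Invisibly, the lines written.
#' @export
writeLexicon <- function(lexicon, file = NULL) {
  e <- lexEntries(lexicon)
  s <- lexSurfaces(lexicon)
  s <- s[s$origin == "source", , drop = FALSE]
  lines <- vapply(seq_len(nrow(e)), function(i) {
    raws <- s$raw[s$canonical_id == e$canonical_id[i]]
    syns <- setdiff(raws, e$preferred_name[i])
    paste(e$canonical_id[i], e$preferred_name[i],
          paste(syns, collapse = "|"), sep = "\t")
  }, "")
  if (!is.null(file)) writeLines(lines, file, useBytes = FALSE)
  invisible(lines)
}

# fast lookup table: normalized key -> canonical_id
surfaceMap <- function(lexicon) {
  s <- lexSurfaces(lexicon)
  u <- unique(s[, c("key", "canonical_id")])
  setNames(u$canonical_id, u$key)
}
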