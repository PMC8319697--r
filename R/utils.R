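# Internal text utilities: tokenization with character offsets and a light
# rule stemmer. Both keyword lists and sentence tokens pass through the same
# stemmer, so only stem-class agreement matters, not linguistic correctness.

#' Tokenize text with character offsets
#'
#' Tokens are maximal runs of ASCII letters and digits; hyphens, underscores
#' and all other punctuation act as separators (so \code{"Huang-Lian"}
#' yields two tokens). Offsets are 0-based half-open into \code{text}.
#'
#' @param text A single string.
#' @return A data.frame with columns \code{token}, \code{start}, \code{end}.
#' @examples
#' tokenizeWithOffsets("Aspirin reduces stroke risk.")
#' @export
tokenizeWithOffsets <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Light rule stemmer
#'
#' Conflates common English inflection: \code{-ies} to \code{-y}, then
#' strips \code{-ing}, \code{-ed}, plural \code{-s} (never \code{-ss}),
#' and finally a trailing \code{-e}. Short tokens are left alone. The
#' stemmer is deliberately aggressive ("cause", "causes", "caused" all
#' stem to \code{caus}); it is applied identically to rulebook keywords
#' and sentence tokens.
#'
#' @param tokens Character vector.
#' @return Character vector of stems, lower-cased.
#' @examples
#' lightStem(c("treating", "causes", "therapies", "interaction"))
#' @export
lightStem <- function(tokens) {
  x <- tolower(tokens)
  n <- nchar(x)
  i <- n > 4L & endsWith(x, "ies")
  x[i] <- sub("ies$", "y", x[i])
  n <- nchar(x)
  j <- !i & n > 5L & endsWith(x, "ing")
  x[j] <- sub("ing$", "", x[j])
  n <- nchar(x)
  k <- !i & !j & n > 4L & endsWith(x, "ed")
  x[k] <- sub("ed$", "", x[k])
  n <- nchar(x)
  l <- !i & !j & !k & n > 3L & endsWith(x, "s") & !endsWith(x, "ss")
  x[l] <- sub("s$", "", x[l])
  n <- nchar(x)
  e <- n > 3L & endsWith(x, "e")
  x[e] <- sub("e$", "", x[e])
  x
}

# stem a multi-word phrase into a single space-joined stem key
stemPhrase <- function(phrase) {
  toks <- tokenizeWithOffsets(phrase)$token
  paste(lightStem(toks), collapse = " ")
}

# run code with a local, restored RNG state seeded deterministically
withLocalSeed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# slice full_text by a 0-based half-open span
sliceText <- function(text, start, end) {
  substring(text, start + 1L, end)
}

emptyMentions <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             entity_type = character(0), norm_id = character(0),
             source = character(0), sentence = integer(0),
             stringsAsFactors = FALSE)
}

emptySentences <- function() {
  data.frame(start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}
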