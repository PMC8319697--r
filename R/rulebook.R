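# The entity-pair schema (which ordered type pairs form relation
# candidates, and which keyword-rule group applies to each family) and
# the default rulebook (trigger keywords per relation type).
#
# Three rule groups cover all families:
#   tc    — Treatment / Cause / Other        (substance vs disease/symptom)
#   ddi   — Advise / Interaction / Effect / Mechanism / Negative /
#           EntityOrigin / Other             (substance vs substance)
#   assoc — PositiveAssociation / NegativeAssociation / Other
#           (gene, pathway and symptom-disease associations)
#
# The high-noise keywords "and", "between" and "no" only fire when they
# occur between the two entity spans.

#' The default entity-pair schema
#'
#' The 31 allowed ordered type-pair families, each mapped to its keyword
#' rule group. Unordered pairs are looked up and canonically re-ordered
#' to the family's (type_a, type_b) order.
#'
#' @return data.frame \code{type_a}, \code{type_b}, \code{family},
#'   \code{group}.
#' @examples
#' head(defaultPairSchema())
#' @export
defaultPairSchema <- function() {
  pairRows <- function(pairs, group) {
    data.frame(type_a = vapply(pairs, `[`, "", 1L),
               type_b = vapply(pairs, `[`, "", 2L),
               group = group, stringsAsFactors = FALSE)
  }
  tc <- list(c("CPM", "Disease"), c("CPM", "Symptom"),
             c("Herb", "Disease"), c("Herb", "Symptom"),
             c("Drug", "Disease"), c("Drug", "Symptom"),
             c("Chemical", "Disease"), c("Chemical", "Symptom"),
             c("Ingredient", "Disease"), c("Ingredient", "Symptom"))
  ddi <- list(c("CPM", "Herb"), c("CPM", "Ingredient"), c("CPM", "Drug"),
              c("CPM", "Chemical"), c("Herb", "Ingredient"),
              c("Herb", "Drug"), c("Herb", "Chemical"),
              c("Ingredient", "Drug"), c("Ingredient", "Chemical"),
              c("Drug", "Chemical"))
  assoc <- list(c("CPM", "Pathway"), c("CPM", "Gene"),
                c("Herb", "Pathway"), c("Herb", "Gene"),
                c("Ingredient", "Pathway"), c("Drug", "Pathway"),
                c("Drug", "Gene"), c("Chemical", "Pathway"),
                c("Symptom", "Disease"), c("Symptom", "Pathway"),
                c("Disease", "Gene"))
  schema <- rbind(pairRows(tc, "tc"), pairRows(ddi, "ddi"),
                  pairRows(assoc, "assoc"))
  schema$family <- paste(schema$type_a, schema$type_b, sep = "-")
  schema[, c("type_a", "type_b", "family", "group")]
}

#' The default relation rulebook
#'
#' Trigger keywords per relation type, in priority order within each
#' rule group (first matching type wins). Each group's fallback type
#' (\code{Other}) has no keywords. Matching mode is \code{"stem"}:
#' keywords and sentence tokens are both passed through [lightStem()].
#'
#' @return A [RuleBook].
#' @examples
#' defaultRuleBook()
#' @export
defaultRuleBook <- function() {
  kw <- function(group, type, priority, keywords, between = FALSE) {
    data.frame(group = group, relation_type = type, priority = priority,
               keyword = keywords,
               between_only = keywords %in% c("and", "between", "no"),
               stringsAsFactors = FALSE)
  }
  rules <- rbind(
    kw("tc", "Treatment", 1L,
       c("therapy", "treating", "cure", "remedy", "inhibit")),
    kw("tc", "Cause", 2L,
       c("induce", "cause", "side effect", "influence", "dynamic")),
    kw("ddi", "Advise", 1L, c("avoid", "should not be")),
    kw("ddi", "Interaction", 2L, c("interaction", "and", "between")),
    kw("ddi", "Effect", 3L, c("enhance", "against", "demonstrated")),
    kw("ddi", "Mechanism", 4L, c("metabolize", "decrease", "increase")),
    kw("ddi", "Negative", 5L, c("no")),
    kw("ddi", "EntityOrigin", 6L, c("include", "contain")),
    kw("assoc", "PositiveAssociation", 1L, c("effect", "induce", "target")),
    kw("assoc", "NegativeAssociation", 2L, c("indifference", "no")))
  fallbacks <- data.frame(group = c("tc", "ddi", "assoc"),
                          relation_type = "Other", stringsAsFactors = FALSE)
  new("RuleBook", rules = rules, fallbacks = fallbacks, mode = "stem")
}

#' Read a rulebook from its TSV serialization
#'
#' One row per keyword: \code{group<TAB>relation_type<TAB>priority<TAB>}
#' \code{keyword<TAB>between_only}; fallback rows carry an empty keyword.
#' A final \code{#mode:} comment records the matching mode.
#'
#' @param file Path, connection or character vector of lines.
#' @return A [RuleBook].
#' @export
readRuleBook <- function(file) {
  lines <- if (is.character(file) && length(file) != 1L) file
           else readLines(file, encoding = "UTF-8", warn = FALSE)
  mode <- "stem"
  modeLn <- grep("^#mode:", lines, value = TRUE)
  if (length(modeLn)) mode <- trimws(sub("^#mode:", "", modeLn[1]))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else "", "")
  df <- data.frame(group = get(1L), relation_type = get(2L),
                   priority = as.integer(get(3L)), keyword = get(4L),
                   between_only = get(5L) == "TRUE",
                   stringsAsFactors = FALSE)
  fb <- unique(df[!nzchar(df$keyword), c("group", "relation_type")])
  rules <- df[nzchar(df$keyword), , drop = FALSE]
  rownames(rules) <- rownames(fb) <- NULL
  new("RuleBook", rules = rules, fallbacks = fb, mode = mode)
}

#' @rdname readRuleBook
#' @param rulebook A [RuleBook].
#' @return For \code{writeRuleBook}, invisibly the lines written.
#' @export
writeRuleBook <- function(rulebook, file = NULL) {
  r <- ruleTable(rulebook)
  fb <- rulebook@fallbacks
  lines <- c(
    sprintf("%s\t%s\t%d\t%s\t%s", r$group, r$relation_type, r$priority,
            r$keyword, r$between_only),
    sprintf("%s\t%s\t%d\t\t", fb$group, fb$relation_type,
            max(c(r$priority, 0L)) + 1L),
    paste0("#mode: ", rulebook@mode))
  if (!is.null(file)) writeLines(lines, file, useBytes = FALSE)
  invisible(lines)
}

#' Relation types applicable to a rule group
#' @param rulebook A [RuleBook].
#' @param group Group id (e.g. \code{"tc"}).
#' @return Character vector of relation types, fallback last.
#' @export
groupTypes <- function(rulebook, group) {
  r <- ruleTable(rulebook)
  r <- r[r$group == group, , drop = FALSE]
  typed <- unique(r$relation_type[order(r$priority)])
  fb <- rulebook@fallbacks
  c(typed, fb$relation_type[fb$group == group])
}
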