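#' Run the full mining pipeline on a corpus
#'
#' Convenience wrapper chaining sentence splitting, dictionary NER, the
#' entity-frequency filter, relation extraction, confidence aggregation
#' and graph assembly.
#'
#' @param corpus List of [Document] objects (raw or sentence-split).
#' @param lexicons List of [Lexicon] objects.
#' @param config A [nerConfig()].
#' @param schema,rulebook See [defaultPairSchema()], [defaultRuleBook()].
#' @param minSupport,confidenceThreshold See [aggregateRelations()].
#' @param whitelist Entity ids exempt from the frequency filter.
#' @param plugin Optional fallback classifier, see [extractRelations()].
#' @return list(\code{corpus} — tagged and filtered documents,
#'   \code{census}, \code{review}, \code{evidences}, \code{relations},
#'   \code{graph}, \code{stats}).
#' @examples
#' cfg <- synthConfig(nDocuments = 6, seed = 7)
#' lex <- generateLexicons(cfg)
#' syn <- generateCorpus(cfg, lex)
#' res <- runPipeline(syn$corpus, lex, config = nerConfig(minEntityCount = 1),
#'                    minSupport = 1)
#' res$graph
#' @export
runPipeline <- function(corpus, lexicons, config = nerConfig(),
                        schema = defaultPairSchema(),
                        rulebook = defaultRuleBook(),
                        minSupport = 2L, confidenceThreshold = 0.5,
                        whitelist = character(0), plugin = NULL) {
  split_ <- lapply(corpus, function(d) {
    if (nrow(sentences(d))) d else splitSentences(d)
  })
  tagged <- tagCorpus(split_, lexicons, config)
  census <- buildCensus(tagged)
  filt <- applyFrequencyFilter(tagged, census, config, whitelist)
  evidences <- extractRelations(filt$corpus, schema, rulebook, plugin)
  relations <- aggregateRelations(evidences, minSupport,
                                  confidenceThreshold)
  keptCensus <- buildCensus(filt$corpus)
  graph <- buildGraph(keptCensus, relations, lexicons)
  list(corpus = filt$corpus, census = census, review = filt$review,
       evidences = evidences, relations = relations, graph = graph,
       stats = graphStats(graph))
}
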