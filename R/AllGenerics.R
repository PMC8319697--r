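# Accessor generics and show methods. Slots are never accessed with @ in
# user code; these accessors are the supported surface.

#' @rdname Document-class
#' @param object,x a Document (or other litkg object as documented).
#' @export
setGeneric("pmid", function(x) standardGeneric("pmid"))
#' @rdname Document-class
#' @export
setMethod("pmid", "Document", function(x) x@pmid)

#' @rdname Document-class
#' @export
setGeneric("fullText", function(x) standardGeneric("fullText"))
#' @rdname Document-class
#' @export
setMethod("fullText", "Document",
          function(x) paste(x@title, x@abstract, sep = " "))

#' @rdname Document-class
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))
#' @rdname Document-class
#' @export
setMethod("sentences", "Document", function(x) x@sentences)

#' @rdname Document-class
#' @export
setGeneric("mentions", function(x) standardGeneric("mentions"))
#' @rdname Document-class
#' @export
setMethod("mentions", "Document", function(x) x@mentions)

#' @rdname Document-class
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))
#' @rdname Document-class
#' @export
setMethod("diagnostics", "Document", function(x) x@diagnostics)

#' @rdname Document-class
#' @export
setMethod("show", "Document", function(object) {
  cat(sprintf("Document pmid=%s | %d sentence(s), %d mention(s)\n",
              object@pmid, nrow(object@sentences), nrow(object@mentions)))
  cat(sprintf("  title: %s\n", substr(object@title, 1, 60)))
  invisible(NULL)
})

#' @rdname Lexicon-class
#' @param x,object a Lexicon.
#' @export
setGeneric("entityType", function(x) standardGeneric("entityType"))
#' @rdname Lexicon-class
#' @export
setMethod("entityType", "Lexicon", function(x) x@entityType)

#' @rdname Lexicon-class
#' @export
setGeneric("lexEntries", function(x) standardGeneric("lexEntries"))
#' @rdname Lexicon-class
#' @export
setMethod("lexEntries", "Lexicon", function(x) x@entries)

#' @rdname Lexicon-class
#' @export
setGeneric("lexSurfaces", function(x) standardGeneric("lexSurfaces"))
#' @rdname Lexicon-class
#' @export
setMethod("lexSurfaces", "Lexicon", function(x) x@surfaces)

#' @rdname Lexicon-class
#' @export
setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon<%s>: %d entries, %d surface keys (max %d tokens)\n",
              object@entityType, nrow(object@entries),
              nrow(object@surfaces), object@maxTokens))
  invisible(NULL)
})

#' @rdname RuleBook-class
#' @param x,object a RuleBook.
#' @export
setGeneric("ruleTable", function(x) standardGeneric("ruleTable"))
#' @rdname RuleBook-class
#' @export
setMethod("ruleTable", "RuleBook", function(x) x@rules)

#' @rdname RuleBook-class
#' @export
setGeneric("fallbackTypes", function(x) standardGeneric("fallbackTypes"))
#' @rdname RuleBook-class
#' @export
setMethod("fallbackTypes", "RuleBook",
          function(x) setNames(x@fallbacks$relation_type, x@fallbacks$group))

#' @rdname RuleBook-class
#' @export
setMethod("show", "RuleBook", function(object) {
  cat(sprintf("RuleBook (%s matching): %d keywords, %d relation types, %d groups\n",
              object@mode, nrow(object@rules),
              length(unique(c(object@rules$relation_type,
                              object@fallbacks$relation_type))),
              nrow(object@fallbacks)))
  invisible(NULL)
})

#' @rdname KnowledgeGraph-class
#' @param x,object a KnowledgeGraph.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname KnowledgeGraph-class
#' @export
setMethod("nodes", "KnowledgeGraph", function(x) x@nodes)

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname KnowledgeGraph-class
#' @export
setMethod("edges", "KnowledgeGraph", function(x) x@edges)

#' @rdname KnowledgeGraph-class
#' @export
setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf("KnowledgeGraph: %d nodes (%d types), %d edges (%d relation types)\n",
              nrow(object@nodes), length(unique(object@nodes$entity_type)),
              nrow(object@edges), length(unique(object@edges$relation_type))))
  invisible(NULL)
})

#' @rdname ConfusionMatrix-class
#' @param x,object a ConfusionMatrix.
#' @export
setGeneric("cmCounts", function(x) standardGeneric("cmCounts"))
#' @rdname ConfusionMatrix-class
#' @export
setMethod("cmCounts", "ConfusionMatrix", function(x) x@counts)

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("cmLabels", function(x) standardGeneric("cmLabels"))
#' @rdname ConfusionMatrix-class
#' @export
setMethod("cmLabels", "ConfusionMatrix", function(x) x@labels)

#' Total overlapped relationships (grand total of the matrix)
#' @rdname ConfusionMatrix-class
#' @export
setGeneric("overlappedRelationships",
           function(x) standardGeneric("overlappedRelationships"))
#' @rdname ConfusionMatrix-class
#' @export
setMethod("overlappedRelationships", "ConfusionMatrix",
          function(x) sum(x@counts))

#' Correctly classified relationships (diagonal sum)
#' @rdname ConfusionMatrix-class
#' @export
setGeneric("correctClassifications",
           function(x) standardGeneric("correctClassifications"))
#' @rdname ConfusionMatrix-class
#' @export
setMethod("correctClassifications", "ConfusionMatrix",
          function(x) sum(diag(x@counts)))

#' @rdname ConfusionMatrix-class
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d labels, %d overlapped, %d correct\n",
              length(object@labels), sum(object@counts),
              sum(diag(object@counts))))
  if (length(object@counts)) print(object@counts)
  invisible(NULL)
})

#' @rdname EvalReport-class
#' @param x,object an EvalReport.
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))
#' @rdname EvalReport-class
#' @export
setMethod("precision", "EvalReport", function(x) x@precision)

#' @rdname EvalReport-class
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))
#' @rdname EvalReport-class
#' @export
setMethod("recall", "EvalReport", function(x) x@recall)

#' @rdname EvalReport-class
#' @export
setGeneric("f1", function(x) standardGeneric("f1"))
#' @rdname EvalReport-class
#' @export
setMethod("f1", "EvalReport", function(x) x@f1)

#' @rdname EvalReport-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname EvalReport-class
#' @export
setMethod("counts", "EvalReport",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn))

#' @rdname EvalReport-class
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s): TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              object@matchMode, object@tp, object@fp, object@fn,
              object@precision, object@recall, object@f1))
  invisible(NULL)
})
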