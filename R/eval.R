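# Evaluation arithmetic: NER precision/recall/F1 against gold spans,
# relation confusion matrices against a reference set, and the correct
# rate (correctly classified relationships / overlapped relationships).
#
# Conventions: zero-denominator precision/recall/F1 report 0; a correct
# rate over zero overlapped pairs is reported as NA (not applicable).
# Percent reporting is two decimals with round-half-even; the sources
# this is compared against mix rounding and truncation, so comparisons
# at the printed precision should allow +/- 0.01.

safeDiv <- function(num, den) if (den == 0) 0 else num / den

#' Score NER predictions against gold mentions
#'
#' \code{strict_span} matches on identical (pmid, start, end,
#' entity_type); \code{id_only} on identical (pmid, norm_id,
#' entity_type). Matching is multiset-aware: duplicated keys pair up at
#' most once each.
#'
#' @param predicted,gold Mention data.frames with columns \code{pmid},
#'   \code{start}, \code{end}, \code{entity_type}, \code{norm_id}
#'   (e.g. from [corpusMentions()]-style tables or gold PubTator files).
#' @param matchMode \code{"strict_span"} or \code{"id_only"}.
#' @return An [EvalReport].
#' @export
scoreNer <- function(predicted, gold,
                     matchMode = c("strict_span", "id_only")) {
  matchMode <- match.arg(matchMode)
  keyOf <- function(m) {
    if (matchMode == "strict_span") {
      paste(m$pmid, m$start, m$end, m$entity_type, sep = "\r")
    } else {
      paste(m$pmid, m$norm_id, m$entity_type, sep = "\r")
    }
  }
  pk <- table(keyOf(predicted))
  gk <- table(keyOf(gold))
  common <- intersect(names(pk), names(gk))
  tp <- if (length(common)) {
    sum(pmin(as.integer(pk[common]), as.integer(gk[common])))
  } else 0L
  fp <- nrow(predicted) - tp
  fn <- nrow(gold) - tp
  p <- safeDiv(tp, tp + fp)
  r <- safeDiv(tp, tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  new("EvalReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), precision = p, recall = r, f1 = f,
      matchMode = matchMode)
}

#' Build a relation confusion matrix against a reference set
#'
#' Both sides are keyed by the unordered entity pair within a family;
#' only pairs present on both sides ("overlapped relationships") enter
#' the matrix, tallied by (predicted type, reference type). Duplicate
#' keys on either side keep their first row.
#'
#' @param predicted,reference data.frames with columns \code{id_a},
#'   \code{id_b}, \code{family}, \code{relation_type}.
#' @return A [ConfusionMatrix] (possibly 0x0 when the pair sets are
#'   disjoint).
#' @export
scoreRelations <- function(predicted, reference) {
  keyOf <- function(d) paste(pmin(d$id_a, d$id_b), pmax(d$id_a, d$id_b),
                             d$family, sep = "\r")
  p <- predicted[!duplicated(keyOf(predicted)), , drop = FALSE]
  r <- reference[!duplicated(keyOf(reference)), , drop = FALSE]
  pk <- keyOf(p); rk <- keyOf(r)
  common <- intersect(pk, rk)
  if (!length(common)) {
    return(new("ConfusionMatrix", labels = character(0),
               counts = matrix(integer(0), 0, 0)))
  }
  pt <- p$relation_type[match(common, pk)]
  rt <- r$relation_type[match(common, rk)]
  labels <- sort(unique(c(pt, rt)))
  counts <- table(factor(pt, levels = labels), factor(rt, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(predicted = labels, reference = labels))
  new("ConfusionMatrix", labels = labels, counts = counts)
}

#' The correct rate of relation classification
#'
#' Correctly classified relationships (diagonal sum) divided by
#' overlapped relationships (grand total).
#'
#' @param cm A [ConfusionMatrix].
#' @param percent When TRUE, return a two-decimal percentage
#'   (round-half-even); otherwise the raw fraction.
#' @return The correct rate, or \code{NA} when no pairs overlap.
#' @examples
#' cm <- confusionMatrix(matrix(c(9, 1, 0, 10), 2, 2,
#'                              dimnames = list(c("A", "B"), c("A", "B"))))
#' correctRate(cm)
#' @export
correctRate <- function(cm, percent = FALSE) {
  total <- overlappedRelationships(cm)
  if (total == 0) {
    message("correct rate not applicable: no overlapped relationships")
    return(NA_real_)
  }
  cr <- correctClassifications(cm) / total
  if (percent) round(100 * cr, 2) else cr
}

#' Harmonic-mean F1 from precision and recall
#'
#' Inputs may be fractions in [0, 1] or percentages in (1, 100]; when
#' either input exceeds 1 both are treated as percentages and the
#' result is returned on the percent scale. Values outside [0, 100]
#' are an error.
#'
#' @param precision,recall Scalars.
#' @return F1 on the same scale as the inputs; 0 when both are 0.
#' @examples
#' f1Score(80.06, 88.92)  # percent in, percent out
#' @export
f1Score <- function(precision, recall) {
  stopifnot(length(precision) == 1L, length(recall) == 1L)
  if (precision < 0 || precision > 100 || recall < 0 || recall > 100) {
    stop("precision and recall must lie in [0, 1] or [0, 100] percent")
  }
  percentScale <- precision > 1 || recall > 1
  p <- if (percentScale) precision / 100 else precision
  r <- if (percentScale) recall / 100 else recall
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  if (percentScale) 100 * f else f
}
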