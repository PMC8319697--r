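---
title: "Mining typed knowledge graphs from annotated abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining typed knowledge graphs from annotated abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkg)
```

## The problem and the pipeline

Biomedical findings — which drugs treat a disease, which herbs make up
a patent formula, which genes associate with a condition — are mostly
reported as free text. `litkg` turns a corpus of abstracts in PubTator
format into a typed knowledge graph through a transparent, fully
rule-based cascade:

1. **Corpus I/O and sentence segmentation.** Abstracts are read from
   PubTator blocks; all offsets are 0-based half-open into the
   concatenation *title + single space + abstract* (PubTator's own
   convention). Sentence spans are computed by a deterministic
   rule-based splitter.
2. **Dictionary NER.** Per-type lexicons (TSV term lists such as those
   exported from TCM and drug databases) are compiled into normalized
   surface indices; documents are tagged longest-match over token
   sequences. Pre-annotated mentions — stand-ins for external taggers
   for diseases, chemicals, genes and pathways — are ingested untouched.
3. **Entity-frequency filter.** Entities mentioned fewer than
   `minEntityCount` times corpus-wide (default 3) are routed to a
   review list that mirrors a manual-inspection step, and excluded
   from relation extraction unless whitelisted.
4. **Relation extraction.** Two typed mentions in one sentence form a
   candidate pair if their type pair is one of 31 allowed families;
   trigger keywords assign a relation type per family group; evidence
   is aggregated per entity pair into a confidence-weighted edge.
5. **Graph assembly and export.** Kept entities become nodes, surviving
   aggregated relations become edges carrying keywords, PMIDs,
   confidence and support; the graph exports to GraphML, Neo4j
   bulk-import CSV, or a TSV triple dump.
6. **Evaluation.** Precision/recall/F1 for NER against gold spans, and
   for relations the *correct rate*: among entity pairs found both by
   the miner and by a reference database ("overlapped relationships"),
   the fraction whose relation type agrees (the diagonal of a
   predicted-by-reference confusion matrix over its grand total).

## Entity and relation model

Nine entity types are recognised: Disease, Symptom, Chemical, Drug,
CPM (Chinese Patent Medicine), Herb, Ingredient, Gene and Pathway.
Three keyword rule groups cover the 31 pair families:

* **tc** (substance vs disease/symptom): `Treatment` (therapy,
  treating, cure, remedy, inhibit), `Cause` (induce, cause, side
  effect, influence, dynamic), fallback `Other`.
* **ddi** (substance vs substance): `Advise`, `Interaction`, `Effect`,
  `Mechanism`, `Negative`, `EntityOrigin` (include, contain — the
  formula-composition signal), fallback `Other`.
* **assoc** (gene/pathway associations and symptom–disease):
  `PositiveAssociation` (effect, induce, target),
  `NegativeAssociation` (indifference, no), fallback `Other`.

Families without a printed keyword set of their own (the pathway and
non-disease gene pairs, symptom–disease) are assigned the association
group as the closest fit; this is a package choice, exposed through
the editable rulebook (`defaultRuleBook()`, `readRuleBook()`).

Within a group, types are checked in a fixed priority order (the order
listed above) and the first keyword hit wins; this tie-break is
deliberate and configurable rather than reconstructed from any
specific upstream tool. The high-noise keywords *and*, *between* and
*no* fire only when they occur strictly between the two entity spans,
which curbs their false-positive rate in ordinary conjunctions.

Keyword matching is stem-based: both keywords and sentence tokens pass
through a light rule stemmer (`lightStem()`) that conflates common
inflection (`-ies`→`-y`, then `-ing`, `-ed`, plural `-s`, trailing
`-e`). Because the same stemmer is applied on both sides, only
stem-class agreement matters; the stemmer is intentionally aggressive
and makes no claim to linguistic correctness. Matching is
sentence-window based — dependency structure is out of scope.

## Confidence aggregation

The same entity pair can co-occur in many sentences with different
keyword outcomes. Per (pair, family), with $n$ co-occurrence sentences
and $c$ of them supporting the majority type,

$$\mathrm{confidence} = c / n, \qquad \mathrm{support} = c.$$

Fallback (`Other`) evidence counts toward $n$ but can only carry the
edge when no typed evidence exists at all. An edge survives iff
`support >= minSupport` (default 2) **and**
`confidence > confidenceThreshold` (default 0.5, strict) — a 1:1 split
vote at 0.5 is dropped. Both knobs are monotone: raising either never
adds edges. The defaults are package choices: the simplest
majority-fraction formula consistent with sentence-level evidence, a
support of 2 so that single accidental co-mentions never form an edge,
and a strict majority so conflicting evidence must be resolved, not
averaged. The upstream study this design follows states a confidence
threshold without publishing its value or formula.

## Normalization and its limits

`normalizeSurface()` case-folds, maps hyphens/underscores to spaces
and collapses whitespace, so *Huang-Lian*, *huang lian* and
*HUANG_LIAN* share one key; `expandVariants()` optionally adds
hyphen/space and *decoction*/*tang* suffix alternations.
Romanization equivalence (e.g. *Hwangryun-Hae-Dok-tang* vs
*Huanglian-Jie-Du-Tang*) is **not** attempted: it is a known recall
limitation of dictionary NER for transliterated TCM names and no
defensible orthographic rule set exists for it. Matching operates on
normalized token sequences, never raw substrings, so no hit can start
or end inside a word.

Within one entity type an ambiguous normalized surface is a load-time
error; across types the same surface may legitimately tag twice
(glucose is both a Chemical and an Ingredient), and both mentions are
emitted.

## The frequency filter

Entities below the threshold are not deleted: all their mentions are
routed to a review list (`entity_id`, surface, count, example PMID)
serialized for manual inspection, and a whitelist reinstates reviewed
entities. Kept and reviewed mentions partition the corpus exactly. The
boundary is *keep iff count ≥ threshold*: with the default 3, an
entity seen exactly 3 times is kept, one seen twice is reviewed.
Unnormalized mentions are counted under their normalized surface in a
`SURF:` namespace so the filter applies uniformly.

## The plugin classifier interface

Machine-learned relation classifiers (transformer models fine-tuned on
curated corpora) are intentionally out of scope, but the cascade keeps
their slot: `extractRelations(..., plugin = f)` consults
`f(sentenceText, candidate)` for exactly those candidates where no
keyword matched, and the rule result always takes precedence when a
keyword was found. A plugin must return a type from the candidate
family's set; anything else is a contract-violation error.

## The synthetic generator: what it emulates, what it does not

`generateLexicons()` / `generateCorpus()` produce a corpus whose every
property is known: CV-syllable entity names (unique per and across
types, with every name token reserved globally and screened against
keyword stems so no accidental matches are possible), supporting
sentences of the template `"<EntityA> <keyword> <EntityB>."`,
distractor sentences with at most one entity, and gold mention/relation
files that are valid inputs to the evaluation module. The defaults —
20 documents of 4–8 sentences, ten planted relations spanning all
three rule groups with 3–5 supporting sentences each, 30% distractor
sentences, zero keyword omission and zero surface-variant noise —
describe a small, clean literature: enough support per relation to
clear the frequency threshold, and unambiguous keyword usage.
Three noise knobs deviate from that ideal deterministically:
`keywordOmissionRate` (neutral verb instead of the trigger, yielding
fallback evidence), `surfaceVariantRate` (hyphen/space/case variants),
and `distractorRate`.

Passing tests on this corpus therefore demonstrate mechanical
correctness — offsets, matching, schema lookup, aggregation arithmetic
— not linguistic robustness. Real abstracts have ambiguous keywords,
anaphora, cross-sentence relations, nested entity names and
transliteration variance that the generator deliberately omits; the
templates are unambiguous *so that* any failure indicates a bug.

`corruptForEval()` injects analytically known noise (each gold mention
dropped with probability `fnRate`; spurious unmatched mentions at rate
`fpRate`), so expected recall is exactly `1 - fnRate`.

## Numerical and degenerate-input conventions

* Offsets: 0-based, half-open, everywhere; validity methods assert
  that every mention span slices to its surface.
* Sentence splitter: boundaries at `. ? !` followed by whitespace and
  an upper-case letter, digit or opening quote/bracket, with an
  abbreviation guard list; the title/abstract junction is always a
  boundary. Mentions crossing a boundary are kept, flagged in
  `diagnostics()`, and excluded from relation extraction.
* Zero-denominator precision/recall/F1 report 0; a correct rate over
  zero overlapped pairs reports `NA` with a message.
* Percent reporting is two decimals, round-half-even; published
  figures this is compared against mix rounding and truncation, so
  comparisons at printed precision should allow ±0.01.
* Majority ties among typed evidence break alphabetically (stable and
  order-independent); keyword ties break by rulebook priority.
* Parallel edges of different relation types (or families) between the
  same pair are retained; same-type duplicates merge with PMID-set
  union, summed support and max confidence.
* The graph property count tallies non-empty attribute values over
  nodes (name, type, MeSH id, mention count) and edges (family, type,
  keywords, PMIDs, confidence, support); ids and endpoints are
  structural and not counted.
* GraphML is serialized as a directed graph so the canonical
  (family-ordered) endpoint order survives the round-trip; semantic
  direction is implied by the family, not asserted per edge.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on generated corpora of 3–20
documents, the candidate-pair oracle on 100 random documents, the
aggregation property suites on up to 60-row evidence sets, and the
noise-recovery check on 1000 gold mentions over 50 replicates — sizes
chosen so the whole suite documents the behaviour it claims while
remaining quick to run anywhere.

## A worked example

```{r example}
cfg <- synthConfig(seed = 11)
lex <- generateLexicons(cfg)
syn <- generateCorpus(cfg, lex)
res <- runPipeline(syn$corpus, lex,
                   config = nerConfig(minEntityCount = 1),
                   minSupport = 1)
res$graph
head(res$relations[, c("id_a", "id_b", "family", "relation_type",
                       "support", "confidence")])
scoreNer(corpusMentions(res$corpus), syn$goldMentions, "strict_span")
```

## Known limitations

* Dictionary NER cannot find names absent from its lexicons, and
  recall on transliterated TCM names is bounded by orthographic
  normalization.
* Relations are sentence-bound; cross-sentence and document-level
  relations are out of scope, as is negation scope beyond the
  *no*-between-entities rule.
* The keyword rules are a deliberately simple, auditable baseline; the
  plugin interface exists precisely so stronger classifiers can slot
  in behind the same aggregation and export machinery.
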