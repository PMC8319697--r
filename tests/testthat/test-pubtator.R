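test_that("reading parses blocks, offsets and pre-annotations", {
  expect_identical(readPubTator(character(0)), list())
  expect_identical(readPubTator(c("", "", "")), list())

  lines <- c("1|t|Aspirin study", "1|a|Aspirin helps.",
             "1\t14\t21\tAspirin\tDrug\tDB00945", "")
  docs <- readPubTator(lines)
  expect_length(docs, 1L)
  d <- docs[[1]]
  expect_identical(fullText(d), "Aspirin study Aspirin helps.")
  m <- mentions(d)
  expect_identical(nrow(m), 1L)
  # slicing the title+space+abstract concatenation at the mention span
  # reproduces the surface exactly (0-based half-open)
  expect_identical(sliceText(fullText(d), m$start, m$end), "Aspirin")
  expect_identical(m$source, "preannotated")
  expect_identical(m$norm_id, "DB00945")
})

test_that("malformed input raises informative errors", {
  expect_error(readPubTator(c("1|t|T", "garbage line here", "")),
               "line 2")
  expect_error(
    readPubTator(c("7|t|Title", "7|a|Abstract text.",
                   "7\t0\t5\tWRONG\tDrug\tX", "")),
    "pmid 7.*\\(0,5\\)")
})

test_that("writing is canonical and round-trips, including non-ASCII", {
  m <- data.frame(
    start = c(20L, 6L), end = c(26L, 12L),
    surface = c("Dang [", "Dang ["), entity_type = c("Herb", "Herb"),
    norm_id = c("HER:1", "HER:1"), source = "preannotated",
    sentence = NA_integer_, stringsAsFactors = FALSE)
  # non-ASCII herb name; mentions supplied in reverse span order
  m$surface <- c("Dāng-Guī", "Dāng-Guī")
  title <- "About Dāng-Guī"
  abstract <- "More Dāng-Guī here."
  ft <- paste(title, abstract, sep = " ")
  hit <- gregexpr("Dāng-Guī", ft)[[1]]
  m$start <- rev(as.integer(hit) - 1L)
  m$end <- rev(as.integer(hit) - 1L + attr(hit, "match.length"))
  m$surface <- sliceText(ft, m$start, m$end)
  d <- Document("42", title, abstract, mentions = m)

  out <- writePubTator(d)
  ann <- grep("\t", out, value = TRUE, fixed = TRUE)
  starts <- as.integer(vapply(strsplit(ann, "\t"), `[`, "", 2L))
  expect_false(is.unsorted(starts))  # emitted sorted by span

  back <- readPubTator(out)
  expect_identical(mentions(back[[1]])$surface, mentions(d)$surface)
  expect_identical(writePubTator(back), out)  # canonical fixed point

  # doc without mentions: exactly |t|, |a| and a blank line
  plain <- writePubTator(Document("9", "T", "A."))
  expect_identical(plain, c("9|t|T", "9|a|A.", ""))
})

test_that("read(write(read(x))) == read(x) on a mixed corpus", {
  lines <- c("1|t|Aspirin study", "1|a|Aspirin helps.",
             "1\t14\t21\tAspirin\tDrug\tDB00945", "",
             "2|t|Second", "2|a|No annotations here.", "")
  r1 <- readPubTator(lines)
  r2 <- readPubTator(writePubTator(r1))
  expect_equal(r2, r1)
})

test_that("invalid mention spans refuse to serialize", {
  d <- Document("1", "Title", "Body text.")
  d@mentions <- data.frame(start = 0L, end = 50L, surface = "x",
                           entity_type = "Drug", norm_id = "X",
                           source = "dictionary", sentence = NA_integer_,
                           stringsAsFactors = FALSE)
  expect_error(writePubTator(d))
})

test_that("sentence splitting follows the documented rules", {
  d <- splitSentences(Document("1", "A. B.", "One more sentence."))
  # title "A. B." -> 2 spans; abstract -> 1 span
  expect_identical(nrow(sentences(d)), 3L)
  s <- sentences(d)
  ft <- fullText(d)
  expect_identical(sliceText(ft, s$start[1], s$end[1]), "A.")
  expect_identical(sliceText(ft, s$start[2], s$end[2]), "B.")

  # abbreviation guard: "e.g." does not split
  d2 <- splitSentences(Document("2", "T", "We saw e.g. aspirin. Then more."))
  segs <- with(sentences(d2), mapply(function(a, b)
    sliceText(fullText(d2), a, b), start, end))
  expect_true("We saw e.g. aspirin." %in% segs)

  # the title/abstract junction is always a boundary even without
  # terminal punctuation on the title
  d3 <- splitSentences(Document("3", "No period title", "Body here."))
  expect_identical(nrow(sentences(d3)), 2L)
})

test_that("sentence spans cover all non-whitespace text", {
  texts <- c("One. Two! Three?", "Single",
             "Numbers 3.5 stay. Next one.")
  for (tx in texts) {
    d <- splitSentences(Document("1", "Head", tx))
    s <- sentences(d)
    ft <- fullText(d)
    covered <- unlist(mapply(function(a, b) seq(a + 1L, b),
                             s$start, s$end, SIMPLIFY = FALSE))
    chars <- strsplit(ft, "")[[1]]
    nonWs <- which(!grepl("\\s", chars))
    expect_true(all(nonWs %in% covered))
    # spans non-overlapping and sorted (validity enforces too)
    expect_true(validObject(d, test = TRUE))
  }
})

test_that("mentions are assigned to sentences; crossers are flagged", {
  lines <- c("5|t|T", "5|a|Aspirin helps. Stroke hurts.",
             "5\t2\t9\tAspirin\tDrug\tDB00945",
             "5\t17\t23\tStroke\tDisease\tMESH:D020521", "")
  d <- splitSentences(readPubTator(lines)[[1]])
  m <- mentions(d)
  expect_identical(m$sentence[m$surface == "Aspirin"], 1L)
  expect_identical(m$sentence[m$surface == "Stroke"], 2L)
  expect_length(diagnostics(d), 0L)

  # a mention spanning the boundary keeps sentence = NA and is flagged
  ft <- fullText(d)
  crossing <- data.frame(start = 2L, end = 23L,
                         surface = sliceText(ft, 2L, 23L),
                         entity_type = "Drug", norm_id = "X",
                         source = "preannotated", sentence = NA_integer_,
                         stringsAsFactors = FALSE)
  d2 <- splitSentences(Document("5", "T", "Aspirin helps. Stroke hurts.",
                                mentions = crossing))
  expect_true(is.na(mentions(d2)$sentence[1]))
  expect_length(diagnostics(d2), 1L)
  expect_match(diagnostics(d2), "crosses")
})

test_that("single-sentence mention gets containing-sentence index 0", {
  lines <- c("6|t|Aspirin helps patients", "6|a|",
             "6\t0\t7\tAspirin\tDrug\tDB00945", "")
  d <- splitSentences(readPubTator(lines)[[1]])
  expect_identical(mentions(d)$sentence, 0L)
})
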