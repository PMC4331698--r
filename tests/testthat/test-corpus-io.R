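test_that("abstracts files parse, preserve order, and reject malformed input", {
  tf <- withr::local_tempfile()
  writeLines(c("D1\tAspirin works.\tWe gave aspirin.",
               "D2\tSecond title.\tSecond abstract."), tf)
  docs <- read_abstracts(tf)
  expect_equal(docs$doc_id, c("D1", "D2"))
  expect_equal(docs$title[1], "Aspirin works.")
  expect_equal(docs$abstract[1], "We gave aspirin.")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_abstracts(empty)), 0)

  bad <- withr::local_tempfile()
  writeLines("D1\tonly two fields", bad)
  expect_error(read_abstracts(bad), "line 1")

  dup <- withr::local_tempfile()
  writeLines(c("D1\ta\tb", "D1\tc\td"), dup)
  expect_error(read_abstracts(dup), "duplicate")
})

test_that("annotations verify text against document substrings", {
  docs <- data.frame(doc_id = "D1", title = "Aspirin works.",
                     abstract = "We gave aspirin.", stringsAsFactors = FALSE)
  tf <- withr::local_tempfile()
  writeLines("D1\tA\t8\t15\taspirin\tTRIVIAL", tf)
  m <- read_annotations(tf, docs)
  expect_equal(m$text, "aspirin")
  expect_equal(m$section, "ABSTRACT")
  expect_equal(m$etype, "TRIVIAL")

  writeLines("D1\tA\t8\t14\taspirin\tTRIVIAL", tf)
  expect_error(read_annotations(tf, docs), "mismatch")

  writeLines("D1\tA\t8\t15\taspirin\tNOT_A_TYPE", tf)
  expect_error(read_annotations(tf, docs), "unknown entity type")

  writeLines("D1\tA\t8\t99\taspirin\tTRIVIAL", tf)
  expect_error(read_annotations(tf, docs), "out of range")
})

test_that("span <-> BIO conversion matches the worked multi-token example", {
  toks <- tokenize("N-acetyl-L cysteine", section = "ABSTRACT")
  expect_equal(toks$tokens$text, c("N", "-", "acetyl", "-", "L", "cysteine"))
  m <- data.frame(doc_id = "D1", section = "ABSTRACT", start = 0L, end = 19L,
                  text = "N-acetyl-L cysteine", etype = "SYSTEMATIC",
                  stringsAsFactors = FALSE)
  labels <- spans_to_bio(toks, m)
  expect_equal(labels, c("B", "I", "I", "I", "I", "I"))
  back <- bio_to_spans(toks, labels, "D1")
  expect_equal(back$start, 0L)
  expect_equal(back$end, 19L)
  expect_equal(back$text, "N-acetyl-L cysteine")
})

test_that("BIO encoding handles adjacency, orphans, and empty cases", {
  toks <- tokenize("abc def", section = "ABSTRACT")
  # two adjacent single-token mentions -> B B
  m <- data.frame(doc_id = "D", section = "ABSTRACT", start = c(0L, 4L),
                  end = c(3L, 7L), text = c("abc", "def"),
                  etype = c("TRIVIAL", "TRIVIAL"), stringsAsFactors = FALSE)
  expect_equal(spans_to_bio(toks, m), c("B", "B"))
  # no mentions -> all O
  expect_equal(spans_to_bio(toks, m[0, ]), c("O", "O"))
  # orphan I repaired to B at decode time
  toks3 <- tokenize("a b c", section = "ABSTRACT")
  sp <- bio_to_spans(toks3, c("O", "I", "O"), "D")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$text, "b")
  # length mismatch errors
  expect_error(bio_to_spans(toks3, c("O", "O")), "length")
  # overlapping mentions rejected
  bad <- data.frame(doc_id = "D", section = "ABSTRACT", start = c(0L, 2L),
                    end = c(3L, 5L), text = c("abc", "c d"),
                    etype = c("TRIVIAL", "TRIVIAL"), stringsAsFactors = FALSE)
  expect_error(spans_to_bio(tokenize("abc d", section = "ABSTRACT"), bad),
               "overlap")
})

test_that("BIO round trip is the identity for token-aligned mention sets", {
  corp <- generate_corpus(synth_config(n_documents = 12, seed = 7))
  for (r in seq_len(nrow(corp$documents))) {
    for (section in c("TITLE", "ABSTRACT")) {
      text <- if (section == "TITLE") corp$documents$title[r] else corp$documents$abstract[r]
      toks <- tokenize(text, section = section)
      m <- corp$mentions[corp$mentions$doc_id == corp$documents$doc_id[r] &
                           corp$mentions$section == section, , drop = FALSE]
      back <- bio_to_spans(toks, spans_to_bio(toks, m), corp$documents$doc_id[r])
      expect_equal(back$start, sort(m$start))
      expect_equal(back$end, m$end[order(m$start)])
      expect_equal(back$text, m$text[order(m$start)])
    }
  }
})

test_that("prediction files rank by confidence with deterministic ties", {
  docs <- tiny_documents()
  m <- data.frame(doc_id = "D1", section = c("ABSTRACT", "TITLE", "ABSTRACT"),
                  start = c(8L, 0L, 0L), end = c(15L, 7L, 2L),
                  text = c("aspirin", "Aspirin", "We"),
                  etype = "TRIVIAL", stringsAsFactors = FALSE)
  tf <- withr::local_tempfile()
  write_predictions(m, c(0.4, 0.9, 0.4), tf)
  lines <- readLines(tf)
  fields <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(fields[, 3], c("1", "2", "3"))
  expect_equal(fields[1, 2], "T:0:7")         # highest confidence first
  # tie at 0.4: title section would come first, here both are abstract/…
  expect_equal(fields[2, 2], "A:0:2")         # tie broken by start offset
  expect_equal(fields[3, 2], "A:8:15")
  rt <- read_predictions(tf, docs)
  expect_equal(nrow(rt$mentions), 3)
  expect_equal(sort(rt$mentions$text), sort(m$text))
  expect_error(write_predictions(m, c(0.4, 0.9, 1.4), tf), "\\[0, 1\\]")
})

test_that("corpus statistics add up and cover all types", {
  counts <- c(ABBREVIATION = 4538, FAMILY = 4090, FORMULA = 4448,
              IDENTIFIER = 672, MULTIPLE = 202, SYSTEMATIC = 6656,
              TRIVIAL = 8832, NO_CLASS = 40)
  m <- do.call(rbind, lapply(names(counts), function(ty) {
    if (counts[ty] == 0) return(NULL)
    data.frame(doc_id = "D", section = "ABSTRACT", start = 0L, end = 1L,
               text = "x", etype = rep(ty, counts[ty]), stringsAsFactors = FALSE)
  }))
  st <- corpus_statistics(m)
  expect_equal(st$counts[names(counts)], counts)
  expect_equal(st$total, 29478)
  expect_equal(st$total, nrow(m))
  empty <- corpus_statistics(m[0, ])
  expect_true(all(empty$counts == 0))
  expect_equal(empty$total, 0)
})

test_that("CoNLL vertical format round-trips tokens, tags and labels", {
  toks <- tokenize("We gave aspirin. It worked.", section = "ABSTRACT")
  labels <- rep("O", nrow(toks$tokens)); labels[3] <- "B"
  pos <- heuristic_pos_tag(toks$tokens$text)
  tf <- withr::local_tempfile()
  write_conll(toks, labels, pos, tf)
  back <- read_conll(tf)
  expect_equal(back$text, toks$tokens$text)
  expect_equal(back$start, toks$tokens$start)
  expect_equal(back$label, labels)
  expect_equal(back$pos, pos)
  expect_equal(back$sentence_index, toks$tokens$sentence_index)
})
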