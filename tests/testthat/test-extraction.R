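test_that("headword is the last word, or the last word before a preposition", {
  expect_equal(headword_of("infantile autism disease"), "disease")
  expect_equal(headword_of("insulin"), "insulin")
  expect_equal(headword_of("inhibitor of kinase"), "inhibitor")
  expect_error(headword_of("  "), "empty")
})

test_that("the figure sentences yield exactly the expected candidates", {
  corp <- figure_corpus()
  expect_equal(pattern1_candidates(corp[[1]], "disease")$text,
               "infantile autism")
  expect_equal(sort(pattern2_candidates(corp[[2]], "protein")$surface),
               c("ArhGAP9", "Coflin"))
  expect_equal(pattern3_candidates(corp[[3]], "protein")$surface, "TBCE")
  expect_equal(pattern3_candidates(corp[[3]], "cells")$surface,
               "Cholangiocytes")
})

test_that("pattern 1 requires the reduction to recur as a noun phrase", {
  rec <- tag_record(abstract_record("U1", "A report on other topics",
    "The viral takomin disease was examined ."))
  expect_equal(nrow(pattern1_candidates(rec, "disease")), 0)

  # substring recurrence inside another phrase is not a noun-phrase match
  rec2 <- tag_record(abstract_record("U2",
    "The viral takomin syndrome was common",
    "The viral takomin disease was examined ."))
  expect_equal(nrow(pattern1_candidates(rec2, "disease")), 0)
})

test_that("pattern 2 rejects clauses without a determiner-initiated definition", {
  rec <- tag_record(abstract_record("P2", "x",
    "The cell , however , divides rapidly ."))
  expect_equal(nrow(pattern2_candidates(rec, "cell")), 0)
})

test_that("pattern 3 rejects pronouns in the X slot", {
  rec <- tag_record(abstract_record("P3", "x", "It is a protein ."))
  expect_equal(nrow(pattern3_candidates(rec, "protein")), 0)
})

test_that("planted corpora are recovered exactly, independent of record order", {
  spec <- sim_spec(n_records = 30, seed = 13)
  corp <- generate_corpus(spec)
  recs <- tag_corpus(corp$records)
  harvest <- function(records) {
    out <- list()
    for (r in records) for (hw in spec$headwords) {
      out <- c(out, list(pattern1_candidates(r, hw),
                         pattern2_candidates(r, hw),
                         pattern3_candidates(r, hw)))
    }
    df <- do.call(rbind, out)
    df[order(df$record_id, df$pattern, df$text), ]
  }
  got <- harvest(recs)
  key <- function(d) paste(d$record_id, d$pattern, d$headword, d$text)
  expect_setequal(key(got), key(corp$truth))

  set.seed(1)
  shuffled <- harvest(sample(recs))
  expect_equal(sort(key(shuffled)), sort(key(got)))
})

test_that("no candidate equals or ends with its headword, and spans index real tokens", {
  spec <- sim_spec(n_records = 30, seed = 77)
  corp <- generate_corpus(spec)
  recs <- tag_corpus(corp$records)
  for (r in recs) for (hw in spec$headwords) {
    cand <- rbind(pattern1_candidates(r, hw),
                  pattern2_candidates(r, hw),
                  pattern3_candidates(r, hw))
    if (nrow(cand) == 0) next
    hw_lemma <- lemmatize(hw)
    for (i in seq_len(nrow(cand))) {
      words <- strsplit(cand$text[i], " ")[[1]]
      expect_false(words[length(words)] == hw_lemma)
      s <- r$sentences[[cand$sentence_index[i]]]
      expect_true(cand$start[i] >= 1 && cand$end[i] <= nrow(s$tokens) + 1L)
      expect_equal(paste(s$tokens$surface[cand$start[i]:(cand$end[i] - 1L)],
                         collapse = " "),
                   cand$surface[i])
    }
  }
})

test_that("the packaged template table has 40 entries that all parse", {
  tab <- load_pattern_table()
  expect_length(tab, 40)
  parses <- lapply(tab, parse_template)
  expect_true(all(vapply(parses, `[[`, TRUE, "parsed")))
  expect_true(all(vapply(parses, `[[`, "", "connective") %in%
                    c("is", "are", "as", "such as", "and other", "")))

  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tab[-1], short)
  expect_error(load_pattern_table(short), "40")
})

test_that("enumeration-guard drops list contexts when enabled", {
  rec <- tag_record(abstract_record("E1", "x",
    "Talvek is a viral gene , the NTS1 spacer , the ribosomal gene , and more ."))
  expect_equal(pattern3_candidates(rec, "gene")$surface, "Talvek")
  expect_equal(nrow(pattern3_candidates(rec, "gene",
                                        enumeration_guard = TRUE)), 0)
})
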