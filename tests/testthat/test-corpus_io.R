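test_that("TSV corpus reading preserves records and catches malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\ttitle\tbody",
               "101\tFirst title\tFirst body text",
               "102\tSecond title\tSecond body text"), path)
  recs <- read_abstracts(path)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, "", "record_id"), c("101", "102"))
  expect_equal(recs[[2]]$title, "Second title")

  writeLines("record_id\ttitle\tbody", path)
  expect_length(read_abstracts(path), 0)

  writeLines(c("record_id\ttitle\tbody", "only_one_field"), path)
  expect_error(read_abstracts(path), "line 2")

  writeLines(c("record_id\ttitle\tbody", "1\ta\tb", "1\tc\td"), path)
  expect_error(read_abstracts(path), "duplicate")
})

test_that("a generated corpus round-trips write -> read unchanged", {
  corp <- generate_corpus(sim_spec(n_records = 50, seed = 42))$records
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_abstracts(corp, p1)
  back <- read_abstracts(p1)
  expect_length(back, 50)
  for (i in seq_along(corp)) {
    expect_equal(back[[i]]$record_id, corp[[i]]$record_id)
    expect_equal(back[[i]]$title, corp[[i]]$title)
    expect_equal(back[[i]]$body, corp[[i]]$body)
  }
  write_abstracts(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("MEDLINE-style records parse PMID, TI and AB with continuations", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "PMID- 12345",
    "TI  - A study of",
    "      epithelial cells",
    "AB  - The body of the abstract",
    "      continues here.",
    "FAU - Someone, Ignored",
    "",
    "PMID- 67890",
    "TI  - Second record",
    "AB  - Second body."), path)
  recs <- read_abstracts(path, format = "medline")
  expect_length(recs, 2)
  expect_equal(recs[[1]]$record_id, "12345")
  expect_equal(recs[[1]]$title, "A study of epithelial cells")
  expect_equal(recs[[1]]$body, "The body of the abstract continues here.")
  expect_equal(recs[[2]]$record_id, "67890")
})

test_that("vocabulary labels follow the positive-category set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tcategory",
               "p53 protein\tCAT_A",
               "liver\tCAT_B",
               "\tCAT_B"), path)
  expect_warning(v <- read_vocabulary(path, positive_categories = "CAT_A"),
                 "skipped")
  expect_equal(nrow(v), 2)
  expect_equal(v$label[v$surface == "p53 protein"], 1L)
  expect_equal(v$label[v$surface == "liver"], -1L)
  expect_equal(v$term[v$surface == "p53 protein"], "p53 protein")
})

test_that("label counts equal category counts on a mixed vocabulary", {
  spec <- sim_spec(n_pos = 60, n_neg = 40, seed = 9)
  vocab <- generate_vocabulary(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, path)
  v <- read_vocabulary(path, positive_categories = "TARGET")
  expect_equal(sum(v$label == 1L), sum(vocab$category == "TARGET"))
  expect_equal(sum(v$label == -1L), sum(vocab$category == "OTHER"))
})

test_that("lemmatization is deterministic, idempotent and case-stable", {
  expect_equal(lemmatize("cells"), "cell")
  expect_equal(lemmatize("protein"), "protein")
  expect_equal(lemmatize("Diseases"), "disease")
  expect_equal(lemmatize(c("viruses", "analyses", "bodies", "classes")),
               c("virus", "analysis", "body", "class"))
  set.seed(31)
  words <- c(
    replicate(700, paste(sample(letters, sample(3:9, 1), TRUE),
                         collapse = "")),
    paste0(replicate(300, paste(sample(letters, sample(3:6, 1), TRUE),
                                collapse = "")),
           sample(c("s", "es", "ies", "is", "us", "ss"), 300, TRUE)))
  once <- lemmatize(words)
  expect_identical(lemmatize(once), once)                  # idempotent
  expect_identical(lemmatize(toupper(words)), once)        # case-stable
})
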