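test_that("quotation matching finds exact normalized substrings", {
  fix <- tiny_fixture()
  a1 <- fix$corpus[["a1"]]
  idx <- match_quotation(a1, "sealed opaque envelopes")
  expect_length(idx, 1L)
  expect_match(a1$sentences$text[a1$sentences$index == idx],
               "sealed opaque envelopes")
  expect_equal(match_quotation(a1, "this text appears nowhere"),
               integer(0))
  # typographic variants still match after normalization
  expect_equal(match_quotation(a1, "“Sealed, opaque envelopes”"), idx)
})

test_that("quotations spanning a sentence boundary mark all overlapped sentences", {
  a <- article_document(
    "sp1", title = "Trial report.",
    body = paste("Allocation was concealed with sequentially numbered sealed opaque envelopes.",
                 "Randomization used a computer generated sequence for every centre."))
  q <- paste("concealed with sequentially numbered sealed opaque envelopes.",
             "Randomization used a computer generated sequence")
  idx <- match_quotation(a, q)
  expect_setequal(idx, c(1L, 2L))
})

test_that("overlap stage tolerates hyphenation noise in the quotation", {
  a <- article_document(
    "n1", title = "Trial.",
    body = "Sequentially numbered sealed opaque envelopes concealed the allocation.")
  noisy <- "“sequentially numbered sealed opaque envelopes concealed the allo-cation”"
  expect_length(match_quotation(a, noisy), 1L)
  # a short noisy quotation without a 30-character run does not match
  expect_length(match_quotation(a, "sealed opa-que envelopes"), 0L)
})

test_that("sentence label inference follows the relevant / not-relevant / unlabelled rule", {
  fix <- tiny_fixture()
  lab1 <- infer_sentence_labels(fix$corpus[["a1"]], fix$records,
                                "alloc_conc")
  expect_equal(sum(lab1 == "relevant"), 1L)
  expect_equal(sum(lab1 == "unlabelled"), length(lab1) - 1L)

  lab2 <- infer_sentence_labels(fix$corpus[["a2"]], fix$records,
                                "alloc_conc")
  expect_true(all(lab2 == "not_relevant"))

  lab3 <- infer_sentence_labels(fix$corpus[["a3"]], fix$records,
                                "alloc_conc")
  expect_true(all(lab3 == "unlabelled"))

  # exactly one label per sentence by construction
  expect_length(lab1, nrow(fix$corpus[["a1"]]$sentences))
})

test_that("quotation match combined with no-information is a conflict error", {
  fix <- tiny_fixture()
  recs <- c(fix$records, list(
    assessment_record("s3", "alloc_conc", "unclear", no_information = TRUE,
                      referenced_article_ids = "a1")))
  expect_error(
    infer_sentence_labels(fix$corpus[["a1"]], recs, "alloc_conc"),
    "conflict")
})

test_that("judgement collapsing maps high and unclear to not_low", {
  expect_equal(infer_article_label("low"), "low")
  expect_equal(infer_article_label("high"), "not_low")
  expect_equal(infer_article_label("unclear"), "not_low")
  expect_equal(infer_article_label(c("low", "unclear")),
               c("low", "not_low"))
  expect_error(infer_article_label("medium"), "unknown judgement")
})

test_that("labelling regimes partition sentences as specified", {
  fix <- tiny_fixture()
  total <- sum(vapply(fix$corpus, function(a) nrow(a$sentences), 0L))

  rest <- build_sentence_dataset(fix$corpus, fix$records, "alloc_conc",
                                 "relevant_rest")
  expect_equal(nrow(rest), total)

  rel_not <- build_sentence_dataset(fix$corpus, fix$records, "alloc_conc",
                                    "relevant_not")
  n_rel <- sum(rest$class == "relevant")
  n_notrel <- sum(rest$class == "not_relevant")
  expect_equal(nrow(rel_not), n_rel + n_notrel)
  expect_true(all(rel_not$class != "unlabelled"))
  expect_equal(sum(rel_not$y), n_rel)

  # every sentence carries exactly one of the three classes
  expect_true(all(rest$class %in% c("relevant", "not_relevant",
                                    "unlabelled")))
})

test_that("untrainable sentence datasets raise errors", {
  a <- article_document("only", title = "Title.", body = "One sentence.")
  recs <- list(assessment_record("s", "blind", "unclear",
                                 no_information = TRUE,
                                 referenced_article_ids = "only"))
  expect_error(build_sentence_dataset(corpus(list(a)), recs, "blind",
                                      "relevant_not"), "untrainable")
})

test_that("article dataset admits only no-information or quotation-matched articles", {
  fix <- tiny_fixture()
  d <- build_article_dataset(fix$corpus, fix$records, "alloc_conc")
  expect_setequal(d$article_id, c("a1", "a2"))  # a3 unreferenced
  expect_equal(d$label[d$article_id == "a1"], "low")
  expect_equal(d$label[d$article_id == "a2"], "not_low")

  # a record whose quotation matches nothing does not admit the article
  recs <- c(fix$records, list(
    assessment_record("s4", "alloc_conc", "low",
                      quotations = "text found in no article at all",
                      referenced_article_ids = "a3")))
  d2 <- build_article_dataset(fix$corpus, recs, "alloc_conc")
  expect_false("a3" %in% d2$article_id)
})

test_that("label distribution reports counts and proportions", {
  d <- label_distribution(c(rep("low", 3), rep("not_low", 1)))
  expect_equal(d$n[d$label == "low"], 3L)
  expect_equal(d$proportion[d$label == "low"], 0.75)
})

test_that("assessment records round-trip through JSONL", {
  fix <- tiny_fixture()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records(fix$records, path)
  back <- read_records(path)
  expect_equal(back, fix$records)
})
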