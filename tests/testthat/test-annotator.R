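lex <- default_lexicon()
gz <- default_gazetteers()

test_that("context window is the containing sentence, capped at 300 chars", {
  doc <- list(doc_id = "d",
              text = "Seen today. She is in constant pain. Plan made.")
  w <- context_window(doc, list(start = 31, end = 35))
  expect_identical(as.character(w), "She is in constant pain.")
  expect_identical(attr(w, "start"), 12L)

  single <- list(doc_id = "s", text = "She is in constant pain")
  w2 <- context_window(single, list(start = 19, end = 23))
  expect_identical(as.character(w2), single$text)

  # unbroken line: 300-character cap on each side
  long <- paste(c(rep("a", 500), "pain", rep("b", 500)), collapse = " ")
  doc3 <- list(doc_id = "l", text = long)
  st <- regexpr("pain", long) - 1L
  w3 <- context_window(doc3, list(start = st, end = st + 4L))
  expect_lte(st - attr(w3, "start"), 300L)
  expect_lte(nchar(w3), 300L + 4L + 300L)
  expect_true(grepl("pain", w3))

  # newline is a sentence boundary
  doc4 <- list(doc_id = "n", text = "no history\nchronic pain noted\nplan")
  st4 <- regexpr("pain", doc4$text) - 1L
  w4 <- context_window(doc4, list(start = st4, end = st4 + 4L))
  expect_identical(as.character(w4), "chronic pain noted")
})

annotate_one <- function(text) {
  annotate_document(tibble::tibble(doc_id = "x", text = text), lex, gz)
}

test_that("correctness rejects lexical false positives and inanimate burns", {
  a <- annotate_one("He likes burning things")
  expect_identical(a$correct, "no")
  expect_identical(a$relevance, "n/a")

  b <- annotate_one("She painted a picture of the situation")
  expect_identical(b$correct, "no")

  c1 <- annotate_one("She is in constant pain")
  expect_identical(c1$correct, "yes")

  d <- annotate_one("There were burn marks on the door")
  expect_identical(d$correct, "no")

  e <- annotate_one("Complains of heartburn after meals")
  expect_identical(e$correct, "yes")
})

test_that("relevance rules fire in documented precedence", {
  expect_identical(
    annotate_one("Afraid I will be in pain if surgery is unsuccessful")$relevance,
    "not_relevant"
  )
  expect_identical(annotate_one("He is not on painkillers")$relevance,
                   "negated")
  expect_identical(annotate_one("?migraine")$relevance, "not_relevant")
  expect_identical(annotate_one("migraine?")$relevance, "not_relevant")
  expect_identical(annotate_one("His mother was always in pain")$relevance,
                   "not_relevant")
  expect_identical(annotate_one("no pain reported")$relevance, "negated")
  expect_identical(annotate_one("she is now pain free")$relevance, "negated")
  expect_identical(
    annotate_one("sticking out like a sore thumb")$relevance,
    "not_relevant"
  )
  # uncertainty outranks negation
  expect_identical(annotate_one("No pain?")$relevance, "not_relevant")
  # emotional-context approximation
  expect_identical(
    annotate_one("despite the relationship causing her a lot of pain she returns to him")$relevance,
    "not_relevant"
  )
})

test_that("anatomy detection uses compounds and nearby body-part terms", {
  a <- annotate_one("He suffers from severe headaches")
  expect_identical(a$anatomy, "mentioned")
  expect_identical(a$anatomy_location, "head")

  b <- annotate_one("She is in constant pain")
  expect_identical(b$anatomy, "n/a")
  expect_true(is.na(b$anatomy_location))

  c1 <- annotate_one("chronic back pain")
  expect_identical(c1$anatomy, "mentioned")
  expect_identical(c1$anatomy_location, "back")

  d <- annotate_one("complains of abdominal pain tonight")
  expect_identical(d$anatomy_location, "abdomen")
})

test_that("pain character requires an explicit chronic token", {
  a <- annotate_one("She is in constant pain")
  expect_identical(a$character, "other")
  expect_identical(a$character_surface, "constant")

  b <- annotate_one("chronic back pain")
  expect_identical(b$character, "chronic")

  c1 <- annotate_one("ongoing back pain")
  expect_false(identical(c1$character, "chronic"))

  d <- annotate_one("she reports period pain this week")
  expect_identical(d$character, "other")
})

test_that("management distinguishes medication from other measures", {
  a <- annotate_one("He is not on painkillers")
  expect_identical(a$management, "medication")

  b <- annotate_one("She is in constant pain")
  expect_identical(b$management, "n/a")

  c1 <- annotate_one("referred to the pain clinic for ongoing back pain")
  expect_true(all(c1$management == "other"))
})

test_that("the six worked annotation examples reproduce exactly", {
  fx <- table3_fixture()
  for (i in seq_len(nrow(fx))) {
    a <- annotate_document(fx[i, c("doc_id", "text")], lex, gz)
    expect_identical(nrow(a), 1L, label = fx$text[i])
    expect_identical(a$surface, fx$surface[i], label = fx$text[i])
    expect_identical(a$canonical_word, fx$keyword[i], label = fx$text[i])
    expect_identical(a$correct, fx$correct[i], label = fx$text[i])
    expect_identical(a$relevance, fx$relevance[i], label = fx$text[i])
    expect_identical(a$anatomy, fx$anatomy[i], label = fx$text[i])
    expect_identical(a$character, fx$character[i], label = fx$text[i])
    expect_identical(a$management, fx$management[i], label = fx$text[i])
  }
})

test_that("multi-sentence documents are annotated per containing sentence", {
  a <- annotate_one("No headache today. Chronic back pain persists.")
  expect_identical(nrow(a), 2L)
  expect_identical(a$surface, c("headache", "pain"))
  expect_identical(a$relevance, c("negated", "relevant"))
  expect_identical(a$anatomy_location, c("head", "back"))
  expect_identical(a$character, c("n/a", "chronic"))
})

test_that("incorrect mentions force all downstream attributes to n/a", {
  corp <- generate_corpus(synthetic_config(seed = 5, n_patients = 20,
                                           words_per_doc_mean = 60,
                                           incorrect_rate = 0.4))
  ann <- annotate_corpus(corp$documents, lex, gz)
  no <- dplyr::filter(ann, correct == "no")
  expect_gt(nrow(no), 0L)
  expect_true(all(no$relevance == "n/a"))
  expect_true(all(no$anatomy == "n/a"))
  expect_true(all(no$character == "n/a"))
  expect_true(all(no$management == "n/a"))
  expect_true(all(is.na(no$anatomy_location)))
})

test_that("prepending a negation flips trigger-free relevant mentions", {
  templates <- c(
    "Severe back pain.",
    "She is in constant pain.",
    "Complains of headaches.",
    "Abdominal cramping noted."
  )
  for (tpl in templates) {
    base <- annotate_one(tpl)
    expect_identical(base$relevance[1], "relevant", label = tpl)
    neg <- annotate_one(paste0("There is no ", tolower(tpl)))
    expect_identical(neg$relevance[1], "negated", label = tpl)
    expect_identical(neg$correct[1], base$correct[1], label = tpl)
  }
})

test_that("relevance agrees with a naive rule interpreter on random windows", {
  vocab <- c(
    "she", "reports", "today", "mild", "the", "ward", "plan", "review",
    "no", "not", "denies", "without", "mother", "husband", "staff",
    "afraid", "if", "risk", "case", "free", "reported", "severe"
  )
  withr::with_seed(2024, {
    for (k in 1:150) {
      n <- sample(3:20, 1)
      toks <- sample(vocab, n, replace = TRUE)
      idx <- sample(n, 1)
      toks[idx] <- "pain"
      punct_before <- sample(c("", "?"), 1, prob = c(.8, .2))
      punct_after <- sample(c("", "?"), 1, prob = c(.8, .2))
      window <- paste(toks, collapse = " ")
      if (nzchar(punct_before)) {
        pre <- if (idx > 1) paste(toks[seq_len(idx - 1)], collapse = " ") else ""
        window <- paste0(
          pre, if (nzchar(pre)) " ", punct_before,
          paste(toks[idx:n], collapse = " ")
        )
      }
      if (nzchar(punct_after)) {
        st <- regexpr("\\bpain\\b", window)
        window <- paste0(
          substring(window, 1, st + 3), punct_after,
          substring(window, st + 4)
        )
      }
      st <- as.integer(regexpr("\\bpain\\b", window)) - 1L
      mention <- list(start = st, end = st + 4L, surface = "pain")
      got <- classify_relevance(mention, structure(window, start = 0L), gz)
      want <- oracle_relevance(toks, idx, punct_before, punct_after, gz)
      expect_identical(got, want, label = window)
    }
  })
})
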