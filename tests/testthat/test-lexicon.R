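test_that("wildcard compilation matches anchored alphabetic semantics", {
  expect_true(compile_pattern("%ache")("headache"))
  expect_true(compile_pattern("%ache")("Backache"))
  expect_false(compile_pattern("%ache")("attached"))

  # literal patterns match exactly
  lum <- compile_pattern("lumbago")
  expect_true(lum("lumbago"))
  expect_false(lum("lumbagos"))

  # brute-force substring oracle over a small vocabulary
  vocab <- c("pain", "pains", "painful", "painted", "spain", "pan")
  got <- vocab[compile_pattern("%pain%")(vocab)]
  want <- vocab[vapply(vocab, function(t) oracle_match("%pain%", t),
                       logical(1))]
  expect_identical(got, want)
  expect_identical(got, c("pain", "pains", "painful", "painted", "spain"))
})

test_that("malformed patterns are rejected with a clear message", {
  expect_error(compile_pattern("pa%in"), "interior|start or end")
  expect_error(compile_pattern("%"), "malformed|empty|literal")
  expect_error(compile_pattern(""), "empty")
})

test_that("the default lexicon covers its documented pattern table", {
  lex <- default_lexicon()
  expect_gte(nrow(lex$patterns), 15L)
  expect_true("%algia%" %in% lex$patterns$raw)
  expect_identical(
    lex$patterns$canonical_word[lex$patterns$raw == "%algia%"], "Algia"
  )
  expect_setequal(
    lex$full_terms$term, c("mittelschmerz", "lumbago", "migraine")
  )
  expect_setequal(
    lex$exclusion_terms,
    c("paint", "painting", "paints", "painted", "spain", "attached",
      "attaches")
  )
  expect_length(intersect(lex$full_terms$term, lex$exclusion_terms), 0L)

  # every documented example word is matched by its own row's pattern
  examples <- list(
    "%pain%" = c("pains", "painful"),
    "%ache" = c("headache", "backache"),
    "%aches" = c("headaches", "aches"),
    "sore%" = c("soreness", "sores"),
    "%algesi%" = c("analgesia", "analgesic"),
    "%algia%" = c("proctalgia", "neuralgias"),
    "%burn%" = c("heartburn", "burns", "burning"),
    "colic%" = "colicky",
    "cramp%" = c("cramps", "cramping"),
    "%dynia%" = c("allodynia", "glossodynia"),
    "hurt%" = c("hurts", "hurting"),
    "rheumati%" = c("rheumatic", "rheumatism"),
    "sciati%" = c("sciatic", "sciatica"),
    "spasm%" = c("spasms", "spasmic"),
    "tender%" = "tenderness"
  )
  for (raw in names(examples)) {
    m <- compile_pattern(raw)
    expect_true(all(m(examples[[raw]])), label = raw)
  }
})

test_that("find_mentions locates and labels tokens as documented", {
  lex <- default_lexicon()
  d1 <- tibble::tibble(doc_id = "a", text = "He suffers from severe headaches")
  m1 <- find_mentions(d1, lex)
  expect_identical(m1$surface, "headaches")
  expect_identical(m1$canonical_word, "Ache")
  expect_false(m1$excluded)

  d2 <- tibble::tibble(doc_id = "b",
                       text = "She painted a picture of the situation")
  m2 <- find_mentions(d2, lex)
  expect_identical(m2$surface, "painted")
  expect_identical(m2$canonical_word, "Pain")
  expect_true(m2$excluded)

  d3 <- tibble::tibble(doc_id = "c", text = "The meeting was uneventful")
  expect_identical(nrow(find_mentions(d3, lex)), 0L)

  empty_lex <- pain_lexicon(
    tibble::tibble(raw = character(), canonical_word = character())
  )
  expect_error(find_mentions(d1, empty_lex), "empty")
})

test_that("mention offsets slice back to their surface on random documents", {
  lex <- default_lexicon()
  withr::with_seed(421, {
    for (k in 1:25) {
      doc <- random_document(paste0("r", k), n_tokens = sample(5:60, 1))
      m <- find_mentions(doc, lex)
      if (nrow(m)) {
        expect_identical(
          substring(doc$text, m$start + 1L, m$end), m$surface
        )
        expect_true(all(diff(m$start) > 0))
        expect_true(all(m$end[-nrow(m)] <= m$start[-1])) # non-overlapping
      }
      # determinism
      expect_identical(m, find_mentions(doc, lex))
      # case-insensitivity: spans are unchanged under uppercasing
      up <- doc
      up$text <- toupper(up$text)
      mu <- find_mentions(up, lex)
      expect_identical(mu[c("start", "end", "pattern")],
                       m[c("start", "end", "pattern")])
    }
  })
})

test_that("find_mentions agrees with the brute-force per-token oracle", {
  lex <- default_lexicon()
  withr::with_seed(99, {
    for (k in 1:20) {
      doc <- random_document(paste0("o", k), n_tokens = sample(3:50, 1))
      got <- as.data.frame(find_mentions(doc, lex))
      want <- oracle_find_mentions(doc, lex)
      rownames(want) <- NULL
      expect_equal(got, want, ignore_attr = TRUE)
    }
  })
})

test_that("coverage audit reports exactly the unmatched terms", {
  lex <- default_lexicon()
  r <- verify_coverage(c("backache", "sciatica"), lex)
  expect_true(all(r$covered))
  expect_length(attr(r, "uncovered"), 0L)

  expect_identical(nrow(verify_coverage(character(), lex)), 0L)

  r2 <- verify_coverage(c("dysmenorrhoea", "back pain"), lex)
  expect_identical(attr(r2, "uncovered"), "dysmenorrhoea")
})

test_that("lexicon constructor enforces its invariants", {
  expect_error(
    pain_lexicon(
      tibble::tibble(raw = "%pain%", canonical_word = "Pain"),
      full_terms = tibble::tibble(term = "Lumbago",
                                  canonical_word = "Lumbago")
    ),
    "lowercase"
  )
  expect_error(
    pain_lexicon(
      tibble::tibble(raw = "%pain%", canonical_word = "Pain"),
      full_terms = tibble::tibble(term = "lumbago",
                                  canonical_word = "Lumbago"),
      exclusion_terms = "lumbago"
    ),
    "both"
  )
})
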