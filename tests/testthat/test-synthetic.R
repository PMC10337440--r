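test_that("identical seeds give byte-identical corpora", {
  cfg <- synthetic_config(seed = 7, n_patients = 10,
                          words_per_doc_mean = 80)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$gold, c2$gold)

  c3 <- generate_corpus(synthetic_config(seed = 8, n_patients = 10,
                                         words_per_doc_mean = 80))
  expect_false(identical(c1$documents$text, c3$documents$text))
})

test_that("degenerate mixtures are honoured exactly", {
  cfg <- synthetic_config(
    seed = 3, n_patients = 60, words_per_doc_mean = 40,
    relevance_mix = c(relevant = 1, not_relevant = 0, negated = 0),
    incorrect_rate = 0
  )
  corp <- generate_corpus(cfg)
  expect_gt(nrow(corp$gold), 300L)
  expect_true(all(corp$gold$correct == "yes"))
  expect_true(all(corp$gold$relevance == "relevant"))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(
    synthetic_config(relevance_mix = c(relevant = 0.8, not_relevant = 0.3,
                                       negated = 0.1)),
    "relevance_mix"
  )
  expect_error(synthetic_config(incorrect_rate = 1.5), "incorrect_rate")
  expect_error(synthetic_config(words_per_doc_mean = -5),
               "words_per_doc_mean")
})

test_that("every gold span slices to its surface", {
  corp <- generate_corpus(synthetic_config(seed = 41, n_patients = 30,
                                           words_per_doc_mean = 80))
  g <- corp$gold
  txt <- stats::setNames(corp$documents$text, corp$documents$doc_id)
  expect_identical(
    substring(txt[g$doc_id], g$start + 1L, g$end),
    stats::setNames(g$surface, g$doc_id)
  )
})

test_that("gold label frequencies recover the configured mixtures", {
  cfg <- synthetic_config(seed = 13, n_patients = 250,
                          words_per_doc_mean = 50)
  corp <- generate_corpus(cfg)
  g <- dplyr::filter(corp$gold, correct == "yes")
  n <- nrow(g)
  expect_gte(n, 1500L)
  tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

  for (lv in names(cfg$relevance_mix)) {
    p <- unname(cfg$relevance_mix[lv])
    expect_lt(abs(mean(g$relevance == lv) - p), tol3(p, n) + 1e-9,
              label = paste("relevance", lv))
  }
  rel <- dplyr::filter(g, relevance == "relevant")
  p <- cfg$anatomy_rate_given_relevant
  expect_lt(abs(mean(rel$anatomy == "mentioned") - p),
            tol3(p, nrow(rel)))
  for (lv in names(cfg$character_mix)) {
    p <- unname(cfg$character_mix[lv])
    expect_lt(abs(mean(g$character == lv) - p), tol3(p, n) + 1e-9,
              label = paste("character", lv))
  }
  for (lv in names(cfg$management_mix)) {
    p <- unname(cfg$management_mix[lv])
    expect_lt(abs(mean(g$management == lv) - p), tol3(p, n) + 1e-9,
              label = paste("management", lv))
  }
  # incorrect rate over all matches
  p <- cfg$incorrect_rate
  expect_lt(abs(mean(corp$gold$correct == "no") - p),
            tol3(p, nrow(corp$gold)))
})

test_that("double annotation perturbs labels at the requested rate", {
  # large synthetic gold table built directly; the perturbation operates on
  # label columns only
  n <- 5000L
  gold <- tibble::tibble(
    doc_id = sprintf("d%05d", seq_len(n)), start = 0L, end = 4L,
    surface = "pain", pattern = "%pain%", canonical_word = "Pain",
    excluded = FALSE, correct = "yes",
    relevance = sample(c("relevant", "negated", "not_relevant"), n, TRUE),
    anatomy = sample(c("mentioned", "n/a"), n, TRUE),
    anatomy_location = NA_character_,
    character = sample(c("chronic", "other", "n/a"), n, TRUE),
    character_surface = NA_character_,
    management = sample(c("medication", "other", "n/a"), n, TRUE)
  )
  pair <- generate_double_annotations(gold, disagreement_rate = 0.1,
                                      seed = 5)
  expect_identical(pair$a, gold)
  flip <- mean(pair$b$character != gold$character)
  expect_lt(abs(flip - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # rate 0: perfect copy; rate 1 on a binary attribute: forced flip
  p0 <- generate_double_annotations(gold, 0, seed = 1)
  expect_identical(p0$b, gold)
  p1 <- generate_double_annotations(gold, 1, seed = 1)
  expect_true(all(p1$b$anatomy != gold$anatomy))
  expect_identical(
    generate_double_annotations(gold, 0.3, seed = 9)$b,
    generate_double_annotations(gold, 0.3, seed = 9)$b
  )
})

test_that("the filler bank contains no lexicon token", {
  lex <- default_lexicon()
  for (s in paincorpus:::synthetic_filler_bank()) {
    m <- find_mentions(tibble::tibble(doc_id = "f", text = s), lex)
    expect_identical(nrow(m), 0L, label = s)
  }
})

test_that("the annotator recovers gold labels on rule-covered templates", {
  corp <- generate_corpus(synthetic_config(seed = 17, n_patients = 40,
                                           words_per_doc_mean = 120))
  pred <- annotate_corpus(corp$documents)
  g <- dplyr::arrange(corp$gold, doc_id, start)
  p <- dplyr::arrange(pred, doc_id, start)
  expect_identical(nrow(g), nrow(p))
  expect_identical(g$start, p$start)
  labs <- c("correct", "relevance", "anatomy", "character", "management")
  recovery <- mean(unlist(g[labs]) == unlist(p[labs]))
  expect_gte(recovery, 0.95)
})
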