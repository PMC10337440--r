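# Independent oracles used to cross-check the implementation. These share
# no code with the package: matching is done with base string predicates,
# tokenization with a character scan, and kappa from a full contingency
# table.

# Brute-force wildcard semantics: a leading/trailing "%" relaxes the anchor
# on that side; no "%" means exact equality. Tokens are alphabetic already.
oracle_match <- function(raw, token) {
  lead <- startsWith(raw, "%")
  trail <- endsWith(raw, "%")
  body <- tolower(gsub("%", "", raw))
  token <- tolower(token)
  if (lead && trail) {
    grepl(body, token, fixed = TRUE)
  } else if (lead) {
    endsWith(token, body)
  } else if (trail) {
    startsWith(token, body)
  } else {
    token == body
  }
}

# Character-scan tokenizer: maximal alphabetic runs with 0-based, half-open
# offsets.
oracle_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_alpha <- grepl("[[:alpha:]]", chars)
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (is_alpha[i]) {
      j <- i
      while (j < n && is_alpha[j + 1L]) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(
        token = paste(chars[i:j], collapse = ""),
        start = i - 1L, end = j
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  toks
}

# Per-token scan of every pattern and full term with explicit precedence:
# longest literal part wins, ties alphabetical by raw pattern.
oracle_find_mentions <- function(doc, lexicon) {
  cand <- rbind(
    data.frame(
      raw = lexicon$patterns$raw,
      canonical = lexicon$patterns$canonical_word,
      lit = nchar(gsub("%", "", lexicon$patterns$raw))
    ),
    if (nrow(lexicon$full_terms)) {
      data.frame(
        raw = lexicon$full_terms$term,
        canonical = lexicon$full_terms$canonical_word,
        lit = nchar(lexicon$full_terms$term)
      )
    }
  )
  out <- list()
  for (tk in oracle_tokenize(doc$text)) {
    hits <- which(vapply(
      cand$raw, function(r) oracle_match(r, tk$token), logical(1)
    ))
    if (length(hits)) {
      best <- hits[order(-cand$lit[hits], cand$raw[hits])][1]
      out[[length(out) + 1L]] <- data.frame(
        doc_id = doc$doc_id, start = tk$start, end = tk$end,
        surface = tk$token, pattern = cand$raw[best],
        canonical_word = cand$canonical[best],
        excluded = tolower(tk$token) %in% lexicon$exclusion_terms
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      doc_id = character(), start = integer(), end = integer(),
      surface = character(), pattern = character(),
      canonical_word = character(), excluded = logical()
    ))
  }
  do.call(rbind, out)
}

# Contingency-table kappa: observed diagonal vs expected from margins.
oracle_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  tb <- table(factor(a, cats), factor(b, cats))
  n <- sum(tb)
  po <- sum(diag(tb)) / n
  pe <- sum(rowSums(tb) * colSums(tb)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(if (po == 1) 1 else NA_real_)
  }
  (po - pe) / (1 - pe)
}

# Naive interpreter of the relevance precedence, written as literal rule
# tests over a token list; independent of the package's window machinery.
# `tokens` are the lowercased window tokens, `mention_idx` the mention's
# index, `punct_before`/`punct_after` the non-space characters touching the
# mention.
oracle_relevance <- function(tokens, mention_idx, punct_before, punct_after,
                             gz) {
  if (identical(punct_before, "?") || identical(punct_after, "?")) {
    return("not_relevant")
  }
  for (i in seq_along(tokens)) {
    if (i < mention_idx && tokens[i] %in% gz$experiencer_triggers) {
      return("not_relevant")
    }
  }
  joined <- paste(tokens, collapse = " ")
  for (ph in gz$hypothetical_triggers) {
    if (grepl(paste0("\\b", ph, "\\b"), joined)) {
      return("not_relevant")
    }
  }
  has_caus <- any(grepl("^caus(e|es|ed|ing)$", tokens))
  if (has_caus && any(tokens %in% gz$emotional_triggers)) {
    return("not_relevant")
  }
  for (i in seq_along(tokens)) {
    if (i < mention_idx && mention_idx - i <= gz$negation_window &&
        tokens[i] %in% gz$negation_triggers) {
      return("negated")
    }
  }
  if (mention_idx < length(tokens) && tokens[mention_idx + 1L] == "free") {
    return("negated")
  }
  "relevant"
}

# The six worked example sentences with their expected label rows.
table3_fixture <- function() {
  tibble::tibble(
    doc_id = sprintf("ex%d", 1:6),
    text = c(
      "He likes burning things",
      "She painted a picture of the situation",
      "She is in constant pain",
      "He suffers from severe headaches",
      "He is not on painkillers",
      "Afraid I will be in pain if surgery is unsuccessful"
    ),
    surface = c("burning", "painted", "pain", "headaches", "painkillers",
                "pain"),
    keyword = c("Burn", "Pain", "Pain", "Ache", "Pain", "Pain"),
    correct = c("no", "no", "yes", "yes", "yes", "yes"),
    relevance = c("n/a", "n/a", "relevant", "relevant", "negated",
                  "not_relevant"),
    anatomy = c("n/a", "n/a", "n/a", "mentioned", "n/a", "n/a"),
    character = c("n/a", "n/a", "other", "other", "n/a", "n/a"),
    management = c("n/a", "n/a", "n/a", "n/a", "medication", "n/a")
  )
}

# Random clinical-looking text built from a mixed vocabulary (pain words,
# false-positive lookalikes, neutral words) and punctuation, for property
# tests.
random_document <- function(id, n_tokens, seed_words = NULL) {
  vocab <- c(
    "pain", "pains", "painful", "painted", "spain", "headache", "aches",
    "soreness", "burning", "cramps", "hurts", "tenderness", "sciatica",
    "visit", "plan", "review", "sleep", "mood", "team", "week", "notes",
    seed_words
  )
  seps <- c(" ", " ", " ", ". ", ", ", "\n", " - ", "? ")
  toks <- sample(vocab, n_tokens, replace = TRUE)
  caps <- sample(c(TRUE, FALSE), n_tokens, replace = TRUE, prob = c(.2, .8))
  toks <- ifelse(
    caps,
    paste0(toupper(substring(toks, 1, 1)), substring(toks, 2)),
    toks
  )
  text <- paste0(
    paste0(toks, sample(seps, n_tokens, replace = TRUE), collapse = ""),
    "end"
  )
  tibble::tibble(doc_id = id, text = text)
}
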