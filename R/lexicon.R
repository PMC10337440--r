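#' Compile a wildcard pain-term pattern into a token matcher
#'
#' Lexicon terms are generalised with `%` placeholders so that a short list of
#' patterns covers a large vocabulary of pain-related words: `%pain%` matches
#' "pain", "pains", "painful" (and, deliberately over-broadly, "painted" and
#' "spain" -- such false positives are weeded out later, at the correctness
#' stage of annotation). A `%` matches zero or more alphabetic characters
#' *within a single token*; matching is case-insensitive and anchored, so a
#' pattern with no leading `%` must match from the token's first character and
#' one with no trailing `%` must match through its last.
#'
#' @param raw Pattern string: a word with at most one leading and one trailing
#'   `%`. A `%` anywhere else is an error. A pattern with no `%` matches the
#'   token literally (and exactly).
#' @return A predicate function of one argument: a character vector of tokens,
#'   returning a logical vector of the same length. The compiled regular
#'   expression is attached as attribute `"regex"` and the length of the
#'   literal (non-`%`) part as attribute `"literal_nchar"`.
#' @examples
#' m <- compile_pattern("%ache")
#' m(c("headache", "backache", "attached"))
#' @export
compile_pattern <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  if (!nzchar(raw)) {
    stop("pattern is empty", call. = FALSE)
  }
  body <- sub("^%", "", sub("%$", "", raw))
  if (grepl("%", body, fixed = TRUE)) {
    stop(
      "malformed pattern ", encodeString(raw, quote = '"'),
      ": '%' is only allowed at the start or end of a pattern",
      call. = FALSE
    )
  }
  if (!nzchar(body)) {
    stop(
      "malformed pattern ", encodeString(raw, quote = '"'),
      ": no literal characters", call. = FALSE
    )
  }
  lead <- startsWith(raw, "%")
  trail <- endsWith(raw, "%")
  rx <- paste0(
    "^",
    if (lead) "[[:alpha:]]*",
    stringr::str_escape(tolower(body)),
    if (trail) "[[:alpha:]]*",
    "$"
  )
  f <- function(tokens) {
    grepl(rx, tolower(tokens), perl = TRUE)
  }
  attr(f, "regex") <- rx
  attr(f, "literal_nchar") <- nchar(body)
  f
}

#' Construct a pain lexicon
#'
#' A lexicon bundles three term sets: wildcard `patterns` (see
#' [compile_pattern()]), literal `full_terms` used without wildcards (words
#' whose shape does not generalise, e.g. "mittelschmerz"), and
#' `exclusion_terms` -- known false-positive surface forms ("paint", "spain",
#' ...) that the patterns inevitably pick up. Exclusion terms are *flagged*,
#' not dropped, at match time; the decision that a flagged match is not a real
#' pain mention belongs to the annotation stage, mirroring manual practice
#' where such hits are eliminated during annotation rather than extraction.
#'
#' @param patterns Data frame with columns `raw` (wildcard pattern) and
#'   `canonical_word` (the base pain word the pattern generalises).
#' @param full_terms Data frame with columns `term` (lowercase literal) and
#'   `canonical_word`.
#' @param exclusion_terms Character vector of lowercase surface forms.
#' @return An object of class `pain_lexicon`.
#' @seealso [default_lexicon()], [read_lexicon()], [write_lexicon()]
#' @export
pain_lexicon <- function(patterns, full_terms = NULL, exclusion_terms = character()) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("raw", "canonical_word") %in% names(patterns)))
  if (is.null(full_terms)) {
    full_terms <- tibble::tibble(term = character(), canonical_word = character())
  }
  full_terms <- tibble::as_tibble(full_terms)
  stopifnot(all(c("term", "canonical_word") %in% names(full_terms)))
  exclusion_terms <- as.character(exclusion_terms)

  if (any(full_terms$term != tolower(full_terms$term))) {
    stop("full_terms must be lowercase", call. = FALSE)
  }
  if (any(exclusion_terms != tolower(exclusion_terms))) {
    stop("exclusion_terms must be lowercase", call. = FALSE)
  }
  both <- intersect(full_terms$term, exclusion_terms)
  if (length(both)) {
    stop(
      "terms cannot be both full terms and exclusion terms: ",
      paste(both, collapse = ", "), call. = FALSE
    )
  }
  if (grepl("%", paste(patterns$canonical_word, collapse = ""), fixed = TRUE)) {
    stop("canonical_word must not contain '%'", call. = FALSE)
  }

  # compile once; matchers are reused for every document
  matchers <- lapply(patterns$raw, compile_pattern)
  patterns$literal_nchar <- vapply(matchers, attr, integer(1), "literal_nchar")

  structure(
    list(
      patterns = patterns,
      full_terms = full_terms,
      exclusion_terms = exclusion_terms,
      matchers = matchers
    ),
    class = "pain_lexicon"
  )
}

#' @export
print.pain_lexicon <- function(x, ...) {
  cat(
    "<pain_lexicon>: ", nrow(x$patterns), " wildcard patterns, ",
    nrow(x$full_terms), " literal terms, ",
    length(x$exclusion_terms), " exclusion terms\n",
    sep = ""
  )
  cat(
    "  patterns:  ", paste(x$patterns$raw, collapse = " "), "\n",
    "  literals:  ", paste(x$full_terms$term, collapse = " "), "\n",
    "  excluded:  ", paste(x$exclusion_terms, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Default pain lexicon
#'
#' The shipped lexicon: 16 wildcard patterns covering 15 base pain words
#' (`ache` is generalised by three patterns -- `%ache`, `%aches`, `achin%` --
#' rather than a single `%ache%`, so that "attached"/"attaches"-type false
#' positives are mostly avoided), plus literal terms whose shape does not
#' generalise ("mittelschmerz", "lumbago", "migraine"), plus the exclusion
#' list of known false-positive surfaces. Override or extend it by editing a
#' config file written with [write_lexicon()] and loading it with
#' [read_lexicon()].
#'
#' @return A `pain_lexicon`.
#' @examples
#' lex <- default_lexicon()
#' lex
#' @export
default_lexicon <- function() {
  patterns <- tibble::tribble(
    ~raw,        ~canonical_word,
    "%pain%",    "Pain",
    "%ache",     "Ache",
    "%aches",    "Ache",
    "achin%",    "Ache",
    "sore%",     "Sore",
    "%algesi%",  "Algesia",
    "%algia%",   "Algia",
    "%burn%",    "Burn",
    "colic%",    "Colic",
    "cramp%",    "Cramp",
    "%dynia%",   "Dynia",
    "hurt%",     "Hurt",
    "rheumati%", "Rheumatic",
    "sciati%",   "Sciatic",
    "spasm%",    "Spasm",
    "tender%",   "Tender"
  )
  full_terms <- tibble::tribble(
    ~term,           ~canonical_word,
    "mittelschmerz", "Mittelschmerz",
    "lumbago",       "Lumbago",
    "migraine",      "Migraine"
  )
  exclusion_terms <- c(
    "paint", "painting", "paints", "painted",
    "spain", "attached", "attaches"
  )
  pain_lexicon(patterns, full_terms, exclusion_terms)
}

# Tokenize text into maximal alphabetic runs.
# Returns a tibble with token, start, end (0-based, half-open character
# offsets into `text`). Hyphens, digits, apostrophes: all separators.
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  m <- gregexpr("[[:alpha:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(
      token = character(), start = integer(), end = integer()
    ))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1L),
    start = as.integer(m) - 1L,
    end = as.integer(m) + len - 1L
  )
}

# Match a vector of tokens against every pattern and full term of a lexicon.
# Returns, per token, the index of the winning pattern (longest literal part,
# ties broken alphabetically by raw pattern) or the winning full term.
# Full terms compete as fully-literal patterns.
match_tokens <- function(tokens, lexicon) {
  n <- length(tokens)
  out <- tibble::tibble(
    matched = logical(n),
    pattern = NA_character_,
    canonical_word = NA_character_
  )
  if (n == 0L) {
    return(out)
  }
  low <- tolower(tokens)
  uniq <- unique(low)

  cand_raw <- c(lexicon$patterns$raw, lexicon$full_terms$term)
  cand_canon <- c(lexicon$patterns$canonical_word, lexicon$full_terms$canonical_word)
  cand_lit <- c(lexicon$patterns$literal_nchar, nchar(lexicon$full_terms$term))
  # resolve precedence once: order candidates worst-to-best, later assignments
  # overwrite earlier ones, so the longest-literal (alphabetically-first on
  # ties) candidate ends up winning
  ord <- order(cand_lit, -rank(cand_raw))

  hit <- rep(NA_integer_, length(uniq))
  np <- nrow(lexicon$patterns)
  for (i in ord) {
    ok <- if (i <= np) {
      lexicon$matchers[[i]](uniq)
    } else {
      uniq == cand_raw[i]
    }
    hit[ok] <- i
  }
  idx <- hit[match(low, uniq)]
  out$matched <- !is.na(idx)
  out$pattern <- cand_raw[idx]
  out$canonical_word <- cand_canon[idx]
  out
}

#' Locate candidate pain mentions in a document
#'
#' Tokenizes the text into maximal alphabetic runs (anything else is a
#' separator) and reports every token matched by a lexicon pattern or literal
#' term. When several patterns match one token the pattern with the longest
#' literal (non-`%`) part wins, ties broken alphabetically by raw pattern.
#' Matches flagged `excluded` have a surface form on the lexicon's exclusion
#' list; they are kept in the output because the correctness decision belongs
#' to the annotator, not the extractor.
#'
#' @param doc A one-row data frame (or list) with at least `doc_id` and
#'   `text`.
#' @param lexicon A [pain_lexicon()].
#' @return A tibble of mentions, one row per matched token, sorted by `start`:
#'   `doc_id`, `start`, `end` (0-based, half-open character offsets),
#'   `surface`, `pattern`, `canonical_word`, `excluded`. Token matches are
#'   disjoint by construction, so mentions never overlap.
#' @examples
#' doc <- tibble::tibble(doc_id = "d1", text = "He suffers from severe headaches")
#' find_mentions(doc, default_lexicon())
#' @export
find_mentions <- function(doc, lexicon) {
  stopifnot(inherits(lexicon, "pain_lexicon"))
  if (nrow(lexicon$patterns) + nrow(lexicon$full_terms) == 0L) {
    stop("lexicon is empty", call. = FALSE)
  }
  doc <- as.list(doc)
  text <- doc$text
  stopifnot(is.character(text), length(text) == 1L)

  toks <- tokenize(text)
  m <- match_tokens(toks$token, lexicon)
  keep <- m$matched
  tibble::tibble(
    doc_id = doc$doc_id,
    start = toks$start[keep],
    end = toks$end[keep],
    surface = toks$token[keep],
    pattern = m$pattern[keep],
    canonical_word = m$canonical_word[keep],
    excluded = tolower(toks$token[keep]) %in% lexicon$exclusion_terms
  )
}

#' Find pain mentions across a corpus of documents
#'
#' @param documents Data frame with columns `doc_id` and `text` (one row per
#'   document).
#' @inheritParams find_mentions
#' @return A tibble of mentions (see [find_mentions()]) over all documents.
#' @export
find_mentions_corpus <- function(documents, lexicon) {
  documents <- tibble::as_tibble(documents)
  purrr::map_dfr(
    seq_len(nrow(documents)),
    function(i) find_mentions(documents[i, ], lexicon)
  )
}

#' Audit lexicon coverage of an external term list
#'
#' Wildcard generalisation trades a long curated term list for a short pattern
#' list; this audits the trade. Each term is tokenized the same way documents
#' are; a term counts as covered when at least one of its tokens is matched by
#' a pattern or full term.
#'
#' @param term_list Character vector of terms (single- or multi-word).
#' @param lexicon A [pain_lexicon()].
#' @return A tibble with columns `term` and `covered`; the attribute
#'   `"uncovered"` holds the uncovered terms as a character vector.
#' @examples
#' verify_coverage(c("backache", "sciatica", "dysmenorrhoea"), default_lexicon())
#' @export
verify_coverage <- function(term_list, lexicon) {
  stopifnot(length(term_list) >= 0, is.character(term_list))
  covered <- vapply(term_list, function(term) {
    toks <- tokenize(term)$token
    if (length(toks) == 0L) {
      return(FALSE)
    }
    any(match_tokens(toks, lexicon)$matched)
  }, logical(1), USE.NAMES = FALSE)
  out <- tibble::tibble(term = term_list, covered = covered)
  attr(out, "uncovered") <- term_list[!covered]
  out
}
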