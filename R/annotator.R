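#' @keywords internal
"_PACKAGE"

# Label vocabularies used throughout the annotation scheme.
pain_labels <- list(
  correct = c("yes", "no"),
  relevance = c("relevant", "negated", "not_relevant", "n/a"),
  anatomy = c("mentioned", "n/a"),
  character = c("chronic", "other", "n/a"),
  management = c("medication", "other", "n/a")
)

# Attributes carried by every annotation besides the mention itself.
pain_attributes <- c("relevance", "anatomy", "character", "management")

#' Extract the context window for a mention
#'
#' Annotation decisions are made from the sentence containing the mention:
#' text between the nearest sentence boundaries, where a boundary is `.`,
#' `!` or `?` followed by whitespace and a capital letter, or a newline.
#' Each side is capped at 300 characters from the mention, so pathological
#' unbroken lines yield a bounded window.
#'
#' @param doc A one-row data frame (or list) with a `text` field.
#' @param mention A one-row data frame (or list) with 0-based half-open
#'   `start`/`end` offsets into `doc$text`.
#' @param cap Maximum number of characters kept on each side of the mention.
#' @return The window as a length-1 character vector; the 0-based offset of
#'   its first character within the document is attached as attribute
#'   `"start"`.
#' @examples
#' doc <- list(doc_id = "d", text = "Seen today. She is in constant pain. Plan made.")
#' context_window(doc, list(start = 31, end = 35))
#' @export
context_window <- function(doc, mention, cap = 300L) {
  doc <- as.list(doc)
  mention <- as.list(mention)
  text <- doc$text
  n <- nchar(text)
  m_start <- mention$start # 0-based
  m_end <- mention$end
  stopifnot(m_start >= 0, m_end <= n, m_start < m_end)

  b <- gregexpr("[.!?](?=[[:space:]]+[[:upper:]])|\n", text, perl = TRUE)[[1]]
  bpos <- if (b[1] == -1L) integer() else as.integer(b) # 1-based boundary char

  # left cut: last boundary strictly before the mention; skip boundary char
  # and the whitespace that follows it
  left1 <- 1L # 1-based window start
  lb <- bpos[bpos <= m_start] # boundary char at or before 0-based start
  if (length(lb)) {
    p <- max(lb) + 1L
    while (p <= n && grepl("^[[:space:]]$", substring(text, p, p))) {
      p <- p + 1L
    }
    left1 <- p
  }
  # right cut: first boundary at or after the mention end; sentence-final
  # punctuation is part of the sentence, a newline is not
  right1 <- n # 1-based inclusive window end
  rb <- bpos[bpos >= m_end + 1L] # boundary char at or after the mention end
  if (length(rb)) {
    p <- min(rb)
    right1 <- if (substring(text, p, p) == "\n") p - 1L else p
  }

  left1 <- max(left1, m_start + 1L - cap)
  right1 <- min(right1, m_end + cap)
  out <- substring(text, left1, right1)
  attr(out, "start") <- as.integer(left1) - 1L # back to 0-based
  out
}

# --- window utilities ---------------------------------------------------

# Tokens of a window with the index of the mention's own token.
window_tokens <- function(window, rel_start) {
  toks <- tokenize(as.character(window))
  idx <- which(toks$start <= rel_start & toks$end > rel_start)
  list(tokens = tolower(toks$token), starts = toks$start, ends = toks$end,
       mention_idx = if (length(idx)) idx[1] else NA_integer_)
}

rel_offsets <- function(mention, window) {
  off <- attr(window, "start")
  if (is.null(off)) off <- 0L
  m <- as.list(mention)
  c(start = m$start - off, end = m$end - off)
}

# Whole-word phrase presence in a lowercased window.
phrase_in_window <- function(window, phrases) {
  if (!length(phrases)) {
    return(FALSE)
  }
  low <- tolower(as.character(window))
  any(vapply(
    phrases,
    function(p) {
      grepl(paste0("\\b", stringr::str_escape(p), "\\b"), low, perl = TRUE)
    },
    logical(1)
  ))
}

#' Decide whether a matched mention is a pain mention in the medical sense
#'
#' A match is incorrect if its surface form is on the lexicon's exclusion
#' list (lexical false positives such as "painted" or "spain"), or if a
#' "burn"-family match is immediately followed by an inanimate referent
#' ("burn marks", "burning incense", "burnt toast"): burning applied to an
#' object is not pain. Everything else is accepted; finer assertions are the
#' relevance stage's job.
#'
#' @param mention One-row data frame (or list) with `surface`,
#'   `canonical_word`, `excluded`, and offsets.
#' @param window Context window from [context_window()].
#' @param lexicon A [pain_lexicon()]; consulted when the mention has no
#'   `excluded` flag.
#' @param gazetteers A [pain_gazetteers()].
#' @return `"yes"` or `"no"`.
#' @export
classify_correct <- function(mention, window, lexicon = default_lexicon(),
                             gazetteers = default_gazetteers()) {
  m <- as.list(mention)
  excluded <- m$excluded
  if (is.null(excluded)) {
    excluded <- tolower(m$surface) %in% lexicon$exclusion_terms
  }
  if (isTRUE(excluded)) {
    return("no")
  }
  if (identical(m$canonical_word, "Burn")) {
    ro <- rel_offsets(mention, window)
    wt <- window_tokens(window, ro["start"])
    i <- wt$mention_idx
    if (!is.na(i)) {
      after <- wt$tokens[seq_len(length(wt$tokens)) > i]
      after <- utils::head(after, 2L)
      if (any(after %in% gazetteers$inanimate_referents)) {
        return("no")
      }
    }
  }
  "yes"
}

#' Classify the relevance of a correct pain mention
#'
#' Applies the assertion rules in a fixed precedence:
#' \enumerate{
#'   \item uncertainty: a question mark immediately adjacent to the mention
#'     (before or after, ignoring whitespace) marks it inconclusive ->
#'     `not_relevant`;
#'   \item experiencer: a third-person experiencer trigger before the
#'     mention in the window attributes the pain to someone other than the
#'     patient -> `not_relevant`;
#'   \item hypothetical or metaphorical: a hypothetical trigger anywhere in
#'     the window ("fear of", "if", "sore thumb", ...), or a
#'     relationship-context trigger alongside a "causing" verb (emotional
#'     rather than physical pain; best-effort) -> `not_relevant`;
#'   \item negation: a negation trigger within `negation_window` tokens
#'     before the mention, or the "<mention> free" frame -> `negated`;
#'   \item otherwise `relevant`.
#' }
#'
#' @inheritParams classify_correct
#' @return One of `"relevant"`, `"negated"`, `"not_relevant"`.
#' @examples
#' doc <- list(text = "He is not on painkillers")
#' men <- list(start = 13, end = 24, surface = "painkillers")
#' w <- context_window(doc, men)
#' classify_relevance(men, w)
#' @export
classify_relevance <- function(mention, window, gazetteers = default_gazetteers()) {
  ro <- rel_offsets(mention, window)
  wtext <- as.character(window)

  # (1) uncertainty: "?" adjacent to the mention, whitespace ignored
  before <- substring(wtext, 1L, ro["start"])
  after <- substring(wtext, ro["end"] + 1L, nchar(wtext))
  if (grepl("\\?[[:space:]]*$", before) || grepl("^[[:space:]]*\\?", after)) {
    return("not_relevant")
  }

  wt <- window_tokens(window, ro["start"])
  i <- wt$mention_idx

  # (2) experiencer before the mention
  if (!is.na(i)) {
    exp_pos <- which(wt$tokens %in% gazetteers$experiencer_triggers)
    if (any(exp_pos < i)) {
      return("not_relevant")
    }
  }

  # (3) hypothetical / metaphorical / emotional context
  if (phrase_in_window(window, gazetteers$hypothetical_triggers)) {
    return("not_relevant")
  }
  if (grepl("\\bcaus(e|es|ed|ing)\\b", tolower(wtext), perl = TRUE) &&
      phrase_in_window(window, gazetteers$emotional_triggers)) {
    return("not_relevant")
  }

  # (4) negation within scope before the mention; "<mention> free" frame
  if (!is.na(i)) {
    neg_pos <- which(wt$tokens %in% gazetteers$negation_triggers)
    if (any(neg_pos < i & i - neg_pos <= gazetteers$negation_window)) {
      return("negated")
    }
    if (i < length(wt$tokens) && wt$tokens[i + 1L] == "free") {
      return("negated")
    }
  }

  "relevant"
}

#' Detect an anatomical location for a pain mention
#'
#' A location is attached when (a) the mention surface itself encodes one
#' (compound words: headache -> head, backache -> back, heartburn -> chest),
#' or (b) a body-part term occurs within `proximity_window` tokens of the
#' mention in the window. Abdominal and pelvic terms normalize to "abdomen".
#' When several terms are in range the nearest wins (ties: the earlier one).
#'
#' @inheritParams classify_correct
#' @return A list with elements `anatomy` (`"mentioned"` or `"n/a"`) and
#'   `location` (normalized label, or `NA_character_`).
#' @export
detect_anatomy <- function(mention, window, gazetteers = default_gazetteers()) {
  m <- as.list(mention)
  surf <- tolower(m$surface)
  comp <- gazetteers$anatomy_compounds
  if (surf %in% names(comp)) {
    return(list(anatomy = "mentioned", location = unname(comp[[surf]])))
  }
  ro <- rel_offsets(mention, window)
  wt <- window_tokens(window, ro["start"])
  i <- wt$mention_idx
  if (!is.na(i)) {
    amap <- gazetteers$anatomy_map
    pos <- which(wt$tokens %in% names(amap) & seq_along(wt$tokens) != i)
    pos <- pos[abs(pos - i) <= gazetteers$proximity_window]
    if (length(pos)) {
      best <- pos[order(abs(pos - i), pos)][1]
      return(list(
        anatomy = "mentioned",
        location = unname(amap[[wt$tokens[best]]])
      ))
    }
  }
  list(anatomy = "n/a", location = NA_character_)
}

#' Classify the character of a pain mention
#'
#' The character is `chronic` only when the literal token "chronic" occurs
#' within `proximity_window` tokens before the mention; duration words like
#' "ongoing" are inconclusive and never count. Otherwise a qualitative
#' descriptor ("shooting", "throbbing", "severe", "constant", ...) within
#' `proximity_window` tokens gives `other`, as does the special frame
#' "period <mention>". Everything else is `n/a`.
#'
#' @inheritParams classify_correct
#' @return A list with elements `character` (`"chronic"`, `"other"` or
#'   `"n/a"`) and `descriptor` (the surface descriptor, or `NA_character_`).
#' @export
classify_character <- function(mention, window, gazetteers = default_gazetteers()) {
  ro <- rel_offsets(mention, window)
  wt <- window_tokens(window, ro["start"])
  i <- wt$mention_idx
  if (is.na(i)) {
    return(list(character = "n/a", descriptor = NA_character_))
  }
  k <- gazetteers$proximity_window
  pos_chronic <- which(wt$tokens == "chronic")
  if (any(pos_chronic < i & i - pos_chronic <= k)) {
    return(list(character = "chronic", descriptor = "chronic"))
  }
  if (i > 1L && wt$tokens[i - 1L] == "period") {
    return(list(character = "other", descriptor = "period"))
  }
  pos <- which(wt$tokens %in% gazetteers$character_descriptors &
                 seq_along(wt$tokens) != i)
  pos <- pos[abs(pos - i) <= k]
  if (length(pos)) {
    best <- pos[order(abs(pos - i), pos)][1]
    return(list(character = "other", descriptor = wt$tokens[best]))
  }
  list(character = "n/a", descriptor = NA_character_)
}

#' Classify pain management measures around a mention
#'
#' `medication` when the mention surface itself is a drug-related trigger
#' ("painkillers", "analgesia") or such a trigger occurs in the window;
#' otherwise `other` for non-drug measures (physiotherapy, pain clinic,
#' massage); otherwise `n/a`. Management is assessed for negated mentions
#' too ("he is not on painkillers" is negated pain with medication
#' management).
#'
#' @inheritParams classify_correct
#' @return One of `"medication"`, `"other"`, `"n/a"`.
#' @export
classify_management <- function(mention, window, gazetteers = default_gazetteers()) {
  m <- as.list(mention)
  surf <- tolower(m$surface)
  if (surf %in% gazetteers$management_medication_triggers ||
      phrase_in_window(window, gazetteers$management_medication_triggers)) {
    return("medication")
  }
  if (phrase_in_window(window, gazetteers$management_other_triggers)) {
    return("other")
  }
  "n/a"
}

#' Annotate every pain mention in a document
#'
#' Runs the full scheme: [find_mentions()], then per mention
#' [context_window()] and [classify_correct()]; mentions judged correct get
#' [classify_relevance()], [detect_anatomy()], [classify_character()] and
#' [classify_management()], while incorrect mentions have every downstream
#' attribute structurally `"n/a"`.
#'
#' @param doc One-row data frame (or list) with `doc_id` and `text`.
#' @param lexicon A [pain_lexicon()].
#' @param gazetteers A [pain_gazetteers()].
#' @return A tibble with one row per mention, in mention order: the mention
#'   columns of [find_mentions()] plus `correct`, `relevance`, `anatomy`,
#'   `anatomy_location`, `character`, `character_surface`, `management`.
#' @examples
#' doc <- tibble::tibble(doc_id = "d", text = "No headache today. Chronic back pain persists.")
#' annotate_document(doc)
#' @export
annotate_document <- function(doc, lexicon = default_lexicon(),
                              gazetteers = default_gazetteers()) {
  mentions <- find_mentions(doc, lexicon)
  annotate_mentions(doc, mentions, lexicon, gazetteers)
}

# Label a precomputed mention table for one document.
annotate_mentions <- function(doc, mentions, lexicon, gazetteers) {
  n <- nrow(mentions)
  lab <- tibble::tibble(
    correct = character(n),
    relevance = character(n),
    anatomy = character(n),
    anatomy_location = rep(NA_character_, n),
    character = character(n),
    character_surface = rep(NA_character_, n),
    management = character(n)
  )
  for (j in seq_len(n)) {
    men <- mentions[j, ]
    w <- context_window(doc, men)
    corr <- classify_correct(men, w, lexicon, gazetteers)
    lab$correct[j] <- corr
    if (corr == "no") {
      lab$relevance[j] <- "n/a"
      lab$anatomy[j] <- "n/a"
      lab$character[j] <- "n/a"
      lab$management[j] <- "n/a"
    } else {
      lab$relevance[j] <- classify_relevance(men, w, gazetteers)
      an <- detect_anatomy(men, w, gazetteers)
      lab$anatomy[j] <- an$anatomy
      lab$anatomy_location[j] <- an$location
      ch <- classify_character(men, w, gazetteers)
      lab$character[j] <- ch$character
      lab$character_surface[j] <- ch$descriptor
      lab$management[j] <- classify_management(men, w, gazetteers)
    }
  }
  dplyr::bind_cols(mentions, lab)
}

#' Annotate every document of a corpus
#'
#' @param documents Data frame with columns `doc_id` and `text`.
#' @inheritParams annotate_document
#' @return A tibble of annotations over all documents (see
#'   [annotate_document()]).
#' @export
annotate_corpus <- function(documents, lexicon = default_lexicon(),
                            gazetteers = default_gazetteers()) {
  documents <- tibble::as_tibble(documents)
  purrr::map_dfr(
    seq_len(nrow(documents)),
    function(i) annotate_document(documents[i, ], lexicon, gazetteers)
  )
}
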