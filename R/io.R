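#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

STANDOFF_SCHEMA_VERSION <- "1.0"

normalize_newlines <- function(x) {
  gsub("\r\n?", "\n", x)
}

#' Read a corpus of clinical documents
#'
#' Three on-disk layouts are supported: a directory of UTF-8 `.txt` files
#' (one document per file, file stem as `doc_id`), a delimited table
#' (`.csv` / `.tsv`), or JSON-lines (`.jsonl` / `.ndjson`, one object per
#' line). Tables must carry `doc_id` and `text`; `patient_id`,
#' `source_type`, `diagnosis_chapter` and demographic columns are kept when
#' present. Text is preserved byte-for-byte apart from newline
#' normalization to `"\n"` (offsets elsewhere in the package are computed on
#' the normalized text). Documents are returned in lexicographic `doc_id`
#' order.
#'
#' @param path Directory or file path.
#' @param format One of `"auto"`, `"plain-dir"`, `"delimited"`,
#'   `"json-lines"`. `"auto"` infers from the path.
#' @return A tibble of documents.
#' @export
read_documents <- function(path,
                           format = c("auto", "plain-dir", "delimited",
                                      "json-lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "plain-dir"
    } else if (grepl("\\.(csv|tsv)$", path, ignore.case = TRUE)) {
      "delimited"
    } else if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
      "json-lines"
    } else {
      stop("cannot infer document format from path: ", path, call. = FALSE)
    }
  }
  docs <- switch(format,
    "plain-dir" = {
      files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
      if (!length(files)) {
        stop("no .txt files found under ", path, call. = FALSE)
      }
      tibble::tibble(
        doc_id = tools::file_path_sans_ext(basename(files)),
        text = vapply(
          files,
          function(f) paste(readr::read_lines(f), collapse = "\n"),
          character(1), USE.NAMES = FALSE
        )
      )
    },
    "delimited" = {
      delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
      readr::read_delim(path, delim = delim, show_col_types = FALSE,
                        progress = FALSE)
    },
    "json-lines" = {
      lines <- readr::read_lines(path)
      lines <- lines[nzchar(lines)]
      rows <- lapply(seq_along(lines), function(i) {
        rec <- tryCatch(
          jsonlite::fromJSON(lines[i]),
          error = function(e) {
            stop("line ", i, " of ", path, " is not valid JSON: ",
                 conditionMessage(e), call. = FALSE)
          }
        )
        if (is.null(rec$text)) {
          stop("line ", i, " of ", path, " lacks required field 'text'",
               call. = FALSE)
        }
        if (is.null(rec$doc_id)) {
          stop("line ", i, " of ", path, " lacks required field 'doc_id'",
               call. = FALSE)
        }
        tibble::as_tibble(rec[lengths(rec) == 1L])
      })
      dplyr::bind_rows(rows)
    }
  )
  docs <- tibble::as_tibble(docs)
  missing <- setdiff(c("doc_id", "text"), names(docs))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  docs$doc_id <- as.character(docs$doc_id)
  dup <- unique(docs$doc_id[duplicated(docs$doc_id)])
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  docs$text <- normalize_newlines(docs$text)
  if (any(!nzchar(docs$text))) {
    stop("empty text for doc_id: ",
         paste(utils::head(docs$doc_id[!nzchar(docs$text)], 5),
               collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(docs, .data$doc_id)
}

#' Write documents as a delimited table or JSON-lines
#'
#' @param documents Document tibble.
#' @param path Output file; `.csv`, `.tsv`, or `.jsonl`.
#' @return `path`, invisibly.
#' @export
write_documents <- function(documents, path) {
  documents <- tibble::as_tibble(documents)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- vapply(
      seq_len(nrow(documents)),
      function(i) {
        jsonlite::toJSON(as.list(documents[i, ]), auto_unbox = TRUE,
                         na = "null")
      },
      character(1)
    )
    readr::write_lines(lines, path)
  } else {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    readr::write_delim(documents, path, delim = delim)
  }
  invisible(path)
}

#' Read and write standoff annotations
#'
#' Annotations are stored standoff-style as JSON-lines: one object per
#' annotation carrying `doc_id`, the 0-based half-open `start`/`end`
#' offsets, `surface`, the matched pattern bookkeeping, the five labels, and
#' an explicit `schema_version`. The pair of functions round-trips
#' losslessly.
#'
#' @param annotations Annotation tibble (see [annotate_document()]).
#' @param path File path (conventionally `.jsonl`).
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- tibble::as_tibble(annotations)
  lines <- vapply(
    seq_len(nrow(annotations)),
    function(i) {
      rec <- as.list(annotations[i, ])
      rec$schema_version <- STANDOFF_SCHEMA_VERSION
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA)
    },
    character(1)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) {
        stop("line ", i, " of ", path, " is not valid JSON: ",
             conditionMessage(e), call. = FALSE)
      }
    )
    ver <- rec$schema_version
    if (!is.null(ver) && ver != STANDOFF_SCHEMA_VERSION) {
      stop("line ", i, ": unsupported schema_version ", ver, call. = FALSE)
    }
    rec$schema_version <- NULL
    rec[vapply(rec, is.null, logical(1))] <- NA
    tibble::as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    for (col in intersect(
      c("anatomy_location", "character_surface"), names(out)
    )) {
      out[[col]] <- as.character(out[[col]])
    }
  }
  out
}

# --- sectioned config dialect -------------------------------------------
# One entry per line; sections introduced by "[name]"; fields within a line
# separated by a tab; "#" starts a comment. Round-trips exactly.

read_config_sections <- function(path) {
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  section <- NA_character_
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln, which = "right")
    if (grepl("^\\[.+\\]$", trimws(ln))) {
      section <- sub("^\\[(.+)\\]$", "\\1", trimws(ln))
      out[[section]] <- list()
    } else {
      if (is.na(section)) {
        stop("config line outside any [section]: ", ln, call. = FALSE)
      }
      out[[section]] <- c(out[[section]], list(strsplit(ln, "\t")[[1]]))
    }
  }
  out
}

write_config_sections <- function(sections, path, header = NULL) {
  lines <- character()
  if (!is.null(header)) {
    lines <- paste("#", header)
  }
  for (nm in names(sections)) {
    lines <- c(lines, paste0("[", nm, "]"))
    for (entry in sections[[nm]]) {
      lines <- c(lines, paste(entry, collapse = "\t"))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write lexicon config files
#'
#' A plain sectioned text format: `[patterns]` lines are
#' `pattern<TAB>canonical word`, `[full_terms]` lines are
#' `term<TAB>canonical word`, `[exclusions]` lines are a single term.
#' `#` starts a comment. The pair round-trips exactly.
#'
#' @param lexicon A [pain_lexicon()].
#' @param path File path.
#' @return `read_lexicon()` returns a `pain_lexicon`; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "pain_lexicon"))
  sections <- list(
    patterns = purrr::map2(
      lexicon$patterns$raw, lexicon$patterns$canonical_word, c
    ),
    full_terms = purrr::map2(
      lexicon$full_terms$term, lexicon$full_terms$canonical_word, c
    ),
    exclusions = as.list(lexicon$exclusion_terms)
  )
  write_config_sections(sections, path, header = "pain lexicon config")
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  s <- read_config_sections(path)
  two_col <- function(entries, what) {
    if (!length(entries)) {
      return(tibble::tibble(a = character(), b = character()))
    }
    bad <- which(lengths(entries) != 2L)
    if (length(bad)) {
      stop(what, " entries need two tab-separated fields (entry ", bad[1],
           ")", call. = FALSE)
    }
    tibble::tibble(
      a = vapply(entries, `[`, character(1), 1),
      b = vapply(entries, `[`, character(1), 2)
    )
  }
  pat <- two_col(s$patterns, "[patterns]")
  names(pat) <- c("raw", "canonical_word")
  ft <- two_col(s$full_terms, "[full_terms]")
  names(ft) <- c("term", "canonical_word")
  pain_lexicon(
    patterns = pat,
    full_terms = ft,
    exclusion_terms = unlist(s$exclusions) %||% character()
  )
}

#' Read and write gazetteer config files
#'
#' Same sectioned dialect as the lexicon config, one section per rule
#' family. Map-like sections (`anatomy_map`, `anatomy_compounds`) use
#' `term<TAB>normalized location` lines; `options` holds the numeric scope
#' windows. The pair round-trips exactly.
#'
#' @param gazetteers A [pain_gazetteers()].
#' @param path File path.
#' @return `read_gazetteers()` returns a `pain_gazetteers`;
#'   `write_gazetteers()` returns `path` invisibly.
#' @export
write_gazetteers <- function(gazetteers, path) {
  stopifnot(inherits(gazetteers, "pain_gazetteers"))
  gz <- unclass(gazetteers)
  map_fields <- c("anatomy_map", "anatomy_compounds")
  sections <- list()
  for (nm in setdiff(names(gz), c("negation_window", "proximity_window"))) {
    v <- gz[[nm]]
    sections[[nm]] <- if (nm %in% map_fields) {
      purrr::map2(names(v), unname(v), c)
    } else {
      as.list(unname(v))
    }
  }
  sections$options <- list(
    c("negation_window", as.character(gz$negation_window)),
    c("proximity_window", as.character(gz$proximity_window))
  )
  write_config_sections(sections, path, header = "pain gazetteer config")
}

#' @rdname write_gazetteers
#' @export
read_gazetteers <- function(path) {
  s <- read_config_sections(path)
  as_map <- function(entries) {
    stats::setNames(
      vapply(entries, `[`, character(1), 2),
      vapply(entries, `[`, character(1), 1)
    )
  }
  opts <- as_map(s$options %||% list())
  pain_gazetteers(
    negation_triggers = unlist(s$negation_triggers),
    experiencer_triggers = unlist(s$experiencer_triggers),
    hypothetical_triggers = unlist(s$hypothetical_triggers),
    emotional_triggers = unlist(s$emotional_triggers),
    anatomy_map = as_map(s$anatomy_map),
    anatomy_compounds = as_map(s$anatomy_compounds),
    character_descriptors = unlist(s$character_descriptors),
    management_medication_triggers = unlist(s$management_medication_triggers),
    management_other_triggers = unlist(s$management_other_triggers),
    inanimate_referents = unlist(s$inanimate_referents),
    negation_window = as.integer(opts[["negation_window"]] %||% "6"),
    proximity_window = as.integer(opts[["proximity_window"]] %||% "3")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic-corpus manifest
#'
#' Records the generator configuration and seed alongside simulated output
#' so a corpus can be regenerated exactly.
#'
#' @param corpus A `pain_corpus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(corpus, path) {
  stopifnot(inherits(corpus, "pain_corpus"))
  manifest <- list(
    seed = corpus$config$seed,
    config = unclass(corpus$config),
    n_documents = nrow(corpus$documents),
    n_patients = length(unique(corpus$documents$patient_id)),
    n_annotations = nrow(corpus$gold)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
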