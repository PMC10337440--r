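#' Descriptive summary of an annotated corpus
#'
#' Computes the standard descriptive tables for a pain-annotation corpus:
#' overall totals (patients, documents, annotations), per-document and
#' per-patient annotation statistics, words and characters per document,
#' the relevance distribution, the anatomy rate among relevant mentions,
#' the location ranking, character and management distributions, a
#' diagnosis-chapter breakdown, and the most frequently annotated surface
#' forms ("concepts" are grouped by lowercased surface, so "pain",
#' "headache" and "painful" count separately). Word count is the number of
#' alphabetic tokens; character count is raw string length. Percentages are
#' reported to integer precision alongside the exact counts they derive
#' from.
#'
#' @param documents Data frame of documents (columns `doc_id`, `text`,
#'   optionally `patient_id`, `diagnosis_chapter`).
#' @param annotations Annotation tibble (see [annotate_document()]); every
#'   `doc_id` must exist in `documents`.
#' @return An object of class `pain_corpus_summary`: a named list of tibbles.
#' @examples
#' corp <- generate_corpus(synthetic_config(seed = 3, n_patients = 3,
#'                                          words_per_doc_mean = 60))
#' summarize_corpus(corp$documents, corp$gold)
#' @export
summarize_corpus <- function(documents, annotations) {
  documents <- tibble::as_tibble(documents)
  annotations <- tibble::as_tibble(annotations)

  dangling <- setdiff(annotations$doc_id, documents$doc_id)
  if (length(dangling)) {
    stop("annotations reference unknown doc_id: ",
         paste(utils::head(dangling, 5), collapse = ", "), call. = FALSE)
  }

  n_ann <- nrow(annotations)
  per_doc <- annotations |>
    dplyr::count(.data$doc_id, name = "n_annotations")
  per_patient <- NULL
  if ("patient_id" %in% names(documents)) {
    per_patient <- annotations |>
      dplyr::left_join(
        dplyr::select(documents, "doc_id", "patient_id"),
        by = "doc_id"
      ) |>
      dplyr::count(.data$patient_id, name = "n_annotations")
  }

  word_counts <- vapply(
    documents$text, function(t) length(tokenize(t)$token), integer(1),
    USE.NAMES = FALSE
  )
  char_counts <- nchar(documents$text)

  overall <- tibble::tibble(
    n_patients = if ("patient_id" %in% names(documents)) {
      length(unique(documents$patient_id))
    } else {
      NA_integer_
    },
    n_documents = nrow(documents),
    n_annotations = n_ann,
    mean_words_per_doc = mean(word_counts),
    mean_chars_per_doc = mean(char_counts)
  )

  stat_block <- function(x) {
    if (length(x) == 0L) {
      tibble::tibble(mean = NA_real_, min = NA_integer_, max = NA_integer_)
    } else {
      tibble::tibble(mean = mean(x), min = min(x), max = max(x))
    }
  }

  dist_of <- function(col, data = annotations) {
    if (nrow(data) == 0L) {
      return(tibble::tibble(
        label = character(), n = integer(), percent = integer()
      ))
    }
    data |>
      dplyr::count(label = .data[[col]], name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$label) |>
      dplyr::mutate(percent = as.integer(round(100 * .data$n / sum(.data$n))))
  }

  correct_ann <- dplyr::filter(annotations, .data$correct == "yes")
  relevant_ann <- dplyr::filter(correct_ann, .data$relevance == "relevant")

  diagnosis <- NULL
  if ("diagnosis_chapter" %in% names(documents)) {
    diagnosis <- annotations |>
      dplyr::left_join(
        dplyr::select(documents, "doc_id", "diagnosis_chapter"),
        by = "doc_id"
      ) |>
      dist_of(col = "diagnosis_chapter")
  }

  top_concepts <- annotations |>
    dplyr::count(surface = tolower(.data$surface), name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$surface)

  structure(
    list(
      overall = overall,
      annotations_per_document = stat_block(per_doc$n_annotations),
      annotations_per_patient = if (is.null(per_patient)) {
        NULL
      } else {
        stat_block(per_patient$n_annotations)
      },
      relevance = dist_of("relevance", correct_ann),
      anatomy_among_relevant = dist_of("anatomy", relevant_ann),
      locations = rank_locations(annotations),
      character = dist_of("character", correct_ann),
      management = dist_of("management", correct_ann),
      diagnosis = diagnosis,
      top_concepts = top_concepts
    ),
    class = "pain_corpus_summary"
  )
}

#' @export
print.pain_corpus_summary <- function(x, ...) {
  ov <- x$overall
  cat("<pain_corpus_summary>\n")
  cat(sprintf(
    "  %s patients, %d documents, %d annotations\n",
    ifelse(is.na(ov$n_patients), "?", ov$n_patients),
    ov$n_documents, ov$n_annotations
  ))
  cat(sprintf(
    "  words/document: %.0f   characters/document: %.0f\n",
    ov$mean_words_per_doc, ov$mean_chars_per_doc
  ))
  if (nrow(x$relevance)) {
    cat("  relevance (correct mentions): ",
        paste(sprintf("%s %d (%d%%)", x$relevance$label, x$relevance$n,
                      x$relevance$percent), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$locations)) {
    cat("  top locations: ",
        paste(utils::head(x$locations$location, 5), collapse = " > "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname summarize_corpus
#' @param x A `pain_corpus_summary`.
#' @param ... Unused.
#' @method tidy pain_corpus_summary
#' @export
tidy.pain_corpus_summary <- function(x, ...) {
  blocks <- c("relevance", "anatomy_among_relevant", "character",
              "management", "diagnosis")
  purrr::map_dfr(blocks, function(b) {
    df <- x[[b]]
    if (is.null(df) || nrow(df) == 0L) {
      return(NULL)
    }
    dplyr::mutate(df, block = b, .before = 1)
  })
}

#' @rdname summarize_corpus
#' @method glance pain_corpus_summary
#' @export
glance.pain_corpus_summary <- function(x, ...) {
  dplyr::mutate(
    x$overall,
    relevant_fraction = {
      r <- x$relevance
      if (nrow(r)) {
        sum(r$n[r$label == "relevant"]) / sum(r$n)
      } else {
        NA_real_
      }
    }
  )
}

#' Rank anatomical locations by annotation frequency
#'
#' Only annotations with `anatomy == "mentioned"` contribute. Descending
#' count order; ties broken alphabetically.
#'
#' @param annotations Annotation tibble.
#' @return Tibble with columns `location` and `n`.
#' @export
rank_locations <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) == 0L) {
    return(tibble::tibble(location = character(), n = integer()))
  }
  annotations |>
    dplyr::filter(.data$anatomy == "mentioned",
                  !is.na(.data$anatomy_location)) |>
    dplyr::count(location = .data$anatomy_location, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$location)
}

#' Plot the label distributions of a corpus summary
#'
#' @param object A `pain_corpus_summary`.
#' @param ... Unused.
#' @return A ggplot object with one facet per attribute distribution.
#' @method autoplot pain_corpus_summary
#' @export
autoplot.pain_corpus_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$label, .data$n), y = .data$n)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~block, scales = "free") +
    ggplot2::labs(x = NULL, y = "annotations") +
    ggplot2::theme_minimal()
}
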