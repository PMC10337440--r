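#' Cohen's kappa for two nominal label sequences
#'
#' Chance-corrected agreement between two annotators:
#' `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o` is the observed agreement
#' fraction and `p_e` the chance agreement implied by the two marginal label
#' distributions. Kappa is unweighted -- the annotation categories are
#' nominal. The degenerate case `p_e = 1` (both annotators constant on the
#' same category) is handled explicitly: perfect observed agreement returns
#' exactly `1`, anything else is undefined and returned as `NA` with a
#' warning rather than as a floating-point accident.
#'
#' @param labels_a,labels_b Equal-length non-empty categorical vectors.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' cohens_kappa(c("x", "x", "x", "y"), c("x", "x", "y", "y"))
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length (", length(labels_a), " vs ",
         length(labels_b), ")", call. = FALSE)
  }
  if (length(labels_a) == 0L) {
    stop("label sequences are empty", call. = FALSE)
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  pa <- tabulate(match(labels_a, cats), length(cats)) / n
  pb <- tabulate(match(labels_b, cats), length(cats)) / n
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < 1e-12) {
    if (p_o == 1) {
      return(1)
    }
    warning("kappa undefined: chance agreement is 1 but observed is not",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

# Align two annotation sets on identical mention spans; error naming the
# offending spans otherwise.
align_annotations <- function(ann_a, ann_b) {
  ann_a <- tibble::as_tibble(ann_a)
  ann_b <- tibble::as_tibble(ann_b)
  key_a <- paste(ann_a$doc_id, ann_a$start, ann_a$end)
  key_b <- paste(ann_b$doc_id, ann_b$start, ann_b$end)
  if (nrow(ann_a) != nrow(ann_b) || !all(sort(key_a) == sort(key_b))) {
    off <- union(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop(
      "annotation sets are not aligned on mention spans; offending ",
      "doc_id/start/end: ", paste(utils::head(off, 5), collapse = "; "),
      call. = FALSE
    )
  }
  ord_a <- order(key_a)
  ord_b <- order(key_b)
  list(a = ann_a[ord_a, ], b = ann_b[ord_b, ])
}

#' Inter-annotator agreement report
#'
#' Percent agreement and Cohen's kappa for each annotation attribute
#' (relevance, anatomy, pain character, pain management) over two annotation
#' sets aligned on identical mention spans, plus two overall figures:
#' `overall` treats each mention's full label tuple as a single item, and
#' `overall_labels` is raw accuracy over all attribute labels pooled -- both
#' are reported because "overall agreement" is ambiguous between the two.
#'
#' @param ann_a,ann_b Annotation tibbles (see [annotate_document()]) covering
#'   the same mention spans.
#' @return An object of class `pain_agreement` with fields `n_items`,
#'   `by_attribute` (tibble: attribute, percent_agreement, kappa),
#'   `confusion` (named list of contingency tables), and
#'   `overall_label_agreement`. Use [generics::tidy()] / [generics::glance()]
#'   to extract tidy summaries.
#' @export
agreement_report <- function(ann_a, ann_b) {
  al <- align_annotations(ann_a, ann_b)
  a <- al$a
  b <- al$b
  n <- nrow(a)
  attrs <- pain_attributes

  rows <- purrr::map_dfr(attrs, function(at) {
    tibble::tibble(
      attribute = at,
      percent_agreement = mean(a[[at]] == b[[at]]),
      kappa = suppressWarnings(cohens_kappa(a[[at]], b[[at]]))
    )
  })
  tup_a <- do.call(paste, c(a[attrs], sep = "|"))
  tup_b <- do.call(paste, c(b[attrs], sep = "|"))
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    attribute = "overall",
    percent_agreement = mean(tup_a == tup_b),
    kappa = suppressWarnings(cohens_kappa(tup_a, tup_b))
  ))
  confusion <- lapply(stats::setNames(attrs, attrs), function(at) {
    table(a = factor(a[[at]], pain_labels[[at]]),
          b = factor(b[[at]], pain_labels[[at]]))
  })
  structure(
    list(
      n_items = n,
      by_attribute = rows,
      confusion = confusion,
      overall_label_agreement = mean(unlist(a[attrs]) == unlist(b[attrs]))
    ),
    class = "pain_agreement"
  )
}

#' @export
print.pain_agreement <- function(x, ...) {
  cat("<pain_agreement> over ", x$n_items, " aligned mentions\n", sep = "")
  df <- as.data.frame(x$by_attribute)
  df$percent_agreement <- sprintf("%.1f%%", 100 * df$percent_agreement)
  df$kappa <- sprintf("%.2f", df$kappa)
  print(df, row.names = FALSE)
  cat(sprintf(
    "pooled per-label agreement: %.1f%%\n", 100 * x$overall_label_agreement
  ))
  invisible(x)
}

#' @rdname agreement_report
#' @param x A `pain_agreement` object.
#' @param ... Unused.
#' @method tidy pain_agreement
#' @export
tidy.pain_agreement <- function(x, ...) {
  x$by_attribute
}

#' @rdname agreement_report
#' @method glance pain_agreement
#' @export
glance.pain_agreement <- function(x, ...) {
  ov <- x$by_attribute[x$by_attribute$attribute == "overall", ]
  tibble::tibble(
    n_items = x$n_items,
    percent_agreement = ov$percent_agreement,
    kappa = ov$kappa,
    label_agreement = x$overall_label_agreement
  )
}

#' Plot per-attribute agreement
#'
#' Bar chart of Cohen's kappa (and percent agreement) by attribute, the
#' shape in which agreement across annotation rounds is usually reported.
#'
#' @param object A `pain_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pain_agreement
#' @export
autoplot.pain_agreement <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$by_attribute,
    cols = c("percent_agreement", "kappa"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$attribute, y = .data$value, fill = .data$measure
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(NA, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Inter-annotator agreement by attribute"
    ) +
    ggplot2::theme_minimal()
}

#' Adjudicate a doubly annotated mention set
#'
#' Where the two annotators agree, the shared label is kept. Where they
#' differ, the deterministic guideline rules (the annotator module, run on
#' the same context window) act as tie-breaker, exactly as a written
#' guideline resolves human disagreements. Every adjudicated attribute value
#' equals one of the two inputs or the rule output, and each decision is
#' logged.
#'
#' @param ann_a,ann_b Aligned annotation tibbles.
#' @param documents Data frame of the documents the annotations refer to
#'   (needed to recompute rule output on disagreements).
#' @param lexicon,gazetteers Rule resources for the tie-breaker.
#' @return The adjudicated annotation tibble; the decision log (one row per
#'   disagreeing mention-attribute, with both inputs and the chosen value)
#'   is attached as attribute `"log"`.
#' @export
adjudicate <- function(ann_a, ann_b, documents,
                       lexicon = default_lexicon(),
                       gazetteers = default_gazetteers()) {
  al <- align_annotations(ann_a, ann_b)
  a <- al$a
  b <- al$b
  documents <- tibble::as_tibble(documents)
  out <- a
  log <- list()
  cols <- c("correct", pain_attributes, "anatomy_location",
            "character_surface")
  needs_rule <- which(vapply(
    seq_len(nrow(a)),
    function(i) !identical(unclass(a[i, cols]), unclass(b[i, cols])),
    logical(1)
  ))
  for (i in needs_rule) {
    doc <- documents[documents$doc_id == a$doc_id[i], ]
    if (nrow(doc) == 0L) {
      stop("adjudicate: no document with doc_id ", a$doc_id[i],
           call. = FALSE)
    }
    mention_cols <- c("doc_id", "start", "end", "surface", "pattern",
                      "canonical_word", "excluded")
    ruled <- annotate_mentions(doc[1, ], a[i, mention_cols], lexicon,
                               gazetteers)
    for (col in cols) {
      if (!identical(a[[col]][i], b[[col]][i])) {
        out[[col]][i] <- ruled[[col]][1]
        log[[length(log) + 1L]] <- tibble::tibble(
          doc_id = a$doc_id[i], start = a$start[i], end = a$end[i],
          attribute = col, annotator_a = as.character(a[[col]][i]),
          annotator_b = as.character(b[[col]][i]),
          adjudicated = as.character(ruled[[col]][1])
        )
      }
    }
  }
  attr(out, "log") <- dplyr::bind_rows(log)
  out
}
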