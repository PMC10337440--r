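#' Configuration for the synthetic clinical-note generator
#'
#' Real mental-health records are access-restricted, so the generator emulates
#' the statistical shape of such a corpus: long notes (about a thousand words
#' on average), a handful of pain mentions per note with a long right tail,
#' and an annotation-label mixture dominated by relevant mentions (roughly
#' 71/15/13 relevant / not relevant / negated after excluding lexical false
#' positives), with about 63% of relevant mentions carrying an anatomical
#' location. Mixture defaults are normalised so each sums to exactly 1.
#'
#' @param seed Integer seed; identical configs yield byte-identical corpora.
#' @param n_patients Number of patients.
#' @param docs_per_patient_mean Mean documents per patient (truncated
#'   geometric, minimum 1).
#' @param mentions_per_doc_mean Mean pain mentions per document (truncated
#'   geometric, minimum 1, maximum `mentions_per_doc_max`).
#' @param mentions_per_doc_max Upper truncation for mentions per document.
#' @param words_per_doc_mean Mean words per document; filler sentences pad
#'   each note to a normally varying target around this mean.
#' @param relevance_mix Named proportions over `relevant`, `not_relevant`,
#'   `negated` (applied to correct mentions only).
#' @param incorrect_rate Proportion of matches that are lexical false
#'   positives (the source corpus does not report this; the default is a
#'   package choice).
#' @param anatomy_rate_given_relevant Probability a relevant mention carries
#'   an anatomical location.
#' @param location_weights Named weights over the location vocabulary used
#'   when anatomy is present; the default ranks chest > head > back >
#'   abdomen > neck.
#' @param character_mix Named proportions over `chronic`, `other`, `n/a`.
#' @param management_mix Named proportions over `medication`, `other`, `n/a`.
#' @param diagnosis_mix Named proportions over ICD-10 chapter labels used as
#'   document metadata.
#' @param demographics_mix List of named proportion vectors `age`, `gender`,
#'   `ethnicity` for patient metadata.
#' @param source_type_mix Named proportions over document source types.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_patients = 25L,
                             docs_per_patient_mean = 2.75,
                             mentions_per_doc_mean = 3,
                             mentions_per_doc_max = 84L,
                             words_per_doc_mean = 1026,
                             relevance_mix = c(
                               relevant = 0.71, not_relevant = 0.15,
                               negated = 0.13
                             ) / 0.99,
                             incorrect_rate = 0.05,
                             anatomy_rate_given_relevant = 0.63,
                             location_weights = c(
                               chest = 0.30, head = 0.25, back = 0.20,
                               abdomen = 0.15, neck = 0.10
                             ),
                             character_mix = c(
                               chronic = 0.03, other = 0.08, "n/a" = 0.89
                             ),
                             management_mix = c(
                               medication = 0.07, other = 0.03, "n/a" = 0.89
                             ) / 0.99,
                             diagnosis_mix = default_diagnosis_mix(),
                             demographics_mix = default_demographics_mix(),
                             source_type_mix = c(
                               Event = 0.78, Attachment = 0.22
                             )) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    docs_per_patient_mean = docs_per_patient_mean,
    mentions_per_doc_mean = mentions_per_doc_mean,
    mentions_per_doc_max = as.integer(mentions_per_doc_max),
    words_per_doc_mean = words_per_doc_mean,
    relevance_mix = relevance_mix,
    incorrect_rate = incorrect_rate,
    anatomy_rate_given_relevant = anatomy_rate_given_relevant,
    location_weights = location_weights / sum(location_weights),
    character_mix = character_mix,
    management_mix = management_mix,
    diagnosis_mix = diagnosis_mix,
    demographics_mix = demographics_mix,
    source_type_mix = source_type_mix
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  mixes <- list(
    relevance_mix = cfg$relevance_mix,
    character_mix = cfg$character_mix,
    management_mix = cfg$management_mix,
    diagnosis_mix = cfg$diagnosis_mix,
    source_type_mix = cfg$source_type_mix,
    location_weights = cfg$location_weights,
    "demographics_mix$age" = cfg$demographics_mix$age,
    "demographics_mix$gender" = cfg$demographics_mix$gender,
    "demographics_mix$ethnicity" = cfg$demographics_mix$ethnicity
  )
  for (nm in names(mixes)) {
    v <- mixes[[nm]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(
        "invalid mixture '", nm, "': proportions must be non-negative and ",
        "sum to 1 (got sum = ", format(sum(v), digits = 12), ")",
        call. = FALSE
      )
    }
  }
  rates <- c(
    incorrect_rate = cfg$incorrect_rate,
    anatomy_rate_given_relevant = cfg$anatomy_rate_given_relevant
  )
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) {
    stop("invalid rate '", bad[1], "': must lie in [0, 1]", call. = FALSE)
  }
  means <- c(
    docs_per_patient_mean = cfg$docs_per_patient_mean,
    mentions_per_doc_mean = cfg$mentions_per_doc_mean,
    words_per_doc_mean = cfg$words_per_doc_mean
  )
  bad <- names(means)[means <= 0]
  if (length(bad)) {
    stop("invalid mean '", bad[1], "': must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_diagnosis_mix <- function() {
  counts <- c(
    "Mood disorders (F30-39)" = 1857,
    "Anxiety and other nonpsychotic mental disorders (F40-49)" = 1122,
    "Schizophrenia and other nonmood psychotic disorders (F20-29)" = 786,
    "Mental disorder due to known physiological condition (F01-09)" = 460,
    "Mental disorder, not otherwise specified" = 327,
    "Mental and behavioral disorders due to substance use (F10-19)" = 311,
    "Miscellaneous (other examination or no diagnosis)" = 222,
    "Person with feared complaint in whom no diagnosis is made (Z71.1)" = 186,
    "Developmental disorders (F80-89)" = 104,
    "Behavioral (F50-59)" = 103,
    "Behavioral and emotional disorders, childhood onset (F90-98)" = 85,
    "Personality disorder (F60-69)" = 59,
    "Intellectual disabilities (F70-79)" = 21
  )
  counts / sum(counts)
}

#' @rdname synthetic_config
#' @export
default_demographics_mix <- function() {
  age <- c("<=20" = 538, "21-40" = 1205, "41-60" = 1439, "61-80" = 1888,
           ">80" = 566)
  gender <- c(male = 2991, female = 2653)
  ethnicity <- c(white = 3659, mixed = 84, black = 941, asian = 247,
                 other = 713)
  list(
    age = age / sum(age),
    gender = gender / sum(gender),
    ethnicity = ethnicity / sum(ethnicity)
  )
}

# --- template bank ------------------------------------------------------
# Every mention-bearing sentence is assembled from frames whose labels the
# contextual rules recover by construction (rule-covered frames). Filler
# sentences contain no lexicon token at all.

synthetic_filler_bank <- function() {
  c(
    "Seen at the community clinic this morning.",
    "Medication reviewed and no changes were made.",
    "She slept well and appetite is stable.",
    "Mood remains settled with good engagement.",
    "He attended the group session on time.",
    "Plan to review again in two weeks.",
    "Discussed coping strategies during the visit.",
    "Sleep pattern has improved since last review.",
    "He continues to engage with the care plan.",
    "No concerns were raised by the ward team.",
    "She is looking forward to the weekend.",
    "Appointment letter sent to the home address.",
    "Blood results were reviewed and unremarkable.",
    "Risperidone dose unchanged at this visit.",
    "The occupational therapist will visit on Friday."
  )
}

# Lexical false-positive sentences: exactly one lexicon match each, with the
# mention given as pre / surface / post so offsets need no re-scanning.
synthetic_incorrect_bank <- function() {
  list(
    list(pre = "She ", surface = "painted", post = " a picture of the situation.",
         pattern = "%pain%", canonical_word = "Pain", excluded = TRUE),
    list(pre = "He likes ", surface = "burning", post = " things.",
         pattern = "%burn%", canonical_word = "Burn", excluded = FALSE),
    list(pre = "They discussed ", surface = "painting", post = " during therapy.",
         pattern = "%pain%", canonical_word = "Pain", excluded = TRUE),
    list(pre = "He returned from ", surface = "Spain", post = " last week.",
         pattern = "%pain%", canonical_word = "Pain", excluded = TRUE),
    list(pre = "There were ", surface = "burn", post = " marks on the door.",
         pattern = "%burn%", canonical_word = "Burn", excluded = FALSE)
  )
}

# Descriptors safe for template use: none of them is itself a lexicon match.
synthetic_descriptors <- c(
  "severe", "constant", "throbbing", "sharp", "stabbing", "shooting", "dull"
)

synthetic_medication_words <- c("paracetamol", "ibuprofen", "codeine")
synthetic_other_mgmt_words <- c("physiotherapy", "massage")

# Build the noun-phrase realisation of a mention given its gold attributes.
# Returns pre (text before the mention token), surface, pattern bookkeeping.
realize_np <- function(character, descriptor, anatomy, location, use_compound) {
  mod <- switch(character,
    chronic = "chronic ",
    other = paste0(descriptor, " "),
    "n/a" = ""
  )
  if (anatomy == "mentioned" && use_compound && location %in% c("head", "back")) {
    surface <- if (location == "head") "headaches" else "backaches"
    list(pre = mod, surface = surface, pattern = "%aches",
         canonical_word = "Ache")
  } else if (anatomy == "mentioned") {
    loc_term <- switch(location,
      abdomen = "abdominal",
      location
    )
    list(pre = paste0(mod, loc_term, " "), surface = "pain",
         pattern = "%pain%", canonical_word = "Pain")
  } else {
    list(pre = mod, surface = "pain", pattern = "%pain%",
         canonical_word = "Pain")
  }
}

# Assemble one mention-bearing sentence. Returns pre / surface / post plus
# bookkeeping columns for the gold table.
realize_mention_sentence <- function(labels) {
  if (labels$correct == "no") {
    bank <- synthetic_incorrect_bank()
    s <- bank[[sample.int(length(bank), 1L)]]
    return(s)
  }
  np <- realize_np(
    labels$character, labels$character_surface,
    labels$anatomy, labels$anatomy_location,
    use_compound = stats::runif(1) < 0.4
  )
  mgmt <- switch(labels$management,
    medication = paste0(
      " and takes ",
      sample(synthetic_medication_words, 1L)
    ),
    other = paste0(
      " and attends ",
      sample(synthetic_other_mgmt_words, 1L)
    ),
    "n/a" = ""
  )
  subj <- sample(c("She", "He", "The patient"), 1L)
  out <- switch(labels$relevance,
    relevant = {
      frame <- sample.int(3L, 1L)
      if (frame == 1L) {
        list(pre = paste0(subj, " reports ", np$pre),
             post = paste0(" today", mgmt, "."))
      } else if (frame == 2L) {
        list(pre = paste0(subj, " complains of ", np$pre),
             post = paste0(mgmt, "."))
      } else {
        list(pre = paste0("On examination there is ", np$pre),
             post = paste0(mgmt, "."))
      }
    },
    negated = {
      frame <- sample.int(3L, 1L)
      if (frame == 1L) {
        list(pre = paste0(subj, " does not report any ", np$pre),
             post = paste0(" today", mgmt, "."))
      } else if (frame == 2L) {
        list(pre = paste0("No ", np$pre),
             post = paste0(" reported", mgmt, "."))
      } else {
        list(pre = paste0(subj, " denies ", np$pre),
             post = paste0(mgmt, "."))
      }
    },
    not_relevant = {
      kind <- sample(c("experiencer", "uncertainty", "hypothetical"), 1L)
      if (kind == "experiencer") {
        who <- sample(c("mother", "father", "husband", "wife", "daughter",
                        "son"), 1L)
        list(pre = paste0("Her ", who, " has ", np$pre),
             post = paste0(mgmt, "."))
      } else if (kind == "uncertainty") {
        lead <- switch(labels$management,
          medication = paste0("On ", sample(synthetic_medication_words, 1L),
                              " query "),
          other = paste0("After ", sample(synthetic_other_mgmt_words, 1L),
                         " query "),
          "n/a" = "Query "
        )
        list(pre = paste0(lead, np$pre), post = "?")
      } else {
        list(pre = paste0(subj, " is afraid of ", np$pre),
             post = paste0(" if symptoms worsen", mgmt, "."))
      }
    }
  )
  c(out, list(surface = np$surface, pattern = np$pattern,
              canonical_word = np$canonical_word, excluded = FALSE))
}

# Sample gold labels for one mention from the configured mixtures.
sample_mention_labels <- function(cfg) {
  if (stats::runif(1) < cfg$incorrect_rate) {
    return(list(
      correct = "no", relevance = "n/a", anatomy = "n/a",
      anatomy_location = NA_character_, character = "n/a",
      character_surface = NA_character_, management = "n/a"
    ))
  }
  relevance <- sample(names(cfg$relevance_mix), 1L, prob = cfg$relevance_mix)
  anatomy <- "n/a"
  location <- NA_character_
  if (relevance == "relevant" &&
      stats::runif(1) < cfg$anatomy_rate_given_relevant) {
    anatomy <- "mentioned"
    location <- sample(names(cfg$location_weights), 1L,
                       prob = cfg$location_weights)
  }
  pain_character <- sample(names(cfg$character_mix), 1L,
                           prob = cfg$character_mix)
  descriptor <- switch(pain_character,
    chronic = "chronic",
    other = sample(synthetic_descriptors, 1L),
    "n/a" = NA_character_
  )
  management <- sample(names(cfg$management_mix), 1L,
                       prob = cfg$management_mix)
  list(
    correct = "yes", relevance = relevance, anatomy = anatomy,
    anatomy_location = location, character = pain_character,
    character_surface = descriptor, management = management
  )
}

rgeom_trunc <- function(n, mean, max) {
  p <- 1 / mean
  x <- stats::rgeom(n, p) + 1L
  pmin(x, as.integer(max))
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents from a template bank -- neutral clinical filler sentences
#' plus mention-bearing frames instantiated according to sampled gold labels
#' (negation frames, experiencer frames, question-mark frames, and anatomy /
#' character / management slots) -- and records each mention with its
#' intended gold annotation. Every frame in the bank is rule-covered: the
#' deterministic annotator recovers its gold labels, which makes the
#' generator a gold standard for pipeline testing. The generator and the
#' annotator share no code path; gold offsets come from template assembly,
#' never from re-running the matcher.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `pain_corpus`: a list with `documents` (tibble
#'   of notes with patient and diagnosis metadata), `gold` (tibble of gold
#'   annotations in the same shape [annotate_document()] emits), and
#'   `config`.
#' @examples
#' corp <- generate_corpus(synthetic_config(seed = 7, n_patients = 2,
#'                                          words_per_doc_mean = 60))
#' corp$gold
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  with_preserved_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  filler <- synthetic_filler_bank()
  filler_mean_words <- mean(vapply(
    filler, function(s) length(tokenize(s)$token), integer(1)
  ))
  docs <- list()
  golds <- list()
  doc_no <- 0L

  patient_ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  demo <- cfg$demographics_mix
  patients <- tibble::tibble(
    patient_id = patient_ids,
    age_band = sample(names(demo$age), cfg$n_patients, TRUE, demo$age),
    gender = sample(names(demo$gender), cfg$n_patients, TRUE, demo$gender),
    ethnicity = sample(names(demo$ethnicity), cfg$n_patients, TRUE,
                       demo$ethnicity),
    diagnosis_chapter = sample(names(cfg$diagnosis_mix), cfg$n_patients,
                               TRUE, cfg$diagnosis_mix)
  )
  n_docs_per_patient <- rgeom_trunc(
    cfg$n_patients, cfg$docs_per_patient_mean, 300L
  )

  for (p in seq_len(cfg$n_patients)) {
    for (d in seq_len(n_docs_per_patient[p])) {
      doc_no <- doc_no + 1L
      doc_id <- sprintf("D%05d", doc_no)
      n_mentions <- rgeom_trunc(1L, cfg$mentions_per_doc_mean,
                                cfg$mentions_per_doc_max)
      target_words <- max(
        20L, round(stats::rnorm(1, cfg$words_per_doc_mean,
                                0.25 * cfg$words_per_doc_mean))
      )

      mention_sents <- vector("list", n_mentions)
      mention_labels <- vector("list", n_mentions)
      for (k in seq_len(n_mentions)) {
        lab <- sample_mention_labels(cfg)
        mention_labels[[k]] <- lab
        mention_sents[[k]] <- realize_mention_sentence(lab)
      }
      mention_words <- sum(vapply(
        mention_sents,
        function(s) length(tokenize(paste0(s$pre, s$surface, s$post))$token),
        integer(1)
      ))
      n_filler <- max(0L, ceiling(
        (target_words - mention_words) / filler_mean_words
      ))
      filler_sents <- if (n_filler > 0L) {
        sample(filler, n_filler, replace = TRUE)
      } else {
        character()
      }

      n_sent <- n_mentions + length(filler_sents)
      mention_slots <- sort(sample.int(n_sent, n_mentions))
      sents <- character(n_sent)
      sents[setdiff(seq_len(n_sent), mention_slots)] <- filler_sents

      # assemble text and record gold offsets (0-based, half-open)
      offset <- 0L
      gold_rows <- vector("list", n_mentions)
      fi <- 0L
      for (s in seq_len(n_sent)) {
        k <- match(s, mention_slots)
        if (!is.na(k)) {
          ms <- mention_sents[[k]]
          sent <- paste0(ms$pre, ms$surface, ms$post)
          lab <- mention_labels[[k]]
          gold_rows[[k]] <- tibble::tibble(
            doc_id = doc_id,
            start = offset + nchar(ms$pre),
            end = offset + nchar(ms$pre) + nchar(ms$surface),
            surface = ms$surface,
            pattern = ms$pattern,
            canonical_word = ms$canonical_word,
            excluded = ms$excluded,
            correct = lab$correct,
            relevance = lab$relevance,
            anatomy = lab$anatomy,
            anatomy_location = lab$anatomy_location,
            character = lab$character,
            character_surface = lab$character_surface,
            management = lab$management
          )
          sents[s] <- sent
        } else {
          sent <- sents[s]
        }
        offset <- offset + nchar(sent) + 1L # sentences joined by one space
      }
      text <- paste(sents, collapse = " ")

      docs[[doc_no]] <- tibble::tibble(
        doc_id = doc_id,
        patient_id = patients$patient_id[p],
        source_type = sample(names(cfg$source_type_mix), 1L,
                             prob = cfg$source_type_mix),
        diagnosis_chapter = patients$diagnosis_chapter[p],
        age_band = patients$age_band[p],
        gender = patients$gender[p],
        ethnicity = patients$ethnicity[p],
        text = text
      )
      golds[[doc_no]] <- dplyr::bind_rows(gold_rows)
    }
  }

  structure(
    list(
      documents = dplyr::bind_rows(docs),
      gold = dplyr::bind_rows(golds),
      config = cfg
    ),
    class = "pain_corpus"
  )
}

#' @export
print.pain_corpus <- function(x, ...) {
  cat(
    "<pain_corpus>: ", nrow(x$documents), " documents, ",
    length(unique(x$documents$patient_id)), " patients, ",
    nrow(x$gold), " gold annotations (seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a doubly annotated label set
#'
#' Emulates a two-annotator setting over a gold corpus: annotator A returns
#' the gold labels; annotator B returns gold with each label independently
#' perturbed, with probability `disagreement_rate`, to a uniformly chosen
#' *different* category of that attribute. Useful for exercising agreement
#' statistics with a known ground truth.
#'
#' @param corpus A `pain_corpus` from [generate_corpus()], or a gold
#'   annotation tibble.
#' @param disagreement_rate Per-label perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with annotation tibbles `a` and `b`, aligned row-for-row.
#' @export
generate_double_annotations <- function(corpus, disagreement_rate, seed = 1L) {
  stopifnot(disagreement_rate >= 0, disagreement_rate <= 1)
  gold <- if (inherits(corpus, "pain_corpus")) corpus$gold else
    tibble::as_tibble(corpus)
  b <- gold
  with_preserved_seed(as.integer(seed), {
    for (col in c("correct", pain_attributes)) {
      cats <- pain_labels[[col]]
      flip <- stats::runif(nrow(b)) < disagreement_rate
      if (any(flip)) {
        b[[col]][flip] <- vapply(
          b[[col]][flip],
          function(cur) sample(setdiff(cats, cur), 1L),
          character(1)
        )
      }
    }
  })
  list(a = gold, b = b)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
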