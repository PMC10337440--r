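#' Construct rule gazetteers for the pain annotator
#'
#' Each rule family of the annotator is driven by a small editable phrase
#' list rather than hard-coded logic, so the scheme can be tuned to a new
#' corpus without touching code. All phrases must be lowercase. The
#' `anatomy_map` maps surface terms to a closed vocabulary of normalized
#' body regions and includes compound mappings for pain words that encode
#' their own location (headache -> head, heartburn -> chest).
#'
#' @param negation_triggers Single tokens signalling absence, effective
#'   within a 6-token window before a mention ("no", "denies", ...).
#' @param experiencer_triggers Tokens naming a third-person experiencer
#'   (relatives, carers, staff); a mention attributed to someone other than
#'   the patient is not relevant.
#' @param hypothetical_triggers Phrases marking hypothetical, feared, or
#'   metaphorical pain ("fear of", "sore thumb", ...); matched anywhere in
#'   the context window.
#' @param emotional_triggers Relationship-context tokens used, together with
#'   a "causing"-verb, to flag emotional rather than physical pain;
#'   best-effort.
#' @param anatomy_map Named character vector: surface term -> normalized
#'   location. Abdominal and pelvic terms normalize to "abdomen".
#' @param anatomy_compounds Named character vector: mention surfaces that
#'   themselves encode a location.
#' @param character_descriptors Qualitative pain descriptors other than
#'   "chronic" ("shooting", "throbbing", "severe", ...).
#' @param management_medication_triggers Drug-related management phrases.
#' @param management_other_triggers Non-drug management phrases
#'   (physiotherapy, pain clinic, massage).
#' @param inanimate_referents Objects that, immediately after a "burn"-family
#'   mention, mark it as not a pain sense ("burn marks", "burning incense").
#' @param negation_window Number of tokens before a mention within which a
#'   negation trigger is in scope (default 6, a standard clinical-negation
#'   window).
#' @param proximity_window Number of tokens either side of a mention within
#'   which anatomy terms and character descriptors attach (default 3).
#' @return An object of class `pain_gazetteers`.
#' @seealso [default_gazetteers()], [read_gazetteers()], [write_gazetteers()]
#' @export
pain_gazetteers <- function(negation_triggers,
                            experiencer_triggers,
                            hypothetical_triggers,
                            emotional_triggers,
                            anatomy_map,
                            anatomy_compounds,
                            character_descriptors,
                            management_medication_triggers,
                            management_other_triggers,
                            inanimate_referents,
                            negation_window = 6L,
                            proximity_window = 3L) {
  gz <- list(
    negation_triggers = negation_triggers,
    experiencer_triggers = experiencer_triggers,
    hypothetical_triggers = hypothetical_triggers,
    emotional_triggers = emotional_triggers,
    anatomy_map = anatomy_map,
    anatomy_compounds = anatomy_compounds,
    character_descriptors = character_descriptors,
    management_medication_triggers = management_medication_triggers,
    management_other_triggers = management_other_triggers,
    inanimate_referents = inanimate_referents,
    negation_window = as.integer(negation_window),
    proximity_window = as.integer(proximity_window)
  )
  phrase_fields <- setdiff(names(gz), c("negation_window", "proximity_window"))
  for (f in phrase_fields) {
    v <- gz[[f]]
    if (any(c(v, names(v)) != tolower(c(v, names(v))))) {
      stop("gazetteer phrases must be lowercase (field ", f, ")", call. = FALSE)
    }
  }
  structure(gz, class = "pain_gazetteers")
}

#' @export
print.pain_gazetteers <- function(x, ...) {
  cat("<pain_gazetteers>\n")
  for (f in names(x)) {
    v <- x[[f]]
    if (is.numeric(v)) {
      cat("  ", f, ": ", v, "\n", sep = "")
    } else if (!is.null(names(v)) && any(nzchar(names(v)))) {
      cat("  ", f, ": ", paste0(names(v), "->", v, collapse = ", "), "\n", sep = "")
    } else {
      cat("  ", f, ": ", paste(v, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Default rule gazetteers
#'
#' Ships every trigger phrase needed to reproduce the worked annotation
#' examples the scheme is defined by, plus common clinical variants.
#' "Ongoing" is deliberately absent from the chronicity rule: pain character
#' is labelled chronic only when the word "chronic" is explicit, because
#' durations like "ongoing" are inconclusive. The descriptor list carries
#' both "neuropathic" and the variant spelling "uropathic" seen in clinical
#' free text.
#'
#' @return A `pain_gazetteers`.
#' @export
default_gazetteers <- function() {
  pain_gazetteers(
    negation_triggers = c("no", "not", "denies", "denied", "without", "nil"),
    experiencer_triggers = c(
      "mother", "father", "wife", "husband", "son", "daughter",
      "friend", "family", "carer", "staff", "brother", "sister"
    ),
    hypothetical_triggers = c(
      "fear of", "afraid", "if", "would be", "in case", "risk of",
      "sore thumb"
    ),
    emotional_triggers = c(
      "relationship", "partner", "boyfriend", "girlfriend", "divorce",
      "breakup", "marriage"
    ),
    anatomy_map = c(
      head = "head", chest = "chest", back = "back",
      abdomen = "abdomen", abdominal = "abdomen", pelvis = "abdomen",
      pelvic = "abdomen", stomach = "abdomen", tummy = "abdomen",
      belly = "abdomen", neck = "neck", shoulder = "shoulder",
      arm = "arm", leg = "leg", knee = "knee", hip = "hip",
      hand = "hand", foot = "foot", feet = "foot"
    ),
    anatomy_compounds = c(
      headache = "head", headaches = "head",
      backache = "back", backaches = "back",
      heartburn = "chest",
      migraine = "head", migraines = "head",
      lumbago = "back",
      stomachache = "abdomen", stomachaches = "abdomen",
      mittelschmerz = "abdomen"
    ),
    character_descriptors = c(
      "shooting", "throbbing", "burning", "severe", "constant", "sharp",
      "dull", "aching", "stabbing", "neuropathic", "uropathic", "colicky"
    ),
    management_medication_triggers = c(
      "painkiller", "painkillers", "analgesia", "analgesic", "analgesics",
      "paracetamol", "ibuprofen", "codeine", "morphine", "tramadol",
      "pain relief medication"
    ),
    management_other_triggers = c(
      "physiotherapy", "pain clinic", "massage"
    ),
    inanimate_referents = c(
      "things", "marks", "incense", "toast", "candle", "candles",
      "door", "fire", "rubbish", "paper", "food", "wood", "calories"
    )
  )
}
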