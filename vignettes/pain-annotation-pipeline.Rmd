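---
title: "Rule-based pain-mention annotation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based pain-mention annotation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincorpus)
```

## The problem

Pain is common in people under mental-health care, but it is usually a
symptom rather than a diagnosis, so it rarely appears in the coded fields of
an electronic health record. What clinicians write about pain lives in free
text: progress notes and clinical correspondence. Building a labelled corpus
of pain mentions from such text involves a pipeline of distinct steps, and
this package implements each one as a testable, deterministic component:

1. **Extraction** — a wildcard lexicon locates candidate pain mentions.
2. **Annotation** — contextual rules assign the label scheme: is the match
   a real pain mention (*correct*); is it the patient's own physical pain
   (*relevant* / *negated* / *not relevant*); and, where stated, the
   anatomical location, the pain character, and any management measure.
3. **Agreement** — percent agreement and Cohen's $\kappa$ quantify how well
   two annotation passes align, and disagreements are adjudicated.
4. **Summaries** — descriptive tables of the annotated corpus.
5. **Simulation** — because real mental-health records cannot be shared, a
   seeded generator produces synthetic corpora with gold labels whose
   statistical shape matches published summaries of such data.

## Wildcard matching

A lexicon of several hundred pain terms is compressed into a short list of
patterns generalised with `%` placeholders (`%pain%`, `%ache`, `sore%`).
The matcher's semantics have to be pinned down precisely to be testable, and
we fix them as: a `%` matches **zero or more alphabetic characters within a
single token**; matching is case-insensitive and anchored on any side
without a `%`. Tokens are maximal alphabetic runs — hyphens and digits are
separators, which makes edge cases like `e-pain` or `pain123` resolve
predictably (the alphabetic part still matches). These semantics reproduce
all the documented example words and, deliberately, the documented false
positives: `%pain%` matches *painted* and *spain*, and `%aches` matches
*attaches*. Recall is preferred at extraction time; known false-positive
surfaces are **flagged, not dropped**, and the correctness decision is made
by the annotation stage, mirroring manual practice where such hits are
eliminated during annotation.

When several patterns match one token, the pattern with the longest literal
part wins, with alphabetical order on the raw pattern as tie-break, so
output never depends on lexicon ordering. Offsets are 0-based and half-open
throughout; that convention is stated once and asserted everywhere
(`substring(text, start + 1, end)` recovers the surface).

The shipped default covers 16 wildcard patterns over 15 base pain words
(the `ache` family is split into `%ache`, `%aches`, `achin%` rather than a
single `%ache%`, which avoids most *attach*-type hits), three literal terms
(`mittelschmerz`, `lumbago`, `migraine`) and seven exclusion surfaces. A
larger user-supplied term list can be audited against any lexicon with
`verify_coverage()`.

## The annotation rules

Human annotators read surrounding text; a deterministic emulation has to
make the context explicit. We use **the sentence containing the mention**,
bounded by `.`, `!` or `?` followed by whitespace and a capital letter, or
by a newline, and capped at 300 characters on each side of the mention so
unbroken lines cannot produce unbounded windows. The cap and the two scope
windows below are the tunable parameters that matter:

* `negation_window` (default 6 tokens before the mention) — the span within
  which a negation trigger takes scope; six tokens is the conventional
  clinical-negation window size.
* `proximity_window` (default 3 tokens) — how far an anatomy term or a
  character descriptor may sit from the mention and still attach to it.

Relevance applies its rules in a **fixed precedence**, which the scheme's
category definitions leave open; we order them uncertainty > experiencer >
hypothetical/metaphor > negation, with *relevant* as the default. The
ordering is motivated by specificity: a question mark touching the mention
(`?migraine`) marks the whole statement inconclusive regardless of other
cues; a third-person experiencer ("his mother was always in pain")
overrides a negation in the same sentence; and hypothetical frames ("afraid
I will be in pain if ...") are not assertions at all, so they outrank the
negation test. The precedence is asserted by a dedicated property test.

Other decisions worth stating explicitly:

* **Chronicity is literal.** Pain character is `chronic` only when the
  token *chronic* occurs within the proximity window before the mention.
  Duration words such as *ongoing* are inconclusive and never count. Any
  other qualitative descriptor (*severe*, *throbbing*, *shooting*, ...)
  gives `other`; *period pain* is special-cased to `other`.
* **Attributes are computed for negated and not-relevant mentions too.**
  "He is not on painkillers" is a negated mention whose management is
  `medication`; zeroing attributes for non-relevant mentions would lose
  that. Only mentions judged *incorrect* have all downstream attributes
  structurally `n/a`.
* **Experiencer detection is positional, not parsed**: a trigger before the
  mention within the sentence. A full dependency parse would be more
  precise but non-deterministic across parser versions; the positional rule
  reproduces all documented examples.
* **Emotional pain is best-effort.** "Causing her a lot of pain" in a
  relationship context is flagged via a small emotional-context trigger
  list combined with a *causing*-verb; this is the least reliable rule and
  is documented as such.
* **Location normalization** maps surface terms to a closed vocabulary;
  abdominal and pelvic terms normalize to *abdomen*. Compound pain words
  carry their own location (headache → head, heartburn → chest). The
  vocabulary beyond the five most frequent regions (chest, head, back,
  abdomen, neck) is a package choice. The descriptor gazetteer carries both
  *neuropathic* and the variant spelling *uropathic* seen in clinical text.

Every gazetteer ships as an editable sectioned config file
(`inst/extdata/default_gazetteers.cfg`), so all rules can be retuned
without touching code.

## Agreement and adjudication

Cohen's $\kappa$ is unweighted — the categories are nominal. The degenerate
case where chance agreement is 1 (both annotators constant on the same
category) returns exactly 1 for perfect agreement and an explicit `NA`
otherwise, never a floating-point accident. Because "overall agreement" is
ambiguous between mention-level and label-level pooling, the report emits
both: `overall` treats each mention's full label tuple as one item, and a
pooled per-label accuracy is reported alongside. Adjudication resolves each
disagreeing label deterministically by re-running the guideline rules on
the same context window and logs every decision.

## The synthetic generator

The generator's role is to stand in for data that cannot leave its source
system. It emulates the published shape of a mental-health pain corpus:
documents of about 1026 words on average; about 3 mentions per document
with a long right tail (truncated geometric, maximum 84); a relevance mix
of roughly 71/15/13 relevant / not relevant / negated among correct
mentions; 63% of relevant mentions carrying an anatomical location ranked
chest > head > back > abdomen > neck; character chronic/other/none near
3/8/89; management medication/other/none near 7/3/89; and diagnosis-chapter
and demographic metadata matching the published cohort breakdown. Printed
mixes that sum to 99% from rounding are renormalised to exactly 1. The
fraction of extraction matches that are lexical false positives is not
reported anywhere, so its default (5%) is a package choice.

Documents are assembled from a template bank: neutral clinical filler
sentences (verified to contain no lexicon token) plus mention-bearing
frames instantiated per the sampled gold labels — negation frames,
experiencer frames, question-mark frames, hypothetical frames, and
anatomy / character / management slots. Two properties follow by
construction and are tested rather than assumed:

* **Span validity** — gold offsets come from template assembly, not from
  re-running the matcher, and every gold span slices to its surface.
* **Closure** — every frame in the bank is *rule-covered*: the annotator
  recovers its gold labels. The generator and annotator share no code path,
  so closure is a genuine end-to-end check of both sides. The suite
  requires at least 95% label recovery; in practice recovery is complete.

What the generator does **not** emulate: real lexical variety, discourse
structure, spelling noise, de-identification artefacts, and mentions whose
interpretation needs world knowledge. Passing the closure and mixture tests
therefore shows the pipeline is internally correct and statistically
calibrated, not that it would reach the same accuracy on real clinical
text.

Determinism: a config seed fully determines the corpus (byte-identical
output, RNG state restored afterwards); the double-annotation simulator
perturbs each label independently to a uniformly chosen different category
with a given probability, which makes expected percent agreement exactly
$1 - d$ per attribute.

## Sample size for annotation campaigns

`minimum_annotations()` implements the standard sensitivity-style
calculation $n = \lceil z^2 p(1-p) / (d^2 q) \rceil$ for estimating a
detection proportion $p$ to margin $d$ at a given confidence when a
fraction $q$ of items contain the class. All inputs are explicit so any
published parameterisation can be replayed; the function is maximal at
$p = 0.5$ and quadruples when the margin halves.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep binomial 3-sigma
tolerances meaningful while staying desk-scale: mixture recovery uses
corpora of about 2000 mentions at the default 1026-word document length,
closure uses about 700, and perturbation recovery uses 5000 labels. The
$\kappa$ implementation is checked against an exhaustive contingency-table
oracle over all label-pair sequences up to length 4 over a 3-symbol
alphabet (7380 pairs) plus thousands of seeded random sequences up to
length 8, and against an independent library implementation. Empty inputs,
misaligned spans, malformed patterns and invalid mixtures are rejected with
errors naming the offending field rather than propagating `NaN`s.

## A worked run

```{r example, eval = FALSE}
library(paincorpus)

docs <- read_documents(
  system.file("extdata", "example_notes.jsonl", package = "paincorpus")
)
annotate_corpus(docs)

corp <- generate_corpus(synthetic_config(seed = 7, n_patients = 50))
summary <- summarize_corpus(corp$documents, corp$gold)
glance(summary)

pair <- generate_double_annotations(corp, disagreement_rate = 0.1, seed = 8)
tidy(agreement_report(pair$a, pair$b))
```

## Known limitations

* The rules are a deterministic emulation of a human guideline; they have
  no access to discourse context beyond one sentence and no coreference.
* The emotional-pain rule and the location vocabulary beyond the five major
  regions are best-effort package choices.
* The default lexicon is the documented pattern table plus literal terms;
  published full lexicons of several hundred terms are not redistributed
  here, but `verify_coverage()` audits any supplied list.
* Synthetic corpora validate mechanics and calibration, not real-world
  accuracy.
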