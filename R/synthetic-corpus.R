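# Synthetic annotated RCT-like abstracts.
#
# The generator targets the statistical structure of structured RCT
# abstracts, not fluent prose: four rhetorical sections with
# section-specific vocabulary, PICO entity phrases planted (and annotated)
# only in the title and methods sentences, and unannotated lexical copies of
# those phrases planted in results/conclusions to emulate the duplication of
# interventions and outcomes across sections.

.bg_vocab <- c("chronic", "burden", "evidence", "prior", "management",
               "unclear", "limited", "guidelines", "prevalence", "morbidity",
               "worldwide", "uncertainty", "remains", "whether", "benefit",
               "unmet", "need", "rationale", "epidemiology", "comorbid")

.mt_vocab <- c("randomized", "assigned", "allocation", "double-blind",
               "enrolled", "protocol", "baseline", "weeks", "daily",
               "received", "eligibility", "conducted", "multicenter",
               "stratified", "masked", "criteria", "screened", "consented",
               "administered", "randomization")

.rs_vocab <- c("observed", "significant", "difference", "reduction",
               "confidence", "interval", "compared", "events", "incidence",
               "estimate", "occurred", "improvement", "change", "median",
               "follow-up", "adjusted", "absolute", "relative", "greater",
               "attained")

.cc_vocab <- c("conclude", "suggest", "findings", "support", "clinical",
               "practice", "implications", "future", "warranted", "overall",
               "summary", "demonstrates", "tolerated", "effective",
               "recommend", "further", "research", "confirm", "caution",
               "generalizable")

.shared_vocab <- c("study", "group", "treatment", "trial", "data", "effect",
                   "period", "analysis", "measure", "primary")

.conditions <- c("hypertension", "migraine", "asthma", "osteoarthritis",
                 "insomnia", "psoriasis", "fibromyalgia", "depression",
                 "obesity", "dyslipidemia", "anemia", "gout")

.drugs <- c("metoprolol", "liraglutide", "sertraline", "montelukast",
            "apixaban", "infliximab", "gabapentin", "rosuvastatin",
            "omalizumab", "empagliflozin", "donepezil", "baricitinib")

.dose_tags <- c("low-dose", "high-dose", "adjunctive", "intravenous", "oral")

.controls <- c("placebo", "matching placebo", "saline placebo", "usual care",
               "standard care", "sham procedure")

.measures <- c("pain", "fatigue", "mobility", "anxiety", "glycemic",
               "stiffness", "pruritus", "adherence", "cognition", "dyspnea")

.measure_tails <- c("score", "index", "scale")

#' Configuration for the synthetic corpus generator
#'
#' The defaults describe the study conditions the generator emulates: PICO
#' mentions concentrated in the title and methods sentences, heavy
#' duplication of intervention/outcome phrases into the results section, an
#' entity class mix dominated by interventions and outcomes with
#' comparatively few controls, and "placebo" variants dominating the control
#' class. Identical configurations produce bit-identical corpora.
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed; each document draws from its own substream
#'   keyed by `(seed, doc index)`, so corpora are stable under `n_docs`
#'   changes.
#' @param section_vocab_overlap Fraction of filler-word draws taken from a
#'   vocabulary shared across sections (0 = fully section-specific).
#' @param entities_per_methods_sentence Mean number of entity phrases
#'   planted per methods sentence (Poisson).
#' @param cross_section_repeat_prob Probability that a methods/title entity
#'   phrase is copied verbatim (unannotated) into a results sentence.
#' @param label_noise Fraction of body sentences whose gold section label is
#'   flipped to a different label (robustness experiments only; 0 by
#'   default).
#' @param class_probs Sampling probabilities for planted entity classes,
#'   named P/I/C/O.
#' @param placebo_prob Probability that a control phrase is the bare word
#'   "placebo" (the dominant surface form of the class).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 100, seed = 1,
                         section_vocab_overlap = 0.2,
                         entities_per_methods_sentence = 2,
                         cross_section_repeat_prob = 0.8,
                         label_noise = 0,
                         class_probs = c(P = 0.15, I = 0.40, C = 0.08, O = 0.37),
                         placebo_prob = 0.5) {
  cfg <- list(n_docs = as.integer(n_docs), seed = as.integer(seed),
              section_vocab_overlap = section_vocab_overlap,
              entities_per_methods_sentence = entities_per_methods_sentence,
              cross_section_repeat_prob = cross_section_repeat_prob,
              label_noise = label_noise,
              class_probs = class_probs[entity_classes()],
              placebo_prob = placebo_prob)
  fracs <- c(cfg$section_vocab_overlap, cfg$cross_section_repeat_prob,
             cfg$label_noise, cfg$placebo_prob)
  if (any(is.na(fracs)) || any(fracs < 0) || any(fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$n_docs < 0) stop("n_docs must be non-negative")
  if (cfg$entities_per_methods_sentence < 0)
    stop("entities_per_methods_sentence must be non-negative")
  if (any(is.na(cfg$class_probs)) || any(cfg$class_probs < 0) ||
      sum(cfg$class_probs) <= 0)
    stop("class_probs must be non-negative and named P, I, C, O")
  cfg$class_probs <- cfg$class_probs / sum(cfg$class_probs)
  structure(cfg, class = "synth_config")
}

# Draw a filler word for a section, honouring the overlap fraction.
draw_filler <- function(section_vocab, overlap) {
  if (overlap > 0 && stats::runif(1) < overlap) sample(.shared_vocab, 1)
  else sample(section_vocab, 1)
}

# Draw an entity phrase of a given class. `numbers` enables numeric cohort
# sizes in Population phrases (disabled in the separable regime so numeric
# tokens stay class-exclusive).
draw_entity_phrase <- function(cls, placebo_prob, numbers = TRUE) {
  switch(cls,
    P = {
      head <- if (numbers && stats::runif(1) < 0.7)
        paste(sample(20:400, 1), "patients") else
        paste(sample(c("adults", "patients", "participants"), 1))
      paste(head, "with", sample(.conditions, 1))
    },
    I = paste(sample(.dose_tags, 1), sample(.drugs, 1)),
    C = if (stats::runif(1) < placebo_prob) "placebo" else sample(.controls, 1),
    O = paste(sample(.measures, 1), sample(.measure_tails, 1))
  )
}

# Assemble a sentence from alternating filler runs and entity phrases,
# returning the text plus the character spans of the planted phrases.
build_sentence <- function(section_vocab, overlap, entity_specs) {
  words <- character(0)
  spans <- list()
  nlead <- sample(2:4, 1)
  for (k in seq_len(nlead)) words <- c(words, draw_filler(section_vocab, overlap))
  for (sp in entity_specs) {
    prefix <- paste(words, collapse = " ")
    start <- if (nzchar(prefix)) nchar(prefix) + 1L else 0L
    words <- c(words, sp$phrase)
    spans[[length(spans) + 1L]] <- list(start = start,
                                        end = start + nchar(sp$phrase),
                                        cls = sp$cls, text = sp$phrase)
    ntrail <- sample(1:3, 1)
    for (k in seq_len(ntrail)) words <- c(words, draw_filler(section_vocab, overlap))
  }
  text <- paste0(paste(words, collapse = " "), " .")
  list(text = text, spans = spans)
}

generate_document <- function(cfg, i, separable = FALSE) {
  with_seed(substream_seed(cfg$seed, i), {
    overlap <- if (separable) 0 else cfg$section_vocab_overlap
    doc_id <- sprintf("synth%04d", i)
    # Title: one I phrase and one P phrase, annotated.
    ip <- draw_entity_phrase("I", cfg$placebo_prob, numbers = !separable)
    pp <- draw_entity_phrase("P", cfg$placebo_prob, numbers = !separable)
    title <- paste(ip, "in", pp)
    ents <- rbind(
      data.frame(sid = TITLE_SID, start = 0L, end = nchar(ip), cls = "I",
                 text = ip, stringsAsFactors = FALSE),
      data.frame(sid = TITLE_SID, start = nchar(ip) + 4L,
                 end = nchar(title), cls = "P", text = pp,
                 stringsAsFactors = FALSE))
    planted <- c(ip, pp)
    sentences <- list()
    add_sent <- function(text, section) {
      s <- new_sentence(length(sentences), text, gold_section = section)
      sentences[[length(sentences) + 1L]] <<- s
      s
    }
    # Background: filler only.
    for (k in seq_len(sample(1:2, 1)))
      add_sent(build_sentence(.bg_vocab, overlap, list())$text, "background")
    # Methods: filler + annotated entity phrases.
    n_mt <- sample(2:4, 1)
    for (k in seq_len(n_mt)) {
      n_ent <- stats::rpois(1, cfg$entities_per_methods_sentence)
      specs <- list()
      if (n_ent > 0) {
        classes <- sample(entity_classes(), n_ent, replace = TRUE,
                          prob = cfg$class_probs)
        for (cls in classes)
          specs[[length(specs) + 1L]] <-
            list(cls = cls,
                 phrase = draw_entity_phrase(cls, cfg$placebo_prob,
                                             numbers = !separable))
      }
      built <- build_sentence(.mt_vocab, overlap, specs)
      s <- add_sent(built$text, "methods")
      for (sp in built$spans) {
        ents <- rbind(ents, data.frame(sid = s$sid, start = sp$start,
                                       end = sp$end, cls = sp$cls,
                                       text = sp$text, stringsAsFactors = FALSE))
        planted <- c(planted, sp$text)
      }
    }
    # Results: filler, plus unannotated verbatim copies of planted phrases.
    repeats <- planted[stats::runif(length(planted)) < cfg$cross_section_repeat_prob]
    n_rs <- sample(2:3, 1)
    rs_texts <- character(n_rs)
    for (k in seq_len(n_rs))
      rs_texts[k] <- build_sentence(.rs_vocab, overlap, list())$text
    if (length(repeats)) {
      slot <- sample(seq_len(n_rs), length(repeats), replace = TRUE)
      for (j in seq_along(repeats)) {
        body <- sub(" \\.$", "", rs_texts[slot[j]])
        rs_texts[slot[j]] <- paste0(body, " ", repeats[j], " .")
      }
    }
    for (k in seq_len(n_rs)) add_sent(rs_texts[k], "results")
    # Conclusions: filler only.
    for (k in seq_len(sample(1:2, 1)))
      add_sent(build_sentence(.cc_vocab, overlap, list())$text, "conclusions")
    # Optional gold-label noise on body sentences (robustness runs only).
    if (cfg$label_noise > 0) {
      for (k in seq_along(sentences)) {
        if (stats::runif(1) < cfg$label_noise) {
          others <- setdiff(classifier_labels(), sentences[[k]]$gold_section)
          sentences[[k]]$gold_section <- sample(others, 1)
        }
      }
    }
    new_abstract(doc_id, title, sentences, entities = ents, structured = TRUE)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Each document has a title containing one Population and one Intervention
#' phrase, followed by the four sections background, methods, results,
#' conclusions in order, each built from section-specific template
#' vocabulary. Gold entity spans are planted only in the title and methods
#' sentences; with probability `cross_section_repeat_prob` per phrase, a
#' verbatim unannotated copy is inserted into a results sentence. Generation
#' is bit-reproducible given the configuration, and each document draws from
#' a substream keyed by `(seed, doc index)`.
#'
#' @param config A [synth_config()].
#' @return A `pico_corpus` with attributes `config` and `lexicons` (the
#'   per-class entity lexicons and per-section filler vocabularies).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  docs <- lapply(seq_len(config$n_docs),
                 function(i) generate_document(config, i, separable = FALSE))
  corp <- as_corpus(docs)
  attr(corp, "config") <- config
  attr(corp, "lexicons") <- synth_lexicons()
  corp
}

#' @rdname generate_corpus
#' @details `generate_separable_corpus()` forces disjoint per-section filler
#' vocabularies (`section_vocab_overlap = 0`) and suppresses numeric cohort
#' sizes so every entity token belongs to exactly one class lexicon and no
#' filler vocabulary; a consistent learner can reach near-perfect accuracy
#' on such a corpus, which makes it the harness for parameter-recovery
#' tests.
#' @export
generate_separable_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  config$section_vocab_overlap <- 0
  docs <- lapply(seq_len(config$n_docs),
                 function(i) generate_document(config, i, separable = TRUE))
  corp <- as_corpus(docs)
  attr(corp, "config") <- config
  attr(corp, "lexicons") <- synth_lexicons()
  corp
}

#' Lexicons used by the synthetic generator
#'
#' @return A list with per-class entity lexicons (`P`, `I`, `C`, `O`), the
#'   per-section filler vocabularies and the shared overlap vocabulary.
#' @export
synth_lexicons <- function() {
  list(
    P = unique(c("adults", "patients", "participants", "with", .conditions)),
    I = unique(c(.dose_tags, .drugs)),
    C = unique(unlist(strsplit(.controls, " ", fixed = TRUE))),
    O = unique(c(.measures, .measure_tails)),
    filler = list(background = .bg_vocab, methods = .mt_vocab,
                  results = .rs_vocab, conclusions = .cc_vocab,
                  shared = .shared_vocab)
  )
}
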