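# Two-step extraction pipeline: classify sections, filter to title +
# methods, tag PICO entities, aggregate unique elements per document.

#' Select the sentences a tagger should see
#'
#' Returns the title pseudo-sentence plus every sentence whose effective
#' section label (predicted if available, else gold, per `source`) is in
#' `sections_to_tag`, preserving document order.
#'
#' @param abstract A `pico_abstract`.
#' @param sections_to_tag Character vector of section labels (may be empty:
#'   title only).
#' @param source `"auto"`, `"gold"` or `"pred"`.
#' @return A list of `pico_sentence`, title first.
#' @export
filter_sentences <- function(abstract, sections_to_tag = c("title", "methods"),
                             source = c("auto", "gold", "pred")) {
  source <- match.arg(source)
  keep <- list(abstract$title)
  for (sent in abstract$sentences) {
    sec <- switch(source,
      gold = sent$gold_section,
      pred = sent$pred_section,
      auto = if (!is.na(sent$pred_section)) sent$pred_section
             else sent$gold_section)
    if (!is.na(sec) && sec %in% sections_to_tag)
      keep[[length(keep) + 1L]] <- sent
  }
  keep
}

# Dedup normalization: case-fold and collapse whitespace. Lexical-variant
# merging (abbreviations, coreference) is deliberately out of scope.
normalize_mention <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Aggregate unique PICO elements of one document
#'
#' Within each class, predicted (or gold) entity strings are deduplicated by
#' case-insensitive exact match after whitespace collapsing; every unique
#' string is backed by at least one source span.
#'
#' @param abstract A `pico_abstract`.
#' @param which `"pred"` (default) or `"gold"` spans.
#' @return A list of class `pico_record` with fields `doc_id`, `unique`
#'   (data frame `cls`, `text_norm`, `n_spans`) and `spans` (the backing
#'   span table with a `text_norm` column).
#' @export
pico_record <- function(abstract, which = c("pred", "gold")) {
  which <- match.arg(which)
  spans <- if (which == "pred") {
    if (is.null(abstract$pred_entities)) empty_entities()
    else abstract$pred_entities
  } else abstract$entities
  spans$text_norm <- normalize_mention(spans$text)
  if (nrow(spans)) {
    agg <- stats::aggregate(list(n_spans = spans$sid),
                            by = list(cls = spans$cls,
                                      text_norm = spans$text_norm),
                            FUN = length)
    agg <- agg[order(match(agg$cls, entity_classes()), agg$text_norm), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(cls = character(0), text_norm = character(0),
                      n_spans = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(doc_id = abstract$doc_id, unique = agg, spans = spans),
            class = "pico_record")
}

#' @export
print.pico_record <- function(x, ...) {
  cat(sprintf("<pico_record> %s: %d unique elements (%d spans)\n", x$doc_id,
              nrow(x$unique), nrow(x$spans)))
  for (cl in entity_classes()) {
    u <- x$unique$text_norm[x$unique$cls == cl]
    if (length(u)) cat(sprintf("  %s: %s\n", cl, paste(u, collapse = "; ")))
  }
  invisible(x)
}

#' Run the two-step extraction pipeline
#'
#' Classifies every non-title sentence (unless headings are trusted),
#' restricts tagging to the title plus the sentences whose predicted
#' section is in `sections_to_tag`, decodes PICO spans, and aggregates the
#' unique elements per document.
#'
#' @param classifier A `pico_section_model`.
#' @param tagger A `pico_tagger_model`.
#' @param corpus A `pico_corpus`.
#' @param sections_to_tag Sections whose sentences are tagged (default
#'   title + methods).
#' @param trust_headings Copy gold headings instead of classifying
#'   (ablation; default `FALSE` so unstructured abstracts are handled).
#' @param monotone Enforce monotone section order in classification.
#' @return A list with `corpus` (annotated: `pred_section` +
#'   `pred_entities`) and `records` (list of `pico_record`).
#' @export
run_pipeline <- function(classifier, tagger, corpus,
                         sections_to_tag = c("title", "methods"),
                         trust_headings = FALSE, monotone = FALSE) {
  if (!length(corpus))
    return(list(corpus = corpus, records = list()))
  corpus <- classify_corpus(classifier, corpus,
                            trust_headings = trust_headings,
                            monotone = monotone)
  corpus <- tag_corpus(tagger, corpus, sections_to_tag = sections_to_tag,
                       section_source = "pred")
  records <- lapply(corpus, pico_record, which = "pred")
  list(corpus = corpus, records = records)
}
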