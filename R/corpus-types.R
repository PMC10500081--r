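#' @keywords internal
#' @importFrom glmnet glmnet
#' @importFrom Matrix sparseMatrix
#' @importFrom jsonlite write_json read_json
#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_text xml_attr
#' @importFrom stats predict runif rnorm rpois aggregate setNames
#' @importFrom utils read.delim
#' @importFrom tools file_path_sans_ext
"_PACKAGE"

# Label inventories ---------------------------------------------------------

#' Section labels and entity classes
#'
#' `section_labels()` returns the five rhetorical section labels used
#' throughout the package; `"title"` is assigned structurally (the title is a
#' pseudo-sentence) and is never produced by the classifier, which predicts
#' only the remaining four. `entity_classes()` returns the four PICO entity
#' classes: Population, Intervention, Comparison/Control, Outcome.
#' `bio_labels()` returns the nine-label BIO inventory (`O` plus `B-`/`I-`
#' for each class) in the fixed preference order used for tie-breaking:
#' `O` first, then lexicographic.
#'
#' @return A character vector of labels.
#' @export
section_labels <- function() c("title", "background", "methods", "results", "conclusions")

#' @rdname section_labels
#' @export
classifier_labels <- function() c("background", "methods", "results", "conclusions")

#' @rdname section_labels
#' @export
entity_classes <- function() c("P", "I", "C", "O")

#' @rdname section_labels
#' @export
bio_labels <- function() {
  c("O", paste0("B-", sort(entity_classes())), paste0("I-", sort(entity_classes())))
}

TITLE_SID <- -1L

# Seed hygiene: all randomness is driven by explicit seed arguments; the
# caller's global RNG state is saved and restored around every use.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item substream seed, kept within 32-bit integer range.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65536 * 100003 + as.numeric(i) * 7919) %% 2147483629)
}

# Constructors --------------------------------------------------------------

empty_entities <- function() {
  data.frame(sid = integer(0), start = integer(0), end = integer(0),
             cls = character(0), text = character(0), stringsAsFactors = FALSE)
}

#' Build a sentence
#'
#' A sentence carries its index within the document (`sid`, 0-based; the
#' title pseudo-sentence has the reserved `sid = -1`), its raw text, a token
#' table with 0-based half-open character offsets, and optional gold and
#' predicted section labels.
#'
#' @param sid Integer sentence index within the document.
#' @param text Sentence text.
#' @param gold_section,pred_section Section label or `NA`.
#' @return A list of class `pico_sentence`.
#' @export
new_sentence <- function(sid, text, gold_section = NA_character_,
                         pred_section = NA_character_) {
  structure(list(sid = as.integer(sid), text = text,
                 tokens = tokenize(text),
                 gold_section = gold_section, pred_section = pred_section),
            class = "pico_sentence")
}

#' Build an abstract
#'
#' An abstract is a document: a title (modelled as a pseudo-sentence with
#' `sid = -1` and the fixed section label `"title"`), an ordered list of body
#' sentences with contiguous 0-based `sid`s, a table of gold entity spans and
#' optionally a table of predicted spans. Entity spans are character-offset
#' standoff annotations (0-based, half-open) within one sentence, must align
#' with token boundaries, and may not overlap.
#'
#' @param doc_id Non-empty document identifier, unique within a corpus.
#' @param title Title text.
#' @param sentences List of `pico_sentence` objects (without the title).
#' @param entities Gold entity span table with columns
#'   `sid, start, end, cls, text`.
#' @param structured Logical: did the source carry recognised section headings?
#' @param pred_entities Optional predicted span table (same columns).
#' @return A list of class `pico_abstract`.
#' @export
new_abstract <- function(doc_id, title, sentences = list(),
                         entities = empty_entities(), structured = FALSE,
                         pred_entities = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  title_sent <- new_sentence(TITLE_SID, title, gold_section = "title",
                             pred_section = "title")
  ab <- structure(list(doc_id = doc_id, title = title_sent,
                       sentences = sentences,
                       entities = as_entity_frame(entities),
                       pred_entities = if (is.null(pred_entities)) NULL
                                       else as_entity_frame(pred_entities),
                       structured = isTRUE(structured)),
                  class = "pico_abstract")
  validate_abstract(ab)
}

as_entity_frame <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(empty_entities())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x <- x[, c("sid", "start", "end", "cls", "text")]
  x$sid <- as.integer(x$sid); x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  rownames(x) <- NULL
  x
}

#' Retrieve a sentence by sid (sid -1 returns the title pseudo-sentence)
#' @param abstract A `pico_abstract`.
#' @param sid Sentence index; `-1` for the title.
#' @return A `pico_sentence`.
#' @export
get_sentence <- function(abstract, sid) {
  if (sid == TITLE_SID) return(abstract$title)
  idx <- sid + 1L
  if (idx < 1L || idx > length(abstract$sentences))
    stop("no sentence with sid ", sid, " in document ", abstract$doc_id)
  abstract$sentences[[idx]]
}

#' All sentences of an abstract, optionally including the title
#' @inheritParams get_sentence
#' @param include_title Include the title pseudo-sentence first?
#' @return List of `pico_sentence`.
#' @export
abstract_sentences <- function(abstract, include_title = TRUE) {
  if (include_title) c(list(abstract$title), abstract$sentences)
  else abstract$sentences
}

validate_abstract <- function(ab) {
  sids <- vapply(ab$sentences, function(s) s$sid, integer(1))
  if (length(sids) && !identical(sids, seq_along(sids) - 1L))
    stop("sentence sids must be contiguous 0-based in document ", ab$doc_id)
  validate_spans(ab, ab$entities)
  if (!is.null(ab$pred_entities)) validate_spans(ab, ab$pred_entities)
  ab
}

# Check span invariants: sid resolves, offsets in range, text matches slice,
# token-aligned, non-overlapping within a sentence.
validate_spans <- function(ab, spans) {
  if (nrow(spans) == 0L) return(invisible(spans))
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    sent <- get_sentence(ab, sp$sid)
    n <- nchar(sent$text)
    if (sp$start < 0L || sp$end > n || sp$start >= sp$end)
      stop(sprintf("invalid span [%d,%d) in doc %s sid %d",
                   sp$start, sp$end, ab$doc_id, sp$sid))
    slice <- substr(sent$text, sp$start + 1L, sp$end)
    if (!identical(slice, sp$text))
      stop(sprintf("span text mismatch in doc %s sid %d: '%s' vs sliced '%s'",
                   ab$doc_id, sp$sid, sp$text, slice))
    tok <- sent$tokens
    if (!(sp$start %in% tok$start) || !(sp$end %in% tok$end))
      stop(sprintf("span [%d,%d) '%s' in doc %s sid %d is not token-aligned",
                   sp$start, sp$end, sp$text, ab$doc_id, sp$sid))
    if (!(sp$cls %in% entity_classes()))
      stop("unknown entity class: ", sp$cls)
  }
  for (s in unique(spans$sid)) {
    ss <- spans[spans$sid == s, , drop = FALSE]
    ss <- ss[order(ss$start), , drop = FALSE]
    if (nrow(ss) > 1L && any(ss$start[-1L] < ss$end[-nrow(ss)]))
      stop(sprintf("overlapping spans in doc %s sid %d (flat schema required)",
                   ab$doc_id, s))
  }
  invisible(spans)
}

#' @export
print.pico_abstract <- function(x, ...) {
  cat(sprintf("<pico_abstract> %s%s\n", x$doc_id,
              if (x$structured) " [structured]" else ""))
  cat("  title: ", substr(x$title$text, 1, 70), "\n", sep = "")
  cat(sprintf("  %d sentences, %d gold spans%s\n", length(x$sentences),
              nrow(x$entities),
              if (!is.null(x$pred_entities))
                sprintf(", %d predicted spans", nrow(x$pred_entities)) else ""))
  invisible(x)
}

#' @export
print.pico_corpus <- function(x, ...) {
  nsent <- sum(vapply(x, function(a) length(a$sentences), integer(1)))
  nent <- sum(vapply(x, function(a) nrow(a$entities), integer(1)))
  cat(sprintf("<pico_corpus> %d documents, %d sentences, %d gold spans\n",
              length(x), nsent, nent))
  invisible(x)
}

#' Assemble a corpus from abstracts
#' @param abstracts List of `pico_abstract` objects with unique `doc_id`s.
#' @return A list of class `pico_corpus`.
#' @export
as_corpus <- function(abstracts) {
  ids <- vapply(abstracts, function(a) a$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus: ",
                               ids[duplicated(ids)][1])
  structure(abstracts, names = ids, class = "pico_corpus")
}
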