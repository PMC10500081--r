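# Tokenization and sentence segmentation -----------------------------------

#' Tokenize a sentence with character offsets
#'
#' Deterministic rule-based tokenizer: the text is split on whitespace, then
#' leading and trailing punctuation characters of each chunk are peeled off
#' as single-character tokens. Internal punctuation (hyphens in "COVID-19",
#' decimal points, slashes) stays inside the token. Offsets are 0-based,
#' half-open, and slicing the sentence with them reproduces each token
#' exactly, so tokenization is offset-faithful by construction.
#'
#' @param text A character scalar (may be empty).
#' @return A data frame with columns `text`, `start`, `end` (0-based,
#'   half-open character offsets into `text`).
#' @examples
#' tokenize("86 hospitalized COVID-19 patients")$text
#' tokenize("placebo.")$text
#' @export
tokenize <- function(text) {
  empty <- data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L            # to 0-based
  lens <- attr(m, "match.length")
  out_text <- character(0); out_start <- integer(0); out_end <- integer(0)
  chunks <- regmatches(text, gregexpr("\\S+", text))[[1]]
  for (k in seq_along(chunks)) {
    chars <- strsplit(chunks[k], "", fixed = TRUE)[[1]]
    is_punct <- grepl("[^[:alnum:]]", chars)
    n <- length(chars)
    lead <- 0L
    while (lead < n - 1L && is_punct[lead + 1L]) lead <- lead + 1L
    trail <- 0L
    while (trail < n - 1L - lead && is_punct[n - trail]) trail <- trail + 1L
    base <- starts[k]
    if (lead > 0L) for (j in seq_len(lead)) {
      out_text <- c(out_text, chars[j])
      out_start <- c(out_start, base + j - 1L); out_end <- c(out_end, base + j)
    }
    core_start <- base + lead
    core_end <- base + n - trail
    out_text <- c(out_text, substr(chunks[k], lead + 1L, n - trail))
    out_start <- c(out_start, core_start); out_end <- c(out_end, core_end)
    if (trail > 0L) for (j in seq_len(trail)) {
      out_text <- c(out_text, chars[n - trail + j])
      out_start <- c(out_start, core_end + j - 1L)
      out_end <- c(out_end, core_end + j)
    }
  }
  data.frame(text = out_text, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

# Abbreviations protected from sentence splitting (compared lowercased,
# final period stripped).
.protected_abbrev <- c("vs", "e.g", "i.e", "dr", "mr", "mrs", "ms", "prof",
                       "fig", "al", "etc", "ca", "approx", "no", "st", "resp")

#' Split text into sentences
#'
#' Rule-based splitter: a sentence boundary is a run of `.`, `?` or `!`
#' followed by whitespace and an uppercase letter or digit, unless the word
#' immediately before the period is a protected abbreviation ("vs.", "e.g.",
#' "Dr.", ...). Deterministic and total.
#'
#' @param text A character scalar.
#' @return Character vector of sentence strings (trimmed, possibly empty).
#' @export
split_sentences <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  m <- gregexpr("[.?!]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  cut_after <- integer(0)
  for (k in seq_along(m)) {
    pos <- as.integer(m[k]); len <- attr(m, "match.length")[k]
    before <- substr(text, 1, pos - 1L)
    word <- regmatches(before, regexpr("[A-Za-z]+(\\.[A-Za-z]+)*$", before))
    if (length(word) == 1L && tolower(word) %in% .protected_abbrev) next
    cut_after <- c(cut_after, pos + len - 1L)
  }
  if (!length(cut_after)) return(text)
  bounds <- c(0L, cut_after, nchar(text))
  out <- character(0)
  for (k in seq_len(length(bounds) - 1L)) {
    piece <- trimws(substr(text, bounds[k] + 1L, bounds[k + 1L]))
    if (nzchar(piece)) out <- c(out, piece)
  }
  out
}

# Section normalization and heading maps ------------------------------------

#' Normalize a raw section category
#'
#' Maps a raw NLM-style category to one of the four classifier section
#' labels. Following the convention of collapsing rhetorically similar
#' openings, `objective` is remapped to `background`; the other four
#' categories map to themselves (so the function is idempotent). Matching is
#' case-insensitive.
#'
#' @param raw Raw category string, one of background, objective, methods,
#'   results, conclusions (any case).
#' @return One of `"background"`, `"methods"`, `"results"`, `"conclusions"`.
#' @export
normalize_section <- function(raw) {
  r <- tolower(trimws(raw))
  if (identical(r, "objective")) return("background")
  if (r %in% classifier_labels()) return(r)
  stop("unmappable category: '", raw, "'")
}

normalize_heading <- function(h) {
  toupper(trimws(sub(":\\s*$", "", trimws(h))))
}

#' Read a heading-to-category mapping table
#'
#' A two-column tab-separated table mapping structured-abstract headings
#' (e.g. `MATERIALS AND METHODS`) to one of the raw categories background,
#' objective, methods, results, conclusions. Headings are matched
#' case-insensitively after stripping a trailing colon. A default map with
#' ~40 common headings ships with the package.
#'
#' @param path Path to a TSV file with columns `heading` and `category`;
#'   default is the packaged map.
#' @return A data frame of class `pico_heading_map`.
#' @export
read_heading_map <- function(path = system.file("extdata", "heading_map.tsv",
                                                package = "picopipe")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("heading", "category") %in% names(df)))
  df$heading <- normalize_heading(df$heading)
  df$category <- tolower(trimws(df$category))
  bad <- setdiff(df$category, c(classifier_labels(), "objective"))
  if (length(bad)) stop("heading map contains unknown categories: ",
                        paste(bad, collapse = ", "))
  structure(df, class = c("pico_heading_map", "data.frame"))
}

#' @rdname read_heading_map
#' @export
default_heading_map <- function() {
  if (is.null(.pkg_cache$heading_map))
    .pkg_cache$heading_map <- read_heading_map()
  .pkg_cache$heading_map
}

.pkg_cache <- new.env(parent = emptyenv())

# Look up a heading; returns the normalized section label or NA (unknown).
map_heading <- function(heading, map = default_heading_map()) {
  h <- normalize_heading(heading)
  i <- match(h, map$heading)
  if (is.na(i)) return(NA_character_)
  normalize_section(map$category[i])
}

# Readers -------------------------------------------------------------------

check_encoding <- function(lines) {
  ok <- validUTF8(lines)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    raw_line <- charToRaw(lines[bad])
    off <- which(!validUTF8(sapply(seq_along(raw_line), function(i)
      rawToChar(raw_line[seq_len(i)]))))
    stop(sprintf("undecodable bytes at line %d, byte offset %d", bad,
                 if (length(off)) off[1] else 1L))
  }
  invisible(lines)
}

#' Read a MEDLINE-style plain-text abstract
#'
#' The first non-empty line is the title; each subsequent line is either
#' `HEADING: text` (the heading is looked up in the heading map and stripped)
#' or plain text, which inherits the currently open section (if any).
#' Unknown headings produce a warning and leave their sentences unlabeled so
#' unstructured abstracts still flow through the classifier path.
#'
#' @param path Path to a text file, or a character vector of lines via
#'   `lines =`.
#' @param doc_id Document identifier; defaults to the file name.
#' @param map A `pico_heading_map`.
#' @param lines Optional character vector used instead of reading `path`.
#' @return A `pico_abstract`; `structured` is `TRUE` iff at least one heading
#'   matched the map.
#' @export
read_abstract_text <- function(path = NULL, doc_id = NULL,
                               map = default_heading_map(), lines = NULL) {
  if (is.null(lines)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (is.null(doc_id)) doc_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(doc_id)) doc_id <- "doc"
  check_encoding(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty document")
  title <- trimws(lines[1])
  body <- lines[-1]
  sentences <- list()
  structured <- FALSE
  current <- NA_character_
  for (ln in body) {
    hm <- regexec("^([A-Za-z][A-Za-z /&,-]*):\\s*(.*)$", ln)[[1]]
    txt <- ln
    if (hm[1] != -1L) {
      parts <- regmatches(ln, regexec("^([A-Za-z][A-Za-z /&,-]*):\\s*(.*)$", ln))[[1]]
      sec <- map_heading(parts[2], map)
      if (is.na(sec)) {
        warning("unknown heading '", parts[2], "' in document ", doc_id)
        current <- NA_character_
      } else {
        structured <- TRUE
        current <- sec
      }
      txt <- parts[3]
    }
    for (s in split_sentences(txt)) {
      sentences[[length(sentences) + 1L]] <-
        new_sentence(length(sentences), s, gold_section = current)
    }
  }
  new_abstract(doc_id, title, sentences, structured = structured)
}

#' Read abstracts from a PubMed-XML subset
#'
#' Supports a minimal PubMed XML dialect: one or more `PubmedArticle`
#' records (or a single record as the whole document), each with an
#' `ArticleTitle` and zero or more `AbstractText` elements whose optional
#' `NlmCategory` (or `Label`) attribute carries the raw section category.
#' `OBJECTIVE` is normalized to `background`; records without any
#' `AbstractText` yield an empty sentence list with a warning.
#'
#' @param path Path to an XML file (or an XML string).
#' @param map A `pico_heading_map` used to resolve `Label` attributes that
#'   are not canonical NLM categories.
#' @return A `pico_corpus`.
#' @export
read_pubmed_xml <- function(path, map = default_heading_map()) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (!length(arts)) arts <- list(doc)
  out <- list()
  for (i in seq_along(arts)) {
    art <- arts[[i]]
    pmid <- xml2::xml_find_first(art, ".//PMID")
    doc_id <- if (inherits(pmid, "xml_missing") || is.na(xml2::xml_text(pmid)))
      sprintf("pmid_%d", i) else xml2::xml_text(pmid)
    title_node <- xml2::xml_find_first(art, ".//ArticleTitle")
    title <- if (inherits(title_node, "xml_missing")) "" else
      trimws(xml2::xml_text(title_node))
    abst <- xml2::xml_find_all(art, ".//AbstractText")
    sentences <- list()
    structured <- FALSE
    if (!length(abst)) {
      warning("record ", doc_id, " has no AbstractText; empty abstract")
    }
    for (node in abst) {
      cat_attr <- xml2::xml_attr(node, "NlmCategory")
      if (is.na(cat_attr)) cat_attr <- xml2::xml_attr(node, "Label")
      sec <- NA_character_
      if (!is.na(cat_attr) && nzchar(cat_attr)) {
        sec <- tryCatch(normalize_section(cat_attr), error = function(e) NA_character_)
        if (is.na(sec)) sec <- map_heading(cat_attr, map)
        if (is.na(sec)) warning("unmappable category '", cat_attr,
                                "' in record ", doc_id)
        else structured <- TRUE
      }
      for (s in split_sentences(trimws(xml2::xml_text(node)))) {
        sentences[[length(sentences) + 1L]] <-
          new_sentence(length(sentences), s, gold_section = sec)
      }
    }
    out[[length(out) + 1L]] <- new_abstract(doc_id, title, sentences,
                                            structured = structured)
  }
  as_corpus(out)
}

# BIO codec ------------------------------------------------------------------

#' Convert entity spans to a BIO tag sequence
#'
#' The first token of each span receives `B-<cls>`, subsequent tokens
#' `I-<cls>`, and all remaining tokens `O`. Spans must be token-aligned and
#' non-overlapping; violations are errors naming the offending span.
#' `bio_to_spans()` inverts the encoding losslessly on valid input.
#'
#' @param sentence A `pico_sentence`.
#' @param spans Entity span table restricted to this sentence's `sid`.
#' @return Character vector of BIO tags, one per token.
#' @export
spans_to_bio <- function(sentence, spans) {
  tok <- sentence$tokens
  tags <- rep("O", nrow(tok))
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)]))
    stop("overlapping spans in sid ", sentence$sid)
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    ti <- which(tok$start >= sp$start & tok$end <= sp$end)
    aligned <- length(ti) > 0L &&
      tok$start[ti[1]] == sp$start && tok$end[ti[length(ti)]] == sp$end
    if (!aligned)
      stop(sprintf("span [%d,%d) '%s' is not token-aligned", sp$start, sp$end,
                   sp$text))
    tags[ti[1]] <- paste0("B-", sp$cls)
    if (length(ti) > 1L) tags[ti[-1L]] <- paste0("I-", sp$cls)
  }
  tags
}

#' Repair an invalid BIO sequence
#'
#' Applies the conservative-begin policy: an `I-c` tag whose predecessor is
#' neither `B-c` nor `I-c` becomes `B-c`, which preserves the predicted
#' extent. Valid sequences pass through unchanged.
#'
#' @param tags Character vector of BIO tags.
#' @return Repaired tag vector.
#' @export
repair_bio <- function(tags) {
  if (!length(tags)) return(tags)
  prev <- "O"
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      cls <- substring(t, 3)
      if (!(prev %in% paste0(c("B-", "I-"), cls)))
        tags[i] <- paste0("B-", cls)
    }
    prev <- tags[i]
  }
  tags
}

#' @rdname spans_to_bio
#' @param tags Character vector of BIO tags (one per token); invalid
#'   sequences are first repaired with [repair_bio()].
#' @export
bio_to_spans <- function(sentence, tags) {
  tok <- sentence$tokens
  if (length(tags) != nrow(tok))
    stop(sprintf("tag/token length mismatch in sid %d: %d tags, %d tokens",
                 sentence$sid, length(tags), nrow(tok)))
  tags <- repair_bio(tags)
  out <- empty_entities()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      cls <- substring(tags[i], 3)
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", cls))
        j <- j + 1L
      start <- tok$start[i]; end <- tok$end[j]
      out <- rbind(out, data.frame(
        sid = sentence$sid, start = start, end = end, cls = cls,
        text = substr(sentence$text, start + 1L, end),
        stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Gold/predicted tag helpers used throughout evaluation.
sentence_tags <- function(abstract, sentence, which = c("gold", "pred")) {
  which <- match.arg(which)
  spans <- if (which == "gold") abstract$entities else {
    if (is.null(abstract$pred_entities)) empty_entities()
    else abstract$pred_entities
  }
  spans_to_bio(sentence, spans[spans$sid == sentence$sid, , drop = FALSE])
}

# CoNLL ---------------------------------------------------------------------

#' Write/read a corpus in CoNLL token/tag format
#'
#' One token per line as `token<TAB>tag`, blank line between sentences, and a
#' `-DOCSTART- <doc_id> <sid> <section>` comment line opening each sentence
#' block (the title pseudo-sentence uses sid -1). Sentence text is
#' reconstructed by joining tokens with single spaces, so the round trip is
#' exact on tokens, tags and section labels (not raw whitespace).
#'
#' @param corpus A `pico_corpus`.
#' @param path Output/input file path.
#' @param which Which annotation layer to serialize (`"gold"` or `"pred"`).
#' @return `read_conll()` returns a `pico_corpus`; `write_conll()` its path,
#'   invisibly.
#' @export
write_conll <- function(corpus, path, which = c("gold", "pred")) {
  which <- match.arg(which)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (ab in corpus) {
    for (sent in abstract_sentences(ab)) {
      sec <- if (sent$sid == TITLE_SID) "title" else
        if (is.na(sent$gold_section)) "NA" else sent$gold_section
      writeLines(sprintf("-DOCSTART- %s %d %s", ab$doc_id, sent$sid, sec), con)
      tags <- sentence_tags(ab, sent, which)
      if (nrow(sent$tokens))
        writeLines(paste(sent$tokens$text, tags, sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  docs <- list()
  cur_doc <- NULL; cur_title <- NULL
  cur_sents <- list(); cur_ents <- empty_entities()
  pending <- NULL   # list(doc_id, sid, section, tokens, tags)
  flush_sentence <- function() {
    if (is.null(pending)) return()
    text <- paste(pending$tokens, collapse = " ")
    sent <- new_sentence(pending$sid, text,
                         gold_section = if (pending$section %in% c("NA", ""))
                           NA_character_ else pending$section)
    sp <- bio_to_spans(sent, pending$tags)
    if (pending$sid == TITLE_SID) cur_title <<- sent
    else cur_sents[[length(cur_sents) + 1L]] <<- sent
    cur_ents <<- rbind(cur_ents, sp)
    pending <<- NULL
  }
  flush_doc <- function() {
    if (is.null(cur_doc)) return()
    flush_sentence()
    title_text <- if (is.null(cur_title)) "" else cur_title$text
    docs[[length(docs) + 1L]] <<- new_abstract(
      cur_doc, title_text, cur_sents, entities = cur_ents,
      structured = any(vapply(cur_sents, function(s) !is.na(s$gold_section),
                              logical(1))))
    cur_title <<- NULL; cur_sents <<- list(); cur_ents <<- empty_entities()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush_sentence(); next }
    if (startsWith(ln, "-DOCSTART-")) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 4L)
        stop("malformed -DOCSTART- line at line ", i)
      flush_sentence()
      if (!identical(parts[2], cur_doc)) { flush_doc(); cur_doc <- parts[2] }
      pending <- list(doc_id = parts[2], sid = as.integer(parts[3]),
                      section = parts[4], tokens = character(0),
                      tags = character(0))
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L)
      stop("ragged line at line ", i, ": expected 2 tab-separated fields, got ",
           length(fields))
    if (is.null(pending)) stop("token line outside a sentence block at line ", i)
    pending$tokens <- c(pending$tokens, fields[1])
    pending$tags <- c(pending$tags, fields[2])
  }
  flush_doc()
  as_corpus(docs)
}

# Standoff JSON --------------------------------------------------------------

entities_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Write/read a corpus as standoff JSON
#'
#' Character-offset standoff serialization: each document carries its
#' `doc_id`, title, `structured` flag, sentences (text plus gold/predicted
#' section labels) and entity spans (`sid`, `start`, `end`, `cls`, `text`;
#' offsets 0-based, half-open). On load each span's `text` is re-validated
#' against the sliced sentence text and mismatches are rejected with an error
#' naming the document and span.
#'
#' @param corpus A `pico_corpus`.
#' @param path File path.
#' @return `read_standoff_json()` returns a `pico_corpus`;
#'   `write_standoff_json()` its path, invisibly.
#' @export
write_standoff_json <- function(corpus, path) {
  payload <- lapply(unname(as.list(corpus)), function(ab) {
    list(doc_id = ab$doc_id, title = ab$title$text, structured = ab$structured,
         sentences = lapply(ab$sentences, function(s)
           list(sid = s$sid, text = s$text,
                gold_section = s$gold_section, pred_section = s$pred_section)),
         entities = entities_to_list(ab$entities),
         pred_entities = if (is.null(ab$pred_entities)) NULL
           else entities_to_list(ab$pred_entities))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
  invisible(path)
}

list_to_entities <- function(lst) {
  if (is.null(lst) || !length(lst)) return(empty_entities())
  do.call(rbind, lapply(lst, function(e)
    data.frame(sid = as.integer(e$sid), start = as.integer(e$start),
               end = as.integer(e$end), cls = e$cls, text = e$text,
               stringsAsFactors = FALSE)))
}

#' @rdname write_standoff_json
#' @export
read_standoff_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  docs <- lapply(payload, function(d) {
    sents <- lapply(d$sentences, function(s)
      new_sentence(s$sid, s$text,
                   gold_section = if (is.null(s$gold_section)) NA_character_
                     else s$gold_section,
                   pred_section = if (is.null(s$pred_section)) NA_character_
                     else s$pred_section))
    ab <- tryCatch(
      new_abstract(d$doc_id, d$title, sents,
                   entities = list_to_entities(d$entities),
                   structured = isTRUE(d$structured),
                   pred_entities = if (is.null(d$pred_entities)) NULL
                     else list_to_entities(d$pred_entities)),
      error = function(e) stop("while loading doc ", d$doc_id, ": ",
                               conditionMessage(e)))
    ab
  })
  as_corpus(docs)
}
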