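test_that("tokenizer splits on whitespace and peels edge punctuation", {
  cases <- list(
    list("86 hospitalized COVID-19 patients",
         c("86", "hospitalized", "COVID-19", "patients")),
    list("placebo.", c("placebo", ".")),
    list("(n=42)", c("(", "n=42", ")")),
    list("", character(0)),
    list("   ", character(0)),
    list("vs. placebo-controlled trial.",
         c("vs", ".", "placebo-controlled", "trial", ".")))
  for (cs in cases) expect_identical(tokenize(cs[[1]])$text, cs[[2]],
                                     info = cs[[1]])
})

test_that("token offsets are 0-based half-open and offset-faithful", {
  withr_seed <- 42; set.seed(withr_seed)
  texts <- c("A double-blind trial (RCT) of X.",
             "  leading and   irregular   spacing ",
             replicate(20, paste(sample(c("alpha", "beta-2", "(x)", "3.5",
                                          "mg/dl", "p<0.05"), 8, TRUE),
                                 collapse = " ")))
  for (txt in texts) {
    tok <- tokenize(txt)
    if (!nrow(tok)) next
    expect_true(all(tok$start >= 0 & tok$start < tok$end &
                      tok$end <= nchar(txt)))
    expect_identical(substring(txt, tok$start + 1, tok$end), tok$text)
    expect_true(all(tok$start[-1] >= tok$end[-nrow(tok)]))  # sorted, disjoint
    # concatenating slices with the skipped gaps reconstructs the text
    rebuilt <- ""
    prev_end <- 0L
    for (i in seq_len(nrow(tok))) {
      rebuilt <- paste0(rebuilt, substr(txt, prev_end + 1, tok$start[i]),
                        tok$text[i])
      prev_end <- tok$end[i]
    }
    rebuilt <- paste0(rebuilt, substr(txt, prev_end + 1, nchar(txt)))
    expect_identical(rebuilt, txt)
  }
})

test_that("sentence splitter honours boundaries and protected abbreviations", {
  expect_identical(split_sentences("We did X. We measured Y."),
                   c("We did X.", "We measured Y."))
  expect_identical(split_sentences("Drug A vs. placebo was tested. It worked."),
                   c("Drug A vs. placebo was tested.", "It worked."))
  expect_identical(split_sentences("Dosing (e.g. 5 mg) was fixed."),
                   "Dosing (e.g. 5 mg) was fixed.")
  expect_identical(split_sentences(""), character(0))
  expect_identical(split_sentences("No terminal punctuation here"),
                   "No terminal punctuation here")
})

test_that("normalize_section remaps objective to background and is idempotent", {
  expect_identical(normalize_section("OBJECTIVE"), "background")
  expect_identical(normalize_section("methods"), "methods")
  for (s in classifier_labels())
    expect_identical(normalize_section(normalize_section(s)),
                     normalize_section(s))
  expect_error(normalize_section("design"), "unmappable")
})

test_that("MEDLINE-style text reader maps headings and tracks structure", {
  # title-only document
  ab <- read_abstract_text(lines = "Only a title here.", doc_id = "t")
  expect_length(ab$sentences, 0)
  expect_false(ab$structured)

  ab <- read_abstract_text(lines = c("T.", "METHODS: We did X. We measured Y."),
                           doc_id = "d1")
  expect_length(ab$sentences, 2)
  expect_identical(vapply(ab$sentences, function(s) s$gold_section,
                          character(1)), c("methods", "methods"))
  expect_true(ab$structured)
  expect_false(grepl("METHODS", ab$sentences[[1]]$text))

  # unknown heading: warning, unlabeled sentences, unstructured
  expect_warning(
    ab2 <- read_abstract_text(lines = c("T.", "FOO: We did X."), doc_id = "d2"),
    "unknown heading")
  expect_true(is.na(ab2$sentences[[1]]$gold_section))
  expect_false(ab2$structured)

  # continuation lines inherit the open section
  ab3 <- read_abstract_text(lines = c("T.", "RESULTS: First result.",
                                      "Second result."), doc_id = "d3")
  expect_identical(vapply(ab3$sentences, function(s) s$gold_section,
                          character(1)), c("results", "results"))

  expect_error(read_abstract_text(lines = character(0), doc_id = "e"),
               "empty document")
})

test_that("PubMed XML reader normalizes categories and handles degenerate records", {
  xml <- paste0(
    '<PubmedArticleSet>',
    '<PubmedArticle><MedlineCitation><PMID>111</PMID><Article>',
    '<ArticleTitle>Trial of X.</ArticleTitle><Abstract>',
    '<AbstractText Label="OBJECTIVE" NlmCategory="OBJECTIVE">We aimed high.</AbstractText>',
    '<AbstractText Label="METHODS" NlmCategory="METHODS">We did X. We did Y.</AbstractText>',
    '</Abstract></Article></MedlineCitation></PubmedArticle>',
    '<PubmedArticle><MedlineCitation><PMID>222</PMID><Article>',
    '<ArticleTitle>No abstract.</ArticleTitle>',
    '</Article></MedlineCitation></PubmedArticle>',
    '</PubmedArticleSet>')
  expect_warning(corp <- read_pubmed_xml(xml), "no AbstractText")
  expect_length(corp, 2)
  secs <- vapply(corp[["111"]]$sentences, function(s) s$gold_section,
                 character(1))
  expect_identical(secs, c("background", "methods", "methods"))
  expect_true(corp[["111"]]$structured)
  expect_length(corp[["222"]]$sentences, 0)
  expect_error(read_pubmed_xml("<unclosed>"), regexp = ".")
})

test_that("spans_to_bio follows the BIO definition", {
  s <- new_sentence(0L, "aa bb cc dd")
  sp <- entity_df(0L, 0L, 5L, "P", "aa bb")
  expect_identical(spans_to_bio(s, sp), c("B-P", "I-P", "O", "O"))
  expect_identical(spans_to_bio(s, NULL), rep("O", 4))
  # adjacent spans of different classes
  sp2 <- rbind(entity_df(0L, 0L, 2L, "I", "aa"),
               entity_df(0L, 3L, 5L, "C", "bb"))
  expect_identical(spans_to_bio(s, sp2), c("B-I", "B-C", "O", "O"))
  # non-aligned span rejected by name
  expect_error(spans_to_bio(s, entity_df(0L, 0L, 4L, "P", "aa b")),
               "not token-aligned")
  # overlap rejected
  sp3 <- rbind(entity_df(0L, 0L, 5L, "P", "aa bb"),
               entity_df(0L, 3L, 8L, "O", "bb cc"))
  expect_error(spans_to_bio(s, sp3), "overlap")
})

test_that("bio_to_spans inverts spans_to_bio and repairs invalid sequences", {
  s <- new_sentence(0L, "aa bb cc")
  expect_identical(bio_to_spans(s, c("B-P", "I-P", "O")),
                   entity_df(0L, 0L, 5L, "P", "aa bb"))
  # orphan I- repaired via conservative begin
  expect_identical(bio_to_spans(s, c("O", "I-P", "O")),
                   entity_df(0L, 3L, 5L, "P", "bb"))
  expect_identical(repair_bio(c("O", "I-P", "I-C")), c("O", "B-P", "B-C"))
  expect_identical(nrow(bio_to_spans(s, rep("O", 3))), 0L)
  expect_error(bio_to_spans(s, c("O", "O")), "length mismatch")
})

test_that("BIO round-trip is the identity on random valid annotations", {
  set.seed(7)
  for (rep in seq_len(1000)) {
    sent <- random_sentence(0L, sample(1:12, 1))
    spans <- random_spans(sent)
    tags <- spans_to_bio(sent, spans)
    back <- bio_to_spans(sent, tags)
    expect_identical(back[order(back$start), , drop = FALSE],
                     spans[order(spans$start), , drop = FALSE])
  }
})

test_that("CoNLL writer and reader are mutually inverse on tokens, tags, sections", {
  corp <- generate_corpus(synth_config(n_docs = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(corp, path)
  back <- read_conll(path)
  expect_identical(length(back), length(corp))
  for (k in seq_along(corp)) {
    a <- corp[[k]]; b <- back[[k]]
    expect_identical(b$doc_id, a$doc_id)
    expect_identical(length(b$sentences), length(a$sentences))
    for (j in seq_along(a$sentences)) {
      expect_identical(b$sentences[[j]]$tokens$text,
                       a$sentences[[j]]$tokens$text)
      expect_identical(b$sentences[[j]]$gold_section,
                       a$sentences[[j]]$gold_section)
      expect_identical(sentence_bio(b, j), sentence_bio(a, j))
    }
  }
  # ragged line reported with its line number
  writeLines(c("-DOCSTART- d 0 methods", "tok\tO\textra"), path)
  expect_error(read_conll(path), "line 2")
  # empty file -> empty corpus
  writeLines(character(0), path)
  expect_length(read_conll(path), 0)
})

test_that("standoff JSON round-trips and rejects offset/text mismatches", {
  corp <- generate_corpus(synth_config(n_docs = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_standoff_json(corp, path)
  back <- read_standoff_json(path)
  for (k in seq_along(corp)) {
    expect_identical(back[[k]]$doc_id, corp[[k]]$doc_id)
    expect_identical(back[[k]]$entities, corp[[k]]$entities)
    expect_identical(back[[k]]$title$text, corp[[k]]$title$text)
    expect_identical(
      vapply(back[[k]]$sentences, function(s) s$text, character(1)),
      vapply(corp[[k]]$sentences, function(s) s$text, character(1)))
  }
  # corrupt a span's text: loader must reject, naming the document
  txt <- readLines(path, warn = FALSE)
  txt <- sub(corp[[1]]$entities$text[1], "THE WRONG TEXT", txt, fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_standoff_json(path), corp[[1]]$doc_id)
  # empty corpus round-trip
  write_standoff_json(as_corpus(list()), path)
  expect_length(read_standoff_json(path), 0)
})
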