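# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (exhaustive enumeration, per-token loops) and share no
# code with the implementation paths they check.

entity_df <- function(sid, start, end, cls, text) {
  data.frame(sid = as.integer(sid), start = as.integer(start),
             end = as.integer(end), cls = cls, text = text,
             stringsAsFactors = FALSE)
}

# An abstract from plain sentence specs: list(text =, gold =).
make_abstract <- function(doc_id, title = "A title", sents = list(),
                          entities = NULL, pred_entities = NULL) {
  sentences <- lapply(seq_along(sents), function(i)
    new_sentence(i - 1L, sents[[i]]$text,
                 gold_section = if (is.null(sents[[i]]$gold)) NA_character_
                   else sents[[i]]$gold))
  new_abstract(doc_id, title, sentences,
               entities = if (is.null(entities)) NULL else entities,
               structured = TRUE, pred_entities = pred_entities)
}

# The worked example: one methods sentence whose gold Population span is
# the whole phrase, with two fragmentary predictions.
worked_example <- function() {
  txt <- "86 hospitalized COVID-19 patients"
  gold <- make_abstract("we1", sents = list(list(text = txt, gold = "methods")),
                        entities = entity_df(0L, 0L, 33L, "P", txt))
  pred <- make_abstract("we1", sents = list(list(text = txt, gold = "methods")),
                        entities = entity_df(0L, 0L, 33L, "P", txt),
                        pred_entities = rbind(
                          entity_df(0L, 0L, 15L, "P", "86 hospitalized"),
                          entity_df(0L, 25L, 33L, "P", "patients")))
  list(gold = as_corpus(list(gold)), pred = as_corpus(list(pred)))
}

# Random token-aligned, non-overlapping span set over a sentence.
random_spans <- function(sentence, classes = entity_classes(),
                         start_prob = 0.35) {
  tok <- sentence$tokens
  out <- entity_df(integer(0), integer(0), integer(0), character(0),
                   character(0))
  i <- 1L
  while (i <= nrow(tok)) {
    if (stats::runif(1) < start_prob) {
      len <- sample(1:min(3L, nrow(tok) - i + 1L), 1)
      cls <- sample(classes, 1)
      start <- tok$start[i]; end <- tok$end[i + len - 1L]
      out <- rbind(out, entity_df(sentence$sid, start, end, cls,
                                  substr(sentence$text, start + 1L, end)))
      i <- i + len
    } else i <- i + 1L
  }
  out
}

random_sentence <- function(sid, n_tokens) {
  words <- replicate(n_tokens, paste(sample(letters, sample(2:6, 1),
                                            replace = TRUE), collapse = ""))
  # suffix an index so token identities are unique within the sentence
  words <- paste0(words, seq_len(n_tokens))
  new_sentence(sid, paste(words, collapse = " "))
}

# --- Viterbi oracle: exhaustive enumeration over all label paths ----------

# Best path score over every sequence in labels^n, scoring emissions,
# start mask and transitions; -Inf (masked) paths drop out naturally.
enumerate_best_path <- function(E, trans) {
  labs <- bio_labels()
  n <- nrow(E)
  grid <- as.matrix(expand.grid(rep(list(seq_along(labs)), n)))
  sc <- attr(trans, "start")[grid[, 1]] + E[cbind(1L, grid[, 1])]
  if (n > 1) for (t in 2:n) {
    sc <- sc + trans[cbind(grid[, t - 1], grid[, t])] + E[cbind(t, grid[, t])]
  }
  best <- which.max(sc)
  list(score = sc[best], path = labs[grid[best, ]])
}

path_score <- function(tags, E, trans) {
  idx <- match(tags, bio_labels())
  s <- attr(trans, "start")[idx[1]] + E[1, idx[1]]
  if (length(idx) > 1) for (t in 2:length(idx))
    s <- s + trans[idx[t - 1], idx[t]] + E[t, idx[t]]
  s
}

random_tagger_instance <- function(n_tokens) {
  trans <- bio_transition_mask()
  trans[is.finite(trans)] <- stats::rnorm(sum(is.finite(trans)))
  E <- matrix(stats::rnorm(n_tokens * length(bio_labels())), n_tokens)
  list(E = E, trans = trans)
}

# A tagger model whose decode reproduces a given emission matrix: one
# pseudo-feature per token position. Used to drive viterbi_decode through
# its public surface in oracle tests.
model_from_instance <- function(inst, sentence) {
  w <- new.env(parent = emptyenv())
  feats <- picopipe:::sentence_token_features(sentence)
  for (t in seq_len(nrow(inst$E))) {
    # hang the whole row on the first (word) feature of token t
    assign(feats[[t]][1], inst$E[t, ], envir = w)
  }
  structure(list(backend = "perceptron", weights = w, trans = inst$trans,
                 labels = bio_labels(), epochs = 0L,
                 sections = c("title", "methods"),
                 feature_spec_version = 1L, seed = 0L),
            class = "pico_tagger_model")
}

bio_sequence_valid <- function(tags) {
  prev <- "O"
  for (t in tags) {
    if (startsWith(t, "I-")) {
      cls <- substring(t, 3)
      if (!(prev %in% paste0(c("B-", "I-"), cls))) return(FALSE)
    }
    prev <- t
  }
  TRUE
}

# --- Metric oracles --------------------------------------------------------

# Per-token tally, written as an explicit loop with if/else branches.
oracle_token_counts <- function(gold_tags, pred_tags) {
  counts <- list()
  for (cl in entity_classes()) counts[[cl]] <- c(tp = 0, fp = 0, fn = 0)
  cls_of <- function(t) if (t == "O") "Outside" else substring(t, 3)
  for (i in seq_along(gold_tags)) {
    g <- cls_of(gold_tags[i]); p <- cls_of(pred_tags[i])
    if (g == "Outside" && p == "Outside") next
    if (g == p) {
      counts[[g]]["tp"] <- counts[[g]]["tp"] + 1
    } else {
      if (g != "Outside") counts[[g]]["fn"] <- counts[[g]]["fn"] + 1
      if (p != "Outside") counts[[p]]["fp"] <- counts[[p]]["fp"] + 1
    }
  }
  counts
}

# Maximum one-to-one matching of same-class overlapping span pairs
# (Kuhn's augmenting-path algorithm; exact optimum at these sizes).
oracle_optimal_partial_tp <- function(gold, pred) {
  if (!nrow(gold) || !nrow(pred)) return(0L)
  adj <- lapply(seq_len(nrow(gold)), function(gi) {
    which(pred$cls == gold$cls[gi] & pred$sid == gold$sid[gi] &
            pmin(gold$end[gi], pred$end) - pmax(gold$start[gi], pred$start) > 0)
  })
  match_p <- rep(0L, nrow(pred))
  try_aug <- function(gi, st) {
    for (pi in adj[[gi]]) {
      if (st$visited[pi]) next
      st$visited[pi] <- TRUE
      if (match_p[pi] == 0L || try_aug(match_p[pi], st)) {
        match_p[pi] <<- gi
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (gi in seq_len(nrow(gold))) {
    st <- new.env(parent = emptyenv())
    st$visited <- rep(FALSE, nrow(pred))
    if (try_aug(gi, st)) tp <- tp + 1L
  }
  tp
}

# Gold BIO tags of sentence j of an abstract.
sentence_bio <- function(ab, j) {
  s <- ab$sentences[[j]]
  spans_to_bio(s, ab$entities[ab$entities$sid == s$sid, , drop = FALSE])
}

# Small separable corpus + trained models, cached across tests.
.fixture_env <- new.env(parent = emptyenv())
separable_fixture <- function(n_docs = 80, seed = 1) {
  key <- sprintf("sep_%d_%d", n_docs, seed)
  if (is.null(.fixture_env[[key]])) {
    corp <- generate_separable_corpus(synth_config(n_docs = n_docs, seed = seed))
    ntr <- floor(n_docs * 0.75)
    train <- as_corpus(unclass(corp)[seq_len(ntr)])
    test <- as_corpus(unclass(corp)[(ntr + 1):n_docs])
    .fixture_env[[key]] <- list(
      corpus = corp, train = train, test = test,
      classifier = suppressMessages(train_classifier(train, seed = 1)),
      tagger = suppressMessages(train_tagger(train, config = list(epochs = 8),
                                             seed = 3)))
  }
  .fixture_env[[key]]
}
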