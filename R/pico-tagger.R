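# Linear-chain BIO tagger for PICO entities.
#
# Default backend: an averaged structured perceptron over sparse token
# features with a hard-masked transition matrix -- the same linear-chain
# hypothesis class as the classic linear-CRF baselines for this task, with
# a simpler, fully deterministic training rule. Invalid BIO bigrams
# (start->I-c, O->I-c, and I-c'/B-c' -> I-c with c' != c) carry -Inf
# transition weight, so every decoded sequence is BIO-valid by construction
# and needs no post-hoc repair. A transformer fine-tuning backend fits the
# same contract but is not bundled; its published presets (5 epochs, lr
# 1e-5, batch 32; tuned lr 5e-5, batch 8, 10 epochs) are recorded as
# `transformer_presets()` for when an adapter is plugged in.

#' Transition mask over the 9-label BIO inventory
#'
#' A 9 x 9 matrix (rows = previous label, columns = next label) with 0 for
#' permitted bigrams and `-Inf` for BIO-invalid ones; the attribute
#' `"start"` holds the start-position mask (no sequence may open with
#' `I-c`).
#' @return A numeric matrix with dimnames from [bio_labels()].
#' @export
bio_transition_mask <- function() {
  labs <- bio_labels()
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  start <- stats::setNames(rep(0, length(labs)), labs)
  for (nxt in labs) {
    if (!startsWith(nxt, "I-")) next
    cls <- substring(nxt, 3)
    ok_prev <- paste0(c("B-", "I-"), cls)
    m[setdiff(labs, ok_prev), nxt] <- -Inf
    start[nxt] <- -Inf
  }
  attr(m, "start") <- start
  m
}

# Token shape: uppercase -> A, lowercase -> a, digit -> 0, other kept;
# runs compressed ("COVID-19" -> "A-0").
token_shape <- function(tok) {
  s <- gsub("[A-Z]+", "A", tok)
  s <- gsub("[a-z]+", "a", s)
  gsub("[0-9]+", "0", s)
}

# Feature strings for token i of a token vector. The sentence section label
# (title vs methods vs ...) is itself a feature: the desk-scale proxy for
# giving the tagger rhetorical context.
token_features <- function(tokens, i, section) {
  tok <- tokens[i]
  low <- tolower(tok)
  n <- nchar(tok)
  c(paste0("w=", low),
    paste0("sh=", token_shape(tok)),
    paste0("p3=", substr(low, 1, 3)),
    paste0("s3=", substr(low, max(1L, n - 2L), n)),
    paste0("p4=", substr(low, 1, 4)),
    paste0("s4=", substr(low, max(1L, n - 3L), n)),
    paste0("pw=", if (i > 1L) tolower(tokens[i - 1L]) else "<s>"),
    paste0("nw=", if (i < length(tokens)) tolower(tokens[i + 1L]) else "</s>"),
    if (grepl("^[0-9.,]+$", tok)) "num" else NULL,
    paste0("sec=", section),
    "bias")
}

sentence_token_features <- function(sentence, section = NULL) {
  if (is.null(section))
    section <- if (sentence$sid == TITLE_SID) "title"
               else if (!is.na(sentence$gold_section)) sentence$gold_section
               else "unknown"
  toks <- sentence$tokens$text
  lapply(seq_along(toks), function(i) token_features(toks, i, section))
}

# Emission score matrix (tokens x 9) under a weight environment mapping
# feature string -> numeric[9].
emission_scores <- function(weights, feats) {
  nlab <- length(bio_labels())
  E <- matrix(0, length(feats), nlab)
  for (t in seq_along(feats)) {
    for (f in feats[[t]]) {
      w <- get0(f, envir = weights, inherits = FALSE)
      if (!is.null(w)) E[t, ] <- E[t, ] + w
    }
  }
  E
}

# Viterbi over emission matrix E and transition matrix trans (with start
# mask). Tie-break: first maximum in the fixed label order (O first, then
# lexicographic), implemented by which.max/max.col taking the first hit.
viterbi_path <- function(E, trans) {
  labs <- bio_labels(); nlab <- length(labs)
  n <- nrow(E)
  if (n == 0L) return(character(0))
  delta <- matrix(-Inf, n, nlab)
  back <- matrix(NA_integer_, n, nlab)
  delta[1, ] <- E[1, ] + attr(trans, "start")
  if (n > 1) for (t in 2:n) {
    cand <- delta[t - 1, ] + trans            # nlab x nlab, rows = prev
    b <- apply(cand, 2, which.max)
    delta[t, ] <- cand[cbind(b, seq_len(nlab))] + E[t, ]
    back[t, ] <- b
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  labs[path]
}

#' Decode a sentence with a tagger model
#'
#' Returns the argmax BIO label path under the model's emission and
#' transition scores, subject to the hard BIO mask. Ties break toward `O`,
#' then the lexicographically earlier label.
#'
#' @param model A `pico_tagger_model`.
#' @param sentence A `pico_sentence`.
#' @param section Section label to use as a feature (defaults to the
#'   sentence's own label: title for the pseudo-sentence, else its gold
#'   label).
#' @return Character vector of BIO tags (empty for an empty token list).
#' @export
viterbi_decode <- function(model, sentence, section = NULL) {
  feats <- sentence_token_features(sentence, section)
  if (!length(feats)) return(character(0))
  E <- emission_scores(model$weights, feats)
  viterbi_path(E, model$trans)
}

# Training data: one record per selected sentence.
collect_tagger_data <- function(corpus, sections) {
  out <- list()
  for (ab in corpus) {
    for (sent in abstract_sentences(ab)) {
      sec <- if (sent$sid == TITLE_SID) "title" else sent$gold_section
      if (!(identical(sec, "title") || (!is.na(sec) && sec %in% sections)))
        next
      if (!nrow(sent$tokens)) next
      gold <- tryCatch(
        spans_to_bio(sent, ab$entities[ab$entities$sid == sent$sid, ,
                                       drop = FALSE]),
        error = function(e) stop("in doc ", ab$doc_id, " sid ", sent$sid,
                                 ": ", conditionMessage(e)))
      out[[length(out) + 1L]] <- list(doc_id = ab$doc_id, sid = sent$sid,
                                      feats = sentence_token_features(sent),
                                      gold = gold)
    }
  }
  out
}

#' Train the PICO tagger (averaged structured perceptron)
#'
#' For each training sentence the current model decodes a label path; when
#' it differs from the gold path, emission weights are promoted along the
#' gold features and demoted along the predicted ones, and likewise for
#' transition bigram weights (the `-Inf` mask cells are never touched).
#' Final weights are the running average over all updates, which stabilizes
#' the otherwise last-example-sensitive perceptron. Training is
#' deterministic given `(corpus, config, seed)`; a token-level training F1
#' is logged per epoch.
#'
#' @param corpus A `pico_corpus` with gold entities.
#' @param config Optional list: `epochs` (default 10) and `sections`
#'   (sections whose sentences enter training, default title + methods).
#' @param seed Integer seed driving the per-epoch sentence shuffle.
#' @return A model object of class `pico_tagger_model`.
#' @export
train_tagger <- function(corpus, config = list(), seed = 1) {
  epochs <- if (is.null(config$epochs)) 10L else as.integer(config$epochs)
  sections <- if (is.null(config$sections)) c("title", "methods")
              else config$sections
  dat <- collect_tagger_data(corpus, sections)
  if (!length(dat)) stop("no trainable sentences found")
  if (all(vapply(dat, function(d) all(d$gold == "O"), logical(1))))
    warning("training corpus contains zero entity spans; model will predict all O")
  trans_mask <- bio_transition_mask()
  labs <- bio_labels(); nlab <- length(labs)
  w <- new.env(parent = emptyenv())     # feature -> numeric[nlab]
  u <- new.env(parent = emptyenv())     # timestamp-weighted totals
  trans <- matrix(0, nlab, nlab, dimnames = dimnames(trans_mask))
  trans_u <- matrix(0, nlab, nlab)
  t_step <- 0
  bump <- function(env, key, idx, d) {
    cur <- get0(key, envir = env, inherits = FALSE)
    if (is.null(cur)) cur <- numeric(nlab)
    cur[idx] <- cur[idx] + d
    assign(key, cur, envir = env)
  }
  masked <- function(m) {
    m[is.infinite(trans_mask)] <- -Inf
    attr(m, "start") <- attr(trans_mask, "start")
    m
  }
  for (ep in seq_len(epochs)) {
    ord <- with_seed(substream_seed(seed, ep * 131L),
                     sample(seq_along(dat)))
    correct <- 0L; total <- 0L
    gold_tp <- 0L; gold_n <- 0L; pred_n <- 0L
    for (si in ord) {
      d <- dat[[si]]
      t_step <- t_step + 1
      E <- emission_scores(w, d$feats)
      pred <- viterbi_path(E, masked(trans))
      total <- total + length(pred)
      agree <- pred == d$gold
      correct <- correct + sum(agree)
      gold_ent <- d$gold != "O"; pred_ent <- pred != "O"
      gold_tp <- gold_tp + sum(agree & gold_ent)
      gold_n <- gold_n + sum(gold_ent); pred_n <- pred_n + sum(pred_ent)
      if (!all(agree)) {
        gi <- match(d$gold, labs); pi <- match(pred, labs)
        for (tt in seq_along(pred)) {
          if (gi[tt] == pi[tt]) next
          for (f in d$feats[[tt]]) {
            bump(w, f, gi[tt], 1); bump(w, f, pi[tt], -1)
            bump(u, f, gi[tt], t_step); bump(u, f, pi[tt], -t_step)
          }
        }
        if (length(pred) > 1) for (tt in 2:length(pred)) {
          if (gi[tt - 1] == pi[tt - 1] && gi[tt] == pi[tt]) next
          trans[gi[tt - 1], gi[tt]] <- trans[gi[tt - 1], gi[tt]] + 1
          trans[pi[tt - 1], pi[tt]] <- trans[pi[tt - 1], pi[tt]] - 1
          trans_u[gi[tt - 1], gi[tt]] <- trans_u[gi[tt - 1], gi[tt]] + t_step
          trans_u[pi[tt - 1], pi[tt]] <- trans_u[pi[tt - 1], pi[tt]] - t_step
        }
      }
    }
    p <- if (pred_n) gold_tp / pred_n else 0
    r <- if (gold_n) gold_tp / gold_n else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    message(sprintf("epoch %d: token accuracy %.3f, training token F1 %.3f",
                    ep, correct / max(1L, total), f1))
  }
  # Averaged weights: w_avg = w - u / T.
  avg <- new.env(parent = emptyenv())
  for (f in ls(w, sorted = FALSE)) {
    assign(f, get(f, envir = w) - get0(f, envir = u,
                                       ifnotfound = numeric(nlab)) / t_step,
           envir = avg)
  }
  trans_avg <- trans - trans_u / t_step
  trans_avg <- masked(trans_avg)
  attr(trans_avg, "start") <- attr(trans_mask, "start")
  dimnames(trans_avg) <- dimnames(trans_mask)
  structure(list(backend = "perceptron", weights = avg, trans = trans_avg,
                 labels = labs, epochs = epochs, sections = sections,
                 feature_spec_version = FEATURE_SPEC_VERSION,
                 seed = as.integer(seed)),
            class = "pico_tagger_model")
}

#' Tagger weights as a deterministic matrix (for serialization and tests)
#' @param model A `pico_tagger_model`.
#' @return A numeric matrix, one row per feature (sorted), one column per
#'   BIO label.
#' @export
tagger_weights <- function(model) {
  feats <- sort(ls(model$weights))
  m <- do.call(rbind, lapply(feats, get, envir = model$weights))
  if (is.null(m)) m <- matrix(0, 0, length(bio_labels()))
  dimnames(m) <- list(feats, bio_labels())
  m
}

#' Tag a corpus with predicted PICO entity spans
#'
#' Decodes every sentence whose effective section label is in
#' `sections_to_tag`; the title pseudo-sentence is always decoded, mirroring
#' the design of restricting extraction to the title plus selected
#' sections. Decoded tag paths are converted to spans and stored in
#' `pred_entities`.
#'
#' @param model A `pico_tagger_model`.
#' @param corpus A `pico_corpus`.
#' @param sections_to_tag Character vector of section labels to tag
#'   (default title + methods).
#' @param section_source `"gold"` uses gold labels, `"pred"` uses classifier
#'   output (error where absent), `"auto"` prefers predictions and falls
#'   back to gold.
#' @return The corpus with `pred_entities` attached to each abstract.
#' @export
tag_corpus <- function(model, corpus,
                       sections_to_tag = c("title", "methods"),
                       section_source = c("auto", "gold", "pred")) {
  section_source <- match.arg(section_source)
  out <- lapply(corpus, function(ab) {
    preds <- empty_entities()
    for (sent in abstract_sentences(ab)) {
      if (sent$sid == TITLE_SID) {
        sec <- "title"
      } else {
        sec <- switch(section_source,
          gold = sent$gold_section,
          pred = {
            if (is.na(sent$pred_section))
              stop("sentence ", sent$sid, " of doc ", ab$doc_id,
                   " has no predicted section; run the classifier first")
            sent$pred_section
          },
          auto = if (!is.na(sent$pred_section)) sent$pred_section
                 else sent$gold_section)
        if (is.na(sec) || !(sec %in% sections_to_tag)) next
      }
      tags <- viterbi_decode(model, sent, section = sec)
      if (length(tags)) preds <- rbind(preds, bio_to_spans(sent, tags))
    }
    ab$pred_entities <- preds
    ab
  })
  attributes(out) <- attributes(corpus)
  out
}

#' Published hyperparameter presets for a transformer NER adapter
#'
#' The default backend here is the structured perceptron; these presets
#' document the settings a fine-tuned biomedical-BERT adapter would use
#' behind the same contract.
#' @return A data frame of named presets.
#' @export
transformer_presets <- function() {
  data.frame(
    preset = c("base", "tuned"),
    learning_rate = c(1e-5, 5e-5),
    batch_size = c(32L, 8L),
    epochs = c(5L, 10L),
    stringsAsFactors = FALSE)
}
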