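# Sentence section classification.
#
# The default backend is a regularized multinomial logistic regression
# (glmnet) over sparse bag-of-token features of the sentence and its
# neighbours, plus positional features. Sequential context enters through
# the previous/next sentence token bags and the relative position, which is
# the desk-scale counterpart of context-sensitive sentence classifiers. A
# transformer prompt-based backend fits the same contract (backend id +
# opaque parameters + identical report schema) but is not bundled; its
# published defaults (dropout 0.5, batch size 8, learning rate 6e-6, AdamW,
# weight decay 0.01) are recorded here for when such an adapter is plugged
# in.

FEATURE_SPEC_VERSION <- 1L

# Feature strings for one sentence in context. Deterministic.
sentence_features <- function(sentences, i) {
  n <- length(sentences)
  toks <- function(j) {
    if (j < 1L || j > n) return(character(0))
    unique(tolower(sentences[[j]]$tokens$text))
  }
  rel <- if (n > 1L) (i - 1) / (n - 1) else 0
  c(paste0("cur:", toks(i)),
    paste0("prev:", toks(i - 1L)),
    paste0("next:", toks(i + 1L)),
    paste0("pos:", min(4L, floor(rel * 5))),
    if (i == 1L) "first" else NULL,
    if (i == n) "last" else NULL)
}

# Sparse document-term matrix over a fixed vocabulary.
features_matrix <- function(feature_list, vocab) {
  ii <- integer(0); jj <- integer(0)
  for (r in seq_along(feature_list)) {
    idx <- match(feature_list[[r]], vocab)
    idx <- idx[!is.na(idx)]
    ii <- c(ii, rep.int(r, length(idx))); jj <- c(jj, idx)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(feature_list), length(vocab)))
}

# Collect (features, gold label) pairs for all labeled non-title sentences.
collect_classifier_data <- function(corpus) {
  feats <- list(); labels <- character(0)
  for (ab in corpus) {
    sents <- ab$sentences
    for (i in seq_along(sents)) {
      if (is.na(sents[[i]]$gold_section)) next
      feats[[length(feats) + 1L]] <- sentence_features(sents, i)
      labels <- c(labels, sents[[i]]$gold_section)
    }
  }
  list(features = feats, labels = labels)
}

#' Train the sentence section classifier
#'
#' Fits the default backend, a multinomial logistic regression with a small
#' ridge-type penalty over sparse sentence + neighbour-context token
#' features. Training is deterministic given `(corpus, config, seed)`; the
#' training-set accuracy is reported via `message()`.
#'
#' @param corpus A `pico_corpus` whose non-title sentences carry gold
#'   section labels; every one of the four classes must be represented.
#' @param config Optional list: `lambda` (penalty, default `1e-3`) and
#'   `alpha` (elastic-net mixing, default 0 = ridge).
#' @param seed Integer seed (recorded in the model; the fit itself is
#'   deterministic).
#' @return A model object of class `pico_section_model`.
#' @export
train_classifier <- function(corpus, config = list(), seed = 1) {
  dat <- collect_classifier_data(corpus)
  if (!length(dat$labels)) stop("no labeled sentences in training corpus")
  missing <- setdiff(classifier_labels(), unique(dat$labels))
  if (length(missing))
    stop("training data is missing classes: ", paste(missing, collapse = ", "))
  lambda <- if (is.null(config$lambda)) 1e-3 else config$lambda
  alpha <- if (is.null(config$alpha)) 0 else config$alpha
  vocab <- sort(unique(unlist(dat$features)))
  x <- features_matrix(dat$features, vocab)
  y <- factor(dat$labels, levels = classifier_labels())
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                        lambda = c(lambda * 10, lambda), standardize = FALSE)
  model <- structure(list(backend = "glmnet", fit = fit, lambda = lambda,
                          vocab = vocab, labels = classifier_labels(),
                          feature_spec_version = FEATURE_SPEC_VERSION,
                          seed = as.integer(seed)),
                     class = "pico_section_model")
  acc <- mean(predict_sections(model, dat$features) == dat$labels)
  message(sprintf("classifier training accuracy: %.3f (%d sentences)",
                  acc, length(dat$labels)))
  model
}

# Predict section labels for a list of feature vectors. Ties break toward
# the earlier label in the fixed order (background, methods, results,
# conclusions).
predict_sections <- function(model, feature_list) {
  if (!identical(model$labels, classifier_labels()))
    stop("model label set does not match the four section labels")
  x <- features_matrix(feature_list, model$vocab)
  sc <- stats::predict(model$fit, newx = x, s = model$lambda, type = "link")
  sc <- sc[, , 1, drop = FALSE]
  dim(sc) <- dim(sc)[1:2]
  colnames(sc) <- model$fit$classnames
  sc <- sc[, classifier_labels(), drop = FALSE]
  classifier_labels()[max.col(sc, ties.method = "first")]
}

#' Classify the sentences of an abstract
#'
#' Fills `pred_section` for every non-title sentence; the title
#' pseudo-sentence is structural and is never touched. With
#' `trust_headings = TRUE`, a structured abstract's gold heading labels are
#' copied into `pred_section` and the classifier is skipped (ablation
#' switch). With `monotone = TRUE`, per-abstract joint decoding enforces the
#' canonical non-decreasing section order background <= methods <= results
#' <= conclusions via dynamic programming over the per-sentence scores.
#'
#' @param model A `pico_section_model`.
#' @param abstract A `pico_abstract`.
#' @param trust_headings Copy gold headings instead of classifying?
#' @param monotone Enforce monotone section order?
#' @return The abstract with `pred_section` filled.
#' @export
classify_abstract <- function(model, abstract, trust_headings = FALSE,
                              monotone = FALSE) {
  if (!identical(model$feature_spec_version, FEATURE_SPEC_VERSION))
    stop("model feature spec version mismatch")
  sents <- abstract$sentences
  if (!length(sents)) return(abstract)
  if (trust_headings && abstract$structured &&
      all(!vapply(sents, function(s) is.na(s$gold_section), logical(1)))) {
    for (i in seq_along(sents))
      abstract$sentences[[i]]$pred_section <- sents[[i]]$gold_section
    return(abstract)
  }
  feats <- lapply(seq_along(sents), function(i) sentence_features(sents, i))
  if (monotone) {
    x <- features_matrix(feats, model$vocab)
    sc <- stats::predict(model$fit, newx = x, s = model$lambda, type = "link")
    sc <- sc[, , 1, drop = FALSE]; dim(sc) <- dim(sc)[1:2]
    colnames(sc) <- model$fit$classnames
    sc <- sc[, classifier_labels(), drop = FALSE]
    pred <- monotone_decode(sc)
  } else {
    pred <- predict_sections(model, feats)
  }
  for (i in seq_along(sents)) abstract$sentences[[i]]$pred_section <- pred[i]
  abstract
}

# Viterbi-style DP restricted to non-decreasing label indices.
monotone_decode <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  best <- matrix(-Inf, n, k); back <- matrix(NA_integer_, n, k)
  best[1, ] <- scores[1, ]
  if (n > 1) for (t in 2:n) for (j in seq_len(k)) {
    prev <- best[t - 1, seq_len(j)]
    b <- which.max(prev)
    best[t, j] <- prev[b] + scores[t, j]
    back[t, j] <- b
  }
  path <- integer(n)
  path[n] <- which.max(best[n, ])
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  classifier_labels()[path]
}

#' @rdname classify_abstract
#' @param corpus A `pico_corpus`.
#' @export
classify_corpus <- function(model, corpus, trust_headings = FALSE,
                            monotone = FALSE) {
  out <- lapply(corpus, classify_abstract, model = model,
                trust_headings = trust_headings, monotone = monotone)
  attributes(out) <- attributes(corpus)
  out
}

#' Evaluate the section classifier
#'
#' Scores predicted against gold section labels over all labeled non-title
#' sentences, reporting per-class precision/recall/F1 and the micro average
#' computed from summed TP/FP/FN. Because each sentence receives exactly one
#' of the four labels, micro precision, recall and F1 all equal accuracy.
#'
#' @param model A `pico_section_model` (ignored when the corpus already has
#'   predictions and `use_existing = TRUE`).
#' @param corpus A `pico_corpus` with gold section labels.
#' @param use_existing Use `pred_section` already present instead of
#'   re-classifying?
#' @return A `pico_eval_report` with granularity `"sentence"`; rows follow
#'   the order BG, MT, RS, CC plus the micro-averaged Overall row.
#' @export
evaluate_classifier <- function(model, corpus, use_existing = FALSE) {
  gold <- character(0); pred <- character(0)
  if (!use_existing) corpus <- classify_corpus(model, corpus)
  for (ab in corpus) for (s in ab$sentences) {
    if (is.na(s$gold_section)) next
    gold <- c(gold, s$gold_section)
    pred <- c(pred, s$pred_section)
  }
  if (!length(gold)) stop("empty corpus: no labeled sentences to evaluate")
  counts <- lapply(classifier_labels(), function(cl) {
    list(tp = sum(gold == cl & pred == cl),
         fp = sum(gold != cl & pred == cl),
         fn = sum(gold == cl & pred != cl))
  })
  names(counts) <- classifier_labels()
  eval_report(counts, granularity = "sentence")
}
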