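# Scoring: token-level (Outside-excluded), entity-level exact and partial
# match, micro-averaging from summed counts, confusion matrices, Cohen's
# kappa, and document-level cross-validation.

# Precision/recall/F1 with the 0/0 -> 0 convention.
prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

# Build a pico_eval_report from a named list of per-class tp/fp/fn counts.
# Micro scores always come from the summed counts, never from averaging the
# per-class scores.
eval_report <- function(counts, granularity) {
  classes <- names(counts)
  rows <- lapply(classes, function(cl) {
    c <- counts[[cl]]
    s <- prf(c$tp, c$fp, c$fn)
    data.frame(class = cl, tp = c$tp, fp = c$fp, fn = c$fn,
               precision = s$precision, recall = s$recall, f1 = s$f1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tp <- sum(tab$tp); fp <- sum(tab$fp); fn <- sum(tab$fn)
  micro <- prf(tp, fp, fn)
  structure(list(granularity = granularity, table = tab,
                 micro = c(list(tp = tp, fp = fp, fn = fn), micro)),
            class = "pico_eval_report")
}

#' @export
print.pico_eval_report <- function(x, ...) {
  cat(sprintf("<pico_eval_report> granularity: %s\n", x$granularity))
  short <- c(background = "BG", methods = "MT", results = "RS",
             conclusions = "CC")
  tab <- x$table
  tab$class <- ifelse(tab$class %in% names(short), short[tab$class], tab$class)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s P/R/F1 = %.3f/%.3f/%.3f  (TP=%d FP=%d FN=%d)\n",
                tab$class[i], tab$precision[i], tab$recall[i], tab$f1[i],
                tab$tp[i], tab$fp[i], tab$fn[i]))
  cat(sprintf("  %-8s P/R/F1 = %.3f/%.3f/%.3f\n", "Overall",
              x$micro$precision, x$micro$recall, x$micro$f1))
  invisible(x)
}

# Collapse a BIO tag to its token-level class; the outside tag becomes
# "Outside" (distinct from the Outcome class "O").
collapse_tag <- function(tags) {
  ifelse(tags == "O", "Outside", substring(tags, 3))
}

# Walk two corpora in parallel, calling fn(gold_tags, pred_tags, sentence)
# per sentence. Token counts must agree.
walk_aligned <- function(gold_corpus, pred_corpus, fn) {
  if (length(gold_corpus) != length(pred_corpus))
    stop("corpora have different numbers of documents")
  for (k in seq_along(gold_corpus)) {
    g <- gold_corpus[[k]]; p <- pred_corpus[[k]]
    if (!identical(g$doc_id, p$doc_id))
      stop("document order mismatch at position ", k)
    gs <- abstract_sentences(g); ps <- abstract_sentences(p)
    if (length(gs) != length(ps))
      stop("sentence count mismatch in doc ", g$doc_id)
    for (j in seq_along(gs)) {
      if (nrow(gs[[j]]$tokens) != nrow(ps[[j]]$tokens))
        stop("token count mismatch in doc ", g$doc_id, " sid ", gs[[j]]$sid)
      gt <- sentence_tags(g, gs[[j]], "gold")
      pt <- sentence_tags(p, ps[[j]],
                          if (is.null(p$pred_entities)) "gold" else "pred")
      fn(gt, pt, gs[[j]])
    }
  }
}

#' Token-level evaluation (Outside excluded)
#'
#' BIO tags on both sides are collapsed to their entity class; a token
#' counts as TP for class c when gold = pred = c, FP when predicted c but
#' gold differs, FN when gold c but predicted otherwise. Tokens where both
#' sides are Outside contribute nothing, so agreement on the outside label
#' is excluded from the scores.
#'
#' @param gold_corpus Corpus carrying gold entities.
#' @param pred_corpus Aligned corpus carrying predictions in
#'   `pred_entities` (falls back to `entities` when absent, so two gold
#'   corpora can be compared).
#' @return A `pico_eval_report` with granularity `"token"`.
#' @export
token_eval <- function(gold_corpus, pred_corpus) {
  counts <- stats::setNames(
    lapply(entity_classes(), function(cl) list(tp = 0L, fp = 0L, fn = 0L)),
    entity_classes())
  walk_aligned(gold_corpus, pred_corpus, function(gt, pt, sent) {
    g <- collapse_tag(gt); p <- collapse_tag(pt)
    for (cl in entity_classes()) {
      counts[[cl]]$tp <<- counts[[cl]]$tp + sum(g == cl & p == cl)
      counts[[cl]]$fp <<- counts[[cl]]$fp + sum(g != cl & p == cl)
      counts[[cl]]$fn <<- counts[[cl]]$fn + sum(g == cl & p != cl)
    }
  })
  eval_report(counts, "token")
}

# Collect spans of one abstract (gold or predicted side).
side_spans <- function(ab, side) {
  if (side == "gold") ab$entities
  else if (!is.null(ab$pred_entities)) ab$pred_entities
  else ab$entities
}

# Greedy one-to-one partial matching within (doc, class): overlapping
# same-class pairs ordered by overlap length (desc), then gold start, then
# pred start; each span used at most once.
greedy_partial_match <- function(gold, pred) {
  if (!nrow(gold) || !nrow(pred)) return(0L)
  pairs <- list()
  for (gi in seq_len(nrow(gold))) for (pi in seq_len(nrow(pred))) {
    if (gold$sid[gi] != pred$sid[pi]) next
    ov <- min(gold$end[gi], pred$end[pi]) - max(gold$start[gi], pred$start[pi])
    if (ov > 0)
      pairs[[length(pairs) + 1L]] <- c(gi, pi, ov, gold$start[gi],
                                       pred$start[pi])
  }
  if (!length(pairs)) return(0L)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, 3], pm[, 4], pm[, 5]), , drop = FALSE]
  used_g <- logical(nrow(gold)); used_p <- logical(nrow(pred))
  tp <- 0L
  for (i in seq_len(nrow(pm))) {
    gi <- pm[i, 1]; pi <- pm[i, 2]
    if (used_g[gi] || used_p[pi]) next
    used_g[gi] <- TRUE; used_p[pi] <- TRUE
    tp <- tp + 1L
  }
  tp
}

#' Entity-level evaluation (exact or partial match)
#'
#' Exact mode: a predicted span is a TP iff a gold span with identical
#' `(sid, start, end, cls)` exists. Partial mode: greedy one-to-one
#' matching within document and class -- a gold span matches at most one
#' same-class predicted span sharing at least one token, pairs taken
#' longest-overlap-first with ties broken by earlier start. Unmatched
#' predictions are FP, unmatched gold spans FN.
#'
#' @inheritParams token_eval
#' @param mode `"exact"` or `"partial"`.
#' @return A `pico_eval_report` with granularity `"entity_exact"` or
#'   `"entity_partial"`.
#' @export
entity_eval <- function(gold_corpus, pred_corpus, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  counts <- stats::setNames(
    lapply(entity_classes(), function(cl) list(tp = 0L, fp = 0L, fn = 0L)),
    entity_classes())
  if (length(gold_corpus) != length(pred_corpus))
    stop("corpora have different numbers of documents")
  for (k in seq_along(gold_corpus)) {
    gold <- side_spans(gold_corpus[[k]], "gold")
    pred <- side_spans(pred_corpus[[k]], "pred")
    for (cl in entity_classes()) {
      g <- gold[gold$cls == cl, , drop = FALSE]
      p <- pred[pred$cls == cl, , drop = FALSE]
      if (mode == "exact") {
        gk <- paste(g$sid, g$start, g$end); pk <- paste(p$sid, p$start, p$end)
        tp <- length(intersect(gk, pk))
      } else {
        tp <- greedy_partial_match(g, p)
      }
      counts[[cl]]$tp <- counts[[cl]]$tp + tp
      counts[[cl]]$fp <- counts[[cl]]$fp + (nrow(p) - tp)
      counts[[cl]]$fn <- counts[[cl]]$fn + (nrow(g) - tp)
    }
  }
  eval_report(counts, paste0("entity_", mode))
}

#' End-to-end evaluation of the two-step pipeline
#'
#' Scores pipeline output (predicted sections deciding which sentences were
#' tagged) against gold annotations over all sentences, with the same
#' metric as the standalone evaluation: entities predicted in misclassified
#' sections count as false positives, entities missed because their
#' sentence was routed away count as false negatives.
#'
#' @param gold_corpus Corpus with gold entities.
#' @param pipeline_corpus The `corpus` element returned by [run_pipeline()].
#' @param granularity `"token"`, `"entity_exact"` or `"entity_partial"`.
#' @return A `pico_eval_report`.
#' @export
end_to_end_eval <- function(gold_corpus, pipeline_corpus,
                            granularity = c("token", "entity_exact",
                                            "entity_partial")) {
  granularity <- match.arg(granularity)
  switch(granularity,
         token = token_eval(gold_corpus, pipeline_corpus),
         entity_exact = entity_eval(gold_corpus, pipeline_corpus, "exact"),
         entity_partial = entity_eval(gold_corpus, pipeline_corpus, "partial"))
}

#' Token-level confusion matrix
#'
#' Counts (gold, predicted) label pairs over aligned tokens. Basis
#' `"class_token"` uses the four entity classes plus `Outside`;
#' `"iob_token"` uses the full nine-label BIO inventory. Rows are gold,
#' columns predicted; `row_normalized` gives per-gold-label percentages.
#'
#' @inheritParams token_eval
#' @param basis `"class_token"` or `"iob_token"`.
#' @return A list of class `pico_confusion` with `counts` and
#'   `row_normalized` matrices.
#' @export
confusion <- function(gold_corpus, pred_corpus,
                      basis = c("class_token", "iob_token")) {
  basis <- match.arg(basis)
  labs <- if (basis == "class_token") c(entity_classes(), "Outside")
          else bio_labels()
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  walk_aligned(gold_corpus, pred_corpus, function(gt, pt, sent) {
    if (basis == "class_token") { gt <- collapse_tag(gt); pt <- collapse_tag(pt) }
    for (i in seq_along(gt)) m[gt[i], pt[i]] <<- m[gt[i], pt[i]] + 1L
  })
  rn <- m / pmax(1L, rowSums(m))
  structure(list(basis = basis, counts = m, row_normalized = rn),
            class = "pico_confusion")
}

#' @export
print.pico_confusion <- function(x, ...) {
  cat(sprintf("<pico_confusion> basis: %s (rows = gold, cols = predicted)\n",
              x$basis))
  print(x$counts)
  invisible(x)
}

#' Cohen's kappa for inter-annotator agreement
#'
#' Token-level chance-corrected agreement between two annotations of the
#' same tokenized text: kappa = (p_o - p_e) / (1 - p_e), where p_o is the
#' observed agreement rate and p_e the expected agreement under independent
#' annotators with the observed marginal label distributions. The default
#' basis compares the collapsed entity-class labels including Outside; the
#' per-class basis binarizes each class against the rest.
#'
#' @param a,b Two annotations over identical tokens: either two aligned
#'   `pico_corpus` objects (gold entities on each side) or two equal-length
#'   character label vectors.
#' @param basis `"all"` (all labels jointly) or `"per_class"`.
#' @return For `"all"`, a list of class `pico_kappa` with `p_o`, `p_e`,
#'   `kappa`, `basis`; for `"per_class"`, a data frame with one row per
#'   entity class.
#' @export
cohens_kappa <- function(a, b, basis = c("all", "per_class")) {
  basis <- match.arg(basis)
  if (is.character(a) && is.character(b)) {
    if (length(a) != length(b)) stop("annotations have different token counts")
    la <- a; lb <- b
  } else {
    la <- character(0); lb <- character(0)
    walk_aligned(a, b, function(gt, pt, sent) {
      la <<- c(la, collapse_tag(gt)); lb <<- c(lb, collapse_tag(pt))
    })
  }
  if (!length(la)) stop("no tokens to compare")
  kap <- function(x, y) {
    labs <- union(unique(x), unique(y))
    p_o <- mean(x == y)
    p_e <- sum(vapply(labs, function(l) mean(x == l) * mean(y == l),
                      numeric(1)))
    k <- if (p_e >= 1) { if (p_o >= 1) 1 else 0 } else (p_o - p_e) / (1 - p_e)
    structure(list(p_o = p_o, p_e = p_e, kappa = k, basis = basis),
              class = "pico_kappa")
  }
  if (basis == "all") return(kap(la, lb))
  do.call(rbind, lapply(entity_classes(), function(cl) {
    r <- kap(ifelse(la == cl, cl, "rest"), ifelse(lb == cl, cl, "rest"))
    data.frame(class = cl, p_o = r$p_o, p_e = r$p_e, kappa = r$kappa,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.pico_kappa <- function(x, ...) {
  cat(sprintf("<pico_kappa> kappa = %.3f (p_o = %.3f, p_e = %.3f, basis = %s)\n",
              x$kappa, x$p_o, x$p_e, x$basis))
  invisible(x)
}

#' Document-level k-fold cross-validation split
#'
#' Partitions documents (never sentences, to avoid within-document leakage)
#' into k disjoint, exhaustive folds, deterministically per seed.
#'
#' @param corpus A `pico_corpus`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of k lists, each with `train` and `test` `pico_corpus`
#'   elements.
#' @export
kfold_split <- function(corpus, k, seed = 1) {
  n <- length(corpus)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds corpus size (", n, ")")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(f) {
    list(train = as_corpus(unclass(corpus)[fold != f]),
         test = as_corpus(unclass(corpus)[fold == f]))
  })
}

#' Cross-validated evaluation
#'
#' Runs a train/evaluate function over the k folds and averages the
#' fold-level micro precision, recall and F1 (mean of fold scores, not
#' pooled counts).
#'
#' @param corpus A `pico_corpus`.
#' @param k Number of folds.
#' @param seed Integer seed for the split.
#' @param fold_fn Function `(train, test) -> pico_eval_report`.
#' @return A list with `folds` (per-fold micro data frame) and `mean`
#'   (averaged micro precision/recall/F1).
#' @export
cv_report <- function(corpus, k, seed, fold_fn) {
  splits <- kfold_split(corpus, k, seed)
  per <- do.call(rbind, lapply(seq_along(splits), function(i) {
    rep <- fold_fn(splits[[i]]$train, splits[[i]]$test)
    data.frame(fold = i, precision = rep$micro$precision,
               recall = rep$micro$recall, f1 = rep$micro$f1)
  }))
  list(folds = per,
       mean = c(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1)))
}
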