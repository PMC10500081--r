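test_that("token-level scoring of the fragmented-span example", {
  we <- worked_example()
  rep <- token_eval(we$gold, we$pred)
  p_row <- rep$table[rep$table$class == "P", ]
  # "COVID-19" is the only gold Population token the prediction misses
  expect_identical(p_row$tp, 3L)
  expect_identical(p_row$fn, 1L)
  expect_identical(p_row$fp, 0L)
  expect_equal(p_row$precision, 1.0)
  expect_equal(p_row$recall, 0.75)
})

test_that("entity-level exact and partial scoring of the fragmented-span example", {
  we <- worked_example()
  exact <- entity_eval(we$gold, we$pred, "exact")
  expect_identical(exact$micro$tp, 0L)
  expect_identical(exact$micro$fp, 2L)
  expect_identical(exact$micro$fn, 1L)
  partial <- entity_eval(we$gold, we$pred, "partial")
  expect_identical(partial$micro$tp, 1L)
  expect_identical(partial$micro$fp, 1L)
  expect_identical(partial$micro$fn, 0L)
})

test_that("identical annotations score F1 = 1 at every granularity", {
  corp <- generate_corpus(synth_config(n_docs = 4, seed = 19))
  expect_equal(token_eval(corp, corp)$micro$f1, 1.0)
  expect_equal(entity_eval(corp, corp, "exact")$micro$f1, 1.0)
  expect_equal(entity_eval(corp, corp, "partial")$micro$f1, 1.0)
})

test_that("token and entity counts match brute-force tallies on random cases", {
  set.seed(61)
  for (rep in seq_len(500)) {
    sent <- random_sentence(0L, sample(2:10, 1))
    gold_spans <- random_spans(sent)
    pred_spans <- random_spans(sent)
    g_ab <- new_abstract("d", "t", list(sent), entities = gold_spans,
                         structured = FALSE)
    p_ab <- new_abstract("d", "t", list(sent), entities = gold_spans,
                         structured = FALSE, pred_entities = pred_spans)
    gc <- as_corpus(list(g_ab)); pc <- as_corpus(list(p_ab))
    # token level vs per-token loop
    rep_tok <- token_eval(gc, pc)
    oracle <- oracle_token_counts(spans_to_bio(sent, gold_spans),
                                  spans_to_bio(sent, pred_spans))
    for (cl in entity_classes()) {
      row <- rep_tok$table[rep_tok$table$class == cl, ]
      expect_identical(c(row$tp, row$fp, row$fn),
                       as.integer(oracle[[cl]][c("tp", "fp", "fn")]))
    }
    # exact entity level vs set comparison
    rep_ex <- entity_eval(gc, pc, "exact")
    key <- function(df) paste(df$sid, df$start, df$end, df$cls)
    expect_identical(rep_ex$micro$tp,
                     length(intersect(key(gold_spans), key(pred_spans))))
    # partial: greedy never exceeds the optimal assignment
    rep_pa <- entity_eval(gc, pc, "partial")
    opt <- sum(vapply(entity_classes(), function(cl)
      oracle_optimal_partial_tp(gold_spans[gold_spans$cls == cl, ],
                                pred_spans[pred_spans$cls == cl, ]),
      integer(1)))
    expect_lte(rep_pa$micro$tp, opt)
    # monotonicity: exact TP <= partial TP
    expect_lte(rep_ex$micro$tp, rep_pa$micro$tp)
  }
})

test_that("greedy partial matching attains the optimal assignment almost always", {
  set.seed(73)
  agree <- 0L; n_cases <- 300L
  for (rep in seq_len(n_cases)) {
    sent <- random_sentence(0L, sample(4:12, 1))
    gold_spans <- random_spans(sent, classes = "P", start_prob = 0.5)
    pred_spans <- random_spans(sent, classes = "P", start_prob = 0.5)
    greedy <- picopipe:::greedy_partial_match(gold_spans, pred_spans)
    opt <- oracle_optimal_partial_tp(gold_spans, pred_spans)
    expect_lte(greedy, opt)
    if (greedy == opt) agree <- agree + 1L
  }
  expect_gte(agree / n_cases, 0.95)
})

test_that("micro-averaging pools counts instead of averaging per-class scores", {
  # asymmetric case: P has 9 TP / 1 FN, I has 1 TP / 9 FP
  counts <- list(P = list(tp = 9L, fp = 0L, fn = 1L),
                 I = list(tp = 1L, fp = 9L, fn = 0L),
                 C = list(tp = 0L, fp = 0L, fn = 0L),
                 O = list(tp = 0L, fp = 0L, fn = 0L))
  rep <- picopipe:::eval_report(counts, "token")
  expect_equal(rep$micro$precision, 10 / 19)
  expect_equal(rep$micro$recall, 10 / 11)
  macro_p <- mean(rep$table$precision[1:2])
  expect_false(isTRUE(all.equal(rep$micro$precision, macro_p)))
})

test_that("metrics are invariant under document reordering", {
  corp <- generate_corpus(synth_config(n_docs = 6, seed = 23))
  fx <- separable_fixture()
  tagged <- tag_corpus(fx$tagger, corp, section_source = "gold")
  perm <- c(4, 1, 6, 2, 5, 3)
  corp_p <- as_corpus(unclass(corp)[perm])
  tagged_p <- as_corpus(unclass(tagged)[perm])
  for (mode in c("exact", "partial"))
    expect_equal(entity_eval(corp, tagged, mode)$micro,
                 entity_eval(corp_p, tagged_p, mode)$micro)
  expect_equal(token_eval(corp, tagged)$micro,
               token_eval(corp_p, tagged_p)$micro)
})

test_that("confusion matrices count gold/predicted label pairs", {
  we <- worked_example()
  cm <- confusion(we$gold, we$pred, basis = "class_token")
  expect_identical(cm$counts["P", "P"], 3L)
  expect_identical(cm$counts["P", "Outside"], 1L)
  # 4 body tokens + the 2 title pseudo-sentence tokens (Outside on both sides)
  expect_identical(sum(cm$counts), 6L)
  expect_identical(cm$counts["Outside", "Outside"], 2L)
  # perfect predictions give a diagonal matrix
  corp <- generate_corpus(synth_config(n_docs = 3, seed = 29))
  cm_perf <- confusion(corp, corp, basis = "iob_token")
  expect_identical(sum(cm_perf$counts) , sum(diag(cm_perf$counts)))
  # row sums equal gold label counts
  expect_true(all(rowSums(cm_perf$counts) ==
                    rowSums(confusion(corp, corp, "iob_token")$counts)))
  # hand-built 10-token case
  g <- c("B-P", "I-P", "O", "B-I", "O", "O", "B-O", "I-O", "O", "O")
  p <- c("B-P", "O",  "O", "B-C", "O", "B-I", "B-O", "I-O", "O", "O")
  s <- random_sentence(0L, 10)
  ga <- new_abstract("d", "t", list(s), entities = bio_to_spans(s, g),
                     structured = FALSE)
  pa <- new_abstract("d", "t", list(s), entities = bio_to_spans(s, g),
                     structured = FALSE, pred_entities = bio_to_spans(s, p))
  cm2 <- confusion(as_corpus(list(ga)), as_corpus(list(pa)), "class_token")
  expect_identical(cm2$counts["P", "P"], 1L)
  expect_identical(cm2$counts["P", "Outside"], 1L)
  expect_identical(cm2$counts["I", "C"], 1L)
  expect_identical(cm2$counts["Outside", "I"], 1L)
  expect_identical(cm2$counts["O", "O"], 2L)
  # 4 agreeing body Outside tokens + 1 title token
  expect_identical(cm2$counts["Outside", "Outside"], 5L)
})

test_that("Cohen's kappa: perfect, constructed, and degenerate agreement", {
  # identical annotations
  corp <- generate_corpus(synth_config(n_docs = 2, seed = 37))
  k <- cohens_kappa(corp, corp)
  expect_equal(k$kappa, 1.0)
  # constructed 20-token pair with p_o = 0.8 and p_e = 0.5 exactly:
  # both marginals are 10 P / 10 O with 16 agreements
  a <- c(rep("P", 8), rep("O", 8), "P", "P", "O", "O")
  b <- c(rep("P", 8), rep("O", 8), "O", "O", "P", "P")
  k2 <- cohens_kappa(a, b)
  expect_equal(k2$p_o, 0.8)
  expect_equal(k2$p_e, 0.5)
  expect_equal(k2$kappa, 0.6)
  # one annotator all-O against a uniform other: kappa <= 0
  a3 <- rep("Outside", 40)
  b3 <- rep(c("P", "I", "C", "O"), each = 10)
  expect_lte(cohens_kappa(a3, b3)$kappa, 0)
  # per-class basis returns one row per entity class
  pc <- cohens_kappa(corp, corp, basis = "per_class")
  expect_identical(pc$class, entity_classes())
  expect_true(all(pc$kappa == 1.0))
  expect_error(cohens_kappa(c("P", "O"), c("P")), "token counts")
})

test_that("k-fold splitting is a deterministic document-level partition", {
  corp <- generate_corpus(synth_config(n_docs = 10, seed = 41))
  folds <- kfold_split(corpus = corp, k = 5, seed = 9)
  test_ids <- lapply(folds, function(f)
    vapply(f$test, function(ab) ab$doc_id, character(1)))
  expect_true(all(vapply(test_ids, length, integer(1)) == 2L))
  expect_length(unique(unlist(test_ids)), 10)   # disjoint and exhaustive
  folds2 <- kfold_split(corpus = corp, k = 5, seed = 9)
  expect_identical(test_ids, lapply(folds2, function(f)
    vapply(f$test, function(ab) ab$doc_id, character(1))))
  for (f in folds)
    expect_length(intersect(names(f$train), names(f$test)), 0)
  expect_error(kfold_split(corp, k = 11), "exceeds")
  # cv_report averages fold-level micro scores
  cv <- cv_report(corp, k = 2, seed = 3, fold_fn = function(train, test)
    token_eval(test, test))
  expect_equal(unname(cv$mean["f1"]), 1.0)
})
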