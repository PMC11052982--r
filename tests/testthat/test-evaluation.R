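span_of <- function(doc, phrase) {
  start <- as.integer(regexpr(phrase, doc$text, fixed = TRUE)) - 1L
  stopifnot(start >= 0)
  c(start, start + nchar(phrase))
}

mention_at <- function(doc, phrase, type) {
  s <- span_of(doc, phrase)
  entity_mention(type, surface = phrase, start = s[1], end = s[2])
}

test_that("exact match requires type, content tokens, and trimmed span", {
  pair <- fig_pair()
  gold <- mention_at(pair$doc, "corneal scarring", "sign")
  expect_true(is_exact_match(gold, gold, pair$doc))
  expect_false(is_exact_match(gold, mention_at(pair$doc, "corneal scarring",
                                               "symptom"), pair$doc))
  expect_false(is_exact_match(gold, mention_at(pair$doc, "scarring", "sign"),
                              pair$doc))
  # ungrounded prediction never matches
  expect_false(is_exact_match(gold, entity_mention("sign", surface = "corneal scarring"),
                              pair$doc))
})

test_that("boundary differences made only of stop words still match exactly", {
  doc <- document("d", "Imaging showed distention of the kidney was present.")
  gold <- mention_at(doc, "distention of the kidney", "sign")
  pred <- mention_at(doc, "distention of the kidney was", "sign")
  expect_true(is_exact_match(gold, pred, doc))
  # a content-token difference does not match
  pred2 <- mention_at(doc, "distention of the kidney was present", "sign")
  expect_false(is_exact_match(gold, pred2, doc))
})

test_that("relaxed match needs type equality and span overlap", {
  gold <- entity_mention("sign", surface = "corneal scarring",
                         start = 28, end = 44)
  expect_true(is_relaxed_match(gold, entity_mention("sign", surface = "scarring",
                                                    start = 36, end = 44)))
  expect_false(is_relaxed_match(gold, entity_mention("sign", surface = "x",
                                                     start = 0, end = 13)))
  expect_false(is_relaxed_match(gold, entity_mention("symptom",
                                                     surface = "scarring",
                                                     start = 36, end = 44)))
})

test_that("exact match implies relaxed match on random pairs", {
  set.seed(404)
  for (i in 1:200) {
    inst <- random_micro_instance()
    for (g in inst$gold$mentions) {
      for (p in inst$pred$mentions) {
        if (is_exact_match(g, p, inst$doc)) {
          expect_true(is_relaxed_match(g, p))
        }
      }
    }
  }
})

test_that("assign_matches builds one-to-one reports with count identities", {
  pair <- fig_pair()
  same <- assign_matches(pair$ann,
                         annotation_set("fig1", pair$ann$mentions,
                                        role = "predicted"),
                         pair$doc, mode = "exact")
  expect_equal(same$n_correct, 2)
  expect_length(same$unmatched_gold, 0)
  expect_length(same$unmatched_pred, 0)

  one_gold <- annotation_set("fig1", list(
    mention_at(pair$doc, "corneal scarring", "sign")))
  two_preds <- annotation_set("fig1", list(
    mention_at(pair$doc, "corneal scarring", "sign"),
    mention_at(pair$doc, "scarring", "sign")), role = "predicted")
  rep <- assign_matches(one_gold, two_preds, pair$doc, mode = "relaxed")
  expect_equal(nrow(rep$pairs), 1)
  expect_length(rep$unmatched_pred, 1)
  expect_equal(nrow(rep$pairs) + length(rep$unmatched_gold), rep$m)
  expect_equal(nrow(rep$pairs) + length(rep$unmatched_pred), rep$m_hat)

  other <- annotation_set("other", role = "predicted")
  expect_error(assign_matches(one_gold, other, pair$doc), "different documents")
})

test_that("assignment cardinality equals the brute-force maximum matching", {
  set.seed(99)
  for (i in 1:300) {
    inst <- random_micro_instance()
    for (mode in c("exact", "relaxed")) {
      rep <- assign_matches(inst$gold, inst$pred, inst$doc, mode = mode)
      edge <- matrix(FALSE, length(inst$gold$mentions),
                     length(inst$pred$mentions))
      for (g in seq_along(inst$gold$mentions)) {
        for (p in seq_along(inst$pred$mentions)) {
          edge[g, p] <- if (mode == "exact") {
            is_exact_match(inst$gold$mentions[[g]], inst$pred$mentions[[p]],
                           inst$doc)
          } else {
            is_exact_match(inst$gold$mentions[[g]], inst$pred$mentions[[p]],
                           inst$doc) ||
              is_relaxed_match(inst$gold$mentions[[g]], inst$pred$mentions[[p]])
          }
        }
      }
      expect_equal(rep$n_correct, brute_force_max_matching(edge))
    }
  }
})

test_that("compute_metrics micro-averages with the stated conventions", {
  mk_report <- function(n_correct, m, m_hat) {
    structure(list(pairs = NULL, n_correct = n_correct, m = m, m_hat = m_hat),
              class = "MatchReport")
  }
  met <- compute_metrics(list(mk_report(3, 4, 6), mk_report(2, 6, 4)))
  expect_equal(met$precision, 0.5)
  expect_equal(met$recall, 0.5)
  expect_equal(met$f1, 0.5)
  # nothing predicted -> precision and F1 are 0
  zero <- compute_metrics(mk_report(0, 5, 0))
  expect_equal(zero$precision, 0)
  expect_equal(zero$f1, 0)
  no_gold <- compute_metrics(mk_report(0, 0, 5))
  expect_equal(no_gold$recall, 0)
})

test_that("classify_errors covers the five categories", {
  pair <- fig_pair()
  gold <- pair$ann
  # spurious: prediction overlapping no gold ("cause", offsets 19-24)
  pred <- annotation_set("fig1", list(mention_at(pair$doc, "cause", "sign")),
                         role = "predicted")
  rec <- classify_errors(gold, pred, pair$doc)
  expect_setequal(rec$category, c("spurious", "missed"))
  expect_equal(sum(rec$category == "missed"), 2)
  expect_identical(rec$entity_type[rec$category == "spurious"], "sign")

  # type_only: same span, rare disease predicted as disease
  pred2 <- annotation_set("fig1", list(
    mention_at(pair$doc, "Keratomalacia", "disease"),
    mention_at(pair$doc, "corneal scarring", "sign")), role = "predicted")
  rec2 <- classify_errors(gold, pred2, pair$doc)
  expect_identical(rec2$category, "type_only")
  expect_identical(rec2$entity_type, "rare_disease")  # gold-side attribution

  # boundary_only and boundary_and_type
  pred3 <- annotation_set("fig1", list(
    mention_at(pair$doc, "Keratomalacia is a cause", "rare_disease"),
    mention_at(pair$doc, "scarring", "symptom")), role = "predicted")
  rec3 <- classify_errors(gold, pred3, pair$doc)
  expect_setequal(rec3$category, c("boundary_only", "boundary_and_type"))

  expect_equal(nrow(classify_errors(gold,
                                    annotation_set("fig1", gold$mentions,
                                                   role = "predicted"),
                                    pair$doc)), 0)
})

test_that("error partition identities hold on random instances", {
  set.seed(2024)
  for (i in 1:150) {
    inst <- random_micro_instance()
    rec <- classify_errors(inst$gold, inst$pred, inst$doc)
    exact_correct <- assign_matches(inst$gold, inst$pred, inst$doc,
                                    mode = "exact")$n_correct
    n_cat <- function(cat) sum(rec$category == cat)
    shared <- exact_correct + n_cat("boundary_only") + n_cat("type_only") +
      n_cat("boundary_and_type")
    expect_equal(shared + n_cat("spurious"), length(inst$pred$mentions))
    expect_equal(shared + n_cat("missed"), length(inst$gold$mentions))
  }
})

test_that("error_table counts, totals, and half-up percentages", {
  records <- data.frame(
    doc_id = "x",
    category = c(rep("boundary_only", 16), rep("type_only", 48),
                 rep("boundary_and_type", 17), rep("spurious", 4),
                 rep("missed", 72)),
    gold_index = NA_integer_, pred_index = NA_integer_,
    entity_type = "rare_disease", stringsAsFactors = FALSE)
  tab <- error_table(records)
  rd <- tab[tab$entity == "rare_disease", ]
  expect_equal(rd$total, 157)
  expect_equal(rd$pct_type_only, 31)
  expect_equal(rd$pct_boundary_only, 10)
  fmt <- format_error_table(tab)
  expect_identical(fmt$type_only[fmt$entity == "rare_disease"], "48 (31%)")

  empty <- error_table(records[0, ])
  expect_true(all(empty$total == 0))
  expect_equal(nrow(empty), 4)
})

test_that("metrics are invariant to document and mention order", {
  corpus <- small_corpus(8, seed = 21)
  inj <- inject_errors(corpus, error_injection_config(3, 2, 1, 2, 2, seed = 5))
  rep1 <- evaluate_predictions(corpus, inj$predictions)
  shuffled <- rev(corpus)
  pred_shuffled <- lapply(inj$predictions, function(p) {
    annotation_set(p$doc_id, rev(p$mentions), role = "predicted")
  })
  rep2 <- evaluate_predictions(shuffled, pred_shuffled)
  expect_equal(rep1, rep2)
})
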