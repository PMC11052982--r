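## Matching predicted to gold mentions under exact and relaxed criteria,
## micro-averaged precision/recall/F1, and the five-category error taxonomy
## (boundary, type, boundary+type, spurious, missed).

## Characters shared by two mentions' fragment sets (0 if either ungrounded).
overlap_chars <- function(a, b) {
  if (!a$grounded || !b$grounded) return(0L)
  total <- 0L
  for (i in seq_len(nrow(a$fragments))) {
    for (j in seq_len(nrow(b$fragments))) {
      total <- total + max(0L, min(a$fragments[i, 2], b$fragments[j, 2]) -
                               max(a$fragments[i, 1], b$fragments[j, 1]))
    }
  }
  total
}

## Span of a single-fragment mention after trimming leading/trailing tokens
## that are stop words; falls back to the raw fragment when every token is a
## stop word (or no token intersects, e.g. a pure-whitespace slice).
trimmed_span <- function(m, doc_tokens) {
  frag <- m$fragments[1, ]
  idx <- which(doc_tokens$start < frag[2] & doc_tokens$end > frag[1])
  if (length(idx) == 0) return(frag)
  stop <- tolower(doc_tokens$surface[idx]) %in% .stopword_cache()
  keep <- which(!stop)
  if (length(keep) == 0) return(frag)
  i <- idx[keep[1]]; j <- idx[keep[length(keep)]]
  c(max(frag[1], doc_tokens$start[i]), min(frag[2], doc_tokens$end[j]))
}

exact_match_impl <- function(gold, pred, doc_tokens) {
  if (!gold$grounded || !pred$grounded) return(FALSE)
  if (gold$entity_type != pred$entity_type) return(FALSE)
  if (nrow(gold$fragments) > 1 || nrow(pred$fragments) > 1) {
    # exact match on discontinuous mentions requires identical fragments
    return(identical(gold$fragments, pred$fragments))
  }
  if (!identical(strip_stopwords(gold$surface), strip_stopwords(pred$surface))) {
    return(FALSE)
  }
  identical(trimmed_span(gold, doc_tokens), trimmed_span(pred, doc_tokens))
}

#' Exact span match
#'
#' True iff the two mentions have the same entity type, the same stop-word-
#' stripped content-token sequence, and coinciding spans after trimming
#' leading/trailing stop-word tokens. An ungrounded prediction never matches.
#'
#' @param gold,pred [entity_mention()]s referencing `doc`.
#' @param doc the [document()] both mentions refer to.
#' @return logical scalar.
#' @export
is_exact_match <- function(gold, pred, doc) {
  exact_match_impl(gold, pred, tokenize(doc))
}

#' Relaxed span match
#'
#' True iff the two mentions have the same entity type and the character
#' sets covered by their fragments intersect non-emptily.
#'
#' @param gold,pred [entity_mention()]s.
#' @return logical scalar.
#' @export
is_relaxed_match <- function(gold, pred) {
  gold$entity_type == pred$entity_type && overlap_chars(gold, pred) > 0L
}

## ---------------------------------------------------------------------------
## One-to-one assignment (greedy preference + augmenting paths, so the
## cardinality always equals the maximum bipartite matching).

## adj: list, one integer vector of candidate pred indices per gold, in
## preference order. Returns list(match_g, match_p).
kuhn_match <- function(n_gold, n_pred, adj, seed_match_g = NULL) {
  match_p <- rep(NA_integer_, n_pred)
  match_g <- if (is.null(seed_match_g)) rep(NA_integer_, n_gold) else seed_match_g
  for (g in which(!is.na(match_g))) match_p[match_g[g]] <- g
  visited <- logical(n_pred)
  try_aug <- function(g) {
    for (p in adj[[g]]) {
      if (!visited[p]) {
        visited[p] <<- TRUE
        if (is.na(match_p[p]) || try_aug(match_p[p])) {
          match_p[p] <<- g
          match_g[g] <<- p
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (g in seq_len(n_gold)) {
    if (is.na(match_g[g]) && length(adj[[g]]) > 0) {
      visited[] <- FALSE
      try_aug(g)
    }
  }
  list(match_g = match_g, match_p = match_p)
}

## Preference-ordered adjacency from a score matrix: candidates with
## edge[g,p] TRUE, ordered by decreasing score then lowest pred index.
pref_adjacency <- function(edge, score = NULL) {
  lapply(seq_len(nrow(edge)), function(g) {
    p <- which(edge[g, ])
    if (length(p) > 1 && !is.null(score)) p <- p[order(-score[g, p], p)]
    p
  })
}

#' One-to-one assignment of predicted to gold mentions
#'
#' Pairs are assigned exact-first: all exact-matching pairs are matched
#' first; in relaxed mode, remaining mentions are then paired along
#' type-matching overlapping edges, preferring larger character overlap
#' (ties: earliest gold start, lowest predicted index), with augmenting-path
#' completion so the final cardinality equals the maximum matching.
#'
#' @param gold gold [annotation_set()].
#' @param pred predicted [annotation_set()] for the same document.
#' @param doc the shared [document()].
#' @param mode `"exact"` or `"relaxed"`.
#' @return object of class `MatchReport`: list with `pairs` (data.frame
#'   `gold`, `pred`, `exact`), `unmatched_gold`, `unmatched_pred`,
#'   `n_correct`, `m`, `m_hat`, `mode`, `doc_id`.
#' @export
assign_matches <- function(gold, pred, doc, mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  if (!identical(gold$doc_id, pred$doc_id)) {
    stop("gold and predicted sets reference different documents: ",
         gold$doc_id, " vs ", pred$doc_id)
  }
  doc_tokens <- tokenize(doc)
  m <- length(gold$mentions)
  mh <- length(pred$mentions)
  exact <- matrix(FALSE, m, mh)
  for (g in seq_len(m)) {
    for (p in seq_len(mh)) {
      exact[g, p] <- exact_match_impl(gold$mentions[[g]], pred$mentions[[p]],
                                      doc_tokens)
    }
  }
  fit <- kuhn_match(m, mh, pref_adjacency(exact))
  if (mode == "relaxed" && m > 0 && mh > 0) {
    ov <- matrix(0L, m, mh)
    edge <- exact
    for (g in seq_len(m)) {
      for (p in seq_len(mh)) {
        ov[g, p] <- overlap_chars(gold$mentions[[g]], pred$mentions[[p]])
        if (is_relaxed_match(gold$mentions[[g]], pred$mentions[[p]])) {
          edge[g, p] <- TRUE
        }
      }
    }
    fit <- kuhn_match(m, mh, pref_adjacency(edge, ov),
                      seed_match_g = fit$match_g)
  }
  matched_g <- which(!is.na(fit$match_g))
  pairs <- data.frame(gold = matched_g,
                      pred = fit$match_g[matched_g],
                      exact = vapply(matched_g, function(g) {
                        exact[g, fit$match_g[g]]
                      }, logical(1)))
  structure(list(doc_id = gold$doc_id, mode = mode, pairs = pairs,
                 unmatched_gold = setdiff(seq_len(m), matched_g),
                 unmatched_pred = setdiff(seq_len(mh), pairs$pred),
                 n_correct = nrow(pairs), m = m, m_hat = mh),
            class = "MatchReport")
}

#' Micro-averaged precision, recall and F1 from match reports
#'
#' Sums correct/gold/predicted counts over documents before dividing.
#' Precision is 0 when nothing was predicted, recall 0 when there is no
#' gold, and F1 0 when precision + recall is 0. Ratios are rounded half-up
#' to 3 decimals.
#'
#' @param reports list of [assign_matches()] results over disjoint documents
#'   (a single report is also accepted).
#' @return object of class `Metrics`: list with `precision`, `recall`, `f1`,
#'   `n_correct`, `m`, `m_hat`.
#' @export
compute_metrics <- function(reports) {
  if (inherits(reports, "MatchReport")) reports <- list(reports)
  n_correct <- sum(vapply(reports, `[[`, numeric(1), "n_correct"))
  m <- sum(vapply(reports, `[[`, numeric(1), "m"))
  mh <- sum(vapply(reports, `[[`, numeric(1), "m_hat"))
  precision <- if (mh == 0) 0 else n_correct / mh
  recall <- if (m == 0) 0 else n_correct / m
  structure(list(precision = round_half_up(precision, 3),
                 recall = round_half_up(recall, 3),
                 f1 = round_half_up(harmonic_f1(precision, recall), 3),
                 n_correct = n_correct, m = m, m_hat = mh),
            class = "Metrics")
}

## Restrict an annotation set to one entity type (NULL keeps everything).
filter_annotation_set <- function(ann, type = NULL) {
  if (is.null(type)) return(ann)
  keep <- vapply(ann$mentions, function(m) m$entity_type == type, logical(1))
  annotation_set(ann$doc_id, ann$mentions[keep], role = ann$role)
}

## Predicted annotation set out of whatever the pipeline returned.
as_prediction_set <- function(x, doc_id) {
  if (inherits(x, "ExtractionResult")) return(x$predictions)
  if (inherits(x, "AnnotationSet")) return(x)
  if (is.list(x) && !is.null(x$predictions)) return(x$predictions)
  annotation_set(doc_id, role = "predicted")
}

#' Corpus-level evaluation report
#'
#' Per-type rows restrict both gold and predicted sets to that type before
#' matching; the overall row pools all four types. All rows are
#' micro-averaged over the pooled document collection.
#'
#' @param corpus list of `list(doc =, ann =)` entries (gold).
#' @param predictions named list (by doc_id) of predicted annotation sets or
#'   [ground_mentions()] results. Documents without an entry count as zero
#'   predictions.
#' @param modes subset of `c("exact", "relaxed")`.
#' @return data.frame with columns `mode`, `entity`, `precision`, `recall`,
#'   `f1`, `n_correct`, `m`, `m_hat`.
#' @export
evaluate_predictions <- function(corpus, predictions,
                                 modes = c("exact", "relaxed")) {
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (mode in modes) {
    for (entity in c(ENTITY_TYPES, "overall")) {
      type <- if (entity == "overall") NULL else entity
      reports <- lapply(corpus, function(entry) {
        pred <- as_prediction_set(predictions[[entry$doc$doc_id]],
                                  entry$doc$doc_id)
        assign_matches(filter_annotation_set(entry$ann, type),
                       filter_annotation_set(pred, type),
                       entry$doc, mode = mode)
      })
      met <- compute_metrics(reports)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, entity = entity, precision = met$precision,
        recall = met$recall, f1 = met$f1, n_correct = met$n_correct,
        m = met$m, m_hat = met$m_hat, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Error taxonomy

#' Classify disagreements into the five error categories
#'
#' Uses the exact-mode assignment extended with an overlap-association pass
#' (one-to-one, decreasing overlap, augmented to maximum cardinality over
#' all overlapping gold/predicted pairs regardless of type). Exact pairs
#' produce no record. An associated pair with the same type but different
#' boundaries is `boundary_only`; same boundaries but different type,
#' `type_only`; both different, `boundary_and_type`. Predictions left
#' unassociated are `spurious`; gold mentions left unassociated are
#' `missed`. Records are attributed to the gold mention's type when a gold
#' mention participates, else the predicted type.
#'
#' @param gold gold [annotation_set()].
#' @param pred predicted [annotation_set()] for the same document.
#' @param doc the shared [document()].
#' @return data.frame with columns `doc_id`, `category`, `gold_index`,
#'   `pred_index`, `entity_type`.
#' @export
classify_errors <- function(gold, pred, doc) {
  if (!identical(gold$doc_id, pred$doc_id)) {
    stop("gold and predicted sets reference different documents")
  }
  doc_tokens <- tokenize(doc)
  m <- length(gold$mentions)
  mh <- length(pred$mentions)
  exact <- matrix(FALSE, m, mh)
  ov <- matrix(0L, m, mh)
  for (g in seq_len(m)) {
    for (p in seq_len(mh)) {
      exact[g, p] <- exact_match_impl(gold$mentions[[g]], pred$mentions[[p]],
                                      doc_tokens)
      ov[g, p] <- overlap_chars(gold$mentions[[g]], pred$mentions[[p]])
    }
  }
  fit <- kuhn_match(m, mh, pref_adjacency(exact))
  ## association pass: any remaining overlap, regardless of type. Exact
  ## pairs stay frozen: association edges only connect the leftovers, so an
  ## exact-correct pair can never be re-paired into an error record.
  free_p <- setdiff(seq_len(mh), fit$match_g[!is.na(fit$match_g)])
  assoc_adj <- lapply(seq_len(m), function(g) {
    if (!is.na(fit$match_g[g])) return(integer(0))
    p <- free_p[ov[g, free_p] > 0L]
    if (length(p) > 1) p <- p[order(-ov[g, p], p)]
    p
  })
  fit <- kuhn_match(m, mh, assoc_adj, seed_match_g = fit$match_g)
  rec <- function(category, g, p, type) {
    data.frame(doc_id = gold$doc_id, category = category,
               gold_index = if (is.null(g)) NA_integer_ else g,
               pred_index = if (is.null(p)) NA_integer_ else p,
               entity_type = type, stringsAsFactors = FALSE)
  }
  records <- list()
  for (g in seq_len(m)) {
    p <- fit$match_g[g]
    if (is.na(p)) {
      records[[length(records) + 1L]] <-
        rec("missed", g, NULL, gold$mentions[[g]]$entity_type)
      next
    }
    if (exact[g, p]) next
    gm <- gold$mentions[[g]]
    pm <- pred$mentions[[p]]
    same_type <- gm$entity_type == pm$entity_type
    same_boundary <- pm$grounded && identical(gm$fragments, pm$fragments)
    category <- if (same_type) "boundary_only"
                else if (same_boundary) "type_only"
                else "boundary_and_type"
    records[[length(records) + 1L]] <- rec(category, g, p, gm$entity_type)
  }
  for (p in setdiff(seq_len(mh), fit$match_g[!is.na(fit$match_g)])) {
    records[[length(records) + 1L]] <-
      rec("spurious", NULL, p, pred$mentions[[p]]$entity_type)
  }
  if (length(records) == 0) {
    return(data.frame(doc_id = character(0), category = character(0),
                      gold_index = integer(0), pred_index = integer(0),
                      entity_type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, records)
}

#' Classify errors over a whole corpus
#'
#' @param corpus list of `list(doc =, ann =)` entries (gold).
#' @param predictions named list (by doc_id) as in [evaluate_predictions()].
#' @return row-bound [classify_errors()] records.
#' @export
classify_corpus_errors <- function(corpus, predictions) {
  do.call(rbind, lapply(corpus, function(entry) {
    pred <- as_prediction_set(predictions[[entry$doc$doc_id]],
                              entry$doc$doc_id)
    classify_errors(entry$ann, pred, entry$doc)
  }))
}

#' Tabulate error records per entity type
#'
#' Counts per category, the per-type total, and integer percentages
#' (half-up) of each category within that type's total errors.
#'
#' @param records error records from [classify_errors()] /
#'   [classify_corpus_errors()].
#' @return object of class `ErrorTable`: data.frame with one row per entity
#'   type; columns `entity`, the five category counts, `total`, and
#'   `pct_<category>` columns.
#' @export
error_table <- function(records) {
  rows <- lapply(ENTITY_TYPES, function(type) {
    sub <- records[records$entity_type == type, , drop = FALSE]
    counts <- vapply(ERROR_CATEGORIES, function(cat) {
      sum(sub$category == cat)
    }, numeric(1))
    total <- sum(counts)
    pct <- if (total == 0) counts else round_half_up(100 * counts / total, 0)
    out <- data.frame(entity = type, stringsAsFactors = FALSE)
    for (cat in ERROR_CATEGORIES) out[[cat]] <- counts[[cat]]
    out$total <- total
    for (cat in ERROR_CATEGORIES) out[[paste0("pct_", cat)]] <- pct[[cat]]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ErrorTable", class(out))
  out
}

#' Format an error table with `count (pct%)` cells
#'
#' @param tab an [error_table()] result.
#' @return data.frame of character cells mirroring the report layout.
#' @export
format_error_table <- function(tab) {
  out <- data.frame(entity = tab$entity, stringsAsFactors = FALSE)
  for (cat in ERROR_CATEGORIES) {
    out[[cat]] <- sprintf("%d (%d%%)", tab[[cat]], tab[[paste0("pct_", cat)]])
  }
  out$total <- sprintf("%d (100%%)", tab$total)
  out
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report data.frame from [evaluate_predictions()].
#' @param path_prefix output path without extension; `.csv` and `.json` are
#'   appended.
#' @return invisibly, the two file paths.
#' @export
write_metrics_report <- function(report, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, json, dataframe = "rows", digits = NA)
  invisible(c(csv = csv, json = json))
}
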