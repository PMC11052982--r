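## Synthetic rare-disease corpus generator and controlled error injection.
##
## Generated documents emulate the profile of the motivating corpus:
## multi-sentence disease descriptions, per-document entity counts drawn per
## type from Poisson distributions with configurable means, all four entity
## types, occasional repeated surface forms. Fixtures exist to exercise code
## paths with known ground truth, not to imitate medical prose.

#' Default per-type surface vocabularies
#'
#' Chosen so that no entry is a substring of any other entry (or of the
#' sentence-template filler text), which keeps leftmost-substring grounding
#' unambiguous on generated text.
#'
#' @return named list of character vectors, one per entity type.
#' @export
default_entity_vocab <- function() {
  list(
    rare_disease = c("Keratomalacia", "Marfan syndrome", "cat eye syndrome",
                     "CARASIL", "Alkaptonuria", "Fabry disease",
                     "Gaucher disease", "Prader-Willi syndrome",
                     "Bardet-Biedl syndrome", "Niemann-Pick disease"),
    disease = c("cancer", "cardiovascular disease", "diabetes mellitus",
                "rheumatoid arthritis", "asthma", "tuberculosis",
                "epilepsy", "anemia"),
    symptom = c("fatigue", "dizziness", "loss of appetite", "nausea",
                "drowsiness", "malaise", "numbness", "itching"),
    sign = c("rash", "fever", "hydronephrosis", "distention of the kidney",
             "corneal scarring", "high blood pressure", "jaundice",
             "hepatomegaly", "poor lung function", "hearing loss"))
}

#' Default sentence templates
#'
#' Each template consumes exactly one typed placeholder `{x}`. The `filler`
#' sentences carry no entities and are appended to every document; the
#' distractor phrases used for spurious-error injection live inside them.
#'
#' @return named list of character vectors per entity type, plus `filler`.
#' @export
default_sentence_templates <- function() {
  list(
    rare_disease = c("{x} is a rare inherited disorder.",
                     "{x} affects only a small number of individuals worldwide.",
                     "Some patients are eventually diagnosed with {x}."),
    disease = c("The condition may be mistaken for {x}.",
                "Several relatives had a history of {x}."),
    symptom = c("Patients often describe {x}.",
                "Early complaints include {x}."),
    sign = c("Examination may reveal {x}.",
             "Clinicians frequently document {x} in affected individuals."),
    filler = c("Affected individuals benefit from early clinical monitoring.",
               "Families are often referred for genetic counseling."))
}

#' Distractor phrases available for spurious-error injection
#'
#' Each occurs exactly once per generated document, inside the filler
#' sentences, and never overlaps a gold mention.
#'
#' @return character vector.
#' @export
default_distractors <- function() c("clinical monitoring", "genetic counseling")

#' Generator configuration
#'
#' Default per-type mean counts are the per-text means of the motivating
#' corpus profile (rare disease 4.88, disease 2.18, symptom 0.38, sign
#' 3.98); the default fixture size is 200 documents.
#'
#' @param n_docs number of documents.
#' @param means named numeric vector of per-document mean mention counts per
#'   entity type.
#' @param vocab named list of per-type surface vocabularies.
#' @param templates sentence templates, see [default_sentence_templates()].
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param max_per_type truncation cap on per-document counts (template
#'   capacity).
#' @return an object of class `GeneratorConfig`.
#' @export
generator_config <- function(n_docs = 200L,
                             means = c(rare_disease = 4.88, disease = 2.18,
                                       symptom = 0.38, sign = 3.98),
                             vocab = default_entity_vocab(),
                             templates = default_sentence_templates(),
                             seed = 1L, max_per_type = 15L) {
  stopifnot(n_docs >= 1, all(ENTITY_TYPES %in% names(means)),
            all(means >= 0))
  for (t in ENTITY_TYPES) {
    if (means[[t]] > 0 && length(vocab[[t]]) == 0) {
      stop("empty vocabulary for type with positive mean count: ", t)
    }
    if (means[[t]] > 0 && length(templates[[t]]) == 0) {
      stop("no sentence template for type: ", t)
    }
  }
  structure(list(n_docs = as.integer(n_docs), means = means[ENTITY_TYPES],
                 vocab = vocab, templates = templates,
                 seed = as.integer(seed),
                 max_per_type = as.integer(max_per_type)),
            class = "GeneratorConfig")
}

## Substring-ambiguity audit: no vocab surface may occur inside another
## vocab surface or inside the entity-free template text.
validate_generator_config <- function(config) {
  surfaces <- tolower(unlist(config$vocab, use.names = FALSE))
  for (i in seq_along(surfaces)) {
    for (j in seq_along(surfaces)) {
      if (i != j && grepl(surfaces[i], surfaces[j], fixed = TRUE)) {
        stop(sprintf("vocabulary surface %s is a substring of %s",
                     dQuote(surfaces[i]), dQuote(surfaces[j])))
      }
    }
  }
  template_text <- tolower(paste(
    gsub("{x}", "", unlist(config$templates), fixed = TRUE), collapse = " "))
  for (s in surfaces) {
    if (grepl(s, template_text, fixed = TRUE)) {
      stop(sprintf("vocabulary surface %s occurs in template filler text",
                   dQuote(s)))
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic gold-annotated corpus
#'
#' Per document, per-type mention counts are drawn from truncated Poisson
#' distributions; each mention fills a one-placeholder sentence template
#' with a vocabulary surface, sentences are shuffled, and entity-free filler
#' sentences are appended. Gold offsets are recorded at fill time and never
#' re-searched.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, the corpus is persisted as
#'   brat `.txt`/`.ann` pairs via [write_corpus_dir()].
#' @return list of `list(doc =, ann =)` entries.
#' @export
generate_corpus <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  validate_generator_config(config)
  corpus <- with_seed(config$seed, {
    lapply(seq_len(config$n_docs), function(i) {
      sentences <- list()
      for (type in ENTITY_TYPES) {
        k <- min(stats::rpois(1, config$means[[type]]), config$max_per_type)
        for (j in seq_len(k)) {
          template <- sample(config$templates[[type]], 1L)
          surface <- sample(config$vocab[[type]], 1L)
          sentences[[length(sentences) + 1L]] <-
            list(template = template, type = type, surface = surface)
        }
      }
      if (length(sentences) > 1) {
        sentences <- sentences[sample(length(sentences))]
      }
      for (f in config$templates$filler) {
        sentences[[length(sentences) + 1L]] <-
          list(template = f, type = NA_character_, surface = NA_character_)
      }
      text <- ""
      mentions <- list()
      for (s in sentences) {
        prefix <- if (nzchar(text)) paste0(text, " ") else ""
        if (is.na(s$type)) {
          rendered <- s$template
        } else {
          ph <- regexpr("{x}", s$template, fixed = TRUE)
          rendered <- sub("{x}", s$surface, s$template, fixed = TRUE)
          start <- nchar(prefix) + ph - 1L  # offset recorded at fill time
          mentions[[length(mentions) + 1L]] <-
            entity_mention(s$type, surface = s$surface, start = start,
                           end = start + nchar(s$surface))
        }
        text <- paste0(prefix, rendered)
      }
      doc <- document(sprintf("doc%04d", i), text, source = "synthetic")
      list(doc = doc, ann = annotation_set(doc$doc_id, mentions, role = "gold"))
    })
  })
  if (!is.null(dir)) write_corpus_dir(corpus, dir)
  corpus
}

## ---------------------------------------------------------------------------
## Error injection

#' Error-injection configuration
#'
#' @param boundary_only,type_only,boundary_and_type,spurious,missed exact
#'   corpus-wide counts to inject.
#' @param seed integer seed.
#' @return an object of class `ErrorInjectionConfig`.
#' @export
error_injection_config <- function(boundary_only = 0L, type_only = 0L,
                                   boundary_and_type = 0L, spurious = 0L,
                                   missed = 0L, seed = 1L) {
  counts <- c(boundary_only = boundary_only, type_only = type_only,
              boundary_and_type = boundary_and_type, spurious = spurious,
              missed = missed)
  stopifnot(all(counts >= 0))
  structure(list(counts = vapply(counts, as.integer, integer(1)),
                 seed = as.integer(seed)),
            class = "ErrorInjectionConfig")
}

## Whole-token boundary edit of a single-fragment mention. Returns a
## corrupted EntityMention or NULL if no admissible edit exists.
boundary_edit <- function(mention, doc, doc_tokens, other_golds,
                          new_type = NULL) {
  frag <- mention$fragments[1, ]
  idx <- which(doc_tokens$start < frag[2] & doc_tokens$end > frag[1])
  if (length(idx) == 0) return(NULL)
  candidates <- list()
  if (idx[1] > 1) {
    candidates$extend_left <- c(doc_tokens$start[idx[1] - 1L], frag[2])
  }
  if (idx[length(idx)] < nrow(doc_tokens)) {
    candidates$extend_right <- c(frag[1], doc_tokens$end[idx[length(idx)] + 1L])
  }
  if (length(idx) > 1) {
    candidates$shrink_left <- c(doc_tokens$start[idx[2]], frag[2])
    candidates$shrink_right <- c(frag[1], doc_tokens$end[idx[length(idx) - 1L]])
  }
  if (length(candidates) > 1) candidates <- candidates[sample(length(candidates))]
  type <- if (is.null(new_type)) mention$entity_type else new_type
  for (span in candidates) {
    corrupted <- entity_mention(
      type, surface = substring(doc$text, span[1] + 1L, span[2]),
      start = span[1], end = span[2])
    if (overlap_chars(mention, corrupted) == 0L) next
    if (exact_match_impl(mention, corrupted, doc_tokens)) next
    clash <- any(vapply(other_golds, function(g) {
      overlap_chars(g, corrupted) > 0L
    }, logical(1)))
    if (clash) next
    return(corrupted)
  }
  NULL
}

#' Corrupt gold annotations into predictions with exact error counts
#'
#' The constructive inverse of the error taxonomy: `boundary_only` extends
#' or shrinks a gold span by whole tokens (same type); `type_only` keeps the
#' span and swaps the type; `boundary_and_type` does both; `spurious`
#' inserts a mention over a distractor phrase that overlaps no gold;
#' `missed` deletes a gold mention. Untouched gold mentions are copied
#' verbatim. Each gold mention is consumed by at most one corruption, so
#' [classify_errors()] recovers the configured counts exactly.
#'
#' @param corpus gold corpus from [generate_corpus()].
#' @param config an [error_injection_config()].
#' @param distractors phrases available for spurious insertion (must occur
#'   in the documents, outside gold spans).
#' @return list with `predictions` (named list of predicted annotation sets
#'   by doc_id) and `ledger` (data.frame: one row per injected error).
#' @export
inject_errors <- function(corpus, config,
                          distractors = default_distractors()) {
  stopifnot(inherits(config, "ErrorInjectionConfig"))
  counts <- config$counts
  n_gold <- sum(vapply(corpus, function(e) length(e$ann$mentions), integer(1)))
  consuming <- sum(counts[c("boundary_only", "type_only", "boundary_and_type",
                            "missed")])
  if (consuming > n_gold) {
    stop(sprintf("infeasible injection: %d gold-consuming errors requested but only %d gold mentions available",
                 consuming, n_gold))
  }
  spur_capacity <- length(corpus) * length(distractors)
  if (counts[["spurious"]] > spur_capacity) {
    stop(sprintf("infeasible injection: %d spurious errors requested but only %d distractor slots available",
                 counts[["spurious"]], spur_capacity))
  }
  with_seed(config$seed, {
    tokens_by_doc <- lapply(corpus, function(e) tokenize(e$doc))
    ## predictions start as verbatim copies of gold
    preds <- lapply(corpus, function(e) {
      lapply(e$ann$mentions, function(m) m)
    })
    drop <- lapply(corpus, function(e) logical(length(e$ann$mentions)))
    replacement <- lapply(corpus, function(e) vector("list", length(e$ann$mentions)))
    ledger <- list()
    log_entry <- function(doc_id, category, original, corrupted) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        doc_id = doc_id, category = category,
        original = original, corrupted = corrupted, stringsAsFactors = FALSE)
    }
    ## gold candidates, shuffled once
    cand <- do.call(rbind, lapply(seq_along(corpus), function(i) {
      n <- length(corpus[[i]]$ann$mentions)
      if (n == 0) NULL else data.frame(doc = i, mention = seq_len(n))
    }))
    if (!is.null(cand)) cand <- cand[sample(nrow(cand)), , drop = FALSE]
    needs <- counts
    mention_desc <- function(m) {
      sprintf("%s[%s]", m$surface, m$entity_type)
    }
    for (r in seq_len(if (is.null(cand)) 0 else nrow(cand))) {
      if (sum(needs[c("boundary_only", "type_only", "boundary_and_type",
                      "missed")]) == 0) break
      i <- cand$doc[r]; j <- cand$mention[r]
      entry <- corpus[[i]]
      gold_m <- entry$ann$mentions[[j]]
      others <- entry$ann$mentions[-j]
      placed <- FALSE
      for (category in c("boundary_only", "boundary_and_type", "type_only",
                         "missed")) {
        if (needs[[category]] == 0) next
        if (category == "missed") {
          drop[[i]][j] <- TRUE
          log_entry(entry$doc$doc_id, "missed", mention_desc(gold_m), NA)
          placed <- TRUE
        } else if (category == "type_only") {
          new_type <- sample(setdiff(ENTITY_TYPES, gold_m$entity_type), 1L)
          corrupted <- entity_mention(new_type, surface = gold_m$surface,
                                      fragments = gold_m$fragments)
          replacement[[i]][[j]] <- corrupted
          log_entry(entry$doc$doc_id, "type_only", mention_desc(gold_m),
                    mention_desc(corrupted))
          placed <- TRUE
        } else {
          new_type <- if (category == "boundary_and_type") {
            sample(setdiff(ENTITY_TYPES, gold_m$entity_type), 1L)
          } else NULL
          corrupted <- boundary_edit(gold_m, entry$doc, tokens_by_doc[[i]],
                                     others, new_type = new_type)
          if (is.null(corrupted)) next
          replacement[[i]][[j]] <- corrupted
          log_entry(entry$doc$doc_id, category, mention_desc(gold_m),
                    mention_desc(corrupted))
          placed <- TRUE
        }
        if (placed) {
          needs[[category]] <- needs[[category]] - 1L
          break
        }
      }
    }
    unmet <- needs[c("boundary_only", "type_only", "boundary_and_type",
                     "missed")]
    if (sum(unmet) > 0) {
      stop("could not place all requested corruptions; shortfall: ",
           paste(sprintf("%s=%d", names(unmet)[unmet > 0], unmet[unmet > 0]),
                 collapse = ", "))
    }
    ## spurious insertions over distractor slots
    slots <- expand.grid(doc = seq_along(corpus),
                         phrase = seq_along(distractors))
    slots <- slots[sample(nrow(slots)), , drop = FALSE]
    n_spur <- counts[["spurious"]]
    spurious_new <- lapply(corpus, function(e) list())
    placed_spur <- 0L
    for (r in seq_len(nrow(slots))) {
      if (placed_spur >= n_spur) break
      i <- slots$doc[r]
      phrase <- distractors[slots$phrase[r]]
      pos <- regexpr(phrase, corpus[[i]]$doc$text, fixed = TRUE)
      if (pos == -1) next
      start <- as.integer(pos) - 1L
      m <- entity_mention(sample(ENTITY_TYPES, 1L), surface = phrase,
                          start = start, end = start + nchar(phrase))
      if (any(vapply(corpus[[i]]$ann$mentions, function(g) {
        overlap_chars(g, m) > 0L
      }, logical(1)))) next
      spurious_new[[i]][[length(spurious_new[[i]]) + 1L]] <- m
      log_entry(corpus[[i]]$doc$doc_id, "spurious", NA, mention_desc(m))
      placed_spur <- placed_spur + 1L
    }
    if (placed_spur < n_spur) {
      stop("could not place all spurious insertions; shortfall: ",
           n_spur - placed_spur)
    }
    predictions <- stats::setNames(lapply(seq_along(corpus), function(i) {
      kept <- list()
      for (j in seq_along(preds[[i]])) {
        if (drop[[i]][j]) next
        kept[[length(kept) + 1L]] <-
          if (!is.null(replacement[[i]][[j]])) replacement[[i]][[j]]
          else preds[[i]][[j]]
      }
      annotation_set(corpus[[i]]$doc$doc_id, c(kept, spurious_new[[i]]),
                     role = "predicted")
    }), vapply(corpus, function(e) e$doc$doc_id, character(1)))
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(doc_id = character(0), category = character(0),
                 original = character(0), corrupted = character(0),
                 stringsAsFactors = FALSE)
    list(predictions = predictions, ledger = ledger)
  })
}

#' Write an injection ledger as JSON lines
#'
#' @param ledger ledger data.frame from [inject_errors()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_injection_ledger <- function(ledger, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(ledger))) {
    writeLines(jsonlite::toJSON(as.list(ledger[r, ]), auto_unbox = TRUE,
                                na = "null"), con)
  }
  invisible(path)
}

#' Gold-echo completion provider
#'
#' Returns a provider that answers every prompt with the target document's
#' gold entity lists rendered in the pipeline's labeled comma-separated
#' output format (one item per gold mention, in document order, without
#' deduplication — so grounding recovers every repeated occurrence). The
#' target document is identified by the id embedded in the prompt envelope
#' by [run_extraction()]; unknown documents get an empty response.
#'
#' @param corpus gold corpus entries.
#' @return a provider `function(prompt) -> response`.
#' @export
gold_echo_provider <- function(corpus) {
  lists_by_id <- stats::setNames(lapply(corpus, function(entry) {
    lists <- stats::setNames(lapply(ENTITY_TYPES, function(t) character(0)),
                             ENTITY_TYPES)
    for (m in entry$ann$mentions) {
      lists[[m$entity_type]] <- c(lists[[m$entity_type]], m$surface)
    }
    lists
  }), vapply(corpus, function(e) e$doc$doc_id, character(1)))
  function(prompt) {
    id <- envelope_doc_id(prompt)
    if (is.na(id) || is.null(lists_by_id[[id]])) return("")
    render_entity_lists(lists_by_id[[id]])
  }
}

#' Provider built from injected (corrupted) predictions
#'
#' Echoes the corrupted annotation sets from [inject_errors()] in the
#' labeled output format, for end-to-end tests where the pipeline must
#' reproduce a known error profile.
#'
#' @param predictions named list of predicted annotation sets by doc_id.
#' @return a provider `function(prompt) -> response`.
#' @export
echo_predictions_provider <- function(predictions) {
  function(prompt) {
    id <- envelope_doc_id(prompt)
    if (is.na(id) || is.null(predictions[[id]])) return("")
    lists <- stats::setNames(lapply(ENTITY_TYPES, function(t) character(0)),
                             ENTITY_TYPES)
    for (m in predictions[[id]]$mentions) {
      lists[[m$entity_type]] <- c(lists[[m$entity_type]], m$surface)
    }
    render_entity_lists(lists)
  }
}
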