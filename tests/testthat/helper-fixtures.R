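# Fixtures are built in code; nothing is read from disk except packaged
# resources.

FIG_TEXT <- "Keratomalacia is a cause of corneal scarring."
FIG_ANN <- "T1\tRAREDISEASE 0 13\tKeratomalacia\nT2\tSIGN 28 44\tcorneal scarring"

fig_pair <- function() parse_brat(FIG_TEXT, FIG_ANN, doc_id = "fig1")

# Semantic annotation-set equality: type, fragments, surface per mention.
expect_same_ann <- function(a, b) {
  expect_equal(length(a$mentions), length(b$mentions))
  for (i in seq_along(a$mentions)) {
    expect_identical(a$mentions[[i]]$entity_type, b$mentions[[i]]$entity_type)
    expect_equal(unname(a$mentions[[i]]$fragments),
                 unname(b$mentions[[i]]$fragments))
    expect_identical(a$mentions[[i]]$surface, b$mentions[[i]]$surface)
  }
}

# Brute-force maximum bipartite matching cardinality (independent oracle):
# recursion over gold indices, trying every free predicted partner.
brute_force_max_matching <- function(edge) {
  m <- nrow(edge); mh <- ncol(edge)
  if (m == 0 || mh == 0) return(0L)
  best <- function(g, used) {
    if (g > m) return(0L)
    res <- best(g + 1L, used)  # leave gold g unmatched
    for (p in seq_len(mh)) {
      if (edge[g, p] && !used[p]) {
        used[p] <- TRUE
        res <- max(res, 1L + best(g + 1L, used))
        used[p] <- FALSE
      }
    }
    res
  }
  best(1L, logical(mh))
}

# Random micro-instance: token-aligned gold/predicted mentions over a small
# synthetic sentence; spans and types random, some predictions ungrounded.
WORDS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
           "eta", "theta", "iota", "kappa", "lambda", "sigma")

random_micro_instance <- function() {
  n_tok <- sample(6:12, 1)
  words <- sample(WORDS, n_tok, replace = TRUE)
  text <- paste(words, collapse = " ")
  doc <- document("micro", text)
  toks <- tokenize(doc)
  rand_mentions <- function(k) {
    out <- list()
    for (i in seq_len(k)) {
      if (stats::runif(1) < 0.1) {
        out[[i]] <- entity_mention(sample(entity_types(), 1),
                                   surface = "unlocatable phrase")
        next
      }
      a <- sample(n_tok, 1)
      b <- min(n_tok, a + sample(0:2, 1))
      out[[i]] <- entity_mention(sample(entity_types(), 1),
                                 surface = substring(text, toks$start[a] + 1,
                                                     toks$end[b]),
                                 start = toks$start[a], end = toks$end[b])
    }
    out
  }
  list(doc = doc,
       gold = annotation_set("micro", rand_mentions(sample(0:6, 1)),
                             role = "gold"),
       pred = annotation_set("micro", rand_mentions(sample(0:6, 1)),
                             role = "predicted"))
}

# Corpus with exact per-document mention counts (deterministic), used for
# summary-statistics arithmetic.
make_counted_corpus <- function(n_docs, symptom_docs = 0L, disease_per_doc = 0L,
                                extra_disease_docs = 0L) {
  lapply(seq_len(n_docs), function(i) {
    text <- "This record describes one case."
    mentions <- list()
    add_sentence <- function(sentence, surface, type) {
      prefix <- paste0(text, " ")
      start <- nchar(prefix) + regexpr(surface, sentence, fixed = TRUE) - 1L
      mentions[[length(mentions) + 1L]] <<-
        entity_mention(type, surface = surface, start = start,
                       end = start + nchar(surface))
      text <<- paste0(prefix, sentence)
    }
    n_dis <- disease_per_doc + as.integer(i <= extra_disease_docs)
    for (j in seq_len(n_dis)) {
      add_sentence("Several relatives had a history of cancer.", "cancer",
                   "disease")
    }
    if (i <= symptom_docs) {
      add_sentence("Patients often describe fatigue.", "fatigue", "symptom")
    }
    doc <- document(sprintf("c%04d", i), text)
    list(doc = doc, ann = annotation_set(doc$doc_id, mentions, role = "gold"))
  })
}

# Small shared fixture corpus (regenerated per file; generation is fast).
small_corpus <- function(n = 20, seed = 7) {
  generate_corpus(generator_config(n_docs = n, seed = seed))
}
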