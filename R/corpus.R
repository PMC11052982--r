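## Corpus data model: documents, typed entity spans, brat standoff I/O,
## BIO codec, corpus statistics, dataset splitting.
##
## Offsets are 0-based, end-exclusive character offsets (brat convention).

#' Create a document
#'
#' @param doc_id unique identifier string.
#' @param text document text (non-empty).
#' @param source free-form provenance tag.
#' @return an object of class `Document`.
#' @export
document <- function(doc_id, text, source = "unknown") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("document text must be non-empty")
  structure(list(doc_id = doc_id, text = text, source = source),
            class = "Document")
}

#' Create an entity mention
#'
#' A mention is a typed set of character-offset fragments plus the surface
#' string it denotes. Grounded mentions carry one or more non-overlapping
#' fragments whose document slices, joined with a single space, equal the
#' surface. Ungrounded mentions (surfaces a model emitted but that cannot be
#' located in the text) have no fragments.
#'
#' @param entity_type one of [entity_types()] (any recognized spelling).
#' @param surface surface string (required for ungrounded mentions).
#' @param start,end convenience for a single fragment (0-based, end-exclusive).
#' @param fragments two-column matrix of (start, end) rows; overrides
#'   `start`/`end`.
#' @return an object of class `EntityMention`.
#' @export
entity_mention <- function(entity_type, surface = NULL, start = NULL,
                           end = NULL, fragments = NULL) {
  type <- normalize_entity_type(entity_type)
  if (is.null(fragments)) {
    fragments <- if (is.null(start)) {
      matrix(integer(0), ncol = 2)
    } else {
      cbind(as.integer(start), as.integer(end))
    }
  } else {
    fragments <- matrix(as.integer(fragments), ncol = 2)
  }
  colnames(fragments) <- c("start", "end")
  if (nrow(fragments) > 1) {
    fragments <- fragments[order(fragments[, 1]), , drop = FALSE]
  }
  if (nrow(fragments) > 0) {
    if (any(fragments[, 1] >= fragments[, 2])) {
      stop("fragment start must be < end")
    }
    if (nrow(fragments) > 1 &&
        any(fragments[-1, 1] < fragments[-nrow(fragments), 2])) {
      stop("fragments must be pairwise non-overlapping")
    }
  }
  grounded <- nrow(fragments) > 0
  if (!grounded && (is.null(surface) || !nzchar(surface))) {
    stop("ungrounded mention requires a non-empty surface")
  }
  structure(list(fragments = fragments,
                 entity_type = type,
                 surface = if (is.null(surface)) NA_character_ else surface,
                 grounded = grounded),
            class = "EntityMention")
}

## First-fragment start, used for ordering; ungrounded sort last.
mention_start <- function(m) {
  if (m$grounded) m$fragments[1, 1] else .Machine$integer.max
}

## Surface implied by the fragments of a grounded mention.
mention_slice <- function(m, text) {
  paste(substring(text, m$fragments[, 1] + 1L, m$fragments[, 2]),
        collapse = " ")
}

validate_mention <- function(m, text, strict = TRUE) {
  if (!m$grounded) return(invisible(TRUE))
  if (any(m$fragments[, 1] < 0L) || any(m$fragments[, 2] > nchar(text))) {
    stop("mention offsets outside document text (0..", nchar(text), ")")
  }
  slice <- mention_slice(m, text)
  if (!is.na(m$surface) && !identical(slice, m$surface)) {
    msg <- sprintf("mention surface %s differs from text slice %s",
                   dQuote(m$surface), dQuote(slice))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Create an annotation set
#'
#' The gold (`Y`) or predicted (`Y-hat`) label vector for one document: a
#' list of entity mentions. Its cardinality is `m` (gold) or `m-hat`
#' (predicted).
#'
#' @param doc_id identifier of the document the mentions refer to.
#' @param mentions list of [entity_mention()] objects.
#' @param role `"gold"` or `"predicted"`.
#' @return an object of class `AnnotationSet`.
#' @export
annotation_set <- function(doc_id, mentions = list(), role = c("gold", "predicted")) {
  role <- match.arg(role)
  stopifnot(all(vapply(mentions, inherits, logical(1), "EntityMention")))
  if (length(mentions) > 1) {
    mentions <- mentions[order(vapply(mentions, mention_start, numeric(1)))]
  }
  structure(list(doc_id = doc_id, role = role, mentions = unname(mentions)),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("<AnnotationSet %s: %d %s mention(s)>\n",
              x$doc_id, length(x$mentions), x$role))
  for (m in x$mentions) {
    span <- if (m$grounded) {
      paste(apply(m$fragments, 1, function(f) paste(f, collapse = "-")),
            collapse = ";")
    } else "ungrounded"
    cat(sprintf("  [%s] %s (%s)\n", m$entity_type, m$surface, span))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## brat standoff

#' Parse a brat standoff document/annotation pair
#'
#' Reads entity (T) lines of the form
#' `T<id>\t<TYPE> <start> <end>[;<start> <end>]*\t<surface>`; all other line
#' types (relations, events, notes) are ignored. Entity-type labels are
#' normalized case-insensitively onto the four-type vocabulary.
#'
#' @param txt_content document text.
#' @param ann_content annotation file content (may be empty).
#' @param doc_id document identifier.
#' @param policy `"strict"` errors when the recorded surface differs from the
#'   text slice; `"lenient"` keeps the offsets and warns.
#' @return list with elements `doc` ([document()]) and `ann` (gold
#'   [annotation_set()]).
#' @export
parse_brat <- function(txt_content, ann_content, doc_id,
                       policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  doc <- document(doc_id, txt_content, source = "brat")
  lines <- if (nzchar(ann_content)) {
    strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  } else character(0)
  mentions <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[i])
    if (!nzchar(line) || substr(line, 1, 1) != "T") next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    ok <- length(fields) >= 2 && grepl("^T[0-9]+$", fields[1]) &&
      grepl("^\\S+ [0-9]+ [0-9]+(;[0-9]+ [0-9]+)*$", fields[2])
    if (!ok) {
      stop(sprintf("malformed brat T line %d: %s", i, dQuote(line)))
    }
    head_parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
    type <- head_parts[1]
    frag_str <- paste(head_parts[-1], collapse = " ")
    frags <- do.call(rbind, lapply(strsplit(frag_str, ";", fixed = TRUE)[[1]],
                                   function(f) {
                                     as.integer(strsplit(f, " ")[[1]])
                                   }))
    if (any(frags[, 2] > nchar(txt_content)) || any(frags[, 1] < 0)) {
      stop(sprintf("annotation line %d: offsets outside text of length %d",
                   i, nchar(txt_content)))
    }
    surface <- if (length(fields) >= 3) fields[3] else NA_character_
    m <- entity_mention(type, surface = surface, fragments = frags)
    slice <- mention_slice(m, txt_content)
    if (is.na(m$surface)) {
      m$surface <- slice
    } else if (!identical(m$surface, slice)) {
      msg <- sprintf("line %d: surface %s differs from text slice %s",
                     i, dQuote(m$surface), dQuote(slice))
      if (policy == "strict") stop(msg)
      warning(msg, call. = FALSE)
      m$surface <- slice
    }
    mentions[[length(mentions) + 1L]] <- m
  }
  list(doc = doc, ann = annotation_set(doc_id, mentions, role = "gold"))
}

#' Serialize an annotation set to brat standoff
#'
#' Emits one T line per mention with sequential identifiers `T1..Tn` in
#' mention start order; discontinuous fragment lists are joined with `;`.
#'
#' @param doc a [document()].
#' @param ann an [annotation_set()] whose mentions are all grounded and valid
#'   for `doc`.
#' @return annotation file content as a single string (empty for an empty
#'   set).
#' @export
write_brat <- function(doc, ann) {
  if (length(ann$mentions) == 0) return("")
  lines <- vapply(seq_along(ann$mentions), function(i) {
    m <- ann$mentions[[i]]
    if (!m$grounded) {
      stop("cannot serialize ungrounded mention ", dQuote(m$surface))
    }
    validate_mention(m, doc$text, strict = TRUE)
    frag <- paste(apply(m$fragments, 1, paste, collapse = " "),
                  collapse = ";")
    label <- toupper(gsub("_", "", m$entity_type))
    sprintf("T%d\t%s %s\t%s", i, label, frag, mention_slice(m, doc$text))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

## ---------------------------------------------------------------------------
## Corpus directory I/O: one .txt and one .ann per document, shared basename.

#' Read a brat corpus directory
#'
#' @param dir directory containing `.txt`/`.ann` pairs.
#' @param policy surface-mismatch policy passed to [parse_brat()].
#' @return list of entries, each `list(doc =, ann =)`, ordered by basename.
#' @export
read_corpus_dir <- function(dir, policy = "strict") {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0) stop("no .txt files found in ", dir)
  lapply(txts, function(txt) {
    base <- sub("\\.txt$", "", basename(txt))
    annf <- file.path(dir, paste0(base, ".ann"))
    txt_content <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                         collapse = "\n")
    ann_content <- if (file.exists(annf)) {
      paste(readLines(annf, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    } else ""
    parse_brat(txt_content, ann_content, doc_id = base, policy = policy)
  })
}

#' Write a corpus as brat .txt/.ann pairs
#'
#' @param corpus list of `list(doc =, ann =)` entries.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_corpus_dir <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (entry in corpus) {
    writeLines(entry$doc$text, file.path(dir, paste0(entry$doc$doc_id, ".txt")),
               useBytes = TRUE, sep = "\n")
    cat(write_brat(entry$doc, entry$ann),
        file = file.path(dir, paste0(entry$doc$doc_id, ".ann")))
  }
  invisible(dir)
}

## ---------------------------------------------------------------------------
## Tokenizer

#' Tokenize text
#'
#' Tokens are maximal runs of letters/digits, or single punctuation marks;
#' whitespace never appears in a token. Spans are 0-based, end-exclusive,
#' disjoint and sorted, and cover every non-space character.
#'
#' @param x a [document()] or a character scalar.
#' @return data.frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(x) {
  text <- if (inherits(x, "Document")) x$text else x
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L),
             end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## BIO codec

#' Encode annotations as a BIO tag sequence
#'
#' Each token receives `B-<type>` if it is the first token whose span
#' intersects a mention, `I-<type>` for subsequent intersecting tokens, and
#' `O` otherwise. Alignment uses span intersection (not containment) so
#' partial-token overlaps still tag the token. The codec cannot express
#' discontinuous or overlapping mentions.
#'
#' @param doc a [document()].
#' @param ann an [annotation_set()] of continuous, non-overlapping mentions.
#' @param on_invalid `"error"` rejects discontinuous/overlapping mentions;
#'   `"drop"` skips them with a warning.
#' @return object of class `BioSequence`: list with `tokens` (data.frame from
#'   [tokenize()]) and `tags` (character vector of equal length).
#' @export
to_bio <- function(doc, ann, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  tokens <- tokenize(doc)
  tags <- rep("O", nrow(tokens))
  kept <- list()
  for (m in ann$mentions) {
    bad <- !m$grounded || nrow(m$fragments) != 1
    if (!bad) {
      for (k in kept) {
        if (max(k$fragments[1, 1], m$fragments[1, 1]) <
            min(k$fragments[1, 2], m$fragments[1, 2])) {
          if (on_invalid == "error") {
            stop(sprintf("overlapping mentions: %s (%d-%d) and %s (%d-%d)",
                         dQuote(k$surface), k$fragments[1, 1], k$fragments[1, 2],
                         dQuote(m$surface), m$fragments[1, 1], m$fragments[1, 2]))
          }
          bad <- TRUE
          break
        }
      }
    } else if (on_invalid == "error") {
      stop("BIO codec cannot express discontinuous or ungrounded mention ",
           dQuote(m$surface))
    }
    if (bad) {
      warning("dropping mention ", dQuote(m$surface), call. = FALSE)
      next
    }
    kept[[length(kept) + 1L]] <- m
    hit <- which(tokens$start < m$fragments[1, 2] &
                 tokens$end > m$fragments[1, 1])
    if (length(hit) > 0) {
      tags[hit[1]] <- paste0("B-", m$entity_type)
      if (length(hit) > 1) tags[hit[-1]] <- paste0("I-", m$entity_type)
    }
  }
  structure(list(tokens = tokens, tags = tags), class = "BioSequence")
}

validate_bio_tags <- function(tags, lenient = FALSE) {
  prev <- "O"
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag != "O" && !grepl("^[BI]-(rare_disease|disease|symptom|sign)$", tag)) {
      stop("invalid BIO tag: ", tag)
    }
    if (startsWith(tag, "I-")) {
      t <- substring(tag, 3)
      ok <- prev %in% paste0(c("B-", "I-"), t)
      if (!ok) {
        if (!lenient) stop(sprintf("orphan %s at position %d", tag, i))
        tags[i] <- paste0("B-", t)
        tag <- tags[i]
      }
    }
    prev <- tag
  }
  tags
}

#' Decode a BIO tag sequence into an annotation set
#'
#' Each maximal `B-t (I-t)*` run becomes one mention spanning the first
#' token's start to the last token's end.
#'
#' @param seq a `BioSequence` (or a list with `tokens` and `tags`).
#' @param doc_id document identifier for the resulting set.
#' @param doc optional [document()]; when given, mention surfaces are taken
#'   from the text (so round-trips restore multi-token surfaces exactly).
#' @param role role of the resulting annotation set.
#' @param lenient repair orphan `I-t` tags by promoting them to `B-t` instead
#'   of erroring.
#' @return an [annotation_set()].
#' @export
from_bio <- function(seq, doc_id = "doc", doc = NULL, role = "predicted",
                     lenient = FALSE) {
  tokens <- seq$tokens
  tags <- validate_bio_tags(seq$tags, lenient = lenient)
  stopifnot(length(tags) == nrow(tokens))
  mentions <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      type <- substring(tags[i], 3)
      j <- i
      while (j < length(tags) && tags[j + 1L] == paste0("I-", type)) j <- j + 1L
      start <- tokens$start[i]
      end <- tokens$end[j]
      surface <- if (!is.null(doc)) {
        substring(doc$text, start + 1L, end)
      } else {
        paste(tokens$surface[i:j], collapse = " ")
      }
      mentions[[length(mentions) + 1L]] <-
        entity_mention(type, surface = surface, start = start, end = end)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  annotation_set(doc_id, mentions, role = role)
}

## ---------------------------------------------------------------------------
## Corpus statistics and splitting

#' Per-type corpus statistics
#'
#' Totals and per-document mean/SD of mention counts for each entity type,
#' mirroring a corpus summary table.
#'
#' @param corpus list of `list(doc =, ann =)` entries with gold annotations.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return object of class `CorpusStats`: data.frame with one row per entity
#'   type plus an overall row; columns `entity`, `total`, `mean_per_doc`,
#'   `sd_per_doc`; attribute `n_docs`.
#' @export
corpus_stats <- function(corpus, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(corpus) == 0) stop("empty corpus")
  counts <- vapply(corpus, function(entry) {
    types <- vapply(entry$ann$mentions, `[[`, character(1), "entity_type")
    vapply(ENTITY_TYPES, function(t) sum(types == t), numeric(1))
  }, numeric(length(ENTITY_TYPES)))
  counts <- matrix(counts, nrow = length(ENTITY_TYPES),
                   dimnames = list(ENTITY_TYPES, NULL))
  n <- length(corpus)
  sdfun <- function(x) {
    if (sd_type == "sample") {
      if (n < 2) 0 else stats::sd(x)
    } else {
      sqrt(mean((x - mean(x))^2))
    }
  }
  per_type <- data.frame(
    entity = ENTITY_TYPES,
    total = rowSums(counts),
    mean_per_doc = rowMeans(counts),
    sd_per_doc = apply(counts, 1, sdfun),
    stringsAsFactors = FALSE)
  overall <- data.frame(entity = "overall", total = sum(counts),
                        mean_per_doc = mean(colSums(counts)),
                        sd_per_doc = sdfun(colSums(counts)),
                        stringsAsFactors = FALSE)
  out <- rbind(per_type, overall)
  rownames(out) <- NULL
  attr(out, "n_docs") <- n
  attr(out, "sd_type") <- sd_type
  class(out) <- c("CorpusStats", class(out))
  out
}

#' Format corpus statistics for reporting
#'
#' Means and SDs rounded to 2 decimals, half-up.
#'
#' @param stats a `CorpusStats` object.
#' @return data.frame with character `mean (sd)` column.
#' @export
format_corpus_stats <- function(stats) {
  data.frame(entity = stats$entity,
             total = stats$total,
             count_per_text = sprintf("%.2f (%.2f)",
                                      round_half_up(stats$mean_per_doc, 2),
                                      round_half_up(stats$sd_per_doc, 2)),
             stringsAsFactors = FALSE)
}

#' Deterministic train/validation/test split
#'
#' Sizes are `floor(ratio * N)` for validation and test, with the remainder
#' assigned to train; the three lists partition the corpus.
#'
#' @param doc_ids character vector of document ids (or a corpus list, from
#'   which ids are taken).
#' @param ratios numeric length-3 vector `(train, val, test)`, positive,
#'   summing to 1 (tolerance 1e-6).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with character vectors `train`, `val`, `test`.
#' @export
split_corpus <- function(doc_ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is.list(doc_ids)) {
    doc_ids <- vapply(doc_ids, function(e) e$doc$doc_id, character(1))
  }
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-6) stop("ratios must sum to 1")
  n <- length(doc_ids)
  n_groups <- sum(ratios > 0)
  if (n < n_groups) stop("fewer documents than non-zero ratio groups")
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  shuffled <- with_seed(seed, sample(doc_ids, n))
  list(train = sort(shuffled[seq_len(n_train)]),
       val = sort(shuffled[n_train + seq_len(n_val)]),
       test = sort(shuffled[n_train + n_val + seq_len(n_test)]))
}
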