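## Prompt assembly for zero-/few-shot entity extraction, plus few-shot
## example selection (random, or most-similar training text).
##
## A prompt is assembled from five building blocks: task instruction, task
## guidance (entity definitions, optionally distinguishing characteristics),
## output specification, an optional worked example, and an output-retrieval
## cue. Two layouts are shipped as template resources: a conversational
## simple-sentence paragraph and a numbered structured list.

read_template <- function(name) {
  path <- system.file("templates", name, package = "phenoprompt")
  if (!nzchar(path)) stop("missing template resource: ", name)
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

read_entity_tsv <- function(name) {
  path <- system.file("templates", name, package = "phenoprompt")
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  out <- as.list(raw[[2]])
  names(out) <- raw[[1]]
  out[ENTITY_TYPES]
}

#' Default entity definitions used in the task-guidance block
#'
#' The annotation-guideline definitions of the four entity types, shipped as
#' a template resource.
#'
#' @return named list (one entry per entity type) of definition strings.
#' @export
default_entity_definitions <- function() read_entity_tsv("definitions.tsv")

#' Distinguishing characteristics of each entity type
#'
#' Guidance sentences that help a model separate semantically overlapping
#' types (rare disease vs disease; symptom vs sign), with worked examples.
#'
#' @return named list (one entry per entity type) of characteristic strings.
#' @export
default_entity_characteristics <- function() read_entity_tsv("characteristics.tsv")

#' Specification of a prompt
#'
#' @param setting `"zero_shot"` (no worked example) or `"few_shot"` (one
#'   worked example embedded in the prompt).
#' @param format `"simple_sentence"` (conversational paragraph) or
#'   `"structured_list"` (numbered sub-prompts).
#' @param include_characteristics add per-type distinguishing characteristics
#'   to the task guidance.
#' @param entity_definitions named list covering all four entity types.
#' @param characteristics named list covering all four entity types (required
#'   when `include_characteristics`).
#' @param output_format_instruction the output-specification text.
#' @return an object of class `PromptSpec`.
#' @export
prompt_spec <- function(setting = c("zero_shot", "few_shot"),
                        format = c("simple_sentence", "structured_list"),
                        include_characteristics = FALSE,
                        entity_definitions = default_entity_definitions(),
                        characteristics = default_entity_characteristics(),
                        output_format_instruction = read_template("output_specification.txt")) {
  setting <- match.arg(setting)
  format <- match.arg(format)
  if (!setequal(names(entity_definitions), ENTITY_TYPES)) {
    stop("entity_definitions must have exactly the four entity types as keys")
  }
  if (include_characteristics && !all(ENTITY_TYPES %in% names(characteristics))) {
    stop("include_characteristics requires characteristics for all four types")
  }
  structure(list(setting = setting, format = format,
                 include_characteristics = include_characteristics,
                 entity_definitions = entity_definitions[ENTITY_TYPES],
                 characteristics = characteristics,
                 output_format_instruction = output_format_instruction),
            class = "PromptSpec")
}

#' A worked few-shot example
#'
#' @param example_text input text of the example (from the training split).
#' @param gold_lists named list mapping entity types to ordered character
#'   vectors of gold surface strings; every surface must occur verbatim
#'   (case-insensitively) in `example_text`.
#' @return an object of class `FewShotExample`.
#' @export
few_shot_example <- function(example_text, gold_lists) {
  stopifnot(is.character(example_text), nzchar(example_text))
  gold_lists <- gold_lists[intersect(names(gold_lists), ENTITY_TYPES)]
  lower <- tolower(example_text)
  for (type in names(gold_lists)) {
    for (s in gold_lists[[type]]) {
      if (!grepl(tolower(s), lower, fixed = TRUE)) {
        stop(sprintf("example surface %s does not occur in the example text",
                     dQuote(s)))
      }
    }
  }
  full <- stats::setNames(vector("list", length(ENTITY_TYPES)), ENTITY_TYPES)
  for (type in ENTITY_TYPES) full[[type]] <- as.character(gold_lists[[type]])
  structure(list(example_text = example_text, gold_lists = full),
            class = "FewShotExample")
}

#' Build a few-shot example from a gold-annotated document
#'
#' Surfaces are listed in document order and deduplicated case-insensitively.
#'
#' @param doc a [document()].
#' @param ann the document's gold [annotation_set()].
#' @return a [few_shot_example()].
#' @export
example_from_annotations <- function(doc, ann) {
  lists <- stats::setNames(lapply(ENTITY_TYPES, function(t) character(0)),
                           ENTITY_TYPES)
  for (m in ann$mentions) {  # mentions are kept in start order
    t <- m$entity_type
    if (!tolower(m$surface) %in% tolower(lists[[t]])) {
      lists[[t]] <- c(lists[[t]], m$surface)
    }
  }
  few_shot_example(doc$text, lists)
}

## Render per-type lists as the labeled comma-separated output block.
## Shared by the example block, the gold-echo provider, and tests.
render_entity_lists <- function(lists) {
  paste(vapply(ENTITY_TYPES, function(t) {
    items <- lists[[t]]
    value <- if (length(items) == 0) "none" else paste(items, collapse = ", ")
    paste0(ENTITY_LABELS[[t]], ": ", value)
  }, character(1)), collapse = "\n")
}

render_guidance <- function(spec) {
  defs <- spec$entity_definitions
  if (spec$format == "simple_sentence") {
    woven <- vapply(ENTITY_TYPES, function(t) {
      paste0("a ", ENTITY_LABELS[[t]], " means: ",
             sub("\\.$", "", defs[[t]]))
    }, character(1))
    guidance <- paste0(paste(woven[-4], collapse = "; "), "; and ",
                       woven[4], ".")
    if (spec$include_characteristics) {
      guidance <- paste0(guidance, " As additional guidance: ",
                         paste(unlist(spec$characteristics[ENTITY_TYPES]),
                               collapse = " "))
    }
  } else {
    guidance <- paste(vapply(ENTITY_TYPES, function(t) {
      paste0("- ", ENTITY_LABELS[[t]], ": ", defs[[t]])
    }, character(1)), collapse = "\n")
    if (spec$include_characteristics) {
      guidance <- paste0(
        guidance, "\nDistinguishing characteristics:\n",
        paste(vapply(ENTITY_TYPES, function(t) {
          paste0("* ", ENTITY_LABELS[[t]], ": ", spec$characteristics[[t]])
        }, character(1)), collapse = "\n"))
    }
  }
  guidance
}

#' Assemble a prompt
#'
#' Renders, in order: task instruction, task guidance, output specification,
#' the worked example (few-shot only, in the same labeled-list output
#' format), the target text, and an output-retrieval cue. Rendering is a
#' pure, deterministic function of its arguments.
#'
#' @param spec a [prompt_spec()].
#' @param target_text the text to extract entities from.
#' @param example a [few_shot_example()]; required iff `spec$setting` is
#'   `"few_shot"`.
#' @return the rendered prompt string.
#' @export
build_prompt <- function(spec, target_text, example = NULL) {
  stopifnot(inherits(spec, "PromptSpec"), is.character(target_text),
            nzchar(target_text))
  if (spec$setting == "few_shot" && is.null(example)) {
    stop("few_shot prompts require a worked example")
  }
  if (spec$setting == "zero_shot" && !is.null(example)) {
    stop("zero_shot prompts do not take an example")
  }
  example_block <- ""
  if (!is.null(example)) {
    stopifnot(inherits(example, "FewShotExample"))
    example_block <- paste0(
      "\n\nExample:\nInput text: ", example$example_text, "\nOutput:\n",
      render_entity_lists(example$gold_lists))
  }
  layout <- read_template(paste0(spec$format, ".txt"))
  render_template(layout, list(
    task_instruction = read_template("task_instruction.txt"),
    task_guidance = render_guidance(spec),
    output_specification = spec$output_format_instruction,
    example_block = example_block,
    target_text = target_text,
    output_retrieval = read_template("output_retrieval.txt")))
}

## ---------------------------------------------------------------------------
## Few-shot example selection

#' Select a random training document
#'
#' Uniform over the training ids; deterministic given the seed.
#'
#' @param training_ids non-empty character vector of candidate document ids.
#' @param seed integer seed.
#' @return one document id.
#' @export
select_random_example <- function(training_ids, seed) {
  if (length(training_ids) == 0) stop("empty training set")
  with_seed(seed, sample(training_ids, 1L))
}

#' Select the most similar training document
#'
#' Returns the training document whose text maximizes
#' `scorer(target_text, candidate)`; ties are broken by lexicographically
#' smallest document id.
#'
#' @param training_corpus list of `list(doc =, ann =)` entries (or a list of
#'   [document()]s).
#' @param target_text the test text to match against.
#' @param scorer a `function(a, b) -> numeric`; defaults to
#'   [default_similarity()].
#' @return the selected document id.
#' @export
select_similar_example <- function(training_corpus, target_text,
                                   scorer = default_similarity) {
  if (length(training_corpus) == 0) stop("empty training corpus")
  docs <- lapply(training_corpus, function(e) {
    if (inherits(e, "Document")) e else e$doc
  })
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  scores <- vapply(seq_along(docs), function(i) {
    s <- scorer(target_text, docs[[i]]$text)
    if (!is.finite(s)) {
      stop("similarity scorer returned a non-finite value for candidate ",
           dQuote(ids[i]))
    }
    s
  }, numeric(1))
  ord <- order(-scores, ids)
  ids[ord[1]]
}

#' Bag-of-tokens cosine similarity
#'
#' Term-frequency-weighted cosine between the token multisets of two texts
#' (lower-cased, tokenized with [tokenize()]). A pluggable embedding-based
#' scorer can be substituted anywhere this function is accepted.
#'
#' @param a,b character scalars.
#' @return cosine similarity in \[-1, 1\]; 0 if either text has no tokens.
#' @export
default_similarity <- function(a, b) {
  ta <- table(tolower(tokenize(a)$surface))
  tb <- table(tolower(tokenize(b)$surface))
  if (length(ta) == 0 || length(tb) == 0) return(0)
  vocab <- union(names(ta), names(tb))
  u <- as.numeric(ta[vocab]); u[is.na(u)] <- 0
  v <- as.numeric(tb[vocab]); v[is.na(v)] <- 0
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}
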