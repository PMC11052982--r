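## Running prompts against a completion provider, parsing the labeled
## comma-separated response, and grounding extracted surfaces back to
## character spans in the source document.

#' Completion-provider configuration
#'
#' Temperature defaults to 0 so the provider always returns its most likely
#' completion, which is what makes runs reproducible.
#'
#' @param model_name provider/model identifier (bookkeeping only for the
#'   built-in mock).
#' @param temperature sampling temperature; forced to 0 unless overridden.
#' @param max_retries number of additional attempts after a failed call.
#' @return an object of class `ProviderConfig`.
#' @export
provider_config <- function(model_name = "mock", temperature = 0,
                            max_retries = 2L) {
  stopifnot(temperature >= 0, max_retries >= 0)
  structure(list(model_name = model_name, temperature = temperature,
                 max_retries = as.integer(max_retries)),
            class = "ProviderConfig")
}

#' Generic HTTP completion adapter
#'
#' Returns a provider function that POSTs the prompt to a chat-completion
#' endpoint via the system `curl` binary. Never used by the test suite; it
#' exists so a real hosted model can be plugged in behind the same
#' `function(prompt) -> response` contract as the offline mocks.
#'
#' @param endpoint URL of a chat-completions endpoint.
#' @param api_key bearer token.
#' @param config a [provider_config()].
#' @return a provider `function(prompt)`.
#' @export
http_completion_provider <- function(endpoint, api_key,
                                     config = provider_config("gpt-3.5-turbo")) {
  force(endpoint); force(api_key); force(config)
  function(prompt) {
    body <- jsonlite::toJSON(list(
      model = config$model_name,
      temperature = config$temperature,
      messages = list(list(role = "user", content = prompt))),
      auto_unbox = TRUE)
    out <- system2("curl",
                   c("-sS", "-X", "POST", shQuote(endpoint),
                     "-H", shQuote("Content-Type: application/json"),
                     "-H", shQuote(paste("Authorization: Bearer", api_key)),
                     "-d", shQuote(body)),
                   stdout = TRUE, stderr = TRUE)
    parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                                 simplifyVector = FALSE)
    parsed$choices[[1]]$message$content
  }
}

## ---------------------------------------------------------------------------
## Response parsing

RESPONSE_SENTINELS <- c("none", "n/a", "na", "-", "")

## Strip enclosing quotes and whitespace from a list item.
trim_item <- function(x) {
  x <- trimws(x)
  x <- gsub("^[\"'“”‘’`]+|[\"'“”‘’`.]+$", "", x)
  trimws(x)
}

#' Parse a model completion into per-type surface lists
#'
#' The parser is total: lines matching `<entity type>:` are split on commas,
#' items are trimmed of whitespace and enclosing quotes, and sentinel items
#' (`none`, `n/a`, empty) are dropped; all other non-empty lines accumulate
#' in `unparsed_remainder`.
#'
#' @param response raw completion string.
#' @return object of class `RawExtraction`: list with `lists` (named list of
#'   character vectors, one per entity type) and `unparsed_remainder`.
#' @export
parse_response <- function(response) {
  stopifnot(is.character(response), length(response) == 1L)
  lists <- stats::setNames(lapply(ENTITY_TYPES, function(t) character(0)),
                           ENTITY_TYPES)
  remainder <- character(0)
  lines <- strsplit(response, "\n", fixed = TRUE)[[1]]
  label_re <- "^\\s*[-*•]?\\s*(rare[ _-]?diseases?|diseases?|symptoms?|signs?)\\s*:\\s*(.*)$"
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    m <- regexec(label_re, line, ignore.case = TRUE)[[1]]
    if (m[1] == -1) {
      remainder <- c(remainder, line)
      next
    }
    parts <- regmatches(line, list(m))[[1]]
    type <- normalize_entity_type(parts[2])
    items <- trim_item(strsplit(parts[3], ",", fixed = TRUE)[[1]])
    items <- items[!tolower(items) %in% RESPONSE_SENTINELS]
    lists[[type]] <- c(lists[[type]], items)
  }
  structure(list(lists = lists,
                 unparsed_remainder = paste(remainder, collapse = "\n")),
            class = "RawExtraction")
}

## ---------------------------------------------------------------------------
## Span grounding

#' Ground extracted surfaces to character spans
#'
#' For each extracted surface (by entity type, in list order), searches
#' case-insensitively for the leftmost occurrence in the document text not
#' already consumed by an earlier grounding of the same surface. Surfaces
#' that cannot be located (rephrased or hallucinated output) are kept as
#' ungrounded predictions — they still count toward the predicted total
#' `m-hat` and therefore weigh on precision.
#'
#' @param doc a [document()].
#' @param raw a [parse_response()] result (or a bare named list of per-type
#'   surface vectors).
#' @return object of class `ExtractionResult`: list with `predictions`
#'   (a predicted [annotation_set()]) and `ungrounded` (data.frame of
#'   surface/entity_type rows).
#' @export
ground_mentions <- function(doc, raw) {
  lists <- if (inherits(raw, "RawExtraction")) raw$lists else raw
  lower_text <- tolower(doc$text)
  consumed <- new.env(parent = emptyenv())
  mentions <- list()
  ungrounded <- list()
  for (type in ENTITY_TYPES) {
    for (surface in lists[[type]]) {
      key <- tolower(surface)
      hits <- gregexpr(key, lower_text, fixed = TRUE)[[1]]
      used <- if (!is.null(consumed[[key]])) consumed[[key]] else integer(0)
      hits <- if (hits[1] == -1) integer(0) else setdiff(as.integer(hits), used)
      if (length(hits) > 0) {
        pos <- hits[1]  # leftmost unconsumed occurrence
        consumed[[key]] <- c(used, pos)
        start <- pos - 1L
        end <- start + nchar(surface)
        mentions[[length(mentions) + 1L]] <-
          entity_mention(type, surface = substring(doc$text, start + 1L, end),
                         start = start, end = end)
      } else {
        mentions[[length(mentions) + 1L]] <-
          entity_mention(type, surface = surface)
        ungrounded[[length(ungrounded) + 1L]] <-
          data.frame(surface = surface, entity_type = type,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    predictions = annotation_set(doc$doc_id, mentions, role = "predicted"),
    ungrounded = if (length(ungrounded)) do.call(rbind, ungrounded) else
      data.frame(surface = character(0), entity_type = character(0),
                 stringsAsFactors = FALSE)),
    class = "ExtractionResult")
}

#' Content tokens of a surface after stop-word removal
#'
#' Lower-cases and tokenizes the surface and removes tokens on the packaged
#' stop-word list. If every token is a stop word, the full lower-cased token
#' list is returned unchanged (so that, e.g., a gold mention made only of
#' function words still compares by its own tokens).
#'
#' @param surface character scalar.
#' @return character vector of content tokens (possibly empty for an empty
#'   surface).
#' @export
strip_stopwords <- function(surface) {
  tokens <- tolower(tokenize(surface)$surface)
  kept <- tokens[!tokens %in% .stopword_cache()]
  if (length(kept) == 0) tokens else kept
}

.stopword_env <- new.env(parent = emptyenv())
.stopword_cache <- function() {
  if (is.null(.stopword_env$words)) .stopword_env$words <- stopword_list()
  .stopword_env$words
}

## ---------------------------------------------------------------------------
## Pipeline

## Envelope prefix that carries the target-document id to providers that
## need it (the gold-echo mock); stripped of meaning for real providers.
PROMPT_ENVELOPE_RE <- "^### target-document: (\\S+) ###\n"

envelope_prompt <- function(doc_id, prompt) {
  sprintf("### target-document: %s ###\n%s", doc_id, prompt)
}

envelope_doc_id <- function(prompt) {
  m <- regexec(PROMPT_ENVELOPE_RE, prompt)[[1]]
  if (m[1] == -1) return(NA_character_)
  regmatches(prompt, list(m))[[1]][2]
}

audit_write <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
      sep = "", file = path, append = TRUE)
}

#' Run the extraction pipeline over a corpus
#'
#' For each evaluated document: select a few-shot example if requested,
#' build the prompt, call the provider (with bounded retries), parse the
#' response, and ground the extracted surfaces. Every prompt and every
#' response is appended to a JSON-lines audit log. Deterministic given a
#' deterministic provider and the seed.
#'
#' @param corpus evaluated documents: list of `list(doc =, ann =)` entries
#'   (gold annotations optional; they are not consulted).
#' @param spec a [prompt_spec()].
#' @param provider a `function(prompt) -> response` completion provider.
#' @param training training-split entries for few-shot example selection;
#'   must be disjoint from `corpus` (checked by document id).
#' @param selector `"random"` or `"similar"` (few-shot only).
#' @param seed integer seed driving random example selection; per-document
#'   seeds are derived as `seed + document index`.
#' @param config a [provider_config()].
#' @param audit_path path of the JSON-lines audit log, or `NULL` to skip.
#' @return named list mapping doc_id to [ground_mentions()] results; a
#'   document whose provider calls all failed maps to a list with an
#'   `error` string and an empty prediction set.
#' @export
run_extraction <- function(corpus, spec, provider, training = NULL,
                           selector = c("random", "similar"), seed = 1L,
                           config = provider_config(), audit_path = NULL) {
  selector <- match.arg(selector)
  few_shot <- spec$setting == "few_shot"
  if (few_shot) {
    if (is.null(training) || length(training) == 0) {
      stop("few-shot extraction requires a non-empty training split")
    }
    eval_ids <- vapply(corpus, function(e) e$doc$doc_id, character(1))
    train_ids <- vapply(training, function(e) e$doc$doc_id, character(1))
    clash <- intersect(eval_ids, train_ids)
    if (length(clash) > 0) {
      stop("evaluated set intersects training set: ",
           paste(clash, collapse = ", "))
    }
    train_by_id <- stats::setNames(training, train_ids)
  }
  results <- list()
  for (i in seq_along(corpus)) {
    doc <- corpus[[i]]$doc
    example <- NULL
    if (few_shot) {
      ex_id <- if (selector == "random") {
        select_random_example(sort(names(train_by_id)), seed = seed + i)
      } else {
        select_similar_example(training, doc$text)
      }
      entry <- train_by_id[[ex_id]]
      example <- example_from_annotations(entry$doc, entry$ann)
    }
    prompt <- envelope_prompt(doc$doc_id, build_prompt(spec, doc$text, example))
    audit_write(audit_path, list(doc_id = doc$doc_id, kind = "prompt",
                                 body = prompt,
                                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                                 model_name = config$model_name))
    response <- NULL
    err <- NULL
    for (attempt in seq_len(config$max_retries + 1L)) {
      response <- tryCatch(provider(prompt), error = function(e) {
        err <<- conditionMessage(e)
        NULL
      })
      if (!is.null(response)) break
      if (attempt <= config$max_retries) Sys.sleep(min(0.01 * 2^attempt, 0.1))
    }
    if (is.null(response)) {
      audit_write(audit_path, list(doc_id = doc$doc_id, kind = "response",
                                   body = paste("ERROR:", err),
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                                   model_name = config$model_name))
      results[[doc$doc_id]] <- list(
        predictions = annotation_set(doc$doc_id, role = "predicted"),
        ungrounded = data.frame(surface = character(0),
                                entity_type = character(0)),
        error = err)
      next
    }
    audit_write(audit_path, list(doc_id = doc$doc_id, kind = "response",
                                 body = response,
                                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                                 model_name = config$model_name))
    results[[doc$doc_id]] <- ground_mentions(doc, parse_response(response))
  }
  results
}
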