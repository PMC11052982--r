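#' phenoprompt: prompt-based rare-disease phenotype extraction and evaluation
#'
#' Data model for typed entity spans over plain text (brat standoff, BIO tags),
#' a prompt assembler for zero-/few-shot entity extraction with language
#' models, a total parser and span grounder for model completions, exact and
#' relaxed span-matching metrics with a five-category error taxonomy, and a
#' synthetic corpus generator with controlled error injection.
#'
#' @keywords internal
"_PACKAGE"

## Canonical entity-type vocabulary, in reporting order.
ENTITY_TYPES <- c("rare_disease", "disease", "symptom", "sign")

## Display names used in prompts, model responses and reports.
ENTITY_LABELS <- c(rare_disease = "rare disease", disease = "disease",
                   symptom = "symptom", sign = "sign")

ERROR_CATEGORIES <- c("boundary_only", "type_only", "boundary_and_type",
                      "spurious", "missed")

#' Entity types handled by the package
#'
#' @return Character vector of the four canonical entity-type keys, in
#'   reporting order: `rare_disease`, `disease`, `symptom`, `sign`.
#' @export
entity_types <- function() ENTITY_TYPES

#' Normalize an entity-type label onto the canonical vocabulary
#'
#' Annotation files and model responses use varying spellings
#' (`RAREDISEASE`, `Rare disease`, `rare-disease`, plural forms...). All are
#' folded case-insensitively onto the four canonical keys.
#'
#' @param label character vector of raw labels.
#' @return character vector of canonical keys.
#' @export
normalize_entity_type <- function(label) {
  key <- tolower(trimws(label))
  key <- gsub("[ _-]+", "", key)
  key <- sub("s$", "", key)
  out <- c(raredisease = "rare_disease", disease = "disease",
           symptom = "symptom", sign = "sign")[key]
  if (anyNA(out)) {
    stop("unknown entity type label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

## round() in R is round-half-even; reports here use half-up, matching how
## the reference tables were (mostly) rounded.
#' Round half-up
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-away-from-zero at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Harmonic mean of precision and recall
#'
#' Returns 0 when precision + recall is 0 (the convention used throughout
#' the evaluation module).
#'
#' @param precision,recall numeric scalars or vectors in \[0, 1\].
#' @return F1 value(s), unrounded.
#' @export
harmonic_f1 <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Tiny named-placeholder templating: "{name}" -> values[["name"]].
render_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  leftover <- regmatches(template, gregexpr("\\{[a-z_]+\\}", template))[[1]]
  if (length(leftover) > 0) {
    stop("unfilled template placeholder(s): ", paste(leftover, collapse = ", "))
  }
  template
}

#' Stop-word list shipped with the package
#'
#' A fixed, versioned English stop-word list (Snowball-style). Pinning the
#' list keeps exact-match scores reproducible across installations.
#'
#' @return character vector of lower-case stop words.
#' @export
stopword_list <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "phenoprompt")
  if (!nzchar(path)) stop("packaged stop-word list not found")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}
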