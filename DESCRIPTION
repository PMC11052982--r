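Package: phenoprompt
Title: Prompt-Based Extraction and Evaluation of Rare-Disease Phenotype Mentions
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying and extracting rare diseases and their
    phenotypes (diseases, symptoms, signs) from free text with instruction
    prompts for large language models, and for scoring the results. Includes
    a brat standoff reader/writer, a BIO tag codec, corpus statistics and
    deterministic dataset splitting; a prompt assembler for zero- and few-shot
    settings with random or similarity-based example selection; a total parser
    for labelled comma-separated model completions with span grounding back to
    the source text; exact and relaxed span matching with micro-averaged
    precision, recall and F1; a five-category error taxonomy (boundary, type,
    boundary+type, spurious, missed); a synthetic corpus generator with
    measure-exact error injection for offline testing; and a command-line
    interface composing the pieces into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
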