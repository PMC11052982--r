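# phenoprompt

Rare-disease phenotypes — the diseases, symptoms, and signs that characterize
a condition — are mostly locked up in free text, and annotated corpora for
training extraction models are expensive to build. One way around the
annotation bottleneck is to reformulate named entity recognition (NER) as a
text-generation task: prompt a large language model to list the entities it
finds, with zero or one worked example, and score the listed surface strings
against gold character-offset annotations.

`phenoprompt` is an R toolkit for that workflow. It targets corpora annotated
with four overlapping entity types — **rare disease**, **disease**,
**symptom**, **sign** — in the brat standoff format (a `.txt` file per
document plus a `.ann` file of typed character spans), and provides every
piece needed to run and audit a prompt-based extraction study offline:

* **Corpus model** — brat standoff reading/writing, a BIO tag codec
  (`B-t`/`I-t`/`O` per token), per-type corpus statistics, and a
  deterministic 8:1:1 train/validation/test split.
* **Prompt engine** — prompts assembled from five building blocks (task
  instruction, task guidance with entity definitions and optional
  distinguishing characteristics, output specification, a worked few-shot
  example, output retrieval), in a conversational *simple sentence* or a
  numbered *structured list* layout; few-shot examples chosen at random or
  as the most similar training text (term-frequency cosine by default, any
  scorer pluggable).
* **Extraction** — a total parser for labeled comma-separated completions
  (`rare disease: Keratomalacia, ...`), leftmost-unconsumed case-insensitive
  grounding of each extracted surface back to character spans, and a
  pipeline driver with bounded retries, a JSON-lines audit log, and a
  temperature-0 provider contract (offline mocks ship with the package).
* **Evaluation** — one-to-one matching under **exact** (same boundaries
  after stop-word trimming, same type) and **relaxed** (overlapping spans,
  same type) criteria; micro-averaged precision/recall/F1
  (F1 = 2PR/(P+R)) per type and overall; and a five-category error
  taxonomy: wrong boundary, wrong type, wrong boundary **and** type,
  spurious (false positive), missed (false negative).
* **Synthetic fixtures** — a generator for corpora with a realistic
  per-type count profile and known gold offsets, plus a measure-exact error
  injector whose corruptions are recovered category-for-category by the
  evaluator, so the whole pipeline is testable without any network access.

## Worked example

```r
library(phenoprompt)

# a gold-annotated document in brat standoff
pair <- parse_brat(
  "Keratomalacia is a cause of corneal scarring.",
  "T1\tRAREDISEASE 0 13\tKeratomalacia\nT2\tSIGN 28 44\tcorneal scarring",
  doc_id = "fig1")

# generate a synthetic corpus, run the gold-echo mock end to end
corpus <- generate_corpus(generator_config(n_docs = 200, seed = 7))
res <- run_extraction(corpus, prompt_spec("zero_shot", "simple_sentence"),
                      gold_echo_provider(corpus), seed = 1)
report <- evaluate_predictions(corpus, res)
report[report$entity == "overall", ]
#>       mode  entity precision recall f1 n_correct    m m_hat
#> 5    exact overall         1      1  1      2364 2364  2364
#> 10 relaxed overall         1      1  1      2364 2364  2364

# corrupt gold with exactly known error counts and recover them
inj <- inject_errors(corpus, error_injection_config(
  boundary_only = 5, type_only = 3, spurious = 2, missed = 4, seed = 11))
table(classify_corpus_errors(corpus, inj$predictions)$category)
#> boundary_only   missed   spurious   type_only
#>             5        4          2           3
```

A perfect provider gives precision = recall = F1 = 1 in both match modes
(2,364 mentions recovered from 2,364 gold); the injector's corruption counts
come back exactly from the error classifier — that pair of identities is
what certifies the scoring machinery.

The same flow is scriptable:

```sh
phenoprompt gen-fixtures --out corpus/ --n-docs 200 --seed 7
phenoprompt stats --corpus corpus/
phenoprompt extract --corpus corpus/ --out run/ --provider mock --seed 1
phenoprompt evaluate --corpus corpus/ --pred run/predictions --mode exact --mode relaxed
phenoprompt errors --corpus corpus/ --pred run/predictions
```

(`phenoprompt` is the launcher installed from `exec/`; equivalently
`Rscript -e 'phenoprompt::pheno_cli(commandArgs(TRUE))' ...`.)

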