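---
title: "Scoring and simulation methods in phenoprompt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulation methods in phenoprompt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprompt)
```

# The task and its data model

`phenoprompt` treats named entity recognition over rare-disease text as a
comparison between two label vectors per document: the gold annotation
$Y = \{y_1, \ldots, y_m\}$ and a prediction
$\hat{Y} = \{\hat{y}_1, \ldots, \hat{y}_{\hat m}\}$, where each element is a
typed character span $(\text{start}, \text{end}, t)$ with
$t \in \{\text{rare disease}, \text{disease}, \text{symptom}, \text{sign}\}$.
Offsets are 0-based and end-exclusive throughout, the convention of brat
standoff `.ann` files, so parsed annotations are bit-compatible with their
source files; token-index conventions used elsewhere are mapped to character
offsets at the tokenizer boundary. Discontinuous brat fragments
(`start end;start end`) are parsed and preserved; the BIO codec, which
cannot express them, rejects them in strict mode rather than corrupting
counts silently.

The four types overlap semantically — rare diseases are a subset of
diseases, and the symptom/sign distinction is only whether the finding is
subjective to the patient (symptom) or observable/measurable (sign) — which
is exactly why the evaluation needs a type-confusion error category and why
prompts carry per-type definitions.

# Matching and metrics

**Pairwise criteria.** A predicted mention matches a gold mention *exactly*
when the types agree, the stop-word-stripped content-token sequences of the
two surfaces agree, and the spans coincide after trimming leading/trailing
stop-word tokens. It matches under the *relaxed* criterion when the types
agree and the character sets covered by the fragments intersect. The
stop-word handling implements the convention of removing stop words from
both gold and predicted entities before comparison; whether the original
evaluation trimmed spans or only token sequences is not fully specified, so
the trimmed-span rule here is a documented package convention. The stop-word
list itself is a fixed resource shipped with the package
(`inst/extdata/stopwords.txt`): pinning it is what makes exact-match scores
reproducible across installations. If a surface consists only of stop words,
its own token list is used unchanged rather than comparing empty sequences.

**Assignment.** The pairwise criteria say when a pair matches, not which
pairs to count; counting needs a one-to-one assignment, otherwise one
prediction could satisfy several gold mentions. The assignment is
exact-first: all exact pairs are matched, then (relaxed mode) remaining
mentions are paired along type-matching overlap edges, preferring larger
character overlap with ties broken by earliest gold start and lowest
predicted index. A greedy pass alone is only a *maximal* matching — on
crossing-overlap configurations it can strand pairs a different choice
would have saved — so the greedy result is completed with augmenting paths
(Kuhn's algorithm). Augmentation never unmatches a matched mention (Berge's
lemma), so the exact-first discipline survives and the final cardinality
equals the maximum bipartite matching; the test suite checks this against a
brute-force enumeration oracle on over a thousand random micro-instances.
Because the relaxed edge set contains every exact edge, relaxed
`n_correct` is never below exact `n_correct`, which yields the
exact ≤ relaxed monotonicity of all derived metrics.

**Metrics.** Precision is `n_correct / m_hat` (0 when nothing is
predicted), recall `n_correct / m` (0 when there is no gold), F1 the
harmonic mean (0 when both are 0). Aggregation is **micro**: counts are
summed over the pooled test documents before dividing, per type (both sets
restricted to the type before matching) and overall (all four types
pooled). Micro vs macro is not stated in the source benchmark; micro
matches the standard "overall" row convention in NER evaluation and is
therefore used for every row. Ratios are reported rounded half-up to 3
decimals — plain `round()` in R is half-even, which would disagree with
several published cells.

**Ungrounded predictions.** A surface the model emitted but that cannot be
located verbatim in the document (a rephrase or hallucination) is kept as an
ungrounded prediction: it counts toward $\hat m$ and can never match any
gold mention, so it surfaces as a spurious error. The extraction prompt
explicitly demands exact names precisely to avoid these, so penalizing them
matches the metric's intent.

# The five-way error taxonomy

Disagreements are classified from the exact assignment extended with an
overlap-association pass (one-to-one, decreasing overlap, any type, again
completed to maximum cardinality but with exact pairs frozen):

| category | condition |
|---|---|
| `boundary_only` | associated pair, same type, different boundaries |
| `type_only` | associated pair, same boundaries, different type |
| `boundary_and_type` | associated pair, both different |
| `spurious` | prediction associated with no gold (false positive) |
| `missed` | gold associated with no prediction (false negative) |

Freezing the exact pairs during association matters: re-pairing an
exact-correct mention onto a merely-overlapping partner would double-count
it as both correct and erroneous. With the frozen scheme the partition
identities hold per document —
`exact_correct + boundary + type + both + spurious = m_hat` and the same
with `missed` and `m` — and the test suite asserts them on random
instances. Records are attributed to the gold mention's type whenever a
gold mention participates (else the predicted type): the published error
table is organized by entity, and gold-side attribution keeps
`missed + matched` consistent with $m$. Percentages in the tabulated report
are integers, half-up, over each type's error total; raw counts are always
printed alongside because half-up rounding cannot reproduce every published
percentage cell (three cells in the reference table are inconsistent with
any single rounding rule applied to their printed counts), so counts, not
percentages, are the stable quantity.

# Prompt construction

Prompts are assembled from five building blocks — task instruction
(extract *exact* names, no rephrasing), task guidance (the four entity
definitions, optionally per-type distinguishing characteristics), output
specification, a worked example (few-shot only), and an output-retrieval
cue — in two layouts: a conversational *simple sentence* paragraph and a
numbered *structured list*. The source material describes the blocks
schematically rather than printing full prompt wordings, so the connective
text here is authored, stored as versioned template resources under
`inst/templates/` with named placeholders; the distinguishing-characteristic
sentences are embedded as printed.

The output contract is one line per type,
`<entity type>: <name>, <name>, ...`, with sentinel `none` for an empty
list. A bare comma-separated list without per-type labels could not recover
the predicted type $\hat t_k$, so per-type labeling is required by the
evaluation even though the source only specifies "a list separated by
commas". The response parser is total: labeled lines are split on commas
and trimmed, sentinels dropped, and anything else accumulates in an
`unparsed_remainder` field rather than failing — real model output contains
chatter.

Few-shot examples render the gold surfaces of a training document in
document order, deduplicated case-insensitively (document order is
reproducible; whether the original study deduplicated is unknown). Example
selection is either uniform random or argmax of a similarity scorer with
ties to the lexicographically smallest document id. The default scorer is
term-frequency bag-of-tokens cosine; the original used pre-trained word
embeddings, an external asset, so the scorer is a *contract* — the argmax
selection logic is what the method defines, and an embedding backend plugs
in behind the same `function(a, b)` signature. In pipeline runs the random
selector draws per evaluated document with a seed derived as
`run seed + document index`; the alternative (one example reused across the
test set) is equally defensible but less informative in tests.

The provider is likewise a contract: `function(prompt) -> string`, with
temperature fixed at 0 by default for reproducibility, bounded
exponential-backoff retries, and a JSON-lines audit log recording every
prompt and response. The test suite never touches a network; the shipped
providers are offline mocks, and the generic HTTP adapter exists only for
real use.

# The synthetic world

`generate_corpus()` emulates the corpus profile the method was developed
against: multi-sentence disease descriptions with per-document entity
counts drawn per type from truncated Poisson distributions. The default
means are the published per-text means — rare disease 4.88, disease 2.18,
symptom 0.38, sign 3.98 — and the default fixture size is 200 documents.
Poisson is a choice, not a given: the source reports only means and SDs
(and its SDs exceed a Poisson's, reflecting real-document burstiness), but
count recovery, not distributional realism, is what the fixtures must
support. Each mention fills a one-placeholder sentence template at a known
position, so gold offsets are recorded at construction and never
re-searched; two entity-free filler sentences per document host the
distractor phrases used for spurious injection. The default vocabularies
are validated to be substring-free — across entries and against template
filler — so that leftmost-substring grounding on synthetic text is
unambiguous; repeated surface forms within a document, which the grounding
must handle via its leftmost-unconsumed discipline, still arise naturally
from sampling with replacement.

What a green identity test establishes is therefore: the prompt envelope,
response parsing, grounding, matching, and aggregation compose to the
identity on text whose surface forms are unambiguous by construction. It
does **not** establish robustness to real prose — nested or discontinuous
mentions, surfaces that are substrings of one another, inconsistent
annotation — and no synthetic result here says anything about any actual
language model's accuracy.

`inject_errors()` is the constructive inverse of the taxonomy: boundary
edits move a gold span by whole tokens (never mid-token, so corrupted
mentions stay tokenizable) and are rejected if the edit is neutralized by
stop-word trimming or collides with another gold mention; type swaps keep
the span; spurious mentions are placed on distractor phrases that can never
overlap gold; missed deletes. Each gold mention is consumed at most once.
That makes injection *measure-exact* — `classify_errors()` returns exactly
the configured category counts — which is the package's parameter-recovery
test and the reason the taxonomy's edge cases are trustworthy.

# Numerical and degenerate-input conventions

* Rounding in reports is half-up (`round_half_up()`): 2 decimals for corpus
  statistics, 3 for metrics, integer percentages for error tables.
* Standard deviation in corpus statistics defaults to the sample flavor
  (n−1), with a population option; the reference table does not state which
  it used, and two of its mean cells are inconsistent with half-up rounding
  of total/n in either case, so tests assert only the arithmetically stable
  cells.
* Dataset splitting takes `floor(ratio × N)` for validation and test and
  gives the remainder to train (832 documents at 8:1:1 → 666/83/83),
  shuffled under an explicit seed and restored-RNG discipline, so a split
  never perturbs the caller's RNG state.
* Empty corpus → error; empty annotation file → empty gold set; empty model
  response → zero predictions with the document still present in results;
  `m_hat = 0` → precision 0; `precision + recall = 0` → F1 0.
* All randomness (generation, injection, selection, splitting) flows
  through explicit integer seeds; identical seeds give byte-identical
  artifacts.

# Known limitations

* The grounding is exact-substring; a model paraphrase as small as a
  pluralization becomes an ungrounded (spurious) prediction by design.
* Exact matching of discontinuous mentions requires identical fragment
  lists, and relaxed overlap uses the union of fragments — a natural but
  unvalidated extension of the span criteria to brat fragment syntax.
* The published headline benchmark scores (overall relaxed F1 of 0.689
  fine-tuned vs 0.472/0.610 prompted) are not reproducible here: they
  require the full annotated corpus and a proprietary hosted model. The
  package reproduces the *arithmetic* of those tables and the *behavioral
  contracts* of the pipeline, which is what can be verified offline.
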