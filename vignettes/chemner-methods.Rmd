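---
title: "Recognizing chemical mentions with tag schemes, fine-grained tokenization and linear-chain CRFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing chemical mentions with tag schemes, fine-grained tokenization and linear-chain CRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical compounds and drugs are named in wildly heterogeneous ways:
systematic IUPAC-style names with locant lists ("2,4-dinitrophenyl"),
trivial and brand names ("Tylenol"), molecular formulas ("H2SO4"), database
identifiers ("CHEBI:28262"), family names ("alcohols"), abbreviations
("DMS"), and conjoined multi-chemical fragments ("alcohols/esters").
`chemner` implements a complete, testable pipeline for recognizing such
mentions in titles and abstracts: offset-preserving tokenization at two
granularities, four ways of encoding entity spans as per-token tags, a
battery of surface features, a linear-chain conditional random field (CRF),
and the two standard evaluation views — exact-span mention recognition (CEM)
and per-document entity indexing (CDI).

The package's particular focus is the interaction between **tokenization
granularity** and **tag-scheme expressiveness**: finer tokens turn one
multi-symbol chemical name into many tokens, which changes how much the tag
scheme (does it mark entity ends? single-token entities? the second token?)
matters for finding exact boundaries.

```{r, eval = FALSE}
library(chemner)
corpus <- generate_corpus(generator_config(n_docs = 100, seed = 1))
fit <- chemner_fit(corpus$documents, corpus$mentions,
  scheme = "IOBES", tokenizer = "fine"
)
predict(fit, corpus$documents, threshold = 0.5)
```

## Tokenization

All offsets in the package are 0-based, half-open `[start, end)`, so spans
are closed under concatenation and a token's text is always
`substr(section, start + 1, end)`. Input files may use 1-based offsets via
the `offset_base` flag of the readers and writers, since corpora in the wild
do not agree on a convention.

**Sentence splitting** is deliberately simple and rule-based: a boundary
after `.`, `!` or `?` followed by whitespace and an uppercase letter or
digit, guarded by an abbreviation list ("e.g.", "Fig.", ...) and by
single-capital initials. The guard list is a plain text file users can
extend. No pretrained splitter is involved, which keeps the pipeline fully
deterministic and dependency-free.

**Coarse tokenization** follows Penn-Treebank-style conventions:
whitespace-delimited chunks, punctuation detached at chunk edges, a
sentence-final period detached, commas detached unless flanked by digits on
both sides (so "1,000" and the locant list in "2,4-dinitrophenyl" survive),
and contractions and genitives split into their morphemes ("won't" →
"wo" + "n't"). Two deliberate deviations from the full PTB sed script:
quote conversion to `` `` ''`` is disabled (it would destroy offsets), and
brackets are detached only at chunk edges rather than everywhere. The
latter matters for chemistry: "(PAHs)" becomes `(`, `PAHs`, `)` but
"benzo(a)pyrene" and "Na(2)CO(3)" remain single coarse tokens, which is the
behaviour the rest of the pipeline (notably word shapes) assumes.

**Fine-grained tokenization** re-segments each coarse token: every symbol —
any character that is neither a Unicode letter nor a digit — becomes a
standalone token, and splits are inserted between letters and digits (both
directions) and at lowercase→uppercase transitions. Greek letters count as
letters, so "α-phenyl-N-tert-butyl nitrone" yields ten tokens with "α"
intact. Symbols are kept, never deleted, which makes the segmentation
lossless: concatenating the tokens of a sentence and removing whitespace
reproduces the sentence. Uppercase→lowercase transitions are *not* split,
so "CO" stays whole while "DrugBank" splits. Letter/digit splitting is
applied in both directions; the narrower reading (digits only after
letters) would leave "204636a"-style tokens intact, and the symmetric rule
is both simpler and consistent with all the reference examples, so it is
the default and the package has no option to change it.

Fine tokens always nest inside coarse tokens, and fine tokenization is
idempotent; both properties are enforced by randomized tests.

## Tag schemes

Four inventories over the seven mention categories are supported, each
`|prefixes| × 7 + 1` tags:

| scheme  | prefixes        | 1-token entity | 2-token entity | ≥3 tokens        |
|---------|-----------------|----------------|----------------|------------------|
| IOB     | B, I            | B              | B I            | B I … I          |
| IOBE    | B, I, E         | B              | B E            | B I … E          |
| IOBES   | B, I, E, S      | S              | B E            | B I … E          |
| IOB12E  | B1, B2, I, E    | B1             | B1 E (default) | B1 B2 I … E      |

Two underdetermined corners were resolved as package decisions. First,
IOBE has no single-token tag, so single-token entities take `B`: `B` marks
entity onset and `E` is reserved for multi-token ends. Second, a two-token
entity under IOB12E puts the scheme's two claims — "second token" (`B2`)
and "last token" (`E`) — in direct conflict on the same token; the package
defaults to `B1 E`, keeping the entity terminator explicit, and exposes
`iob12e_two_token = "B1B2"` so the alternative is one flag away.

Decoding is **repair-based** and total: any tag sequence a model can emit
decodes without error. An inside/end/second-begin tag without a matching
open entity opens one; a category change or `O` closes the open entity;
`S` is always a singleton. This conservative span-opening maximizes recall
compared with discarding ill-formed runs, and it means the CRF needs no
hard transition constraints at decode time. Round-trip (encode then
decode) and cross-scheme conversion identities hold exactly and are tested
on randomized sentences.

Gold mentions whose character boundaries cut through a token (possible
under coarse tokenization, e.g. gold "octadecanol" inside the coarse token
"octadecanol-covered") are flagged; the default policy expands them to the
covering tokens, and a `drop` policy is available. Discontinuous
(MULTIPLE-category) mentions are aligned as their full covering span;
nested or truly discontinuous encoding is out of scope.

## Features

Per token the extractor emits:

* **word/context**: digit-run-normalized unigrams in a ±2 window, plus all
  contiguous bigram and trigram conjunctions inside that window, with
  `__BOS__`/`__EOS__` sentinels. Digit runs are collapsed to `1`
  ("cyclooxygenase-2" → "cyclooxygenase-1") so numbered homologues share a
  vocabulary entry.
* **affixes**: prefixes and suffixes of 3–5 characters (capped at the token
  length), computed on the normalized form.
* **orthographic patterns**: 18 named regular expressions (locant lists,
  capitalization mixes, alphanumeric mixes, Roman numerals, dashes,
  punctuation, quotes) applied as binary features. The patterns are kept
  exactly as designed, including the `[A-z]` character ranges that
  technically admit a few ASCII punctuation characters; fidelity beats
  intuitive correction here, and `strict_az = FALSE` substitutes
  `[A-Za-z]` for users who want the corrected behaviour.
* **word shapes**: uppercase→`A`, lowercase→`a`, digit→`0`, everything
  else→`_`, plus the run-collapsed variant ("Aaaaa_A" → "Aa_A"). Both raw
  and collapsed shapes are emitted. The digit symbol is configurable
  (`shape_digit = "1"` reproduces a digit-normalized rendering seen in some
  descriptions of this feature); the default follows the rule as stated,
  `0`.
* **syntax**: POS identity features in a ±2 window (a five-tag window) and
  the current chunk tag, when a POS/chunk sidecar is attached. The provider
  is an interface: annotations come from the corpus, from the synthetic
  generator's templates, or from any external tagger — the package does not
  bundle one, and without annotations the family is simply omitted and the
  model degrades gracefully.
* a constant bias feature.

"All contiguous n-grams inside the ±2 window" means 4 bigrams and 3
trigrams per position at the window edges' maximum; positions near sentence
boundaries emit fewer via sentinels. Feature extraction is deterministic
and position-local (editing a token outside the window of position *i*
never changes vector *i*), both property-tested.

## The CRF

The model is a standard first-order linear-chain CRF: the probability of a
tag sequence \(Y\) given the token sequence \(W\) is

\[
p_\lambda(Y \mid W) \;=\; \frac{1}{Z(W)} \exp \sum_{c} \Big( \sum_i \lambda_i f_i(y_{c-1}, y_c, W, c) \Big),
\]

with \(Z(W)\) summing the exponentiated scores over all tag sequences.
Observation features are conjoined with the *current* tag only; tag-pair
indicators form the transition part. Training maximizes the
L2-regularized conditional log-likelihood (Gaussian prior, default
\(\sigma^2 = 1\)) with L-BFGS-B to a projected-gradient tolerance of 1e-4
or 200 iterations; no CRF library is wrapped — forward–backward, Viterbi,
the analytic gradient and a constrained-path forward pass are implemented
in C++ under `src/`. All recursions run in log space; the inner sums over
previous tags use a max-shifted product with the exponentiated transition
matrix, which is algebraically identical to logsumexp but much cheaper.
Correctness is established against an independent oracle: exhaustive path
enumeration on toy instances (≤4 positions × ≤5 tags), where marginals,
path probabilities and Viterbi paths must agree to 1e-8, and the analytic
gradient must match central finite differences to 1e-5.

Viterbi ties break by lexicographic tag order (the inventory is sorted, and
the argmax keeps the lowest index). Training is deterministic for fixed
data and data order; models serialize to a versioned JSON file with weights
printed at full precision (`%.17g`), so a write/read round trip is exact.

**Entity confidence.** The pipeline needs a per-mention confidence for the
0.5 selection threshold and for CDI ranking, but "confidence" is not a
uniquely defined object for a span. The default is the product of the
per-position posterior marginals of the decoded tags over the mention's
tokens — cheap, monotone in the per-token certainty, and slightly
pessimistic because it ignores the tags' dependence. The exact alternative
(`confidence = "exact"`) computes the true probability mass of all paths
agreeing with the decoded tags on the mention's positions via a constrained
forward pass; tests quantify that both agree with enumeration on toy
models. The threshold default of 0.5 is the conventional operating point
for this selection step.

## Evaluation

CEM matching is exact on `(doc_id, section, start, end)` and category-blind
for the overall score; duplicated predictions of one span count once, the
surplus as false positives. CDI compares per-document sets of exact entity
strings (no case folding). Micro scores follow
\(R = TP/(TP+FN)\), \(P = TP/(TP+FP)\), \(F_1 = 2PR/(P+R)\), with any 0/0
defined as 0 and such degenerate categories flagged in the report, so an
empty category visibly rather than silently drags the macro average.
Category-pivoted scoring filters the gold annotations per category and
scores the predictions of that category against them; macro P and R are
unweighted means over the seven categories, and macro-F defaults to the
harmonic mean of macro-P and macro-R (a `mean_f` variant averages the
per-category F1 instead).

CDI conversion removes duplicate entity strings per document keeping the
*maximum* confidence among duplicates (the strongest evidence should rank
the entity), sorts by descending confidence with lexicographic text
tie-breaks, and assigns consecutive ranks — so prediction files are
byte-stable across runs.

`paired_resample_test()` compares two trainable systems: it draws bootstrap
training and development sets (sampling documents **with replacement** at
the configured sizes — resampling "according to the size" of the original
splits is ambiguous between bootstrap and subsampling, and bootstrap is the
choice here), trains both systems per resample, and applies a two-sided
paired t-test to the development F-scores. Two identical deterministic
systems produce zero-variance differences, where the t statistic is
undefined; the package reports p = 1 for that degenerate null case.

## The synthetic corpus generator

Real chemistry corpora cannot ship with a package, so `generate_corpus()`
builds one with known gold offsets: documents assembled from sentence
templates (each with POS/chunk tags per template word, emitted as a
sidecar), with chemical-like names spliced into entity slots. Name
grammars per category: morpheme-based systematic names with digit locant
lists, multipliers, stems and suffixes; element-symbol/count formulas;
database-prefix identifiers; short uppercase abbreviations; word-list
trivial and family names; slash-conjoined "multiple" mentions. Every
constructor produces a surface with an exact, known fine-token count.

Two marginals are configurable: the **category mix** (default: roughly the
proportions seen in chemistry abstracts — systematic and trivial names
dominant at about 28% and 26%, abbreviations and families around 15%,
formulas 10%, identifiers and multiples rare) and the **entity length
distribution** over fine-token lengths 1–8 (default heavily single-token
skewed: 70.9%, 9.2%, 6.2%, 4.4%, remainder over lengths 5–8 — the length
profile typical of chemical corpora after fine tokenization). Not every
category can realize every length (an abbreviation is always one token, an
identifier two or three), so the generator fits the joint
category × length table to both marginals by iterative proportional
fitting over the feasibility mask and samples mentions from that joint;
for corpora of 500+ documents the realized marginals track the configured
ones within a few percent (tested at ±3%).

A 5% **ambiguity rate** (configurable) fills some non-entity slots with
entity-like surfaces that carry no gold annotation, so the learning problem
is not trivially "tag everything that looks chemical". The generator is
fully seeded: one seed makes the corpus byte-identical across runs.

What the generator does *not* emulate — and hence what passing tests do and
do not show: real lexical diversity (vocabulary is a few hundred stems, so
train and test share surface forms far more than real corpora do), real
syntactic variety (a dozen templates), annotation noise, and truly
discontinuous MULTIPLE mentions. The end-to-end separability check (CEM
F ≥ 0.8 after training on 600 generated documents and scoring 200 held-out
ones, IOBES + fine tokenization) is therefore a correctness guarantee of
the pipeline plumbing — features reach the model, spans survive the
round trip, confidences are calibrated enough for thresholding — not a
claim about performance on real abstracts, which depends on corpus
statistics this generator deliberately does not reproduce.

## Problem sizes and numerical choices

The test suite exercises: 10,000 random strings for the tokenization
losslessness/nesting properties; 1,000 random sentences across all four
schemes for encode/decode round trips; 200 enumeration-oracle CRF
instances; an 800-document synthetic corpus (600 train / 200 held-out,
L-BFGS capped at 100 iterations) for end-to-end recovery; and an
80-document corpus with 40/20 bootstrap resamples, 30 of them, L-BFGS
capped at 30 iterations, for the corruption-detection significance check.
These sizes were chosen so the whole suite runs comfortably on a single
CPU while keeping every check at its intended statistical strength.

Other fixed choices: marginal rows are normalized to 1 within 1e-9;
CEM ranking ties break by ascending (section, start, end) with title
before abstract; CDI ties break by text; `optim`'s L-BFGS-B is the
quasi-Newton batch optimizer behind training, with `factr = 1e7`. Empty
inputs (empty corpora, sentences, mention lists) are all defined and
return empty results rather than erroring.

## Limitations

* The sentence splitter and coarse tokenizer are rule subsets, not
  reimplementations of any specific external tool; corpora tokenized by
  other tools will disagree on edge cases (the `offset_base` flag and the
  boundary-crossing alignment policies exist to absorb some of this).
* POS/chunk features are only as good as the sidecar supplied; the package
  ships no tagger.
* The CRF is first-order with observation features on the current tag
  only; higher-order dependencies and feature/transition conjunctions are
  out of scope.
* Confidence calibration is not studied beyond the two definitions offered;
  the 0.5 threshold is a convention, not a fitted operating point.
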