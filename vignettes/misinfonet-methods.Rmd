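---
title: "Methods: classifying trustworthy versus misinformation health content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying trustworthy versus misinformation health content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misinfonet)
```

## The problem

Short health-related social-media posts must be sorted into two classes:
*trustworthy information* and *misinformation* (the positive class of the
binary task). Two features of this setting drive the package's design.
First, labeled data comes from many fact-checking datasets with
incompatible verdict vocabularies, so labels must be harmonized before
pooling. Second, verified trustworthy content is scarce relative to
misinformation, so the training data is strongly imbalanced and the
minority class is *augmented*: unlabeled candidate documents that are
sufficiently similar to verified trustworthy documents are injected into
the trustworthy class, with the similarity threshold calibrated for
precision on a small verified sample.

The package implements the full pipeline — ingestion, cleaning, embedding,
calibration and augmentation, a four-pathway 2-D convolutional classifier
with six comparison models, and the evaluation protocol — driven by a
synthetic tweet-corpus generator so that every stage runs and is tested
without downloading any data.

## Label harmonization

Each source dataset ships a label map (YAML under
`system.file("extdata", "labelmaps", package = "misinfonet")`) with two
disjoint sets of source verdicts: those counted as trustworthy (e.g.
"Correct", "Mostly true", "True") and those counted as misinformation
(e.g. "Fake", "Scam", "Misleading/False"). Matching is case-insensitive
after trimming and collapsing whitespace, because the same verdict appears
in multiple capitalizations across datasets. Verdicts in neither set
("Pants on fire", "Unproven", "Mixture", ...) map to *unlabeled*: the
document is kept but excluded from supervised use, which mirrors the
practice of extracting only labels with clear polarity. Maps are config
data rather than code constants because the source datasets evolve.

## Cleaning

`clean_text()` applies a fixed cascade: URL and @-mention removal,
lowercasing, punctuation replaced by a space, character-wise digit
removal, whitespace tokenization, stop-word removal, and removal of
single-character tokens. Replacing punctuation by a space (rather than
deleting it in place) preserves word boundaries, so "covid-19" contributes
the token "covid" rather than "covid19", and a hashtag keeps its word
body. Digit stripping is character-wise, removing embedded digits as well
as purely numeric tokens; what survives of "5G!!" is a single character,
which the last rule drops. The cascade is idempotent, and duplicates are
detected on cleaned text with the first occurrence retained. The shipped
stop-word list is a standard English list (one word per line, overridable);
because stop-word filtering runs after punctuation removal, contracted
forms appear in it as their apostrophe-split parts.

## Embedding matrices

Each document becomes a fixed-shape `max_tokens x dims` matrix (default
100 x 100): row *i* holds the word vector of token *i*, rows beyond the
document's length are zero, and tokens beyond the budget are ignored.
Out-of-vocabulary words also map to the zero vector — zero is the neutral
element of the convolution sums, so padding and unknown words are
indistinguishable to the model, which is the intended behavior for short,
noisy texts. Pre-trained vectors in the GloVe/word2vec plain-text dialect
load via `load_vectors()` (header-tolerant); the default geometry of 100
dimensions deliberately reduces TextConvoNet's original 300-dimension
recommendation, keeping the input plane square and desk-scale friendly;
both are configurable.

For download-free operation the default embedder is `hash_provider()`:
every word hashes (FNV-1a mixed with a seed) to a deterministic unit-norm
Gaussian direction. The same word and seed give bit-identical vectors on
any machine. Hash embeddings carry no semantic similarity between
different words — two related words are as orthogonal as two unrelated
ones — which is adequate for the synthetic corpora (where class signal is
purely lexical) but is one reason synthetic results do not transfer to
claims about real tweets.

## Similarity, calibration, and augmentation

Documents are represented for similarity as smoothed TF-IDF vectors over
cleaned unigrams (`idf = log((1 + N)/(1 + df)) + 1`, strictly positive),
the standard sparse representation for short text; the embedding matrices
above are tied to the network, not to this step. With nonnegative weights
the cosine lies in [0, 1]. A candidate's score against the verified
trustworthy seed set is its *maximum* cosine over the seeds — a
nearest-trustworthy-example criterion (mean aggregation is available).
When the verified documents are scored for calibration, a trustworthy seed
is compared against the *other* seeds (leave-one-out), since its
self-similarity of 1 would inflate the calibration.

`calibrate_threshold()` tallies, for each candidate threshold, how many
verified trustworthy (`true_count`) and verified misinformation
(`false_count`) documents score strictly above it; the precision
`true/(true + false)` is the fraction of would-be injected documents that
are verified trustworthy. Precision is undefined — reported `NA`, never 0 —
where nothing exceeds the threshold. The chosen threshold maximizes
precision, with ties broken toward the larger injected count (favoring
augmentation volume at equal purity), subject to a configurable minimum
injected count. The default grid is 0.10–0.40 in steps of 0.05. Injection
is strict ("over" the threshold): a candidate scoring exactly the
threshold is not injected. Injected documents are appended with label
`trustworthy` and a provenance flag `injected = TRUE`; pre-existing
documents are never altered, and id collisions are skipped, not
duplicated.

One deliberate hygiene rule: the pipeline injects into the *training
portion only*, after the held-out test set has been split off. Augmenting
the evaluation data as well would contaminate the test labels with the
augmentation's own errors, making the measured performance partly an
artifact of the injection step.

## The convolutional classifier

The classifier consumes the single-channel embedding plane through four
parallel convolutional pathways. Kernel shapes (defaults): inter-sentence
main 12 x 12 and sub 2 x 2; intra-sentence main 11 x 2 and sub 1 x 3. The
intra/inter designation is wiring metadata — all kernels convolve the same
plane; tall kernels span many token rows (inter-sentence patterns), flat
kernels capture local n-gram patterns. Each pathway stacks three
same-padded stride-1 convolutions, then *dropout before the rectification*
(rate 0.5) — a deliberate modification of the original architecture to
curb overfitting — then a ReLU and 2 x 2 max pooling. Pathway outputs are
concatenated, flattened, passed through a 128-unit rectified dense layer
and a single sigmoid unit. The output convention is fixed and documented:
the sigmoid emits `P(misinformation)`, thresholded at 0.5 for hard labels.

Training uses Adam (learning rate 1e-4), binary cross-entropy, batch size
128, and exactly five epochs — a fixed, early stopping point that guards
against overfitting. Beyond that the package fixes: stride 1 with same padding (so three stacked convolutions
compose cleanly with a 12 x 12 kernel on a 100 x 100 plane), a 2 x 2
pooling window, and 4 filters per convolution by default. The filter count
is the one capacity knob chosen by this package: it is configurable, and
the small default keeps a desk-scale training run (a few thousand
documents, five epochs) in the minutes range on one CPU core while being
ample for the synthetic corpora. A reviewer wanting the heavier variant
sets `tcn_config(filters = 16)` and budgets accordingly.

### Engine notes

No deep-learning framework is used: the forward and backward passes are
implemented directly (C++ via RcppArmadillo), in single precision, with
mini-batch Adam. A convolution layer is evaluated as one GEMM over a
column-height patch matrix followed by a shifted reduction of per-tap
partial sums; the backward pass is the exact transpose of those steps, and
the dense-layer weight gradient is accumulated as one GEMM per mini-batch.
The implementation is validated in the test suite against an independent
plain-R reference forward pass and against double-precision finite
differences of that reference (all analytic gradients agree to ~1e-6
relative error at smooth points).

All randomness — Glorot initialization, epoch shuffling, dropout masks —
derives from an internal xorshift generator seeded by `config$seed`,
independent of R's RNG state. Two runs with the same data, configuration
and seed are bit-identical on the same platform; across platforms,
floating-point reproducibility holds to the usual BLAS-reordering caveats.

## Comparison models

The decision tree, random forest and SVM use rpart, randomForest and e1071
with their documented default parameters (the fitted objects record them),
consuming the same TF-IDF vectors (and vocabulary) as the augmentation
step. The stacking ensemble trains those three as base learners, collects
*out-of-fold* predicted probabilities under an internal 5-fold split — the
standard leak-free construction — fits a logistic meta-classifier on them,
then refits the base models on all data for prediction.

The GRU and LSTM baselines are implemented from scratch on matrix algebra
(their gradients likewise verified by finite differences). They consume
token-index sequences padded/truncated to the same 100-token budget, via a
learned embedding (width 16 by default; index 0 is a frozen zero row for
padding and out-of-vocabulary tokens). They train under the convolutional
model's regime (Adam 1e-4, batch 128, five epochs) for comparability, with
dropout on the final hidden state and L2 decay exposed as the standard
anti-overfitting options for recurrent networks. The model grid
— one and two layers with 16/32/64/128 cells — runs via
`recurrent_grid()`, which attaches each model's training history and its
overfitting verdict.

`detect_overfitting()` operationalizes the qualitative "overfitted"
verdict: a run is flagged when train accuracy exceeds validation accuracy
by more than 0.15 for at least two consecutive epochs, or when validation
loss rises while training loss falls for at least two consecutive
transitions. An "overfitted" verdict is inherently qualitative, so both
knobs are arguments with documented defaults.

## Evaluation

`metrics()` evaluates the four standard formulas exactly — accuracy
`(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and
F as the harmonic mean `2PR/(P+R)`. Ratios with zero denominators are
reported absent (`NA`), never zero, so they cannot silently drag fold
averages down. The AUC is computed as the Mann–Whitney concordance
probability with ties counted one half (rank-based, no trapezoids), and
the test suite pins it to a brute-force all-pairs count and to pROC.
`kfold_cv()` performs stratified k-fold cross-validation (every document
tested exactly once, per-class fold sizes within one) with unweighted
arithmetic averaging across folds. Per-class tables treat each class as
positive in turn (one-vs-rest); the per-class "accuracy" column follows
that one-vs-rest reading, which is this package's documented
interpretation — per-class accuracy has no single canonical definition.

The end-to-end pipeline evaluates on a *class-balanced* held-out test set
(equal documents per class, drawn before augmentation). Under strong
imbalance an unbalanced test set makes the majority-class baseline 85%,
leaving no headroom for a meaningful margin; a balanced test set puts the
baseline at 50% and makes minority-class recall visible. This is also the
regime the augmentation itself aims for.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the analysis
assumes: short documents (8–30 tokens by default, never more than 40),
two topic vocabularies of 150 word types each plus 400 shared background
types (the background vocabulary is deliberately larger than a topic
vocabulary, as in real text; this is also what makes mean within-class
cosine similarity increase with topic purity, since the within-class
token-collision rate is roughly `p^2/V_class + (1-p)^2/V_shared`),
token-level topic purity 0.9 (the probability a token comes from
the class vocabulary rather than the background), minority fraction 0.15
with *exact* class allocation (no binomial jitter, so count-based tests
are deterministic), and optional label noise with ground truth retained
separately. Tokens are synthetic all-alphabetic word-like strings
("waab"), disjoint from the stop-word list and invariant under the
cleaning cascade, so pipeline behavior is isolated from linguistic
artifacts; switchable noise options (duplicates, numeric tokens,
punctuation bursts) exercise individual cleaning rules.

`generate_seed_sets()` emulates the verified sample used for calibration —
by default 250 documents split 180 trustworthy / 70 misinformation — plus
an unlabeled candidate pool with hidden ground truth. The pool defaults to
2,000 documents, the same order as the corpus: augmentation draws candidates
from a stream much larger than the verified sample, and its purpose — an
approximately balanced training set — is unreachable with a pool much
smaller than the corpus. Half the pool is trustworthy
in truth by default, so calibration-recovery tests can compare empirical
per-threshold precision against analytic values.

What the generator does *not* model: real language (no grammar, no
polysemy, no semantic neighborhoods — classes are separated lexically),
adversarial or evolving misinformation narratives, tweet metadata, and
distribution shift between the verified sample and the corpus. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that augmentation behaves as designed under the assumed statistical
structure — not that any particular accuracy will be attained on real
social-media data.

## Numerical choices and problem sizes

Smoothed TF-IDF keeps every weight strictly positive for observed terms;
cosines are clamped to [0, 1] against floating-point excursions; the
cross-entropy clamps probabilities at 1e-7 (single precision) and 1e-12
(double precision); Adam uses the conventional 0.9/0.999/1e-8 constants.
The fold assignment, train/validation/test splits, corpus generation and
hash embeddings each draw from private seeded streams, so every stage is
reproducible from the seeds alone and no call disturbs the caller's RNG
state.

The shipped checks run at deliberate desk scale: the end-to-end run uses
the default 2,000-document corpus with the default configuration (one
augmented run and one unaugmented control); unit tests of the network use
reduced geometries (e.g. 20 x 16 planes, 2 filters); the recurrent grid
check runs all 16 configurations for two epochs on a 120-document corpus.
These sizes are the package's choice of a fast, fully reproducible
demonstration; all of them scale up by argument.

## Known limitations

With a learning rate of 1e-4, batch size 128 and five epochs — the fixed
training regime — a corpus of a few thousand documents yields
fewer than a hundred optimizer steps. That is enough for the model to rank
classes well, but the output bias is still dominated by the training class
prior; under heavy imbalance the 0.5 cutoff then collapses hard labels
onto the majority class even when the AUC is high. This is precisely the
failure mode the augmentation step exists to remove, and the end-to-end
check demonstrates it: the unaugmented control shows depressed minority
recall, the augmented run recovers it. Other limitations: hash embeddings
carry no semantics (see above); the engine is CPU-only and single-
threaded beyond BLAS; and multi-class extensions, attention models and
transformer baselines are out of scope.
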