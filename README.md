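# misinfonet

Classifying short health-related social-media posts as **trustworthy
information** versus **misinformation**, with similarity-based minority-class
augmentation and a four-pathway 2-D convolutional text classifier.

## What problem this solves

Automated fact-checking of health content (e.g. COVID-19 tweets) faces two
practical obstacles before any model is trained:

1. **Heterogeneous labels.** Public fact-checking datasets use incompatible
   verdict vocabularies ("Mostly true", "Two pinocchios", "Refute", ...).
   `misinfonet` harmonizes them through per-dataset label maps into three
   canonical classes: `trustworthy`, `misinformation`, `unlabeled`.
2. **Class imbalance.** Verified trustworthy content is the scarce class.
   The package implements cosine-similarity augmentation: candidate
   documents are scored by their maximum TF-IDF cosine against a small
   verified-trustworthy seed set, a similarity threshold is calibrated for
   precision on a verified sample, and candidates scoring strictly above
   the threshold are injected into the trustworthy class.

On top of that sit the models and the evaluation protocol: a
**TextConvoNet-style classifier** — four parallel 2-D convolutional pathways
(kernels 12×12, 2×2, 11×2, 1×3 on a 100×100 paragraph-level embedding
matrix; three stacked same-padded convolutions per pathway, dropout 0.5
placed before the ReLU, 2×2 max pooling, a 128-unit dense layer, sigmoid
output = P(misinformation); Adam, learning rate 1e-4, batch 128, binary
cross-entropy, five epochs) — plus six comparison models (decision tree,
random forest, SVM, their stacking ensemble, GRU and LSTM), stratified
k-fold cross-validation, ROC/AUC, per-class reports, and an overfitting
detector. The convolutional engine and the recurrent networks are
implemented from scratch (RcppArmadillo / base matrix algebra) and verified
against independent references and finite differences in the test suite.

The metrics are the standard ones: accuracy (TP+TN)/(TP+TN+FP+FN),
precision TP/(TP+FP), recall TP/(TP+FN), F = 2PR/(P+R), and AUC as the
Mann–Whitney concordance probability.

A synthetic tweet-corpus generator (`corpus_spec()`, `generate_corpus()`,
`generate_seed_sets()`) reproduces the statistical structure the analysis
assumes — short two-topic documents with shared background vocabulary,
configurable imbalance, purity, and label noise — so the entire pipeline
runs, and is tested, without downloading any data.

## Worked example

Calibrating the injection threshold on a verified sample (here,
reconstructed from the package's shipped verified-count table: 180
trustworthy and 70 misinformation documents):

```r
library(misinfonet)

counts <- read.csv(system.file("extdata", "reported",
                               "calibration_counts.csv",
                               package = "misinfonet"))
edges <- c(0, counts$threshold, 1)
mids  <- (head(edges, -1) + tail(edges, -1)) / 2
bins  <- function(exceed, n) -diff(c(n, exceed, 0))
scores <- c(rep(mids, bins(counts$true_count, 180)),
            rep(mids, bins(counts$false_count, 70)))
labels <- rep(c("trustworthy", "misinformation"), c(180, 70))
calibrate_threshold(scores, labels, thresholds = counts$threshold)
#> Similarity-threshold calibration (verified counts above threshold)
#>  threshold true_count false_count precision chosen
#>       0.10        173          66      0.72       
#>       0.15        167          61      0.73       
#>       0.20        145          48      0.75      *
#>       0.25         98          33      0.75       
#>       0.30         54          18      0.75       
#>       0.35         27           9      0.75       
#>       0.40         11           6      0.65       
#> chosen threshold: 0.2
```

Reading the table: at threshold 0.30, 54 verified-trustworthy and 18
verified-misinformation documents score above the cutoff, so 75% of
would-be injections are genuinely trustworthy (precision 0.75). The
`chosen` rule is argmax precision with ties broken toward the larger
injected count.

The full pipeline on the default synthetic study conditions (2,000
documents, minority fraction 0.15, topic purity 0.9, default model
configuration; a few minutes on one CPU core):

```r
res <- run_pipeline(spec = corpus_spec(seed = 1), seed = 1)
res
#> End-to-end misinformation classification run (augmented) 
#> corpus: 2000 docs (minority fraction 0.15), train 2677 / test 180
#> threshold 0.25, injected 857 candidates
#> test accuracy 0.9056 (majority baseline 0.5000), AUC 0.9962
#> minority (trustworthy) recall 0.8111
```

The run generates the corpus and seed sets, calibrates the threshold,
injects qualifying candidates into the training split, trains the
convolutional classifier for five epochs, and evaluates on a class-balanced
held-out test set (90 documents per class, majority baseline 50%). The
unaugmented control (`augment = FALSE`) shows the imbalance failure mode
that augmentation removes — the model ranks the classes well but the
decision cutoff collapses onto the majority class:

```r
run_pipeline(spec = corpus_spec(seed = 1), seed = 1, augment = FALSE)
#> End-to-end misinformation classification run (unaugmented control) 
#> corpus: 2000 docs (minority fraction 0.15), train 1820 / test 180
#> threshold 0.25, injected 0 candidates
#> test accuracy 0.5000 (majority baseline 0.5000), AUC 0.9506
#> minority (trustworthy) recall 0.0000
```

## Documentation

The methods vignette (`vignettes/misinfonet-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical choices, and known limitations.
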