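---
title: "Methods: semi-supervised deep-belief-network mining of a health-topic tweet stream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised deep-belief-network mining of a health-topic tweet stream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tweetdbn` implements a desk-scale version of a complete infoveillance
workflow for a keyword-collected health-topic tweet stream (the running
example is antibiotics): corpus characterization, multi-rater labeling,
bag-of-stems feature engineering, a semi-supervised deep belief network
(DBN) classifier, cross-validated evaluation, and threshold-based retrieval.
This vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## The synthetic tweet stream

No public tweet corpus accompanies this workflow, so the package ships a
seeded generator (`generator_config()`, `generate_corpus()`) whose defaults
define the study conditions every test and experiment runs under:

* **Daily volume.** Tweet counts per day are Poisson with mean `base_rate`
  (default 100/day over `n_days = 60`), multiplied on spike days by a
  configured factor (default: one five-fold spike halfway through the
  window). This emulates a stream whose baseline chatter is punctuated by
  news-driven surges.
* **Categories.** Each original tweet draws one of nine topic categories
  (Advertisement, Advice/Information, Animals, General use, Other,
  Resistance, Side effects, Wanting/Needing, Misuse) from a prior
  proportional to the published labeled-set class counts, so the class
  imbalance downstream code must survive (a 7-in-417 rarest class) is
  present by default.
* **Text.** A tweet's text is a space-joined sequence of *already-stemmed*
  tokens: at least one signature stem of its true category plus
  Zipf-distributed background stems (`rank^(-s)` over a finite vocabulary,
  exactly normalized). Emitting stems rather than inflected words decouples
  generator correctness from stemmer behavior — the Snowball stemmer acts
  as the identity on synthetic text, which the suite verifies. Hashtags
  (appended as `#tag`) and URLs are the exception: they are realistic
  surface forms, and their tokens stem like ordinary words.
* **Users, retweets, hashtags, URLs.** User activity and hashtag choice are
  Zipf-distributed; a tweet is a retweet with probability 0.279 (the
  retweet share the original stream reported), copying an earlier original
  verbatim with an `RT @user:` prefix and the platform-style source-id
  field; URLs attach with per-category probabilities (advertisements
  almost always carry one, personal anecdotes rarely).
* **Raters.** `generate_rater_table()` simulates independent raters who
  report the true category with probability `agreement` (default 0.8) and
  otherwise a uniformly random other category. Agreement 0.8 over nine
  categories yields Fleiss' kappa near 0.55–0.60, the same moderate-
  agreement regime as real manual coding of tweets.

What the generator does **not** emulate: linguistically realistic English,
follower networks, geolocation, bursty within-day timing (timestamps are
uniform over each UTC day), or topic drift. Tests passing on this generator
therefore certify the pipeline's statistical machinery, not its behavior on
the full messiness of real archives.

## Corpus analytics

`daily_counts()` produces a dense, zero-filled daily series over the
store's UTC date span. `zscore_spikes()` flags days with
\(z_i = (c_i - \bar c)/\sigma > 2\), where \(\sigma\) is the **population**
standard deviation (divisor \(n\)) over the **full** series, spike days
included. Both choices are deliberate: the method describes a whole-
collection descriptive band ("mean ± SD") rather than a rolling or robust
baseline, and a constant series (SD = 0) flags nothing. Partial first/last
days count as ordinary days.

`hashtag_stats()` counts every usage (a tag used twice in one tweet counts
twice) and reports exact relative frequencies; percentages are rendered at
two decimals, with any one-decimal rendering using round-half-even.
`user_concentration()` and `retweet_summary()` are exact tallies; retweet
tallies key on the source tweet id when present and on the normalized text
after the `RT @user:` prefix otherwise, because prefix-only retweets carry
no source id.

## Labels: adjudication and Fleiss' kappa

`adjudicate()` keeps an item when some category reaches `min_agree` votes
(default 2; with three raters the winner is then unique) and drops it
otherwise — reproducing the "2-of-3 majority, else discard" rule that
turned 1000 rated tweets into 416 labeled ones in the original workflow.
`fleiss_kappa()` implements

\[
\kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e},\qquad
P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)},\qquad
\bar P_e = \sum_j \Big(\tfrac{\sum_i n_{ij}}{Nn}\Big)^2 .
\]

Degenerate inputs: when every vote lands in one category \(\bar P_e = 1\)
and the ratio is undefined; the function returns 1 with a warning (the
perfect-agreement reading). Items missing any rater's vote are rejected
rather than imputed, because the statistic assumes a constant number of
ratings per item.

## Features: bag of stems, length bins, URL flag

`tokenize_text()` lowercases, removes URLs and `@`-mentions, keeps hashtag
text without the `#`, splits on non-alphanumerics, and drops a standard
English stopword list (stopwords are removed *before* frequency counting,
so the vocabulary consists of content stems). `stem_tokens()` is a complete
implementation of the English Snowball (Porter2) algorithm, written for
this package because no stemmer library is declared as a dependency; it is
tested on hand-derived algorithm traces ("antibiotics" → "antibiot",
"resistance" → "resist", the `ponies`/`ties`/`cries` family, short-word
e-restoration, and the exceptional forms).

`build_vocabulary()` takes up to the top 50 stems per class (over the
labeled tweets) plus up to the top 1000 stems overall (over the whole
supplied corpus — the choice of corpus is configurable), deduplicated in a
deterministic order with frequency ties broken alphabetically, so model
shapes are reproducible. `featurize_tweets()` emits binary vectors:
stem-presence bits, ten tweet-length bins of 10 characters, and one URL
flag — with a 1372-stem vocabulary that is the canonical 1383 dimensions.
Length is the raw character count of the stored text (including any
`RT @user:` prefix); lengths of 100 or more clamp into the top bin, since
ten bins of width ten only cover 0–99 while tweets run to 140 characters.

## The classifier

The model is a stack of Bernoulli restricted Boltzmann machines unrolled
into a feed-forward network — input, hidden layers of 700, 700 and 300
sigmoid units by default, and a 9-way softmax output whose rows sum to 1.

**Pretraining** (`pretrain_dbn()`) is greedy and layer-wise: RBM 1 trains
on the unlabeled feature matrix by CD-1 (learning rate 0.05, 10 epochs per
layer, batch size 10 — conventional defaults, all configurable); each next
RBM trains on the **mean-field hidden probabilities** of the layer below
rather than samples, trading a little theoretical purity for much lower
variance. In the negative phase hidden states are sampled while the final
visible and hidden phases use probabilities. Weight matrices and hidden
biases seed the feed-forward stack; the output layer stays at its random
initialization (zero-mean Gaussian, SD 0.01, zero biases).

**Fine-tuning** (`finetune_dbn()`) minimizes softmax cross-entropy by
mini-batch SGD (batch 10, 200 epochs and learning rate 0.1 by default,
plain SGD without momentum) with inverted dropout on the hidden layers:
masks are scaled by \(1/(1-p)\) during training so prediction is a plain
deterministic forward pass. **The default dropout rate is 0.2, not the
textbook 0.5.** With batches of 10 and learning rate 0.1, rate-0.5 masking
injects enough gradient variance that training reliably diverges on this
problem (weights grow past |W| ≈ 30 and the model collapses to the
majority class), while 0.2 preserves the regularizing intent and trains to
~0.99 held-out accuracy on the recovery corpus; 0.5 remains one
`finetune_config(dropout_rate = )` call away.

The batch-level inner loops (CD updates, forward/backward passes) are
compiled (RcppArmadillo) with in-place parameter updates; the R-level
reference implementations (`rbm_cd_update()`, the internal gradient
routines) remain the documented contract, and the suite pins the compiled
path to them — a full-batch compiled epoch must equal one reference
gradient step exactly, and a deterministic CD construction must produce
identical updates on both paths. Analytic gradients are verified against
central finite differences at 1e-5 relative tolerance, and RBM
conditionals and likelihood gradients against full-state enumeration on
machines small enough to enumerate.

All randomness flows through R's RNG under explicit seeds: same
configuration, same seed, bit-identical weights — the suite asserts this
through to byte-identical pipeline report files. Models serialize to a
versioned JSON container with doubles printed as `%.17g`, which restores
every IEEE-754 value exactly.

## Evaluation

`stratified_folds()` shuffles within class and deals round-robin from a
random starting fold, so per-class counts across folds differ by at most
one; classes smaller than *k* simply miss some folds. `cross_validate()`
refits per fold and **pools** predictions (the headline accuracy is a
pooled count, not a fold average). When unlabeled pretraining is used, the
RBM stack is pretrained **once** and each fold fine-tunes from those
shared weights: pretraining never sees any labels, so no information leaks
into held-out folds, and a 10-fold run costs one pretraining instead of
ten.

Per-class metrics reduce the task one-vs-rest using that class's softmax
score. `roc_points()` sweeps every distinct score as a threshold
(prediction positive iff score ≥ threshold — the same closed bound
retrieval uses) plus the all-negative endpoint; precision is undefined
(omitted) when nothing is predicted positive. `auc_score()` is the exact
Mann–Whitney statistic with ties at one half; the suite cross-checks it
against trapezoidal integration of the ROC sweep on 200 random instances
at 1e-9. `break_even()` returns the common value of precision and recall
at their crossing, linearly interpolated when the curves cross between
sweep points (the nearest sweep-point value is attached as an attribute,
since the exact crossing rarely lands on a sweep point).

## Retrieval

`assign_categories()` takes the argmax with exact ties broken by scheme
order; `retrieve_tweets()` returns tweets whose class score meets a closed
threshold, sorted by score with ties broken by tweet id, so review
workflows are reproducible. Retrieval size is non-increasing in the
threshold by construction.

## Problem sizes used by the tests and scripts

The package's own experiments run at desk scale, chosen so the full suite
and the acceptance script each complete comfortably on one CPU:

* parameter recovery: 2,000 labeled and 10,000 unlabeled synthetic tweets,
  the default 700/700/300 stack, fine-tuning shortened to 20 epochs,
  pooled stratified 10-fold CV (accuracy ≈ 0.99 against a 0.90 bar);
* semi-supervision check: 200 labels, 3,000 unlabeled tweets, an 80/80/40
  stack, 150 fine-tune epochs, three seeds — mean CV accuracy with
  pretraining must not fall below random initialization (observed:
  ≈ 0.37 vs ≈ 0.27);
* the end-to-end analysis scripts use a 60-day, ~6,400-tweet stream, a
  1,000-tweet rating sample, and a 60/60/30 network at 120 epochs.

## Known limitations

* Synthetic text is statistically, not linguistically, realistic; results
  on it bound what the machinery can do, not what real archives will
  yield.
* With very few labels in a class (the 13-label Misuse class in the demo
  analysis), the softmax never becomes confident enough for that class to
  win an argmax or clear a 0.3 retrieval threshold, even when its
  one-vs-rest AUC is high; the analysis scripts report this honestly
  rather than tuning around it. At the original study's scale (hundreds of
  thousands of unlabeled tweets) the same architecture did retrieve its
  rarest class.
* The Porter2 stemmer is a from-scratch implementation of the published
  algorithm; it matches hand-derived traces and the algorithm's published
  behavior on the tested vocabulary, but has no installed third-party
  stemmer to cross-check against.
* The keyword filter's token-prefix rule ("antibiotic" matches
  "antibiotics") is a reconstruction; the exact matching semantics of the
  original collection API are not recoverable, so the term list and both
  matching rules are configurable.
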