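---
title: "Models and design choices in robrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in robrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`robrank` supports risk-of-bias assessment in systematic reviews for
three methodological properties of randomized trials: sequence
generation, allocation concealment and blinding. This vignette explains
the statistical machinery, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## Label inference

The training signal comes from Cochrane-style assessment records rather
than direct annotation. Each record carries a study-level judgement
(`low`, `high`, `unclear`) for one property, plus either supporting
quotations or a "no information" statement, and references the articles
the reviewer consulted. From these the package infers:

* **Sentence labels.** A sentence is `relevant` if it contains a
  supplied quotation; every sentence of an article attached to a
  no-information study is `not_relevant`; all other sentences are
  `unlabelled`, because reviewers quote exemplary text rather than all
  relevant text. The three classes partition the sentences of an
  article for each property.
* **Article labels.** `high` and `unclear` collapse into `not_low`; a
  reviewer chiefly needs to single out low-risk studies, and an
  `unclear` judgement does not establish adequacy. An article enters
  the article-level dataset only if it is covered by a no-information
  statement or at least one quotation is actually found in its text.

Quotation matching is the one place where the inference must tolerate
noise: reviewer quotations are typed by hand and article text comes from
imperfect extraction. Matching is therefore a deterministic two-stage
rule on *normalized* text (lower-case, typographic quotes and dashes
mapped to ASCII, punctuation replaced by spaces, whitespace collapsed).
Stage one requires the full normalized quotation to be contained in a
sentence. Only if that fails does stage two mark every sentence sharing
a contiguous normalized substring of at least 30 characters with the
quotation; this recovers quotations that span sentence boundaries (all
overlapped sentences are marked, which favours recall — the ranking
use-case prefers surfacing a boundary-spanning match twice over missing
it) and quotations with stray hyphenation. The 30-character floor is
long enough that accidental matches in natural or synthetic text are
negligible, while a hyphenation error near the middle of a typical
quotation still leaves a qualifying run on one side. A quotation match
combined with a no-information flag for the same article and property is
rejected as corrupt input rather than silently resolved.

Two sentence-labelling regimes feed training: `relevant_not` (positives
= relevant, negatives = not-relevant, unlabelled excluded) and
`relevant_rest` (negatives = everything not relevant, so all sentences
are used). The first matches the target concept; the second trades label
purity for sample size. The experiment harness compares them as tests A
(train and test relevant/rest), B (train and test relevant/not) and C
(train relevant/rest, test relevant/not), with B and C scored on
identical test examples per fold so their comparison is paired.

## Features

Featurization is a unigram bag of words with absolute counts. The
pipeline is: lower-case, tokenize on maximal alphanumeric runs
(hyphenated words split, so "double-blind" contributes "double" and
"blind"), drop stop words (a fixed list shipped with the package) and
tokens of one or two characters, then Porter-stem. The stop-word and
length filters act on raw tokens *before* stemming; the minimum-count
filter acts on stems *after* stemming, because stemming merges counts.
Stems seen fewer than `min_count = 10` times in the training data are
dropped. The vocabulary is rebuilt on the training portion of every
cross-validation fold: computing it once on the full dataset would leak
test-set counts into feature selection. (A full-dataset vocabulary can
still be built by calling `build_vocabulary()` on all units.) The Porter
stemmer is implemented in the package from the original algorithm
definition and verified against its published worked examples.

## Model and optimization

The classifier is unregularized logistic regression,
`s = plogis(beta . x + beta0)`, so each weight is a per-occurrence
log-odds increment and the score is a probability. Fitting is plain
stochastic gradient descent: weights start at zero, each epoch visits
the examples in a seed-determined shuffled order, and each example
applies the log-loss gradient step `w <- w + lr * (y - s) * x` with the
intercept updated as an always-one feature. There is no penalty, no
learning-rate decay, no averaging and no feature scaling; the defaults
are learning rate 0.001 with 2000 epochs at sentence level and 0.0001
with 4000 epochs at article level (article datasets are far smaller, so
more epochs at a smaller rate cost little and converge smoothly). The
inner loop is compiled (Rcpp) and draws its shuffles from R's RNG, so
results are bitwise reproducible under a seed. Training with a single
class present is an error, and zero epochs legitimately yield the
all-zero model scoring 0.5 everywhere — useful as a null reference.

## Evaluation

* **Cross-validation.** Stratified 10-fold CV at the article level;
  sentences inherit their article's fold so near-duplicate text never
  straddles the train/test boundary. Stratification deals shuffled
  units of each class round-robin, which keeps per-fold class counts
  within one unit of the proportional share. Within one experiment
  suite every test reuses the same folds, making paired comparisons
  valid by construction.
* **AUC** is computed in Mann–Whitney rank form with ties credited one
  half, and is tested for exact agreement with exhaustive
  pair counting.
* **ROC averaging across folds** parameterizes each fold's curve by the
  proportion of test examples predicted positive, interpolates TPR and
  FPR at a common rate grid, and averages both coordinates with
  normal-approximation pointwise bounds (mean ± z·sd/√folds). The
  option `equalize_counts` first brings every fold to a constant number
  of examples per label by seed-determined random duplication/removal.
  This rate-oriented construction keeps fold curves comparable even
  when folds differ in prevalence; it is the package's own
  interpretation of rate-parameterized averaging with pointwise bounds,
  isolated behind `average_roc()` so an alternative could be swapped
  in.
* **Fold comparisons** use two-tailed t-tests: paired where folds are
  matched, Welch otherwise. A zero-variance comparison is flagged
  `degenerate` and reported as p = 1 rather than NaN.
* **Permutation p-values** use the add-one estimator
  `(1 + #{AUC_perm >= AUC_obs}) / (B + 1)`, the standard finite-sample
  correction that avoids reporting p = 0.
* **Calibration** is summarized over ten equal-width score bins as the
  gap between mean score and observed positive fraction; empty bins are
  reported as `NA`, not zero.

## Triage

Pooling the six published disagreement counts gives 125/474 ≈ 26.4%
of paired assessments with disagreement. The package exposes both the
pooled proportion and the unweighted mean of the six fractions, but
defaults to pooled: the unweighted mean is about 33% and is not
consistent with the published 26.4% figure, while the pooled form
reproduces it exactly. Assuming agreeing reviewers are both correct,
half of the disagreeing assignments are wrong, so the
incorrect-assignment rate is d/2 = 13.2% and the upper threshold is
t = 1 − 13.2% = 0.868. Classification is inclusive at the boundaries
(s ≥ t and s ≤ 1 − t), matching the stated decision rule. Raising t can
only shrink the triaged set, and `triage_summary()` reports a side with
no triaged articles as having *undefined* precision rather than zero.
If calibration holds, the expected precision on each triaged side is at
least t by construction — the mean score beyond a threshold exceeds the
threshold — which is what the triage coherence test checks at
n = 10000.

When deployment prevalence differs from training prevalence,
`prior_shift_adjust()` applies the standard prior-odds correction
`odds(s') = odds(s) × odds(target)/odds(train)`; scores of exactly 0 or
1 pass through unchanged. This is the textbook correction for a label
shift under class-conditional invariance; its adequacy is checked by a
resampling experiment in the test suite.

## The synthetic generator

Real assessment corpora cannot be redistributed, so
`generate_corpus()` produces corpora with the statistical structure the
pipeline assumes:

* background sentences drawn from a 500-word Zipf(1.1) nonsense
  vocabulary (syllable compounds, disjoint from the signal phrases and
  the stop-word list), preserving the heavy-tailed count statistics of
  text without shipping any copyrighted material;
* per property, a latent low/not-low state (`p_low = 0.5`) determining
  the judgement; with probability `p_report = 0.9` the judgement is
  supported by an adequate-method (low) or inadequate-method (not-low)
  phrase planted as its own sentence and recorded verbatim as the
  quotation; otherwise the record states "no information". The defaults
  mean roughly one article in ten per property contributes not-relevant
  sentences, mirroring the mixture of quotation-backed and
  no-information studies that the labelling scheme needs;
* typographic noise (`noise = 0.1`): a tenth of recorded quotations
  carry curly quotes and a stray hyphen in their final word, exercising
  the two-stage matcher's overlap path;
* a gold annotation (true labels, planted sentence indices, planted
  quotations) against which inference can be checked exactly.

The generator emulates the *dependence structure* — label/term
association via planted phrases, quotation/no-information records,
title vs abstract vs body provenance — but not linguistic realism: real
relevant sentences are not single fixed phrases, real vocabularies
overlap between classes, and real PDF extraction noise is richer than
hyphenation. Passing tests on synthetic corpora therefore demonstrate
that the machinery is correct and that directions of effect (e.g.
relevant/not outperforming relevant/rest at test time, full text beating
title-only when the signal lives in the body) are reproduced, not that
any particular AUC carries over to real Cochrane data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
the statistical checks decisive while staying comfortably fast on one
CPU: 500 articles for the exact label round trip, 200–250 articles for
the cross-validated experiments, 200 random instances of up to 200
examples for the AUC/pair-counting identity, and n = 10000 for the
calibration and triage Monte-Carlo checks (binomial error about 0.01
per bin at that size, against tolerances of 0.05). Ties in `top_terms`
break by term order; duplicate article ids, malformed JSONL lines,
single-class training data, empty vocabularies and empty triage sides
all fail loudly rather than propagating silently. Sentence
segmentation is a deterministic rule (terminator + whitespace +
uppercase/digit, with an abbreviation guard list); it does not attempt
to reproduce any particular NLP toolkit's boundaries, and label
inference is designed to be robust to boundary differences via the
overlap matcher.

## Known limitations

* The SGD contract (constant rate, per-epoch shuffling, no averaging)
  is one reasonable instantiation; other SGD variants would give
  slightly different weights, though the same qualitative behaviour.
* The rate-oriented ROC averaging and the prior-shift correction are
  the package's own constructions for operations whose published
  descriptions are brief; both are isolated behind single functions.
* The triage threshold inherits the strong assumption that agreeing
  reviewers are both correct and that mistakes are symmetric between
  low and not-low; t = 0.868 should be treated as an estimate, not a
  property of the world.
* Sentence-level stratification groups by article and stratifies on
  whether an article contains any relevant sentence; corpora in which
  almost every article has relevant sentences for a property need
  enough no-information articles (at least one per fold) for the
  relevant/not experiments to be evaluable.
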