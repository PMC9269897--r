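---
title: "Methods: semantic networks of risk from mini-snowball word associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic networks of risk from mini-snowball word associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowsem)
```

## The task and the analysis pipeline

`snowsem` analyses two-level ("mini-snowball") word-association data around a
focal concept such as *risk*. Each participant names `n_level1` (default 5)
immediate associates of the focal cue — the *level-1* responses — and then
`n_level2` (default 5) associates of each of those, the *level-2* responses,
for 30 responses per person under the default design. The analysis proceeds
in stages:

1. **Preprocessing** (`filter_associations()`): responses are normalised
   (trimmed, case-folded, internal whitespace collapsed), user-supplied
   nonwords are removed at both levels, and the *eligible vocabulary* is the
   set of level-1 responses produced at least `min_count = 3` times across
   participants. The threshold counts level-1 tokens only; level-2 responses
   are kept regardless of their own frequency because they form the profile
   dimensions, not the network nodes.
2. **Profiles** (`build_cooccurrence()`): each eligible level-1 word *w* is
   described by the frequency vector of the level-2 responses it elicited,
   pooled over participants.
3. **Similarity** (`similarity_matrix()`): profile rows are compared with the
   weighted Jaccard (Ruzicka) similarity
   \(J(x, y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)\),
   which lies in \([0, 1]\), equals 1 only for identical profiles, and is 0
   for disjoint support. Two all-zero profiles are assigned \(J = 0\) by
   convention; this cannot occur after filtering but is pinned down for
   safety.
4. **Network and components** (`build_network()`, `louvain()`): the
   similarity matrix becomes a weighted undirected network. Every strictly
   positive similarity is an edge (`min_weight = 0`): thresholding would
   discard the weak between-component relatedness that the method is
   explicitly interested in. Communities ("components of risk") are found by
   modularity maximisation; node importance is weighted PageRank
   (`pagerank()`).
5. **Characterisation**: bootstrap cluster stability (`costability()`),
   retrieval proportions, sentiment propagation, similarity to the focal
   concept (`component_profiles()`), cross-language comparison
   (`crosslingual_compare()`), demographic differences (`age_trends()`,
   `gender_diffs()`), and prediction of self-reported risk-taking propensity
   (`cv_elastic_net()` and friends).

## Community detection

`louvain()` implements two-phase Louvain modularity maximisation on the
weighted network: repeated local moving of nodes to the neighbouring
community with the largest strictly positive modularity gain, followed by
aggregation of communities into super-nodes, iterated until no gain remains.
Modularity is the Newman–Girvan weighted form
\(Q = \sum_c (e_c - a_c^2)\), with \(e_c\) the fraction of edge weight inside
community *c* and \(a_c\) its fraction of weighted degree.

Three design choices deserve comment:

* **Seeded restarts.** The algorithm runs `restarts = 10` times under a user
  seed, shuffling the node visit order each time, and keeps the partition
  with the highest Q. Ties in the modularity gain break toward the lowest
  community index, making each run deterministic given its shuffle.
* **Randomised restarts.** Greedy max-gain moving can land in the *same*
  local optimum for every visit order (we observed this on small random
  graphs), so restarts after the first accept a uniformly chosen strictly
  improving move rather than the maximal one. The first restart remains the
  classical deterministic sweep. This diversification is what lets the
  implementation match exhaustive maximum-modularity search on random graphs
  of up to 8 nodes in the test suite.
* **Resolution.** The resolution parameter is fixed at 1 (standard
  modularity); the number of components is then an output of the method, not
  an input. Component labels are renumbered by decreasing size so that
  "component 1" is always the largest.

PageRank uses damping 0.85 (the conventional value) with transition
probabilities proportional to edge weight, computed by power iteration to an
L1 tolerance of 1e-10; isolated nodes teleport uniformly. The tests verify
agreement with a dense linear solve to 1e-8.

## Bootstrap cluster stability

Stability resamples the level-2 response tokens within each level-1 cue row
(a row-wise multinomial with the original row total), rebuilds the
similarity matrix, and re-runs Louvain with a replicate-specific seed. For a
word *w* and original component *k*, the raw score is the mean fraction of
*k*'s other members found in *w*'s replicate cluster. Dividing by component
size before taking the argmax prevents the largest component from supplying
the most co-members mechanically; scores are then renormalised to sum to one
over components. The modal component is the argmax, with ties resolved
toward the original component and then the lowest index — so a word whose
component is merged wholesale with a larger one still counts as stable,
which is the conservative reading of "stability". Each component is
summarised by the fraction of members whose modal component is the original
one. The default is `B = 1000` replicates; the test suite uses 20–60 because
with disjoint planted vocabularies the result is already deterministic.

The resampling unit is the response token, not the participant: the question
the analysis asks is how sensitive the component structure is to the
sampling noise in the level-2 profiles that define it.

## Sentiment and similarity to the focal concept

Lexicon coverage of association vocabularies is always partial, so sentiment
is propagated: a word's *associate sentiment* is the count-weighted mean of
the lexicon scores of its level-2 responses (count-weighting because the
associates are observed as tokens, and frequent associates should carry
proportionally more of the signal). The inferred score is the average of the
word's own lexicon score and its associate sentiment when both exist, the
associate sentiment alone when the word itself is missing from the lexicon,
and the own score alone when no associate is covered. Inferred scores can
never leave \([-1, 1]\) because they are convex combinations of lexicon
scores.

The focal concept itself does not have a level-2 profile row, so it is
represented by the frequency vector of its level-1 responses projected onto
the level-2 column vocabulary; similarity of each word (and component mean)
to that vector is again weighted Jaccard. Component means of sentiment and
focal similarity carry percentile bootstrap 95% confidence intervals over
member words (`B = 1000` by default).

## Cross-language comparison

`crosslingual_compare()` aligns the reference similarity matrix with one
built from another language's cue–response norms (e.g. converted by
`swow_to_profiles()`) through a two-column translation table, keeping only
terms present in both. It reports the Pearson correlation over all shared
upper-triangle word pairs, K×K within/between-component mean-similarity
tables for both languages (blocks defined by the reference partition and
restricted to shared terms, so a self-comparison yields identical tables and
correlation exactly 1), and optionally the correlation of per-component
retrieval proportions.

## Demographic differences

Word-level age trends model the level-1 retrieval counts across the six age
bins with a Poisson log-linear model using the log of the bin's total
level-1 tokens as exposure offset and a linear term in the bin index; the
slope is a log relative-frequency change per bin and the p-value is a Wald
test. Only words retrieved at least once in every bin are eligible — others
are reported as ineligible, never imputed. A least-squares alternative on
log relative frequencies is available (`method = "gaussian"`) because the
choice between the two is genuinely open; the Poisson form is the default as
the canonical log-linear count model. Gender differences are the difference
in log relative retrieval frequency (additive smoothing 0.5, display only)
with a p-value from the 2×2 chi-square test of the word against all other
level-1 tokens by gender, without continuity correction and on the raw
counts. No multiple-testing correction is applied to the per-word 0.05
flags, but `adjust_effects()` appends Benjamini–Hochberg values for
transparency.

A known limitation: at small per-bin counts the Poisson–Wald test is mildly
conservative (empirical type-I error near 0.03 at the 0.05 level), and for
very frequent words the design itself underdisperses counts — a participant
can name a word at most once per cue page, so frequent-word counts are
binomially thinned relative to the Poisson model. The calibration tests
therefore run at sample sizes where per-bin counts support the asymptotics
(4000 participants, 1250 words), and calibration of the gender chi-square is
evaluated over words with at least 10 tokens, the standard expected-count
validity condition.

## Predicting risk-taking propensity

Each participant is described by K component features: the default feature
for component *k* is the mean, over the participant's in-network level-1
responses, of the mean Jaccard similarity of the response to *k*'s member
words. This similarity-based definition degrades gracefully when a response
sits between components; the harder assignment-proportion variant
(`method = "share"`) is available behind a switch. Out-of-network responses
are dropped (not zero-imputed) and exclusions logged.

Per-item inference uses OLS on z-scored predictors and outcomes
(standardised coefficients with t-tests). Predictive performance uses
repeated k-fold cross-validation (default 10×10) of elastic nets with
mixing fixed at \(\alpha = 0.5\) and the penalty chosen by inner
cross-validation on each training fold; held-out performance is
\(R^2 = 1 - SSE/SST\) on the test fold. Model variants (components only,
demographics only, combined) are compared with the corrected resampled
t-test: for paired fold differences \(d_1, \dots, d_J\),
\(t = \bar d / \sqrt{\hat\sigma^2_d (1/J + n_{test}/n_{train})}\) on
\(J - 1\) degrees of freedom — the variance inflation accounts for the
overlap of cross-validation training sets, without which fold-level t-tests
are badly anticonservative. All folds, inner folds, and bootstrap draws are
reproducible bit-for-bit under a seed.

Word-level exploration correlates the binary retrieved-indicator of every
word named by at least 10 participants with each survey item; correlations
exceeding |0.05| are flagged, and rows are ordered by mean correlation.

## The synthetic-data generator

Because raw association studies of this kind are rarely redistributable, the
package ships a generator whose defaults emulate the study design the
pipeline targets: 1205 participants quota-balanced over six age bins and two
genders (cells differing by at most one), a 5 + 5×5 response scheme, and a
lexicon of K = 5 planted components. Its moving parts:

* **Retrieval.** A participant's level-1 component propensity is
  `softmax(age_effects * age_bin + gender_effects * is_female)`; within a
  component, words follow a Zipf-like rank distribution (exponent 1 by
  default) so that response frequencies are realistically skewed — this
  heterogeneity is what makes the ≥3-occurrence filter consequential. The
  marginal frequency distribution of real associations is unknown to us;
  Zipf is a modelling choice, not an estimate.
* **Leakage.** A level-2 response comes from the eliciting word's home
  component with probability `1 - leakage` (default 0.05), otherwise from a
  uniformly chosen other component. Leakage 0 with disjoint vocabularies
  makes the planted partition exactly recoverable; raising it blurs
  component boundaries.
* **No repeats.** Responses within a cue page are drawn sequentially without
  replacement, which is distributionally identical to rejection-resampling
  duplicates.
* **Sentiment.** Per-word sentiment is Gaussian around the component mean,
  clipped to \([-1, 1]\). The default means plant one negative high-arousal
  component, one positive component, and three mildly negative ones,
  echoing the qualitative structure of risk associations.
* **Survey.** The seven 0–10 items are
  `round(clip(intercept_j + propensities %*% loadings + N(0, noise_sd)))`,
  with item-specific intercepts and loadings shared across items. The
  default loadings give a deliberately weak signal (a percent or two of
  outcome variance), which is the realistic regime for semantic predictors
  of self-reports. Tests that need a known effect size pass the realised
  level-1 component shares as the propensity matrix and scale `noise_sd` to
  plant a target population \(R^2\).
* **Determinism.** Every generator function derives its stream from
  `config$seed` plus a fixed offset, so a config is byte-reproducible
  whether stages are run individually or through `simulate_study()`.

What the generator does **not** emulate: real lexical semantics (tokens are
synthetic labels), polysemy and multi-word responses, spelling errors,
participant-level response-style heterogeneity beyond the demographic
propensity shifts, and item-specific loading patterns. Passing tests on this
generator therefore demonstrate that the pipeline recovers structure that is
present under the stated sampling model — not that five components, or any
particular stability ordering, will emerge from any real dataset.

## Problem sizes used by the test suite

The tests and the acceptance script run end-to-end at sizes chosen to make
their statistical claims meaningful while staying desk-scale: planted-
partition recovery at 1000 participants × 200 words over 20 seeds; null
calibration pooled over eight datasets of 4000 participants × 1250 words
(over 2000 eligible words); regression calibration over 500 noise outcomes;
prediction recovery at 1200 participants with a planted population
\(R^2 = 0.3\); exhaustive Louvain verification on 100 random graphs of up to
8 nodes (4140 partitions each). Bootstrap and cross-validation replicate
counts are scaled down from the defaults where the result is provably
insensitive to them.
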