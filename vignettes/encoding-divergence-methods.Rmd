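---
title: "Methods: time-resolved encoding, divergence scoring, and hypothesis discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved encoding, divergence scoring, and hypothesis discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what its synthetic
benchmarks do and do not demonstrate about real recordings.

## The encoding model

For word $w$ with embedding $\ell_w \in \mathbb{R}^d$ and sensor response
$m_{w} \in \mathbb{R}^{C}$ in one time bin, the encoding model is ridge
regression with an unpenalized intercept,

$$\hat W, \hat b \;=\; \arg\min_{W,b} \;\|M - LW - b\|_F^2 + \lambda \|W\|_F^2 ,$$

fitted independently per 25 ms time bin with all channels as joint targets.
Word-locked neural recordings are strongly autocorrelated in time, so the
cross-validation folds are *contiguous* chunks of the presentation order
(10 by default): random folds would let near-duplicate neighboring words
straddle the train/test boundary and inflate held-out performance.  The
penalty is chosen inside each training fold by nested contiguous
cross-validation (5 inner folds by default), scoring the mean held-out
Pearson correlation across targets; ties break to the smallest penalty so
that selection is deterministic.  Held-out predictions from all folds are
concatenated in presentation order, so every word is predicted exactly once
by a model that never saw it.

Centering conventions matter for an unpenalized intercept: predictors and
targets are centered with *training-fold* means only, the penalized normal
equations are solved on the centered data, and the intercept absorbs the
means.  With $\lambda = 0$ and a rank-deficient centered design the solver
fails loudly rather than silently pseudo-inverting.

Two choices here were open and are exposed as switches, recorded in the
pipeline manifest:

* **Target grouping.**  One model per time bin with channels as joint
  targets (the default) matches the time-resolved correlation maps the
  analysis produces; nothing in the procedure forces channels to share a
  fit, so `lambda_per_channel = TRUE` selects the penalty per channel
  instead.
* **Layer selection.**  When several embedding layers are available, the
  layer maximizing the unweighted mean of the correlation map over all
  channels and time bins is selected, ties to the lowest index.  Equal
  weighting of time bins is itself a choice; restricting the average to a
  window would emphasize late semantic bins.

## The divergence statistic

Model quality is summarized per (channel, time-bin) cell as the Pearson
correlation between actual and predicted responses across words.  Cells
enter the significant set $S$ when the one-sided p-value of $r > 0$ under
the exact transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ (df $= n-2$) falls below
$\alpha = 0.001$.  No multiplicity correction is applied at this gating
step: the gate is deliberately a raw per-cell threshold, and with hundreds
of cells a stray false inclusion dilutes rather than biases the statistic.
The divergence of word $w$ is then

$$\mathrm{MSE}_w = \frac{1}{|S|} \sum_{i \in S} (\hat M_{wi} - M_{wi})^2 .$$

The statistic carries no explicit time index, which leaves its temporal
pooling open.  The default defines $S$ over (channel, time-bin) *cells*, so
the statistic pools the whole significance-gated spatio-temporal grid; a
channel-level variant (`pool = "channel"`: a channel significant in any bin
contributes all its bins) is provided, and `word_mse_by_time()` computes
the per-bin version used by the category analyses.  Sentences score the
unweighted mean $\mathrm{MSE}_w$ of their words regardless of length —
"mean" with no weighting is the simplest defensible reading, but long and
short sentences then mix word counts, so sentence length is worth checking
against scores in any real analysis.  The top 100 sentences by divergence
form the contrast corpus D0, the bottom 100 form D1; with fewer than 200
sentences the corpus size shrinks symmetrically so the corpora stay
disjoint.

## Hypothesis discovery

The discovery loop is a proposer/verifier framework over the contrast
corpora.  Backends are plain functions — `propose(samples_D0, samples_D1,
n)` returning hypothesis strings and `verify(hypothesis, sentence)`
returning a boolean — so a hosted-LLM backend drops in without touching
the pipeline; the shipped mocks are deterministic (the proposer names
tokens over-represented in D0, the verifier tests token membership), which
makes the loop testable at desk scale.

Hypothesis quality is **validity**: the fraction of held-out D0 sentences
the verifier affirms minus the fraction of held-out D1 sentences it
affirms, in $[-1, 1]$ and antisymmetric under swapping the corpora.  Each
of the 3 cross-validation folds proposes from its proposal split and
validates on its held-out split; a hypothesis's final validity is the mean
over the folds where it was evaluated.  The p-value construction was left
open by the analyses this design follows, so the package defines it: corpus
labels are permuted over the pooled held-out sentences (within each
evaluated fold), and the add-one estimator
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_{\text{perm}}+1)$
is reported.  Because verifier verdicts are boolean, the permutation
distribution lives on a lattice; with small held-out corpora the tie mass
makes these p-values noticeably conservative.  The calibration test in the
suite therefore uses 400-sentence held-out corpora and 999 permutations,
where the residual conservatism is small; users validating hypotheses on
100-sentence corpora should expect conservative p-values.

Verification is per sentence by default.  A paired mode (the verifier sees
one sentence from each corpus and picks the better match) is a natural
alternative contract; the per-sentence form was chosen because it makes
validity a simple difference of proportions and needs no pairing scheme.

## Model comparison

Multiple-choice items are scored as $N$ language-modeling problems: each
option is concatenated to the context, the sequence is run through the
scorer, and the logits assigned to the realized option tokens (each read
from the preceding step's prediction) are summed into the option's score.
Summing *raw logits* is the literal reading implemented as the default;
summed log-softmax probabilities — the conventional log-likelihood — are a
switch (`mode = "logprob"`), and the mode used is recorded on the result.
Cross-entropy over the $N$ scores trains the scorer.  The toy scorer is a
bigram next-token model: a $V \times V$ transition matrix plus a start
vector, trained by full-batch gradient descent in seconds, enough to
exercise the scoring and training contracts exactly.

Base and fine-tuned encoding models are compared per (channel, time-bin)
cell with the statistic $\Delta r = r(M, \hat M_{\text{ft}}) - r(M, \hat
M_{\text{base}})$.  The null permutes the *word order of the measured
responses*, applying the same permutation to both correlations in each of
the 10,000 draws, which controls word-level structure; p-values are
two-sided with the add-one rule, and cells are labeled better/worse/not
significant at $\alpha$.  Sidedness and the permutation unit (words rather
than time blocks) were open choices; both are recorded in the output.  No
multiplicity correction is applied by default, matching the stated
procedure of labeling each cell by its own empirical p; an optional
Benjamini–Hochberg switch exists.

Category-wise improvement compares $\Delta\mathrm{MSE}_w =
\mathrm{MSE}_{\text{base},w} - \mathrm{MSE}_{\text{ft},w}$ (positive =
fine-tuned better) between in-category and out-of-category words with a
two-sample Student's t-test per time bin, Benjamini–Hochberg corrected
across bins at 0.05.  The language-modeling-loss control splits a common
token stream into 3 contiguous folds, fine-tunes both scorers on each
training portion with the plain LM objective, and compares mean held-out
next-token loss — similar losses rule out "generically better language
model" as the explanation for an encoding advantage.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the package's benchmarks.

* **Embeddings.**  Each token has a latent vector; a word's embedding is
  its token vector plus a geometrically decaying sum over the preceding
  19 tokens (`context_mix = 0.5`, `context_decay = 0.7`).  This emulates
  the one property of contextual embeddings the pipeline relies on — the
  same word in different contexts has different vectors, with nearby
  context dominating — and nothing else.
* **Responses.**  $M = LW + b + \varepsilon$ with i.i.d. Gaussian noise
  (`noise_sd = 1` response units), a 0–500 ms epoch in 25 ms bins (20 bins;
  the epoch bounds are a configurable convention — analyses of word-locked
  responses typically examine up to 500 ms, and the exposure duration
  itself is 500 ms).  Sensor geometry, autocorrelated noise, and
  cross-subject variability are *not* simulated.
* **The planted category.**  `floor(planted_fraction * n_sentences)`
  sentences are planted: one word is replaced by a marker keyword, all
  their words are flagged, and flagged words receive the structured
  residual $r_w = \frac{\text{planted\_effect}}{\sqrt 2}(P_1 + a_w P_2)$
  with fixed unit-power sensor/time patterns $P_1, P_2$ and word-specific
  $a_w \sim N(0,1)$, giving mean per-cell residual power
  $\text{planted\_effect}^2$.  The $a_w P_2$ term is brain structure no
  function of the embeddings can predict — the divergence the pipeline
  must find.  The deterministic $P_1$ term is a category-mean response
  that a category-aware model *could* predict; without it, no fine-tuned
  model of any kind could improve on planted words and the comparison
  stage would have nothing to recover.  Amplitudes are stimulus-locked
  (shared across repetitions); noise is redrawn per repetition, so
  repetition averaging raises SNR as $1/n$.
* **Multiple choice.**  The correct option reuses the context by opening
  with its final token; distractors open with another token.  Options are
  a single token by default: the planted rule lives entirely in the first
  option transition, and appending random tokens only adds rule-irrelevant
  noise that a bigram scorer overfits, which needlessly caps held-out
  accuracy.  `correct_index` is uniform, so a constant-choice baseline
  scores $1/N$.
* **Seeding.**  All randomness flows from one master seed through named
  sub-streams (tokens, weights, noise, planted amplitudes, …), so growing
  one part of a dataset never perturbs draws elsewhere and identical
  configurations are bit-identical.

Passing the planted-recovery benchmarks therefore shows that the pipeline
correctly localizes and explains *linear-model-unpredictable, category-
locked* structure under Gaussian noise; it does not show robustness to
autocorrelated sensor noise, artifacts, session drift, or the far subtler
effect sizes of real recordings.

## Numerical choices and degenerate inputs

* Ridge systems are solved from the penalized normal equations; the test
  suite cross-checks against an independent QR solution of the augmented
  least-squares system to $10^{-8}$.
* Pearson correlations with a zero-variance column are undefined and
  returned as `NA`, excluded from all averages; constant channels occur in
  degenerate synthetic data and would otherwise poison layer selection.
* Penalty and layer ties break deterministically (smallest penalty, lowest
  index); hypothesis ranking breaks validity ties by ascending p-value
  then text.
* Multiple-choice losses use a shifted log-sum-exp, exact to $10^{-10}$
  against a direct oracle.
* Sentences with no scored word are skipped with a warning; an empty
  significant set is an error (the statistic is undefined, and silently
  returning zeros would rank sentences arbitrarily).

## Problem sizes

The test suite and the acceptance script run the full analysis at reduced
but structurally faithful sizes — typically 300–2,400 words, 6–15
channels, 3–10 bins, with 400-sentence corpora for the recovery benchmarks
and 1,000–2,000 permutation draws where a distribution is being calibrated
rather than a single p-value estimated.  These sizes were chosen so the
planted effects sit at the same signal-to-noise ratios the defaults
define (planted effect $= 3 \times$ noise sd) while a complete run stays
in the seconds-to-minutes range; the pipeline itself has no size-dependent
switches, so scaling up is a configuration change only.

## Known limitations

* The generator's linear forward model matches the encoding model's
  assumptions; the benchmarks cannot reveal misspecification bias that
  real nonlinear responses would induce.
* The mock proposer can only phrase token-membership hypotheses; semantic
  hypotheses require an LLM backend, for which only the interface is
  provided.
* Discrete permutation p-values are conservative on small held-out sets
  (see above).
* The toy scorer is a bigram model: sufficient for the scoring/training
  contracts, far below the representational capacity the real analysis
  assumes of its language models.
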