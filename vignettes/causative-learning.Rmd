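---
title: "Modelling the retreat from causative overgeneralization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the retreat from causative overgeneralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retreat)
```

This vignette is the package's own account of its models and of the design
choices behind them: what is computed, under which assumptions, which knobs
matter, and what the synthetic benchmark does and does not establish.

## The modelling problem

A learner hears verbs in three kinds of construction: a *less-transparent*
causative (English *Someone broke the truck*), a *more-transparent*
causative (*Someone made the truck break*) and everything else
(non-causative uses). From distributional evidence and from verb semantics
they must infer, verb by verb, which causative device is acceptable —
becoming productive (extending devices to verbs never heard in them) while
retreating from overgeneralizations (*\*Someone laughed the man*). The
package implements the three quantities standardly used to model this —
entrenchment, preemption, and event-merge semantics — and a single
discriminative learning mechanism intended to exhibit all three effects at
once.

## Corpus bias statistics

`preemption_statistic()` and `entrenchment_statistic()` reduce a per-verb
count table to signed association statistics on 2×2 contingency tables
(focal verb vs all other verbs; rated structure vs a comparison category).

Choices worth making explicit:

* **Variant.** Uncorrected Pearson chi-square, computed by the closed form
  $N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$. No continuity or smoothing
  correction: the canonical worked example itself contains a zero cell, and
  zero cells are legitimate data here (an unattested combination). A table
  with a zero marginal carries no association information and scores 0; an
  all-zero table is an error.
* **Polarity.** The sign compares the focal verb's odds toward the rated
  structure with the other-verbs' odds via $ad$ vs $bc$, which stays
  well-defined with zero cells. Rating the same table from the opposite
  structure flips the sign and preserves the magnitude exactly
  (column-swap antisymmetry, property-tested on random tables).
* **Base rate.** "All other verbs" means the other verbs *in the supplied
  table*, not a language-wide estimate — the study design this package
  serves treats its verb set as a proxy for the language, and the package
  does not pretend otherwise.
* **Entrenchment decomposition.** The entrenchment table's comparison
  column holds only non-causative uses, so no token counts toward both
  statistics. This is the conservative reading of entrenchment: attested
  uses argue against unattested structures *even when not in competition
  for the same message*.
* **Scale.** Downstream, predictors are Z-scored across verbs
  (sample-SD denominator, the conventional choice); any monotone rescaling
  of the raw statistic is therefore immaterial to correlation- and
  regression-level analyses, and the package makes no attempt to reproduce
  any particular published raw magnitude.

## Semantic profiles

Raters position verbs on continuous analogue scales; the package stores
them in $[0, 100]$ (an arbitrary but readable convention — only relative
positions matter downstream) and aggregates by the arithmetic mean per
(verb, scale). Two derived forms exist: Z scores (the predictor form) and
min–max unit-interval activations (the model-input form). Min–max scaling
across verbs is the minimal monotone map onto the required 0–1 activation
range; both forms preserve verb rank order, so nothing downstream depends
on the raw scale's units. Empty (verb, scale) cells are an error naming the
culprit; missing individual raters are tolerated.

## The discriminative learner

### Architecture and update rule

The model (`causative_learner()`) is a single-layer network: input
$x = [\text{verb one-hot}; \text{causative bit}; s_1..s_4; 1]$, three
softmax outputs for the construction form. There is no hidden layer —
adding one is known to make virtually no difference for this task, which is
deliberately posed at a high level (choosing among pre-given forms, not
learning the forms). Each sampled utterance triggers one online update

$$W \leftarrow W + \eta\,[\,(t - y)\,x^\top - \lambda_{step} W\,],$$

with $t$ the one-hot observed form and $y$ the softmax prediction. Because
semantic inputs are continuous, this is the Widrow–Hoff rather than the
binary-cue Rescorla–Wagner member of the delta-rule family; with softmax
outputs it is exactly stochastic gradient descent on cross-entropy, whose
fixed point matches the empirical conditional form distribution
P(form | input pattern). That convergence is what makes the model's
"judgments" interpretable as learned acceptability: they estimate how the
language distributes forms for that verb, given that causation is being
expressed.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `epochs` | 50 | developmental stages; judgments extracted after each |
| `utterances_per_epoch` | 10,000 | with-replacement tokens per epoch |
| `n_runs` | 48 | ensemble size, one model per simulated participant |
| `eta` | 0.01 | learning rate (dimensionless step size) |
| `decay` | 0.5 | weight-decay strength λ |
| `init_range` | 0.5 | half-width of uniform weight initialization |

The ensemble size, epoch count, utterance count, decay and range defaults
are the study conditions this package models. The learning rate is not a
published quantity; 0.01 makes a 50-epoch run comfortably reach the
conditional-frequency regime without divergence, and every convergence
claim tested is robust to halving or doubling it. The original study fitted
its networks with an off-the-shelf routine whose decay parameter penalizes
an objective rather than scaling a per-step update; this package maps
`decay` to a per-update pull $\lambda_{step} = \lambda / U$ (with $U$
utterances per epoch), preserving the regularization role — decay weakly
shrinks judgment confidence, which is property-tested — without pretending
to replicate an unspecified optimizer. Training is online and
order-dependent by design; batch fitting is out of scope.

### Reproducibility and engines

Run $r$ of an ensemble seeds the RNG with `seed + r`, then draws its
initial weights and its entire utterance stream from that stream, so
ensembles are bit-reproducible and individually reconstructible. The hot
loop (24M updates at study scale) is compiled (Rcpp); a pure-R reference
engine consumes the RNG stream draw-for-draw identically and is tested to
agree with the compiled path to ~1e-12, which guards the compiled code
against silent drift.

### Judgment extraction and split-half validation

After each epoch (and once before training, epoch 0) each run is probed
with learning off: the verb's lexical unit and the causative unit are set
to 1, semantics to the verb's activations. The three output activations are
recorded; their sum is 1 by construction and checked to 1e-9. In
split-half mode the lexicon is partitioned once per ensemble (from the
master seed) into a training half and a judged held-out half; held-out
lexical weights receive no error-driven updates (they still shrink under
decay, like any unused weight), so held-out judgments are carried by the
causative, semantic and bias weights — the model's only route to
generalizing over *unseen* verbs is semantic similarity, which is the
hypothesis being probed. `predict(fit, newdata)` extends the same idea to
arbitrary novel semantic profiles by dropping the lexical contribution
entirely.

## Evaluation

Model and human judgments are compared at the verb level: activations are
averaged over runs (as human ratings are averaged over participants), then
correlated across verbs with judgment means — LESS against LESS, MORE
against MORE, and difference scores (MORE − LESS preference) against each
other, at every epoch (`model_fit_curve()`). Difference scoring and
averaging are both linear, so their order is immaterial (tested). Epochs
with constant predictions — e.g. an untrained `init_range = 0` model — have
no defined correlation and are flagged `degenerate` with `r = NA` rather
than silently scored 0, which would corrupt trajectory plots at epoch 0.
`critical_r()` supplies the significance threshold
$r^* = t^*/\sqrt{t^{*2} + df}$; it is strictly decreasing in both df and
α, and the two-tailed value at α equals the one-tailed value at α/2
(property-tested). `crosslanguage_matrix()` crosses per-language semantic
means with per-language difference scores over a shared lexicon and flags
cells above the threshold.

## The synthetic study

The generator (`synth_spec()`, `synth_dataset()`) produces the three input
tables with known ground truth:

* **Latent semantics**: event-merge $m_v \sim U(0,1)$; three subsidiary
  scales are noisy copies of $m_v$ (clipped), emulating the high
  collinearity of real semantic predictors.
* **Corpus counts**: verb totals Zipfian in rank ($\propto
  \text{rank}^{-s}$, $s = 1$) scaled to 2 million tokens — the order of
  magnitude of the conversational corpora such studies draw on; each token
  is causative with probability 0.1; causative tokens take the
  less-transparent form with probability
  $\operatorname{logit}^{-1}(\beta_0 + \beta_{sem} m_v)$
  ($\beta_0 = 0, \beta_{sem} = 6$). With these defaults high-merge verbs
  are strongly less-transparent-biased and the corpus as a whole prefers
  the less-transparent causative, as English does.
* **Ratings**: 20 raters per scale, rating $= 100 \cdot
  \mathrm{clip}(m + \mathcal N(0, 0.1))$.
* **Judgments**: 48 participants rate each verb in both sentence types;
  the latent acceptability for LESS is $\gamma_{sem}(m_v - \tfrac12) +
  \gamma_{freq} b_v + \mathcal N(0, 0.5)$ with the semantic term negated
  for MORE, where $b_v$ is the verb's smoothed (+0.5 per cell) signed
  log-odds of LESS vs MORE relative to the other-verbs base rate
  (`allocation_bias()`); defaults $\gamma_{sem} = 2$, $\gamma_{freq} = 1$
  make both signals detectable at study scale. The latent is discretized
  to 1–5 by equal-width bins over its deterministic range; noise past the
  ends lands in the extreme categories, and a fully degenerate generator
  (no signal, no noise) maps everything to the midpoint 3.

What the generator deliberately does **not** emulate: any real language's
frequency profile or the empirical distributions of deposited study data;
age-group differences (groups share the generator); rater reliability
structure; and — important when reading benchmark numbers — the sign
structure of raw MORE-form judgments. Because $b_v$ enters both sentence
types with the same sign while the model's MORE activation *falls* with
$b_v$, the synthetic raw MORE correlation comes out strongly negative,
unlike published positive raw-score fits; the difference-score and LESS
correlations, which carry the substantive claims, are unaffected (the
frequency term cancels in the difference). Passing benchmarks therefore
show that the pipeline recovers the structure its generator planted at
realistic scale and noise — not that any particular empirical dataset would
yield the same numbers.

### Benchmark problem sizes

The test suite runs the benchmark at 8 runs × 20 epochs (with the full
48 × 50 exercised in the acceptance script), 20 replicate seeds; at that
scale the final-epoch difference-score correlation between ensemble means
and synthetic judgment means reliably clears the one-tailed p < .01
critical value at df = 58, and held-out split-half correlations are
reliably positive — the synthetic analogue of by-verb fits to human data
and of semantics-driven generalization to unseen verbs.

### The designed retreat corpus

`overgeneralization_corpus()` is a fixed, deterministic stimulus: a
frequent high-merge cluster attested only in LESS (making LESS the
dominant causative corpus-wide), a low-merge cluster attested only in
MORE, and one low-frequency target verb with high-merge semantics whose
causative tokens are all MORE — the profile of verbs like *come*, *cry*,
*laugh*. Early in training the shared causative and semantic weights drag
the target's LESS activation up with its semantic neighbours; its own
accumulating lexical evidence then reverses it. The trajectory (LESS
activation peaking above its final value within the first third of
training, then declining) is the package's reproduction of
overgeneralization-then-retreat, checked over 20 seeds.

## Numerical choices and degenerate inputs

* Chi-square cells are coerced to doubles before products: corpus counts
  exceed $\sqrt{2^{31}}$ and would overflow R's integer arithmetic.
* Constant vectors are errors in `standardize()`, `to_unit_interval()` and
  `byverb_pearson()` (never silent zeros); `model_fit_curve()` is the one
  place that tolerates them, with an explicit flag.
* Convergence-to-conditional-frequency checks estimate the fixed point by
  the ensemble-and-time average over the last third of training: with a
  constant step size the weight chain fluctuates around its fixed point at
  a scale set by $\eta$, and the averaged estimator removes that
  fluctuation without requiring a step-size schedule the model does not
  otherwise need.
* Softmax is computed with max-subtraction; training aborts with a
  diagnostic if weights go non-finite (divergence is detectable, not
  silent).
* Utterance sampling inverts a single uniform draw against the cumulative
  cell distribution, in both engines, so the two consume the RNG stream
  identically.

## Known limitations

* The chi-square bias statistics confound association strength with token
  frequency: across a Zipfian lexicon, a verb's statistic scales with its
  frequency as well as its bias, so the *linear* correlation between the
  signed statistic and a frequency-free log-odds bias is bounded well
  below 1 even for arbitrarily large corpora (rank correlations are much
  higher; the acceptance script reports the measured value). Z-scoring
  does not remove this: it is a property of the statistic, inherited by
  anything built on it.
* The per-epoch training protocol is one consistent online reading of an
  under-specified original (warm-start vs refit per epoch is not
  recoverable); conclusions that depend on the exact optimizer rather than
  on the conditional-frequency fixed point are outside what this package
  can adjudicate.
* Acceptability is equated with output activation; no linking function
  (thresholding, response noise) between activations and 1–5 ratings is
  modelled.
* Trajectory claims are about ensemble means; individual runs are noisy
  and may peak outside the stated window.
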