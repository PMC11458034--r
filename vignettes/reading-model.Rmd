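---
title: "An interactive-activation model of reading with graded predictive activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An interactive-activation model of reading with graded predictive activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readsim)
```

## The model

`readsim` simulates eye-movement control during continuous text reading
with an interactive-activation account of visual word recognition.  The
fixated word *n* and its neighbours *n−1*, *n+1*, *n+2*, *n+3* are
processed in parallel.  Each fixation consists of a sequence of 25 ms
processing cycles; in every cycle the activation `S_w` of each word in
the lexicon is updated as

```
dS_w = (S_max − S_w) · [ c1 · Σ O_ij(w)  −  c2 · Σ_k d(w,k) · S_k  +  A_p(w) ]
       + (S_w − S_min) · τ
```

with activation clamped to `[S_min, S_max] = [0, 1]` afterwards.  The
three bracketed terms are:

* **Bigram excitation.**  Words are coded as sets of *open bigrams* —
  ordered letter pairs up to three positions apart (`open_bigrams()`).
  The visual input of each stimulus letter depends on its eccentricity
  (0.3° of visual angle per letter of distance from fixation), a
  crowding factor (1 for outer letters, 0.5 for inner letters, 3 for
  one-letter words), a Gaussian attentional weight, a cortical
  magnification acuity factor `1/(c_e·(0.018·e + 10.64))`, and a
  per-word normalization by the bigram count plus the discount `c_d = 5`
  (`letter_visual_input()`).  A bigram node's activation is the
  geometric mean of its two letter inputs, and every lexicon word
  containing an active input bigram receives its activation.
* **Overlap inhibition.**  Co-active words inhibit each other in
  proportion to their orthographic overlap.  `overlap_matrix()` reports
  raw shared-bigram counts `d(w,k)`; the simulator weighs them by
  `1/sqrt(nb_w · nb_k)` (the geometric mean of the two bigram-set
  sizes), so that a full orthographic neighbour weighs 1 and a single
  shared pair between two long words weighs little.  With raw counts
  and the inhibition weight `c2 = 2.5`, any single co-active word
  sharing one bigram contributes an inhibition of `2.5·S_k` — in
  practice that suppressed a third to a half of all fixated words below
  threshold permanently, which is incompatible with the stable ~0.9
  recognition accuracy the model is meant to show.  Whether overlap
  should be length-weighted is genuinely open; the normalized form is
  this package's resolution and is confined to `lexicon$inhibition`.
* **Predictive activation** `A_p`, described below.

Decay `τ = −0.1` applies to every word in every cycle through the
`(S_w − S_min)·τ` term; for words with no input overlap the update
reduces to pure decay, which is how activation fades once the eyes move
on.

### Recognition

A text position is recognized when some word's activation reaches its
frequency-dependent threshold `T = t_base · (1 − c_f · freq_norm)`
(`c_f = 0.08`, frequencies max-normalized) *and* that word passes two
gates: its length must be within `ceiling(0.25·len)` letters of the
input word's, and at least a third of its open bigrams must occur in
the input word at that position.  The highest-activation qualifying
candidate wins — which can be an orthographic neighbour of the true
word, producing recognition errors.  Recognition freezes the position
and resets the winner's activation to `S_min` (lexical access consumes
the activation; without the reset, recognized frequent words linger at
ceiling, suppress every later word through overlap inhibition, and
claim further positions of similar length).

Two numerical choices deserve comment.  First, `t_base = 0.75` rather
than the activation ceiling: the clamped update has fixed point
`E/(E + |τ|)` under constant net input `E`, so thresholds near 1 can
only be crossed by saturating in a single cycle (`E ≥ 1`), which makes
recognition an all-or-nothing event.  Placing thresholds at 0.69–0.75
restores a graded regime in which crossing times vary continuously with
input strength and predictive activation.  Second, the global
`input_gain` (default 800) is the model's one free scaling parameter:
the printed constants fix only relative structure.
`calibrate_input_gain()` binary-searches the gain so that in-context
word-recognition accuracy on a reference corpus falls in 0.90–0.94, the
band in which the model is expected to operate stably; the default was
frozen from that calibration (accuracy 0.924 on the default synthetic
corpus).

### Eye-movement control

Saccade programming is deliberately minimal and fully exposed in the
`saccade` section of `default_config()`:

* Initiation is stochastic: after a 4-cycle refractory floor, a saccade
  starts each cycle with probability
  `min(p_base + gain · n_recognized, p_cap)` where `n_recognized`
  counts words recognized since fixation onset (so successful
  recognition durably raises the rate for the rest of the fixation); a
  24-cycle (600 ms) ceiling forces initiation.  Defaults: `p_base =
  0.05`, `gain = 0.3`, `p_cap = 0.9`.
* The target is the most salient unrecognized word among the up to
  three words ahead whose first letter lies inside the attention
  window; salience is the summed letter input as seen from the current
  fixation, so nearer words win ties.  Words recognized parafoveally
  are excluded and therefore skipped.
* The attention window (5–14 letters, step 1, initial 8) grows after
  fixations with at least one recognition and shrinks otherwise.
* Regressions: at fixation end, with probability 0.15, the earliest
  still-unrecognized word within four words behind the eyes becomes the
  target.  This is a reconstruction — the mechanism behind regressions
  is not part of the core account.
* Landing position is the word centre.

All of these constants are reconstructions of qualitative contracts
("stochastic initiation", "recognition raises the likelihood of
moving", "most salient word in the window"), not theory, and none of
the package's conclusions depend on their exact values.

## Graded, parallel, dynamic predictive activation

Contextual predictions modulate recognition through activation, not
through thresholds.  Given a predictability table (from cloze norms or
a language model), every word predicted at a parafoveal position ahead
of fixation receives, each cycle until that position is recognized,

```
A_p = pred_w × pred_{w−1} × c_p
```

where `pred_w` is the candidate's predictability, `c_p ∈ {0.05, 0.1,
0.2}` the predictability weight, and `pred_{w−1}` the *certainty* about
the preceding word: 1 once it has been recognized, otherwise its own
table predictability (0 if absent).  The mechanism is *graded* (every
predicted candidate is pre-activated in proportion to its probability,
not just the true next word), *parallel* (all parafoveal positions at
once), and *dynamic* (certainty changes as recognition unfolds).  The
first word of a passage receives no predictive activation — the
equations are undefined without a preceding context.

Cloze tables are response proportions: with at most 43 respondents per
position the smallest representable probability is 1/43 ≈ 0.023.
Language-model tables keep every token whose probability strictly
exceeds 0.01 and are *not* renormalized afterwards: the excluded tail
is roughly vocabulary-sized, so a softmax over the dozen survivors
would flatten them to indistinguishability (twelve likelihoods spanning
0.011–0.056 all become 0.08 at two decimals), destroying exactly the
variation the mechanism feeds on.  Sub-word vocabularies are bridged by
first-token matching: a predicted token counts as a prediction of every
lexicon word whose first sub-word token it equals, and all matches
receive the token's probability.  Predicted candidates absent from the
lexicon are dropped (their count is recorded on the indexed table).

## Evaluation

Fixation streams are aggregated into the five standard word-level
measures — skipping (SK), first fixation duration (FFD), gaze duration
(GD), total reading time (TRT) and regression (RG) — with the usual
definitions; a word's first pass ends at the first fixation on any word
with a larger index, gaze duration sums the consecutive run of
fixations starting at the word's first fixation, and regression means
being fixated after the eyes have already passed the word.  Model fit
is the standardized RMSE: per-word differences divided by the
across-word human standard deviation of the measure, root-mean-squared
over words.  The score is 0 at a perfect match; a `plus_one` reporting
offset exists purely for visual comparability with conventions that
anchor the minimum at 1, since raw-difference standardization and a
unit floor cannot both hold.  Paired per-simulation scores are compared
with the Wilcoxon signed-rank test, unadjusted by default.  Feature
analyses bin words into 20 equal-width bins of length, frequency,
predictability or position, and POS tags collapse to content
(NOUN/VERB/ADJ/ADV/PROPN), function
(AUX/ADP/CONJ/SCONJ/CCONJ/DET/PART/PRON) and other (NUM/INTJ/X).

## The synthetic-data generator

Everything is testable offline because the generator emulates all four
inputs:

* **Vocabulary and passages.**  Random letter strings (lengths 1–9,
  peaked at 4–6) with Zipf frequencies (`rank^-1`); the most frequent
  ~15% are tagged as function words, a few percent as other, the rest
  as content words.  Passages (default 10 × 50 words, mirroring
  naturalistic multi-sentence passages of about fifty words) follow a
  first-order chain: with probability 0.5 the next word is the current
  word's fixed preferred successor, otherwise a frequency-weighted
  draw.  This is what makes positions predictable at all.
* **Cloze-like tables.**  Per position, 40 pseudo-respondents (≤ 43)
  answer the true next word with a per-position Beta(mean 0.45,
  concentration 2) probability and frequency-weighted distractors
  otherwise.  The Beta spread matters: natural cloze probabilities are
  strongly skewed, with many near-zero and some near-certain
  continuations, and the skipping/facilitation analyses presuppose that
  highly predictable (≥ 0.8) words exist.  Probabilities land on the
  grid `k/n` and sum to 1 per position.
* **LM-like tables.**  A dense Dirichlet-style distribution over the
  whole vocabulary (concentration proportional to frequency) mixed with
  a Beta-distributed true-word mass (mean 0.5), thresholded at 0.01
  without renormalization.  On the default corpus this yields ~10–15
  survivors per position with top-1 mass ~0.5 — the intended
  cloze-comparable shape.
* **Pseudo-human measures.**  The simulator itself, run with a known
  table and configuration, averaged over 5 seeded runs, plus Gaussian
  noise of 0.1 across-word SD per measure.  Pseudo-human data support
  *recovery* tests — can evaluation distinguish the generating table
  from a permuted table and from no predictability? — not claims about
  absolute human realism.

What the generator does **not** emulate: syntax and semantics (the word
chain is first-order), participant-level variability, wrap-up effects
at clause ends, oculomotor noise (range error, landing-site
distributions), or the real corpus's vocabulary statistics.  Passing
tests therefore show that the pipeline is internally coherent and that
the predictive-activation machinery moves eye-movement measures in the
documented directions — not that the model fits real human reading.

## Problem sizes and runtime choices

The test-suite experiments use: 50 passages for the
baseline-equivalence check; 50 seeded runs per predictability level for
facilitation; 10 corpus simulations per weight for skipping
amplification; and 20 paired runs on a 25-passage corpus for recovery.
The 25-passage recovery corpus is deliberately larger than the default
10: single-run RMSE noise scales as `1/sqrt(n_words)`, and 500 words
give per-run noise comparable to the condition separation itself,
whereas 1250 words restore the per-run precision that a full-scale
(~2700-word) corpus would provide.

## Known limitations

* Word recognition under these dynamics is fast when input is
  sufficient; fixation durations are therefore dominated by the
  stochastic saccade timer, with recognition events modulating rather
  than determining them.
* Simulated durations are shorter than typical human means (~130 ms
  FFD vs ~220 ms); the free saccade constants could be re-tuned per
  corpus, but no such fit is attempted here.
* Regression rates are low (~1–5%) because the only modelled cause is
  an unrecognized recent word; integration-driven regressions are out
  of scope.
* The recognition gates (relative length tolerance, 1/3 bigram-overlap
  requirement) are package-level reconstructions of "a word of similar
  length to the word in the visual input"; both are exposed in
  `default_config()$model`.

## A worked example

```{r example, eval = FALSE}
spec <- fixture_spec(n_passages = 4, seed = 1)
fx <- write_fixtures(spec)

cfg <- default_config()            # c_p = 0.1
runs <- simulate_corpus(fx$passages, fx$lexicon, fx$lm, cfg,
                        n_sims = 5, seed = 1)
recognition_accuracy(runs[[1]])

fit <- evaluate_runs(runs, fx$human)
aggregate_fit(fit)

cfg0 <- default_config(); cfg0$model$c_p <- 0
baseline <- simulate_corpus(fx$passages, fx$lexicon, NULL, cfg0,
                            n_sims = 5, seed = 1)
compare_conditions(aggregate_fit(evaluate_runs(runs, fx$human)),
                   aggregate_fit(evaluate_runs(baseline, fx$human)))
```
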