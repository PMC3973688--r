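---
title: "Overlapped-partitioning ensemble LDA for P300 spellers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlapped-partitioning ensemble LDA for P300 spellers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300ensemble)
```

## The problem

A row/column P300 speller presents a 6x6 symbol matrix whose columns (codes
1--6) and rows (codes 7--12) flash in random order. One *sequence* is 12
flashes -- every row and column once -- and a letter is spelled with `j`
sequences (up to 15). The user attends the target symbol and counts its
flashes; the two flashes per sequence that contain the target (its row and
its column) elicit a P300, a positive EEG deflection roughly 300 ms
post-stimulus. Classifying which row and which column carry the P300
identifies the letter.

The discriminative signal is weak relative to background EEG, the feature
vectors are high-dimensional (hundreds of channel x time features), and
practical calibration sessions are short: with five calibration letters only
900 labeled epochs exist, of which just 150 are targets. Classifiers fitted
to such data overfit, and the signal itself drifts across a session
(fatigue, habituation). This package implements an ensemble approach
designed for exactly this regime, together with everything needed to
evaluate it end to end on simulated sessions.

## The classifier

**Weak learners.** Each weak learner is a linear discriminant: on its
training partition, after optional dimension reduction, the weight vector
solves

$$\Sigma\, w_k = \mu_{+} - \mu_{-},$$

where $\Sigma$ is the *total* covariance matrix pooled over the partition's
target and non-target rows and $\mu_{+}, \mu_{-}$ are the class means. We
read "total" literally -- covariance of all rows ignoring class -- and also
expose a pooled-within-class option (`covariance = "within"`) for
sensitivity checks; the two differ only by the between-class rank-one term
and typically yield proportional weights. When $\Sigma$ is numerically
singular (reciprocal condition number below 1e-12, unavoidable when a
partition has fewer epochs than features) the Moore-Penrose pseudo-inverse
supplies the minimal-norm solution rather than failing.

**Overlapped partitioning.** The time-ordered training epochs are cut into
$K$ letter-aligned blocks. Imagining the blocks on a circle, partition $k$
is the union of blocks $k, k+1, \dots, k+B-1$ (wrapping around), so each of
the $K$ partitions holds a fraction $B/K$ of the data and each block is
reused in exactly $B$ partitions. Two special cases anchor the design:
$B = 1$ is the classical naive (disjoint) partitioning, and $B = K$ makes
every partition a copy of the whole training set, which provably collapses
the ensemble to a single classifier -- all weight vectors coincide, every
score is multiplied by $K$, and since decisions are invariant to positive
rescaling the letter decisions are identical. Both identities are asserted
in the test suite for all three dimension-reduction conditions.

**Scoring and decision.** For code $i$ with $j$ sequences, the score is

$$S_i = \sum_{k=1}^{K} \sum_{s=1}^{j} w_k^\top x_{i,s,k},$$

where $x_{i,s,k}$ is the epoch of code $i$ in sequence $s$ transformed by
partition $k$'s dimension-reduction model. The predicted column is the
argmax of $S_1..S_6$, the predicted row the argmax of $S_7..S_{12}$, and the
pair indexes the matrix. Sequences enter in recorded order (the only choice
consistent with online use); argmax ties break toward the lowest code, so
the decision is deterministic even for degenerate all-equal scores.

## Dimension reduction

Three per-partition conditions:

* **stepwise** -- the classical SWLDA selector: an OLS regression of the
  (+1/-1) label on the selected features is grown and pruned by partial
  F-tests. A variable enters if its p-value is below `p_in` and leaves if
  it exceeds `p_out`. The defaults `p_in = 0.10`, `p_out = 0.15` are the
  convention in P300 work. (Some descriptions of the procedure state the
  inequalities the other way around; we deliberately implement the standard
  directions -- adding variables whose p-values are *high* would select
  noise.) Forward and backward phases alternate until a full pass changes
  nothing; a cap of 4D alternations guards against cycling, and `p_in <=
  p_out` makes cycles unlikely in the first place. The implementation
  updates an orthogonal residual basis instead of refitting every candidate
  model, but the test suite proves it equivalent to a literal re-fit-
  everything oracle on small designs. A partition on which nothing passes
  `p_in` yields a weak learner that contributes zero to every score, with a
  warning.
* **pca** -- eigendecomposition of the partition covariance; the top $M$
  orthonormal components are retained and scores are projections of
  centered data. Component signs are fixed (largest-magnitude loading
  positive) so fits are bit-stable. There is no principled $M$ selection
  rule in this setting; the default $M = \min(n-1, \lfloor D/4 \rfloor)$
  keeps the learner well-posed and is sweepable via `n_pcs`.
* **none** -- the identity, as a control. With no fitted transform the $K$
  learners differ only through their training data.

## Evaluation: p/q cross-validation and ITR

Conventional q-fold cross-validation trains on a fraction $(q-1)/q$ of the
data -- far more than a realistic calibration session. The p/q scheme keeps
the full test coverage of q-fold while shrinking the training set: letters
are divided into $q$ time-ordered groups on a circle; fold $i$ trains on
the $p$ consecutive groups starting at group $i$ and tests on the single
following group. Every letter is tested exactly once; $p = q - 1$ recovers
standard q-fold. With 50 letters and $p/q = 1/10$ each fold trains on 5
letters = 900 epochs. `run_experiment()` reuses identical folds across all
$(K, B, \text{dimred})$ conditions, so comparisons are paired, and fits one
model per fold, truncating the score sum at each $j$ rather than
retraining.

`wolpaw_itr()` implements the standard information transfer rate,
$\log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1}$ bits per selection.
Bits per minute require the per-selection time $T$, which depends on cue
and feedback durations outside the classifier's control; $T$ is therefore a
caller-supplied parameter with no default.

## The simulator

`simulate_session()` emulates the protocol the classifier assumes: 6x6
matrix, 12 flashes per sequence in uniform random permutation, 100 ms flash
+ 75 ms blank (SOA 175 ms, i.e. 22 samples at 128 Hz), 15 sequences per
letter, a 3 s target cue before and a 1 s feedback gap after each letter's
flashes. Onsets are rounded to the nearest sample. Per letter with 15
sequences this yields 180 epochs, 30 of them targets.

The signal model adds, on a continuous timeline (so that responses of
neighbouring flashes superpose exactly as they do with a 175 ms SOA and
700 ms windows):

* per-channel AR(1) Gaussian noise, marginal SD `noise_sigma` (default
  10 uV, coefficient 0.9 -- the 1/f-like temporal correlation of band-
  limited EEG; spatial correlation between channels is omitted to keep the
  generator minimal);
* a small half-cosine visual response (default 1 uV, 120 ms latency,
  100 ms wide) on every flash, common to all channels -- it cancels in
  target-minus-nontarget contrasts but keeps "flash happened" information
  in every epoch;
* on target flashes only, a half-cosine P300 (default 5 uV peak, 300 ms
  latency with 30 ms Gaussian jitter, 300 ms wide) scaled by a posterior-
  weighted topography (maximal at Pz) and by the drift factor
  $1 + \text{drift\_rate}\,(\ell - 1)$ for letter $\ell$.

Defaults follow typical ERP magnitudes: single-trial P300 of ~5 uV against
~10 uV background EEG gives realistic single-trial SNR, so letter accuracy
grows from near chance at $j = 1$ toward ceiling as sequences accumulate.
`drift_rate` defaults to 0 (stationary); nonstationary experiments use
-0.01, i.e. 1% amplitude habituation per letter, a mild, realistic decline.
Everything is reproducible from `(config, model, seed)`.

What the simulator does *not* model: eye blinks and muscle artifacts,
spatially correlated noise, hardware timing jitter, trial-to-trial
topography changes, and refractory effects when the same row/column flashes
twice in close succession. Passing tests therefore demonstrate correctness
of the algorithms and the direction of the ensemble effects under
controlled nonstationarity -- not performance figures transferable to real
recordings.

## Preprocessing choices

The pipeline order is fixed: trim, baseline-subtract, smooth, decimate,
vectorize.

* Epoch length is `floor(0.7 * fs)` samples (89 at 128 Hz, 168 at 240 Hz);
  the baseline is the `floor(0.1 * fs)` samples before the onset.
* The moving average is *trailing* (causal) with the window truncated at
  the epoch start, so output length equals input length; a causal filter is
  the only alignment implementable online.
* Decimation keeps every `decim`-th smoothed sample starting at index 0;
  strides of 3 (128 Hz) and 12 (240 Hz) correspond to ~43 Hz and 20 Hz
  effective rates and give feature dimensions 8 x 30 = 240 and
  64 x 14 = 896. Smoothing-then-decimation is assumed (the two steps are
  named separately); block averaging would differ only marginally at these
  strides.
* Vectorization is channel-major (channel 1's samples first). The
  alternative sample-major order is an equivalent permutation; one order
  simply has to be fixed and documented.

## Numerical and degenerate-input policy

Constant feature columns are skipped by the stepwise selector with a
warning. Partitions missing a class are an error (impossible with
letter-aligned blocks and complete sequences). Incomplete sequences and
out-of-range `j` are rejected at scoring time by name. PCA eigenvalues are
clamped at zero against round-off; orthonormality and variance conservation
are asserted to 1e-8 in tests. `pq_splits()` refuses letter counts not
divisible by `q` rather than guessing a best-effort split.

## Problem sizes used in the checks

The statistical checks in the test suite and acceptance script run at desk
scale, chosen as follows: chance-level recovery uses 20 simulated
participants x 50 test letters (1000 letters) with the P300 amplitude set
to zero, asserted against the 99% binomial interval around 1/36;
sequence-averaging monotonicity uses 20 participants x 10 test letters,
with "non-decreasing on average" assessed by McNemar-style paired tests so
that Monte Carlo wiggles at the 200-letters-per-point scale are not
mistaken for real decreases; the small-sample ensemble comparison uses 20
participants, each with 5 nonstationary training letters (900 epochs) and
10 held-out later letters in a single time-ordered fold, stepwise
reduction, K = 5, and mean accuracy over sequences 5--10. Under these
conditions intermediate overlap (B = 3, 4) outperforms both naive
partitioning (B = 1, whose 180-epoch weak learners are data-starved) and
the single classifier (B = 5, which averages away the drift structure) --
the ensemble advantage the method was designed for.

## Known limitations

* Shrinkage or Bayesian covariance estimators are not provided; the
  pseudo-inverse keeps singular fits finite but not well-regularized, which
  is visible as near-chance accuracy for the `none` condition with
  180-epoch partitions and D = 240 -- consistent with expectations for
  unregularized LDA in that regime.
* The simulator's independence across channels makes spatial filters look
  better than they would on real data.
* `run_experiment()` is deliberately serial and deterministic; large grids
  are the user's loop to parallelize.
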