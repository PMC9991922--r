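---
title: "Models and methods behind mesocortex"
author: "mesocortex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesocortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the synthetic-data
generator, and the numerical choices in `mesocortex`, in the spirit of a
methods section: what each step assumes, which knobs matter, and what the
package's passing tests do and do not establish about real recordings.

## The acquisition model

Dual-wavelength widefield imaging alternates blue (calcium-sensitive) and
violet (calcium-insensitive) excitation frame by frame, so a 30 fps camera
yields two interleaved 15 fps channels. We model the recorded
fluorescence as

```
blue(p, t)   = B(p) * (1 + c(p, t) + h(p) * a(t) + noise)
violet(p, t) = B(p) * (1 + g(p) * h(p) * a(t)     + noise)
```

with per-pixel baseline `B`, calcium signal `c`, a shared hemodynamic
artifact with spatial profile `h` and temporal trace `a`, and a per-pixel
violet gain `g`. Because the artifact is multiplicative and shared up to
`g`, the classical correction — interpolate violet to blue frame times,
fit a per-pixel scale by least squares over the session, subtract — is
exactly identified in the noiseless limit.

Two generator choices are worth stating explicitly:

* **In-sample decorrelation of the artifact.** In short synthetic
  sessions, the sample correlation between the calcium loadings and the
  artifact trace does not vanish; it biases the per-pixel least-squares
  scale and leaves artifact residue that no estimator could remove from
  the data alone. Real sessions are an hour long, where this chance
  correlation is negligible. To emulate that asymptotic regime at desk
  scale, the generator orthogonalizes the artifact trace against the
  source loadings in-sample (separately at blue and violet frame times).
* **Smoothness.** All latent traces (artifact, spontaneous activity,
  movement, video features) are white noise passed twice through an
  exponential moving average, making them differentiable at the frame
  timescale, as physiological signals are; a first-order (AR(1)) trace is
  too rough for the violet-to-blue interpolation to track.

ΔF/F is computed against the per-pixel session mean (the baseline window
is not part of the correction contract; `baseline = "none"` treats inputs
as ΔF/F already, which is also how the idempotence property is stated).

## The task and behavior

Trials follow the delayed click-rate discrimination: handle hold drawn
uniformly from 0.25–0.75 s, Poisson click trains on both sides for a
uniform 1–1.5 s, a uniform 0–1 s delay, then a lick response. The rewarded
side is the side with more clicks; tie trials are re-drawn (the reward rule
is undefined on ties). Choices are drawn from a four-parameter psychometric
family,

```
P(right) = lapseLow + (1 - lapseLow - lapseHigh) * logistic(slope * (d - bias))
```

in the signed click-count difference `d`. The same family is fit back to
data by maximum likelihood (`fitPsychometric`, L-BFGS-B with lapses bounded
in [0, 0.45]). Defaults (`slope = 0.3`, lapses 0.05, both click rates
20 Hz) give roughly 80 % accuracy with all four choice × correctness cells
populated, matching a trained animal. Uniform epoch-duration distributions
are an assumption; the durations' ranges are the task's, their family is
not documented.

## Spatial sources

Sources are compactly supported Gaussian blobs (truncated at ~2σ, σ
uniform in 7–13 % of the image height) whose centers are rejected-sampled
to stay at least 0.35·min(dims) apart. Compact support and separation are
realism choices — cortical areas are local and distinct — with a useful
side effect: each source keeps pure pixels, which makes the semi-NMF
factorization identifiable. Loadings are driven by gamma-shaped event
kernels (clicks per side, trial initiation, and strongly side-preferring
lick responses), a movement-coupled term, and an independent spontaneous
trace per source; spontaneous plus movement activity dominates task
responses, as in real widefield data. The calcium movie is exactly
low-rank by construction, which the tests exploit.

## Semi-NMF and the localized variant

The factorization solves `min ||Y − A C||²` with `A ≥ 0` elementwise and
`C` unconstrained (hemodynamic-corrected traces are signed), alternating:

* `C` update: unconstrained least squares;
* `A` update: the nonnegative least-squares subproblem solved by cyclic
  coordinate descent over components (HALS), iterated to convergence
  (up to 50 passes, stopping when the largest coordinate change falls
  below 1e-4 of the largest entry). A single HALS pass is *not* enough:
  with temporally correlated components it acts like marginal regression
  and mixes sources.

All arithmetic stays in the SVD-compressed space (`Y = U M`), so the full
movie is never reconstructed. Convergence is declared at a relative loss
change below 1e-6 (500 iterations maximum; non-convergence returns the
best iterate with a warning).

**Initialization.** Semi-NMF is initialized by successive projection
(SPA): the pixel whose (compressed) time course has the largest norm is
taken as an anchor, all rows are projected orthogonal to it, and the step
repeats k times. For compactly supported sources, anchors are near-pure
pixels, so the iteration starts at the separable (unmixed) solution. We
chose this over an NNDSVD-style seed because the latter starts from
positive parts of SVD components — already mixtures — and the alternating
iteration preserves that mixing (the objective is invariant under any
invertible recombination that keeps `A` nonnegative, so the starting basin
decides the answer).

**Rank selection** is the outcome criterion, not a prior: k grows from 1
until `A C` explains ≥ 99 % of the variance of the SVD reconstruction
(variance measured about per-pixel means). The localized variant seeds one
component per atlas region (in-region mass 1, small out-of-region floor so
mass can legitimately grow outward), shrinks out-of-region mass back
whenever a component's in-region fraction drops below the 50 % threshold,
and adds components to the region with the largest in-region residual
until the variance target is met. After the final localization pass, `C`
is re-fit by least squares — whether the reference procedure re-fits is
unstated; we do, because the localization step changes `A` after the last
`C` update.

## Component typing

Component images are downsampled ×2 (block means), smoothed with a 5×5
Gaussian (σ = 2 px), peak-normalized, and embedded in 2-D by UMAP
(neighborhood 15, min_dist 0.1, fixed seed; UMAP is treated as a black-box
embedding with a transform contract for held-out points). The
leave-one-animal-out classifier embeds all *other* animals' components,
projects the test animal's components into that space, and classifies each
by the majority type of its 10 nearest neighbors among a per-repetition
balanced sample (`perType` per class; classes with fewer components are
sampled with replacement, with a warning). kNN ties — possible with 10
neighbors and 3 classes — go to the class with the smallest summed
neighbor distance.

Component size is reported two ways, because "the square root of the sum
of suprathreshold pixels, converted to mm²" mixes linear and areal units:
the literal `sqrt(N)` statistic and the calibrated area `N · px²`
(default 0.02 mm/pixel). The area is the headline value; both are
returned rather than silently resolving the ambiguity.

## Encoding model

Event variables occupy contiguous blocks of time-shifted unit pulses:
stimulus onsets span from onset to the end of the trial, single clicks a
2 s post-event window, licks −1 s to +2 s, whole-trial variables (choice,
previous choice) the full trial; spans are clipped at trial bounds and the
clipping is logged. Analog movement traces and latent video components
enter as single columns. Near-collinear columns are removed beforehand by
pivoted QR with a 1e-8 relative threshold — ridge would silently share
weight between duplicates and corrupt ΔR² attribution.

The ridge penalty is set per data column by empirical Bayes: with the
weight prior `b ~ N(0, σ²/λ)` the marginal likelihood of the column has a
closed form on the economy SVD of the design, the noise variance profiles
out analytically, and the remaining one-dimensional criterion is searched
over log λ ∈ [log 1e-6, log 1e6] with `optimize()` (golden section). The
evidence curve is unimodal on tested instances, and the selected λ tracks
the ten-fold cross-validation optimum — the point of the method is to get
the cross-validated answer without the cross-validation cost.

cvR² uses ten contiguous folds rotated over the recording, pooling test
residuals; ΔR² shuffles each of a variable's regressors independently
within trials, keeping the full model's penalties (so ΔR² isolates the
information removed, not penalty re-estimation). Event frames snap to the
nearest frame, consistent with trial alignment. Pixel maps of cvR² and of
event kernels are recovered through `U`.

## Choice decoder

Trials are first balanced across the four choice × correctness cells
(uniform down-sampling to the minimum cell). The per-timepoint decoder is
L1-penalized logistic regression (via `glmnet`) on that frame's component
vector, ten folds stratified by the balance cells; accuracy pools the
held-out predictions (averaging per-fold accuracies is the alternative;
pooling is less noisy at these trial counts) and β averages the fold
models. "Penalty = inverse of the test-set size" is implemented as
regularization strength `1/n_test`, with the reciprocal convention and an
explicit `penalty` override exposed: the penalty in absolute units is
meaningful only relative to the feature scale, and desk-scale synthetic
ΔF/F components are much smaller than percent-scale session data.

## Selectivity statistics

Per-neuron choice AUC is the rank statistic (Mann–Whitney U scaled to
[0, 1]) of contralateral- vs ipsilateral-choice trial means over the
stimulus+delay window, after z-scoring each neuron; AUC < 0.5 means
ipsilateral preference. The shuffle null permutes choice labels (100
times by default; fewer than 20 is refused as the p-value grid would be
coarser than α). The empirical p is two-sided,
`2·min(tails)` with the +1 correction in numerator and denominator —
one-sided mode is available and the choice is recorded in the result. Its
resolution floor is `2/(nShuffle+1)` ≈ 0.02. Population fractions carry
Clopper–Pearson 95 % intervals; ipsi-vs-contra imbalance uses the exact
two-sided binomial test with Bonferroni correction across the requested
family. Optogenetic impairment is the percent change from control
performance with exact binomial intervals mapped through the same
transform.

## Problem sizes and determinism

Tests run on 32×28 to 64×54-pixel sessions with 10–300 trials and
populations of up to 1,000 neurons — sizes chosen so the full suite
exercises every stage end to end in about two minutes while leaving the
statistical assertions well-powered; the acceptance script uses the
64×54, 5-source, SNR-10 session. Every stochastic routine takes an
explicit seed and is bit-reproducible; there is no hidden global
randomness.

## What passing tests do and do not show

The generator emulates the data's *structure* — interleaved channels, a
shared multiplicative artifact, low-rank compact sources, Poisson clicks,
randomized epochs, psychometric choices, tuned neuron fractions — not its
biology. Sources are exactly low-rank and compact, the artifact is exactly
rank-one and in-sample decorrelated, noise is i.i.d. Gaussian, and
movements are summarized as latent analog traces rather than rendered
video. Recovery results on this generator therefore validate the
*algorithms* (correction removes what it models, factorization finds
identifiable sources, the decoder finds linearly decodable signal, the
permutation test is calibrated); they do not certify performance on real
sessions with non-rank-one vascular artifacts, correlated noise, brain
motion beyond rigid translation, or overlapping diffuse sources. The
rigid registration handles integer-pixel translations estimated by
regularized phase correlation; nonrigid motion is out of scope, as is any
real atlas beyond a label-image region map.
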