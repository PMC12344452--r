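---
title: "Tail kinematics of detection dogs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tail kinematics of detection dogs: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Detection dogs signal a trained target odour with a fixed alert response,
but handlers report that subtler cues — especially tail movement — change
before the alert. `tailkin` operationalizes that idea as a measurement and
classification pipeline. Its input is the output of a markerless
pose-tracking model applied to overhead 60 fps video of a dog working a
three-area scent wall (one area holding the target odour): per-frame image
coordinates of six body landmarks (nose, front head, shoulders, tail base,
tail middle, tail tip) plus detector confidence, together with a
behavioural event log that records when the dog searched each area and
when it alerted. From these the package produces per-segment tail
kinematics, target/non-target classifications under dog-disjoint
cross-validation, and model-versus-expert comparison statistics.

## Tail angle and the body frame

All kinematics are computed in a body-centred frame anchored at the tail
base $B$ with the $+y$ axis along the shoulders-to-tail-base direction
$\widehat{SB}$ and the $+x$ axis pointing to the dog's right. The tail
angle is

$$\theta = \operatorname{atan2}\!\big(\overrightarrow{BM}\cdot\hat r,\;
\overrightarrow{BM}\cdot\hat b\big)$$

where $M$ is the tail-middle landmark, so $\theta = 0$ when the tail
points straight back and $\theta > 0$ when it is on the dog's right. The
tail middle, not the tip, defines the angle: the tip is unstable,
especially for curly-tailed dogs. In y-down image coordinates of an
overhead, non-mirrored camera the dog's right is $(-\hat b_y, \hat b_x)$;
because camera mirroring is not always knowable from the file, a
`handedness` switch reverses the convention, and mirroring the image flips
the sign of every lateralized quantity (verified exactly in the tests).
Angles are reported in degrees at every interface.

Six per-segment features summarize a search: the mean signed angle, the
extreme rightward and leftward excursions (`amp_positive`,
`amp_negative`, zero-referenced and set to 0 when that side is never
visited — an extremum over an empty side is otherwise undefined), the
mean absolute angular velocity, and the fractions of frames right and
left of the axis (`sum_positive`, `sum_negative`). Two open choices were
resolved as follows: the mean angle is computed over *signed* angles (a
magnitude mean would conflate lateralization with amplitude), and
amplitudes are referenced to zero rather than to the dog's own bias,
keeping the features comparable across dogs. Angular velocity defaults to
deg/s (frame-rate independent); a per-frame mode reproduces the literal
consecutive-frame difference at a fixed 60 fps. Differences are wrapped
into $(-180, 180]$ so a crossing of the $\pm 180^\circ$ cut never counts
as a full-circle jump.

Numerical details worth stating: frames with detector confidence below
0.5 are masked, and masked runs of at most 5 frames are bridged by linear
interpolation *in angle space* (interpolating raw coordinates would pull
the tail through the body); `zero_fraction` is defined as
`1 - (sum_positive + sum_negative)` so the occupancy partition sums to
one exactly in floating point (it differs from the count ratio by at most
one ulp, and the integer count partition is asserted separately in the
tests). The polar occupancy histogram uses 18 sectors of 10 degrees over
the semicircle $[-90, 90]$ (no sector count is canonical; 10-degree
sectors resolve the amplitudes dogs actually produce), with angles beyond
the semicircle clipped into the terminal sectors rather than wrapped.

## Segmentation and alert excision

Event logs follow the tabular export dialect of the BORIS annotation
tool. Area bouts must be mutually exclusive; every interval is half-open
`[start, stop)` so a frame on a boundary belongs to the later bout and is
never double-assigned. The alert is a trained response, not search
behaviour, so frames from 1 s before alert onset (a clock-based buffer —
a frame-count buffer would tie the rule to the frame rate) through alert
end are excised; whatever follows a completed alert is reward and handler
interaction and is discarded rather than re-admitted as search. Segments
left shorter than 0.5 s are dropped: angular velocity needs at least two
frames, and sub-half-second snippets carry almost no wag cycle. For
classifier training, target-area segments count as positives only when
the dog actually alerted in that trial — a target-area segment without an
alert may simply be a dog that never caught the odour.

## The synthetic generator

The study's videos cannot ship with the package, so a generator emulates
the statistical structure the analysis assumes, and every downstream
stage is validated against it. The underlying tail angle of one segment
is

$$\theta(t) = \mathrm{bias} + A(t)\,s(t) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2_\theta)$$

with carrier $s(t) = \sin(2\pi f t + \phi)$ (square and triangle carriers
are available) and $A(t)$ equal to `amp_right` on positive half-cycles
and `amp_left` on negative ones — an asymmetric sinusoid, because left
and right amplitudes are measured separately. Landmarks are placed by
inverting the body-frame geometry exactly (tail middle at half tail
length at angle $\theta$; tail tip at full length with angle
$\theta + \mathrm{lag}\cdot d\theta/dt$, lag 0.05 s, mimicking the tip's
excess mobility), so with noise zeroed the kinematics extractor recovers
the generating angle to below $10^{-6}$ degrees — the inverse-pair oracle
that anchors the geometry tests. The dog's heading follows an
Ornstein–Uhlenbeck random walk (step SD 20 deg/$\sqrt{s}$, reversion 0.5)
with a slow positional drift, so the body frame is exercised under
rotation; no quantitative data exist for heading dynamics during search,
and these defaults are placeholders flagged in the config.

Per-dog wag styles are drawn from a population distribution: baseline
bias $0 \pm 10^\circ$, amplitudes $40 \pm 8^\circ$ per side, frequency
$4 \pm 0.8$ Hz, angle jitter $3 \pm 1^\circ$, body scale $120 \pm 15$ px
and tail length $100 \pm 12$ px (plausible for a medium dog at 720p
overhead). In the target area each dog's parameters shift by its own
`target_shift` scaled by the study's `effect_scale`; the default shift is
a leftward-amplitude increase of $15 \pm 4^\circ$, matching the
group-level lateralization pattern the pipeline is designed to detect
(sign configurable for sensitivity studies). Because searching the target
area does not guarantee odour contact, `simulate_study()` can mix in
"target area but not in odour" segments (`p_in_odour`, default 1): those
segments keep the target label but express no shift — the label noise a
real study carries.

The classifier-recovery experiments use a *strong-lateralization regime*
with shift $35 \pm 3^\circ$. This is a constructed oracle, not a claim
about dogs: the recovery check asks whether the classifiers and the
dog-disjoint protocol recover an effect that is recoverable by
construction, so the shift is set clearly above the between-dog overlap
(the realistic $15^\circ$ shift sits deliberately inside it, and
$25^\circ$ still leaves individual dogs on the wrong side of a cross-dog
decision boundary).

Segment durations are drawn from a lognormal truncated below at 1 s with
$(\mu, \sigma)$ solved numerically so the *truncated* distribution has
mean 3.34 s and SD 3.45 s — solving for the untruncated moments and then
truncating would inflate the realized mean to about 3.85 s and break the
calibration the generator is supposed to reproduce. Detector noise is
applied last: isotropic pixel jitter (SD 2 px), a 2% per-frame chance of
a degraded detection (jitter inflated five-fold, confidence drawn from a
low regime around 0.3 instead of 0.95), confidences clipped to $[0,1]$.
In full-study mode the trial layout rotates the target pseudo-randomly
across the three areas, and the dog alerts with probability
$0.5 + 0.5\min(1, \mathrm{effect\_scale})$ — certain at the trained
concentration, chance-level as the effect vanishes, consistent with a
detection threshold being approached. Threshold-test mode runs one
session per dilution step with effect scales $\{1, 0.5, 0.25, 0.1\}$
tagged as dilution exponents $-3$ to $-6$.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: realistic pose-detector error structure
(occlusion, identity swaps, systematic bias near the wall), tail
elevation (a top-down view is inherently 2-D), posture changes
surrounding the alert, odour-plume dynamics, or any within-session drift
in motivation. Tests against the generator validate the machinery —
geometry, protocol plumbing, statistics — not the biological effect
sizes.

## The sequence classifier

The recurrent classifier consumes, per frame, the three tail landmarks
expressed in the body frame and divided by the shoulders-to-tail-base
distance (making the series invariant to camera placement and dog size;
per-clip min-max scaling is available as an alternative reading of
"normalized location"), plus detector confidence — seven channels. The
architecture is two stacked GRU layers of 32 and 16 units, the final
recurrent state feeding dense ReLU layers of 16, 8 and 4 units, one
dropout layer at $p = 0.1$ after the dense stack, and a single sigmoid
output trained with class-weighted binary cross-entropy and Adam. Class
weights default to inverse class frequency normalized to unit mean — the
scheme that actually neutralizes imbalance — with a config override for
any literal weighting. Variable-length series are padded and masked
(padded steps freeze the hidden state, verified against an unpadded
forward pass), subsampled to 30 fps and capped at 300 frames for memory
predictability.

The implementation is native R with batched matrix operations and full
backpropagation through time, and is verified against numerical
differentiation on every parameter block. Three optimization choices
matter and are deliberate: dense biases initialize at 0.1 because an
all-dead ReLU stack receives exactly zero gradient and never recovers;
gradients are clipped to global norm 5, which removes occasional
divergence of Adam on the final-state-only objective; and the default
learning rate is $3\times10^{-3}$ — at $10^{-3}$ the loss remains on its
initial plateau for tens of epochs on strongly separable data, an
under-convergence failure rather than a tuning preference. Training is
bit-deterministic given the seed.

Two evaluation protocols are first-class and reported separately, since
they answer different questions: stratified 5-fold cross-validation
(performance on the population of clips) and leave-one-dog-out
(generalization to unseen individuals; per-dog accuracies are retained
and dog-disjointness is asserted on every fold). Both classifiers run
under both protocols. On the strong-lateralization study the
angle-feature ensemble transfers to unseen dogs almost perfectly —
angles are morphology-free — while the raw-coordinate recurrent model,
which must disentangle wag amplitude from each dog's body geometry and
style, recovers the effect with a wider per-dog spread, including
occasional collapsed folds for individual dogs; the real study's own
per-dog accuracies spread similarly. Null-calibration runs
(`effect_scale = 0`) are evaluated on class-balanced subsets: with
unequal classes an uninformative classifier is pinned near the
majority-class rate rather than one half, so chance is only a meaningful
reference under balance. For the
low-concentration setting the classifier is the discovered feature
ensemble — gradient-boosted trees of maximum depth 9 and an RBF-kernel
SVM over the six kinematic features, combined by weighted majority vote.
Member weights default to each member's accuracy on an internal
stratified holdout (then members are refit on all training data); ties
break toward `non_target`, the conservative direction for a detection
tool where a false alert is the costly error. SVM probabilities come from
a Platt-style logistic calibration of the decision values fitted
deterministically on the training data, because libsvm's built-in
probability model is internally randomized and would break run-to-run
reproducibility. The concentration-generalization protocol trains on the
highest-concentration sessions and evaluates each lower dilution
separately, without cross-validation, yielding the degradation curve.

## Evaluation statistics

AUC uses the rank (Mann–Whitney) formulation with mid-ranks, so ties are
exact. The paired DeLong test estimates the variances and covariance of
two correlated AUCs from structural components and refers
$z = (\hat A_1 - \hat A_2)/\sqrt{v_1 + v_2 - 2c}$ to the normal
distribution, two-sided; a degenerate variance is reported as such, never
silently replaced. The expert panel's per-video score is the fraction of
responding participants answering "target present" — vote-fraction
pooling, the standard way to put a rater panel on the ROC scale; this is
an open choice (per-participant AUCs are also available) and is flagged
as such. Correlations default to Pearson with a rank option.

Mixed-model fits (GLMM/beta regression) for area effects are outside the
package's scope by design — they belong to general-purpose modelling
software, and `feature_table()`/`write_feature_table()` export exactly
the table such software needs. The in-package area-effect procedure is a
dog-stratified permutation test: the statistic is the within-dog mean
difference of a feature between target and comparison areas averaged
over dogs, and the null permutes area labels within dog-by-session
strata, respecting both repeated measures and session structure.
P-values use the add-one correction, which makes them exactly valid
(stochastically no smaller than uniform) under the null.

## Problem sizes used for validation

The shipped validation runs use sizes chosen to exercise the study
design faithfully while remaining routine on a laptop: the
classifier-recovery study uses 8 dogs, 2 sessions of 10 trials (about
480 segments, near the scale of one real test phase per dog);
calibration checks use 500 replicates (DeLong type-I error, permutation
uniformity) and 100 replicates at 999 permutations (power); the
concentration-degradation check uses 20 replicated threshold studies.
The acceptance script reports every headline quantity recomputed from
scratch at these sizes.

## Known limitations

The analysis is two-dimensional: tail elevation is invisible from
overhead and all lateralization quantities are projections. The nose and
front-head landmarks are carried through IO but never used
kinematically. The generator's heading dynamics and inter-area transit
are placeholders. Synthetic validation bounds what can be claimed: the
pipeline is demonstrated correct and calibrated, but effect sizes,
detector error structure and expert behaviour in real deployments are
empirical questions the package cannot settle from simulation.
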