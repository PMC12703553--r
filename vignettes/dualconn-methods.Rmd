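---
title: "Methods: connectivity analysis of modality compatibility in dual-tasking"
author: "dualconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity analysis of modality compatibility in dual-tasking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualconn)
```

## The scientific problem

When people perform two sensorimotor tasks at once, performance costs depend
systematically on how stimulus and response modalities are paired. Pairing a
visual stimulus with a manual response and an auditory stimulus with a vocal
response ("modality-compatible") produces reliably smaller dual-task costs
than the crossed pairing of visual-vocal with auditory-manual
("modality-incompatible"), a pattern attributed to crosstalk between the
stimulus modality of one task and the anticipated sensory consequence of the
other task's response. `dualconn` implements an analysis chain that asks
where this robust behavioral effect lives in whole-brain functional
connectivity (FC): in global network reconfiguration, or in a small number of
specific connections whose condition differences track individual differences
in behavior.

The chain runs from parcellated BOLD time series and trial tables to

1. integrated behavioral scores and run-level exclusion,
2. per-subject, per-condition Fisher-z FC matrices,
3. network-level dissimilarity and strength statistics with paired tests,
   mixed-model contrasts, and default Bayes factors, and
4. an edge-level brain-behavior selection pipeline stabilized by
   leave-one-out cross-validation against a permutation null.

A synthetic-cohort generator with planted effects provides the ground truth
against which every stage is validated; the package never requires the
original imaging data.

## Behavioral scoring

Speed and accuracy are integrated into the balanced integration score. For
each subject x task type (single/dual) x modality pairing cell we compute the
mean reaction time over correct responses and the accuracy with omissions
counted as errors, then standardize each measure over the pooled set of all
cells and take

$$\mathrm{BIS} = z(\text{accuracy}) - z(\text{mean RT}),$$

so larger values mean better performance and the score is invariant to affine
rescaling of either input (milliseconds versus seconds, proportion versus
percent). The standardization pool is all subject x task type x pairing cells
jointly; this is configurable in principle but the pooled choice is the one
that makes single- and dual-task cells commensurable, which the dual-task
cost needs. A zero-variance pool (degenerate but possible in toy data)
returns all-zero z scores rather than dividing by zero. The dual-task cost is
`bis_single - bis_dual`, positive when dual-task performance is worse;
single-task cells use easy blocks only and average the two component tasks of
the pairing.

Run-level exclusion applies three rules: more than five wrong-response-
modality trials in any block invalidates the run; single-task and localizer
runs with more than 30% errors (omissions included) are invalid; dual-task
runs are judged on congruent trials only (both stimuli requiring the same
response side), because overall dual-task error rates in this paradigm are
high enough that a whole-run criterion would discard much of the sample. The
congruent-trial rate is averaged across the subject's two dual runs by
default; the phrase "averaged for both modality pairings" admits a per-run
reading too, so a `dualCongruentScope = "within"` switch implements that
alternative. A participant is excluded when one dual run, more than one
localizer run, or more than three single runs are invalid.

## Functional connectivity construction

A run enters the analysis only if its mean framewise displacement is below
0.2 mm, fewer than 20% of frames exceed 0.25 mm, and no frame exceeds 5 mm.
Each region's series is then residualized on an intercept plus a 4-term
expansion of ten confounds (global signal, CSF, white matter, six motion
parameters, framewise displacement): the raw value, its backward-difference
temporal derivative, its square, and the squared derivative. The study this
package emulates describes the expansion as "the raw values along with all
three derivatives"; we read that as the standard Satterthwaite-style
expansion above (three derived columns per raw column). Whether framewise
displacement receives the full expansion is likewise not specified anywhere
we could anchor it, so it does by default with an `expandFd = FALSE` escape
hatch.

Task-evoked activity is removed with a finite-impulse-response basis: one
indicator regressor per condition label and post-onset lag `0..firLags-1`
(default 8 frames, which at a 2 s repetition time spans a canonical
hemodynamic response). This removes mean event-locked activity per region
without constraining its shape, leaving the background covariance between
regions — the quantity of interest — untouched. Rank-deficient designs drop
collinear columns with a warning rather than failing.

FC is the matrix of Fisher z-transformed Pearson correlations between all
region pairs. Correlations of magnitude 1 (degenerate inputs) are clipped at
`1 - 1e-7` before `atanh` and flagged; zero-variance regions yield masked
(`NA`) edges that propagate pairwise-complete through every downstream
statistic and are never imputed. Runs of a condition are averaged
element-wise in z space, and the two component single tasks of a pairing are
averaged the same way when a single-task pairing matrix is needed.

## Network-level statistics

Dissimilarity between two FC patterns is the cosine distance
$d_{\cos}(a,b) = 1 - \sum_i a_i b_i / (\lVert a\rVert\,\lVert b\rVert)$,
which is scale-invariant: proportional patterns give 0, orthogonal ones 1,
antipodal ones 2. Euclidean distance and Pearson similarity are provided as
robustness variants. Statistics are evaluated per edge subset: the whole
brain, the seven within-network subsets, and seven between-network subsets
(all edges with exactly one endpoint in the network). Every edge lies in
exactly one within subset or exactly two between subsets. Strength is the
mean absolute (or, as a variant, signed) z value over a subset.

Graph summaries use nonnegative weights obtained by taking edge magnitudes
(default) or positive parts, normalized by the matrix maximum to [0, 1]; the
source analysis does not state its weighting of negative correlations, so
both modes are exposed. Modularity is Newman's weighted
$Q = \frac{1}{2m}\sum_{ij}(w_{ij} - k_i k_j/2m)\,\delta(c_i, c_j)$ evaluated
for the a-priori seven-network partition (reproducible, and matching how the
networks are used elsewhere in the analysis) rather than a data-driven
partition. Global efficiency is the mean inverse shortest-path length with
path lengths summing reciprocal weights; disconnected pairs contribute zero.
Both agree with exhaustive-enumeration oracles on small graphs to 1e-12 in
the test suite.

## Inference

Paired comparisons report the classical two-sided t test plus the default
(JZS) Bayes factor: a Cauchy prior of width $\sqrt{2}/2$ on the standardized
effect (the conventional "medium" default; the emulated analysis does not
state its prior width) against the point null. After integrating out the
effect analytically, BF10 is a one-dimensional integral over the
Zellner-Siow mixing variance with an inverse-gamma(1/2, r^2/2) weight, which
we evaluate in log space with 301-node Gauss-Legendre quadrature on log g.
This is vectorized over t so whole edge panels can be filtered at once and
agrees with adaptive and brute-force quadrature to far better than 1e-6
relative error over the ranges used.

The network-level condition contrast is a linear mixed model (via
`nlme::lme`, maximum likelihood) with a by-subject random intercept and
age, gender, and head-movement covariates. The source description mentions
"participant and modality pairing as random effects", but with one
observation per subject and pairing a pairing random slope is not
identifiable, so the subject random intercept is the default and documented
choice. One numerical subtlety: with ML estimation the residual-variance
estimate is biased low and the fixed-effect t differs slightly from the
paired t even in the balanced case; the estimates coincide to 1e-8, and with
`method = "REML"` the t statistics coincide too. Benjamini-Hochberg
adjustment is delegated to `stats::p.adjust`.

## Edge-level selection pipeline

The brain-behavior analysis works on the subjects x edges panel of
dual-task FC differences (incompatible minus compatible) and the behavioral
difference score (dual-task BIS, incompatible minus compatible):

1. **Evidence filter.** Each edge's difference column is tested against zero
   with the one-sample JZS Bayes factor; edges with BF10 strictly above 3
   survive ("above 3" excludes exactly 3).
2. **Task-cluster filter.** Only edges whose both endpoints overlap a
   univariate task-relevant cluster remain.
3. **Behavior screen.** Partial Spearman correlation with the behavioral
   difference, controlling age, gender, and mean framewise displacement
   (over the two dual runs; an FD-difference variant is a documented
   alternative): ranks are residualized on ranked covariates plus an
   intercept and the residuals correlated; p values use the t approximation
   with `n - 2 - k` degrees of freedom. Candidates are screened at
   uncorrected p < 0.05 — deliberately sensitive, since brain-behavior
   correlations are expected to be small; stability selection provides the
   error control.
4. **Permutation null.** Per candidate edge, `nPermutations` replicates each
   drop one random subject and permute the behavior vector before
   re-correlating. The filters are not re-applied inside the null (the
   rho-only reading of the procedure); a single (drop, permutation) draw is
   shared across edges per replicate while per-edge null distributions are
   retained. The 5% and 95% empirical percentiles (type-7 interpolation, for
   bit-reproducibility) form the null band.
5. **Leave-one-out stability.** For every fold (one subject left out) the
   Bayes filter is recomputed on the remaining subjects and the partial
   correlation re-evaluated. An edge is selected iff it survives the filters
   on every fold and its fold rho values are all below the lower percentile
   or all above the upper percentile. Fold rho values of a real effect are
   nearly identical, so "all on one side" coincides in practice with "each
   outside the band".

All randomness derives from a single configured seed through stage-name
hashing (`childSeed`), so any stage can be re-run reproducibly in isolation.

## The synthetic cohort

The generator emulates the emulated study's design: 47 subjects by default,
a 200-region seven-network parcellation, one 139-frame run per dual-task
pairing and two 183-frame runs per single task, and trial tables whose
reaction-time and error marginals match the published dual-task literature
(dual 752/869 ms and 17.2%/34.3% errors for compatible/incompatible
pairings; singles 508/471 ms, 2.8%/2.5%). Time series are white noise
multiplied by the Cholesky factor of a block-structured target correlation
(within-network 0.3, between-network 0.1 — typical task-state Fisher-z
magnitudes), because the analysis consumes only second-order structure;
there is no hemodynamic model, no temporal autocorrelation, and no
physiological noise. Motion is i.i.d. log-normal framewise displacement with
a subject-specific median (cohort median 0.08 mm), which reproduces
realistic run-exclusion rates without modeling motion artifacts in the
signal.

Condition effects are planted as correlation offsets on designated edges.
Brain-behavior coupling uses one standard-normal latent per subject: each
coupling edge mixes the latent with independent noise at its configured
`coupling_r`, and adds `edgeLatentSd` (default 0.12, a realistic
between-subject spread of an edge's Fisher z) times the result to the
incompatible-condition target correlation; the same latent shifts the
subject's incompatible dual-task RT mean (60 ms per SD) and error rate (6
percentage points per SD). The population correlation between a subject's
planted connectivity delta and the behavioral difference therefore equals
`coupling_r` exactly, while the pipeline-measured correlation is attenuated
by FC sampling noise and trial noise — which is what makes the recovery
experiments informative rather than circular.

What passing tests on this cohort do **not** show: robustness to
autocorrelated or non-Gaussian BOLD noise, to hemodynamic variability, to
motion artifacts that correlate with the signal, or to parcellation
misspecification. The generator is a correctness surface for the analysis
logic, not a biophysical simulator.

## Validation experiments and problem sizes

The test suite runs two simulation experiments chosen to exercise the whole
chain at desk scale:

- **Null calibration**: 100 cohorts of 47 subjects, 50 regions, 300 frames
  per dual run, no planted effects, 500 permutations per null. The full
  pipeline (including behavioral exclusion) must return an empty selection
  in at least 95 of them; a pilot run returned 39/40 empty.
- **Recovery**: 50 cohorts with correlation offsets of 0.3 planted on two
  edges (both endpoints task-cluster-labeled), behavioral coupling 0.6, 60
  subjects, 500 frames. Here the analysis enters with all 60 subjects (the
  planted condition specifies the analysis sample size, so BIS is scored
  without the run-exclusion stage) and each planted edge must appear in the
  final selection in at least 80% of cohorts, with no more than one false
  selection per cohort on average; a pilot run recovered 49/50 planted-edge
  instances with 0.12 false selections per cohort.

These sizes keep the two experiments within a few minutes while leaving the
statistical margins wide enough to be meaningful.

## Numerical choices and degenerate inputs

- Correlations at the +/-1 boundary are clipped (`fisherClip = 1 - 1e-7`)
  and flagged, never silently infinite.
- Zero-variance regions and standardization pools degrade to flagged
  missing edges and all-zero z scores respectively, with log entries.
- Rank-deficient regression designs drop collinear columns with a warning.
- The nearest-positive-definite repair for planted target correlations
  clips eigenvalues at 1e-8 and renormalizes the diagonal; it is logged
  whenever applied.
- Ranks use average ties; permutations are uniform (derangements are not
  enforced); null percentiles use type-7 interpolation.
- Degenerate paired tests (zero-variance differences) report t = 0, p = 1
  when the mean difference is zero and an infinite t with a warning
  otherwise.

## Known limitations

The pipeline consumes parcellated text matrices, not imaging formats; volume
processing, localizer GLMs, and cluster definition are upstream. The
mixed-model random-effects structure is the identifiable subset of the
description it emulates. The Bayes-factor prior width is an assumption
(configurable), not a recovered constant. And the selection procedure
inherits the character of the analysis it reproduces: it is a sensitive,
unregistered screen stabilized by cross-validation, not a familywise-error-
controlled test.
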