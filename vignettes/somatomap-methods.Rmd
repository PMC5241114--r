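---
title: "Methods: simulating and measuring short-term somatotopic remapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring short-term somatotopic remapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Digit representations in primary somatosensory cortex (SI) form an ordered
map: index (D2) to little finger (D5) along one cortical axis. A 24-hour
manipulation of hand use (gluing two adjacent fingers) can shift the
representation of a *non-manipulated* digit — D4 moving toward D5 and away
from D3 — and this cortical shift has perceptual counterparts: temporal
order judgments (TOJ) across D4–D5 worsen while D3–D4 improve, and speeded
button presses confuse D4 and D5 more often. `somatomap` implements the
complete measurement chain behind this kind of study — travelling-wave
digit mapping, Dice overlap, representational similarity analysis (RSA),
TOJ psychometrics, confusion scoring and the repeated-measures inferential
suite — together with a synthetic cohort generator that plants the
remapping structure, so that every stage of the pipeline can be verified
end-to-end without any imaging data.

# The generative model

## Cortical sheet

The registered cortical surface is replaced by a flat 2-D vertex grid
(default 40 × 100 vertices at 1 mm spacing). Digit tuning is Gaussian in
the column (somatotopic) coordinate, with centres at 25/45/65/85 mm,
tuning SD 6 mm, and peak amplitude 1% BOLD signal change. These values
give non-overlapping but adjacent representations in the regime where the
travelling-wave analysis is normally applied. The ROI (the SI
region-of-interest analogue) is the column band covering all centres plus
three tuning widths. The grid must keep every centre at least two tuning
widths away from the edge; note the default geometry leaves 2.5 widths
beyond the D2 and D5 centres, so the margin requirement is set at two
widths rather than three.

Between-subject variability jitters all four centres (SD 1 mm, clamped to
the margin band); between-session jitter adds a further 0.5 mm SD. The
glued session displaces the D4 centre by +3 mm (toward D5) with tuning
width and amplitude unchanged — an *area-preserving* shift, matching the
finding that overlap changes without any change in digit surface area.
The 3 mm default is a choice (no generative value is published): half a
tuning width, large enough to change adjacent overlap by a few Dice
points, small enough never to destroy the D3 < D4 < D5 ordering.

## BOLD runs

Neural time courses are built at 0.1 s resolution (this handles
non-integer block/TR ratios exactly), convolved with a single-gamma HRF
(shape 6, scale 0.9 s, peak-normalised, peak at 4.5 s) and sampled at
TR = 1.5 s. Phase-encoding runs cycle continuously (8 s per digit, cycle
32 s, 8 cycles, 256 s); since there is no rest, the periodic steady-state
(circular) convolution is used, which also makes lagged reference models
exact rotations of each other. The run is sampled at `floor(256 / 1.5) =
170` TRs: the published acquisition is slightly longer than the task
(8 min 50 s for two runs vs 2 × 256 s of task), and the simulator uses the
exact task duration. Block runs alternate 12 s movement with 12 s rest
(4 blocks per digit, 16 + 16 blocks, 384 s = 256 TRs) with ordinary linear
convolution, and digit block orders are rotated across subjects and
sessions.

Noise is white Gaussian per vertex and TR (default SD 1% — the same order
as the signal amplitude, which is typical of high-field single-voxel BOLD)
plus a per-vertex linear drift with slope uniform in ±0.5% per run, and an
optional AR(1) coefficient (default 0). Head motion, spin-history and
physiological noise are deliberately not modelled; the preprocessing that
would remove them is outside the pipeline. Passing tests therefore
demonstrate correctness of the analysis chain, not robustness to every
artefact of real acquisitions.

## Behaviour

The TOJ observer answers "right first" with probability
$\lambda + (1 - 2\lambda)\,\mathrm{logistic}((\mathrm{ISI} - \mu)/s)$,
with lapse $\lambda = 0.01$ (keeps asymptotes realistic while the fitted
model stays near-logistic) and $s = \mathrm{JND}/\ln 3$, so the planted
JND is exactly the 25–75% half-spread. The printed ISI set is
±400, ±250, ±180, ±120, ±70, ±30 ms — the 12 ISIs × 16 repetitions = 192
trials per run. Baseline JND is 60 ms with lognormal subject (CV 0.15) and
session (CV 0.08) variability; glued sessions multiply the D3–D4 JND by
0.7 and the D4–D5 JND by 1.4. A "flat" observer (chance at every ISI) can
be planted for one session to exercise the goodness-of-fit exclusion.

The confusion task cues presses every 700 ms in 4 blocks of 210. Cue
sequences have no immediate repeats and balanced ordered pairings (an
Eulerian circuit over the complete digraph on the four digits, topped up
with no-repeat random cues). Responses follow a row-stochastic confusion
matrix (adjacent mis-press probability 0.03, non-adjacent 0.005); glued
sessions add 0.05 to both D4→D5 and D5→D4. A 5% omission rate draws the
press beyond the 700 ms response window.

All randomness descends from one master seed through fixed per-subject /
per-session / per-run offsets, so a cohort is bit-reproducible and
subject-sessions can be generated independently (the full-study driver
streams them one at a time rather than materialising the whole cohort).

# The analysis chain

## Travelling-wave mapping

The reference model is a gamma-convolved boxcar (8 s on, 24 s off, eight
cycles), circularly shifted by a lag, sampled at the TR and standardised.
Lags run over the full 32 s cycle in 1 s steps (configurable); Pearson
correlations between each (linearly detrended) vertex series and each
lagged model form the lag-correlation stack. Zero-variance vertices are
flagged and excluded rather than yielding undefined correlations.

Each lag belongs to the digit whose block contains the centre of the
shifted on-window; a centre falling exactly on a block boundary goes to
the earlier digit. Per-digit r-maps average the lags of that digit;
forward and backward r-maps are averaged; z-maps use the Fisher transform
$z = \operatorname{atanh}(r)\sqrt{n-3}$ with $n$ the total timepoints of
both runs (the original conversion is unstated; only monotonicity in $r$
matters for thresholding, and the choice is recorded in the map object).
Correlations at $|r| = 1$ are capped just below 1 and flagged. Within the
ROI, each digit's z-map is converted to two-sided normal p-values and
FDR-thresholded (Benjamini–Hochberg, α = 0.01) separately per digit. Only
positively responding vertices (z > 0) enter the binary map: in a
travelling-wave design a vertex tuned to one digit *anticorrelates*
strongly with the antiphase digit's reference, and admitting those
vertices would make "digit maps" that contain their phase opposites.

One consequence worth stating: under the default geometry, noiseless
binary maps of non-adjacent digits are exactly disjoint (the combined
r-profile falls below zero within about one tuning width of the
representation edge), so non-adjacent Dice coefficients are exactly zero
rather than small and graded. Only adjacent pairs carry overlap signal,
which is also the regime the overlap analysis is designed for.

A related geometric subtlety: the planted shift preserves the D4
representation's own surface area (relative change below 1% on synthetic
cohorts) but slightly extends the D3 map toward the vacated territory and
compresses the D5 map — edge effects of the mixture zones. With the
generator's small within-subject variability these few-percent edge
effects can reach significance in a session × digit ANOVA on area even
though the D4 area itself is conserved; in human data, measurement noise
dwarfs them.

## Overlap statistics

Dice = $2|A \cap B| / (|A| + |B|)$ within the ROI; undefined (both maps
empty) propagates as missing, and any subject with a missing cell is
dropped from the ANOVA table (complete-case) with a warning. Surface area
is survivor count × per-vertex area. Peaks are ROI argmaxima of z with a
deterministic lowest-index tie rule (ties flagged). Peak-to-peak distance
is the shortest path on the 8-connected grid graph (spacing for rook
steps, √2 × spacing for diagonal steps) — the synthetic analogue of
surface geodesic distance; on the full uniform grid it has a closed form,
which the tests verify against Dijkstra. Peak distances are produced but
have no planted effect (the planted shift moves map *edges*, mostly
sparing the peak), mirroring the published null finding for this measure.

## RSA

The block-design GLM fits four gamma-HRF digit regressors plus intercept
and linear drift (the published high-pass filtering belongs to the
out-of-scope preprocessing; a linear term matches the synthetic drift).
Betas are univariately noise-normalised by the vertex residual SD
(zero-variance vertices excluded with a log message). The RSA ROI is
defined from the phase-encoding data averaged across sessions — vertices
surviving FDR α = 0.01 on the session-mean z-maps, union over digits.
RDMs are Euclidean distances between the four noise-normalised patterns;
the three adjacent-pair entries feed the session × pair ANOVA.

For visualisation, classical (Torgerson) MDS embeds each RDM in 2-D, and
per-participant embeddings are aligned by iterative group Procrustes
(translation, rotation/reflection, scaling to the evolving mean, with the
mean held at constant scale; convergence when the disparity changes by
< 1e-8 relative, cap 100 iterations). Standard errors of the aligned
points are inflated by $\sqrt{nk/(nk - d)}$ with $n = 4$ points, $k = 2$
dimensions and $d = 4$ alignment degrees of freedom (rotation + scale +
two translations), i.e. √2. The exact correction used in the original
analysis is not published; the factor is a configurable argument and is
reported in the result object.

## Psychophysics

Psychometric fits use binomial maximum likelihood (a logistic regression
of response on signed ISI) — stable with 16 trials per ISI, unlike least
squares on proportions. $R^2$ is the squared Pearson correlation between
observed and fitted per-ISI proportions (the published threshold is an
$R^2$ on a logistic fit with no definition given; this is the natural
one). JND = $s \ln 3$ = half the 25–75% spread by construction. Perfect
separation, non-convergence, or a non-positive slope flags the fit and
yields no JND. A subject is excluded from the JND analysis entirely if
*any* session × pair fit is flagged or falls below $R^2 = 0.4$,
preserving the complete crossing the repeated-measures ANOVA needs.
TOJ trials without a response would simply not enter the per-ISI
denominators. Confusion scoring counts only in-window (≤ 700 ms)
responses into the 4 × 4 target × response matrix; adjacent-pair
mis-presses are presses of d+1 to cue d plus presses of d to cue d+1,
reported as totals and per-block means (the ANOVA uses per-block means).

## Inference

The two-way repeated-measures ANOVA uses the within-subject
sums-of-squares decomposition with each effect tested against its own
effect × subject interaction; partial η² = SS_effect / (SS_effect +
SS_error). Sphericity is assessed per effect with Mauchly's test on
orthonormal contrasts; the Greenhouse–Geisser ε comes from the
eigenvalues of the contrasted covariance. Both uncorrected and corrected
rows are always reported; the default policy applies the correction when
Mauchly's p < 0.05, which reproduces the published mixture of integer and
fractional dfs across measures. Simple main effects are one-way RM-ANOVAs
of session within each digit pair with the *per-level* error term —
df = (2, 2(n−1)), i.e. F(2,16) at n = 9 and F(2,14) at n = 8, matching
the published df shapes (a pooled-error variant is not the default
because it would not). Pairwise session comparisons are paired t-tests
with Sidak correction over m = 3. Shapiro–Wilk normality is computed per
cell as a logged screen, never as an automatic branch. The
control-averaging sensitivity check collapses the two control sessions to
their per-subject mean, reruns the suite, and reports whether the
significance pattern is unchanged.

# Numerical and testing choices

Deterministic tie-breaks everywhere (boundary lags to the earlier digit,
peak ties to the lowest index); degenerate inputs error or flag rather
than silently propagate (empty ROI, zero-variance vertices or differences,
all-identical ANOVA cells, coincident Procrustes configurations).
Because tuning varies only along the column axis, test cohorts shrink the
row dimension (1–2 rows × 100 columns) without changing the science;
property tests use 20 planted cohorts for directional recovery, 200 null
cohorts for type-I calibration, and 500 simulated observers for JND
recovery. The ANOVA suite is verified to 1e-8 against `aov()` error
strata on random tables, and ε against the classic closed-form expression.

# Known limitations

The sheet is flat: no mesh geodesics, no folding, no projection effects.
Noise is white (plus drift); temporally autocorrelated noise is available
(AR(1)) but not default, and no motion or physiological structure is
modelled. Non-adjacent Dice overlap carries no graded signal under the
default geometry (see above). The fitted psychometric model omits the
lapse parameter by design, so recovery tests carry a small, honest bias
at extreme ISIs. Group-level numbers from human cohorts are reproducible
with `analyze_source_tables()` only when the corresponding measurement
tables are supplied; none are redistributed with the package.
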