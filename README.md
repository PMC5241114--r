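# somatomap

Analysis pipeline for short-term remapping of digit somatotopy in human
primary somatosensory cortex (SI), aimed at researchers studying
experience-dependent plasticity with high-field fMRI and tactile
psychophysics. The package implements the full measurement chain of a
digit-gluing remapping study — travelling-wave phase-encoding digit
mapping, inter-digit overlap (Dice) statistics, representational
similarity analysis (RSA) of block-design data, temporal-order-judgment
(TOJ) psychometrics, motor-confusion scoring, and two-way
repeated-measures inference — together with a synthetic cohort generator
that plants the remapping structure, so every stage can be verified
end-to-end with ground truth.

## The methods at its core

**Travelling-wave mapping.** Digits D2–D5 are stimulated cyclically (8 s
blocks, 32 s cycle, 8 cycles). The reference model is a gamma-convolved
boxcar (8 s on, 24 s off), iteratively lag-shifted across the cycle; each
voxel's BOLD series is Pearson-correlated with every lagged model, lags
are assigned to digits by the position of the shifted on-window, r-maps
are averaged over each digit's lags and over forward/backward runs,
converted to z = atanh(r)·√(n−3), FDR-thresholded (Benjamini–Hochberg,
α = 0.01) within an SI ROI and binarised.

**Overlap.** For adjacent digit pairs A, B the Dice coefficient

    Dice(A, B) = 2|A ∩ B| / (|A| + |B|)

is computed within the ROI, along with per-digit surface area and peak
geodesic distances.

**RSA.** A block-design GLM (one gamma-HRF regressor per digit) yields
betas that are univariately noise-normalised by voxel residual SD;
4 × 4 representational dissimilarity matrices use Euclidean distance over
the ROI, summarised by adjacent-pair distances, classical MDS and group
Procrustes alignment with alignment-corrected standard errors.

**Psychophysics.** TOJ responses at 12 signed ISIs × 16 repetitions are
fitted with a logistic P(right first) = 1/(1 + exp(−(ISI − μ)/s)) by
binomial maximum likelihood; the just-noticeable difference is
JND = s·ln 3 (half the 25–75% ISI spread), with subjects excluded when any
fit has R² < 0.4. Confusion runs count in-window (≤ 700 ms) mis-presses
per adjacent pair.

**Inference.** Each measure's subject × session × digit-pair table enters
a two-way repeated-measures ANOVA (partial η², Mauchly/Greenhouse–Geisser
handling), followed by simple main effects per digit pair and
Sidak-corrected pairwise session comparisons, plus a control-averaging
sensitivity check.

The synthetic generator plants the studied effect: in the "glued" session
the D4 tuning centre shifts toward D5 at constant tuning width (an
area-preserving shift), the D3–D4 JND improves while D4–D5 worsens, and
D4↔D5 button confusions increase.

## Worked example

```r
library(somatomap)
spec   <- cohort_spec(n_subjects = 9, seed = 1)   # planted remapping
report <- run_full_study(study_config(cohort = spec))
print(report)
```

```
<study_report> 9 subjects, seed 1
  dice      session x pair: F(4.0,32.0) = 14.102, p = 9.731e-07, partial eta^2 = 0.638
  rsa       session x pair: F(4.0,32.0) = 31.150, p = 1.269e-10, partial eta^2 = 0.796
  jnd       session x pair: F(4.0,32.0) = 5.532, p = 0.001678, partial eta^2 = 0.409
  mispress  session x pair: F(4.0,32.0) = 31.126, p = 1.281e-10, partial eta^2 = 0.796
```

Each line is the session × digit-pair interaction for one measure: the
planted D4 shift makes overlap, representational distance, temporal
acuity and motor confusion all depend on *which* digit pair you look at.
Drilling into the Dice overlap:

```r
report$analyses$dice$simple_effects[, c("digit_pair", "F", "df_effect",
                                        "df_error", "p_reported")]
#>   digit_pair          F df_effect df_error   p_reported
#> 1      D2-D3  0.3289947         2       16 0.7244013118
#> 2      D3-D4 14.1973250         2       16 0.0002846523
#> 3      D4-D5 12.7655495         2       16 0.0004852577

pw <- report$analyses$dice$pairwise
pw[pw$digit_pair == "D4-D5", c("comparison", "mean_diff", "p_sidak")]
#>             comparison    mean_diff      p_sidak
#> 7 control1 vs control2 -0.005598071 0.9181548280
#> 8    control1 vs glued -0.034550763 0.0007262893
#> 9    control2 vs glued -0.028952692 0.0070919305
```

Sessions differ only where the effect was planted: D4–D5 overlap is
higher in the glued session than in either control (by ~0.03 Dice), the
two controls do not differ, and the glued digit pair D2–D3 shows nothing.

Externally supplied measurement tables (long CSV with `subject`,
`session`, `digit_pair`, `value`) can be analysed without any simulation
via `analyze_source_tables()`.

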