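---
title: "Methods: mismatch negativity, partialized connectivity and structure-function overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mismatch negativity, partialized connectivity and structure-function overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mmnpipe` implements the computational chain of a multi-deviant auditory
oddball (mismatch negativity, MMN) study in source-space MEG across
neurodegenerative syndromes: paradigm generation, evoked-response
quantification, frequency-resolved partialized connectivity with permutation
nulls, and voxelwise structure-function overlap statistics. Because the raw
MEG/MRI of such studies are not public, the package carries a synthetic
cohort generator with known ground truth; every downstream stage is tested
against that ground truth. This vignette explains the models, the defaults
and their units, the numerical choices, and what the synthetic validation
does and does not establish.

## The oddball paradigm

The Optimum-1 design alternates a standard tone with deviants drawn from five
dimensions (duration, intensity, frequency, laterality, gap), so that half of
all tones are deviants and each dimension appears equally often. The standard
is a 75-ms complex tone (harmonics 500/1000/1500 Hz, 7-ms raised-cosine
ramps, binaural); each deviant changes exactly one dimension: 25-ms duration,
±6 dB level, ±10 % frequency (fundamentals 550/450 Hz), monaural left/right,
or a 25-ms mid-tone gap.

`generate_sequence()` draws deviant dimensions in non-overlapping blocks of
five, each a uniform random permutation of the five dimensions, redrawing a
block whose first element repeats the previous block's last. This enforces
(i) no two consecutive deviants of the same dimension and (ii) every run of
five deviants covers all five dimensions — a block-wise reading of the
"each type at least once per 10 tones" rule; a sliding-window reading would
be stricter than needed to reproduce the printed counts and is not used.
Rejection sampling is bounded (1000 redraws per block) and deterministic per
block index, so sequences are pure functions of `(n_blocks, pairs_per_block,
seed)`.

Session arithmetic: published block durations, the 500-ms SOA and the
900/900/180 analysed-tone counts cannot all hold exactly at "5-minute"
blocks. We fix each block at 15 excluded block-initial standards plus 300
standard–deviant pairs (~5.1 min at 0.5 s SOA), which preserves every
printed count exactly: 900 analysed standards, 900 deviants, 180 per
dimension, 45 excluded standards. Absolute presentation level (dB HL) is
deliberately not modelled — hearing-level calibration is hardware-specific —
so intensities are relative dB offsets.

## Synthetic cohort generator

`simulation_config()` defaults encode the study conditions: five groups with
the published sizes (48 controls, 23 bvFTD, 10 nfvPPA, 15 PCA, 27 ADMCI) and
age distributions, source time series at 250 Hz epoched −100 to 500 ms for
the 8 network sources (bilateral A1, STG, IFG, IPC), and 150 trials per
condition (scaled down from the session's 180 per deviant dimension;
configurable).

**Evoked content.** Every trial carries an M100-like positive deflection
(Gaussian, peak at 100 ms, SD 20 ms, amplitude 1.5 a.u.) on the auditory
sources (A1 weight 1, STG weight 0.8). Deviant trials additionally carry a
negative half-sine deflection spanning 100–200 ms whose *window mean* equals
the subject's true MMN amplitude; the control amplitude is −1 a.u.,
attenuated per group by the configured fraction (defaults 0.45/0.35/0.55/0.5
for bvFTD/nfvPPA/PCA/ADMCI — all patient groups reduced, none abolished),
plus a between-subject SD of 0.15 a.u. Because only the MMN component is
attenuated, the generator reproduces the study's dissociation: group
differences in MMN coexisting with no group difference in M100.

**Induced content.** Per frequency band (oscillators at 6, 12, 25, 37,
62 Hz for θ/α/β/low-γ/high-γ), each source carries a unit-amplitude
sinusoid whose per-trial phase is coupled across sources: along each edge of
the coupling graph, φ_j = φ_i + lag + ε with ε von Mises. The concentration
is obtained by inverting A(κ) = I₁(κ)/I₀(κ) at the requested strength, so
the *expected PLV of a coupled edge equals the configured strength*
analytically. Edges are applied in table order as a spanning structure;
edges whose endpoints are both already assigned add no constraint (their
coupling is induced transitively). The default lag is 90° so that imaginary
coherence is sensitive to the injected coupling; zero-lag coupling is kept
available as a negative control, since the imaginary part of a real-valued
coherency vanishes. Amplitudes never depend on coupling, so groups that
differ only in coupling have identical expected power spectra — mirroring
the study's control that connectivity differences are not power differences.
White noise (SD 1 a.u.) is added; pink noise is deliberately omitted as the
simplest model satisfying the stationarity the connectivity stage assumes.
The default coupling table gives all 11 connections a 0.3 baseline in every
band, with +0.25 θ on the MD–auditory connections (STG–IPC, STG–IFG, both
sides) in the FTLD-pathology groups and +0.25 high-γ on the same connections
in the Alzheimer-pathology groups — the qualitative frequency-by-pathology
pattern the study reports.

**Structural maps.** Volumes live on a 24×28×24 grid of 4-mm voxels (small
enough for desk-scale voxelwise regression) inside an ellipsoidal mask.
Volume = 1 − group focal atrophy (Gaussian profiles at caricatured disease
loci, all placed *outside* the MD map cores) − `beta_struct` × (subject MMN
magnitude deficit) at voxels where the generative MD probability exceeds
0.5, + linear age (−0.002/yr) and TIV (2×10⁻⁴/ml) effects + voxel noise
(SD 0.02). `beta_struct` defaults to 0.08 volume units per amplitude unit.
The generative MD map and a control network map are smooth bilateral
Gaussian probability fields; the control map is the MD shape translated
posteriorly, with the translation chosen by brute-force search so the
Jaccard overlap of the 5 %-thresholded supports matches a requested value
(default 0.15).

One structural consequence of the generative design is worth flagging: the
MD-voxel deficit is driven by each subject's MMN amplitude, and group means
differ, so a patients-versus-controls volume contrast also recovers MD
voxels. The function-versus-structure dissociation (activation ratio well
above the structural control ratio) therefore emerges when within-group
amplitude variation carries the structure-function signal — as in the
two-group recovery tests — and is deliberately not asserted for the
five-group group-contrast analysis, where the group-mean deficit is itself
a structural effect.

What the generator does *not* emulate: 1/f background spectra, source
leakage/field spread, nonstationarity, registration error, and realistic
VBM covariance. Passing the recovery suites therefore shows that the
estimators are correct and calibrated under their stated assumptions, not
that they are robust to every property of real MEG/MRI data.

## Evoked analysis

Epochs span −100 to 500 ms (151 samples at 250 Hz, both endpoints included;
windows are closed intervals converted to samples with rounding toward the
interior) and are baseline-corrected by subtracting the mean of
[−100, 0) ms. Filtering is zero-phase (forward–backward) Butterworth,
4th order per pass: low-pass at 100 Hz then band-stop 48–52 Hz.

Robust averaging is an iteratively reweighted mean per time point across
trials with Tukey bisquare weights: median start, scale 1.4826×MAD of the
residuals, tuning constant 4.685 (the conventional 95 %-efficiency value),
at most 20 iterations, relative tolerance 10⁻⁶. The original algorithm is
cited in the MEG literature only by name, so these constants are exposed as
arguments rather than assumed; identical trials reproduce the arithmetic
mean exactly, and a time point whose trials are all rejected falls back to
the median and is counted. The averaged waveforms are then low-pass filtered
again at 100 Hz, removing the high-frequency noise that per-timepoint
reweighting introduces.

MMN amplitude is the signed mean of the deviant-average minus
standard-average waveform in left A1 over 100–200 ms; the M100 control is
the peak-deflection magnitude of the standard response in 50–150 ms. Group
statistics use a one-way ANOVA on amplitude, pairwise Welch post hoc tests
with Holm correction (a distribution-free replacement for Tukey–Kramer — a
documented deviation chosen to avoid equal-variance assumptions), and
per-timepoint Welch tests against controls with Benjamini–Hochberg FDR
across time points. Statistics use signed amplitudes throughout; "reduced
MMN" means reduced magnitude of the negative amplitude.

## Partialized connectivity

Induced activity is obtained by subtracting each condition's trial-averaged
waveform from every trial (per source), making the cross-trial mean exactly
zero. Multitaper Fourier coefficients are computed over 0–500 ms (or
0–250 ms for the MMN-focused variant) with a ±4-Hz smoothing box; the taper
count is K = 2TW − 1 (3 tapers for the 0.5-s window, 1 for 0.25 s). Slepian
sequences are computed from the standard symmetric tridiagonal eigenproblem.

The partialization formula is the classical matrix-inversion construction:
with C(f) the cross-spectral matrix averaged over trials and tapers and
P = (C + λI)⁻¹, the partial coherency is K_ij = −P_ij/√(P_ii P_jj). Partial
imaginary coherence is |Im K_ij|; for the partial phase-locking value the
coefficients are first normalized to unit modulus (phase-only) and the same
machinery applied, giving |K_ij|; both are clipped to [0, 1]. The ridge
λ = 10⁻⁸ × mean diagonal is added unconditionally — small enough to leave a
perfectly locked two-source pair at 1 within 10⁻⁶, large enough to keep the
inversion defined. With two sources the construction reduces algebraically
to the classical PLV / |Im coherence|, which the tests exploit as an
independent oracle. Connectivity values are averaged within θ (4–8), α
(8–20, as printed in the source literature, wider than the conventional α),
β (20–30), low-γ (30–45) and high-γ (55–70 Hz); band edges are half-open
[low, high) to resolve the shared 8- and 20-Hz edges, the top band closed at
70, and no band covers the 45–55 Hz line-noise guard.

The permutation null shuffles trial identities independently per source —
including the partialization sources, the conservative reading of
trial-identity shuffling — destroying cross-trial phase alignment while
preserving every marginal spectrum exactly, and recomputes the full
partialized pipeline per iteration (default 100 per subject; per-iteration
seeds derived from a master seed by counter splitting). Group comparison
follows the study's two decision rules: (i) per band, the 11 observed
control-minus-patient connection differences are compared against the
pooled null differences (11 × 100 = 1100 values per band, built by pairing
iteration i across subjects) with a two-sided Welch t test — pooling the 11
connection differences, not subject-level values, matching the printed null
pool size; (ii) a connection is flagged when its observed difference lies
strictly outside the entire range of its per-connection null values, which
for nulls pooled across the configured groups corresponds to a small
permutation p after Bonferroni correction across the five bands.

## Structure-function overlap

The mass-univariate GLM regresses voxel volume on MMN *magnitude* (the
negated signed amplitude, so that "smaller MMN with less volume" appears as
a positive t; the sign convention is configurable) with age and TIV as
covariates, in four designs: all subjects, patients only, and fixed-effect
group-adjusted designs with 2 or 5 group levels. The grouped designs stand
in for the study's "linear mixed models", which are themselves fitted
mass-univariately; true random-effects estimation is out of scope.
Zero-variance voxels are excluded from the mask before fitting and counted.
Maps are thresholded at uncorrected p < 0.001 with t > 0; no familywise or
cluster correction is implemented because the overlap analyses use only the
uncorrected threshold.

Two overlap statistics are computed against probabilistic network maps
(resliced by nearest-neighbour regridding when grids differ; synthetic maps
share a grid): the **overlap proportion**, the fraction of surviving
structure-function voxels inside the network support thresholded at 5 %;
and the **normalized activation ratio**,

$$\mathrm{ratio} = \frac{\sum_v t_v\,p_v \times |\mathrm{mask}|}{\sum_v t_v \times \sum_v p_v},$$

with t the thresholded t map (zeros off the surviving set), p the
*unthresholded* probability map, and sums over the analysis mask. The
printed equation is typographically ambiguous about whether sums run over
the mask or the thresholded support; we sum over the mask, where zeros
outside the support contribute nothing to the numerator, and flag rather
than guess the authorial intent. The ratio is 1 for maps constant over the
mask and invariant to positive rescaling of either map. The **structural
control ratio** applies the same formula to an atrophy-only t map
(patients-vs-controls volume contrast, atrophy positive), quantifying how
much of the apparent network selectivity a pure atrophy pattern would
produce.

## Problem sizes and test design

The published headline values (overlap percentages, activation ratios,
group F statistics) depend on the unreleased study data and external
published maps, so the validation suite instead checks exact structural
numbers (tone counts, null-pool sizes, taper counts) and statistical
properties against the generator's ground truth. Stochastic suites fix
their problem sizes as the package's own choices: calibration of the
per-band Welch permutation test uses 100 seeds of a 2×5-subject no-coupling
cohort with 8 trials per condition; pattern recovery uses 100 seeds of
2×15 subjects with θ coupling of 0.3 on the MD-auditory connections in the
patient group; MMN/M100 recovery uses 5 groups × 6 subjects with 15 trials
per condition; chain-partialization checks use 20 seeds of a 3-source
chain with moderate (0.6) edge coupling, where the partial estimator's
variance stays comparable to the shuffle null (at strong coupling it
inflates by 1/(1-ρ²)² and the strict null comparison becomes
uninformative). Tolerances come from binomial confidence bounds at the nominal
levels or from standard errors computed within the simulation, never from
the observed values themselves.

Two design points in the connectivity validation deserve explanation.
First, the per-band Welch statistic pools the 11 observed connection
differences, so an effect confined to 4 of 11 connections bounds the t
statistic near 2.4 even with noiseless estimates (the mean is diluted
while the connection-wise spread reflects the 4-versus-7 pattern); the
Welch test's power case is therefore a band-wide coupling shift, tested
separately, while the connection-specific injection is validated through
the outside-null flag rule it is designed to detect. Second, the strict
outside-range flag rule is anticonservative when the background itself is
coupled: the PLV estimator's sampling variance at nonzero coupling is
roughly 2.4× its variance under trial shuffling, so with a coupled
background an uninjected band collects a chance flag in a material
fraction of small cohorts regardless of trial count. The pattern-recovery
suite therefore injects the θ effect over a coupling-free background — the
controlled experiment for the flag rule — and pools the per-connection
null to 400 values (via cyclic re-pairing of exchangeable iterations, the
two-group analogue of pooling across four group comparisons as the
multi-group analysis does).

Numerical details worth knowing: multitaper PLV at a bin centred exactly on
an oscillator's frequency is diluted by the higher-order tapers (odd
Slepians have a spectral null at the band centre), so band-averaged absolute
PLV underestimates the injected edge strength; all decision rules compare
groups or compare against nulls, and are unaffected. Degenerate inputs fail
fast and by name: missing conditions, singular cross-spectral matrices
(reported with the offending frequency), collinear design columns, empty
thresholded maps, empty bands.
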