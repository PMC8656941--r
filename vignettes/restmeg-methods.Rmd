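---
title: "Methods and design notes for restmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for restmeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`restmeg` implements a complete resting-state MEG analysis chain — beamformer
source reconstruction, automatic epoch selection, periodogram spectral
features, leakage-corrected amplitude-envelope connectivity, covariate-adjusted
group statistics, and partial least squares correlation (PLSC) against
cognitive variables — together with a synthetic-data module that plants
recoverable ground truth for all of it. This vignette records the models, the
tunable parameters, and the design decisions that were genuinely open, so that
a maintainer can see why the code is the way it is.

## Signal model and spectral analysis

Source signals are treated as region-by-time real matrices at a known sampling
rate (1,250 Hz in the acquisition this pipeline targets; any rate above twice
the top analysis frequency works). Spectral analysis uses the raw
(rectangular-window) periodogram per epoch, not Welch averaging within an
epoch: epochs themselves are the averaging unit, and the per-epoch estimates
are averaged per subject. The analysis range is 0.5–48 Hz, tiled by six bands:
delta 0.5–4, theta 4–8, alpha1 8–10, alpha2 10–13, beta 13–30, gamma
30–48 Hz.

**Band integration convention.** Band power is the rectangle-rule sum of the
one-sided PSD over the frequency bins belonging to the band, with membership
`(f_lo, f_hi]` (the first band also owns its lower edge). Each analysis-range
bin belongs to exactly one band, so relative band powers sum to one *exactly*
and a bin-aligned tone at a shared edge (for example 10 Hz) falls wholly into
the lower band rather than being split. A trapezoidal rule was considered and
rejected: it halves shared-edge bins across two bands, so a pure edge tone
could never reach a relative power of one and double counting has to be
patched case by case. The rectangle rule makes Parseval hold at the bin level:
the 0.5–48 Hz integral of the periodogram equals the variance of a signal
band-limited inside that range to better than 1%.

**Individual peak frequency (IPF)** is the argmax of the occipital-average
PSD, averaged over epochs *before* peak picking (not the average of per-epoch
argmaxes, which is noisier and biased for skewed peaks), restricted to
4–13 Hz. A peak on the search boundary is returned with a warning, since a
monotone spectrum has no genuine peak.

## Filtering and envelopes

Band-pass filtering is two-pass (forward and time-reversed) with a symmetric
least-squares FIR filter, so phase distortion is identically zero. The filter
is the least-squares fit, over the *whole* frequency axis, to a band-pass
target whose edges are smoothed by a triangular spline of width 1 Hz; because
the target has no don't-care regions the optimum is a truncated Fourier
series with a closed form, making multi-thousand-tap designs free. The two
passes are computed as a single FFT convolution with the filter's
autocorrelation.

**Filter order.** The order is
`min(floor(len/3), max(3·fs/f_lo, 4·fs/tw))` with transition width `tw = 1` Hz.
The `3·fs/f_lo` term is the usual three-cycles-of-the-lowest-frequency rule;
the `4·fs/tw` floor exists because the contract this module promises —
stop-band attenuation above 20 dB at 1 Hz beyond the band edges — is
unreachable with the cycles rule alone for high-`f_lo` bands (alpha1 at
1,250 Hz would get 469 taps and a ~2.7 Hz transition). The cap at a third of
the signal length bounds the edge transients; the first and last `order`
envelope samples of every epoch are discarded before any correlation, which
always leaves at least a third of the epoch.

The analytic signal is computed in the frequency domain (positive frequencies
doubled, negative zeroed); the amplitude envelope is its magnitude. Envelopes
are correlated raw — not log-transformed, not low-pass filtered, not
downsampled.

## Corrected amplitude envelope correlation (AECc)

For every ordered region pair within an epoch, the band-passed target signal
is orthogonalized against the reference in the time domain
(`y⊥x = y − (⟨y,x⟩/⟨x,x⟩)x`), which removes the zero-lag (instantaneous
leakage) component; the Pearson correlation of the envelopes is computed in
both directions and averaged; the directed matrix is symmetrized by averaging
its upper and lower triangles and then averaged over the 8 selected epochs.
The orthogonalization is per epoch and per direction. A collinear pair (the
residual variance below 1e-12 of the target's) is pure zero-lag coupling and
scores 0 — leakage carries no corrected connectivity by definition. A
numerically constant envelope (coefficient of variation at machine level)
makes the correlation undefined; it is scored 0 with a warning.

The all-pairs implementation exploits the linearity of the analytic
transform: `env(y − βx) = |A_y − βA_x|` with per-region analytic signals
precomputed, so no per-pair FFT is needed; the unit tests pin this fast path
to the literal filter-orthogonalize-envelope-correlate recomputation at
1e-10.

**What leakage correction can and cannot do.** Orthogonalization nulls the
correlation a *null* pair acquires through instantaneous mixing — the tests
show uncorrected envelope correlation inflating under mixing while AECc stays
near zero. Two limitations are worth knowing. First, when the two *coupled*
sources mix directly and bidirectionally with comparable strength, the
single regression coefficient over-corrects and leaves a residual leak of
order `β − ε`; pairwise orthogonalization assumes the leakage between the two
signals being compared is not itself large and mutual. Second, third-party
leakage (in-band signal from other regions mixed into a coupled region) is
incoherent with both members of the pair and therefore is not removed; it
acts as envelope noise and attenuates the estimated coupling
multiplicatively. Both effects are properties of the estimator, not bugs;
the synthetic leakage tests therefore couple spatially non-adjacent regions,
as genuinely distinct cortical sources would be.

## Beamformer

The scalar minimum-variance beamformer takes fixed-orientation lead fields as
given (no head model, orientation search, or depth weighting — those belong
to the acquisition side). The covariance is estimated from the full recording
after 0.5–48 Hz filtering. The paper-grade formulation leaves the
regularization unstated; the default is diagonal loading with λ = 0.05 of the
mean sensor variance, a common choice that keeps the solve well-posed at
finite samples, and the unit-gain constraint `wᵀl = 1` is verified to 1e-9 in
the tests regardless of λ.

## Epoch scoring and selection

Candidate epochs are consecutive, non-overlapping 16,384-sample windows
(13.1 s at 1,250 Hz) from the start of the recording; the remainder is
dropped. Three rejection rules, in priority order:

- **Amplitude**: peak |z| above 6, where z uses the per-region median and MAD
  of the *whole recording* — scale-free, robust to the artifacts it is meant
  to catch, and not diluted by the artifact itself the way a per-epoch SD
  would be.
- **IPF outlier**: epoch peak frequency outside median ± 3 MAD of the
  subject's candidate epochs.
- **Low occipital alpha1** (drowsiness): below the subject's own 25th
  percentile. Drowsiness is a within-subject phenomenon, so the threshold is
  relative to the subject's recording, not a fixed power.

Survivors are ranked by the *sum of ranks* of epoch IPF and occipital alpha1
power (the two stated criteria, equally weighted — the source methodology
names both but not their combination; rank-sum is monotone in each and
scale-free), the top 8 are kept with earlier start index breaking ties, and
the output is chronological. Selection is deterministic and invariant to
candidate order. Fewer than 8 survivors raises a subject-exclusion error
(class `restmeg_subject_exclusion`), mirroring cohort-level exclusion for
unusable recordings.

## Group statistics

Group effects are tested by nested-model F (full: `y ~ group + covariates`;
reduced: without group), which for a binary group equals the squared t of the
group coefficient — the tests verify this identity numerically. Effect size
is Cohen's *d* between the groups' residuals from the covariate-only model,
pooled SD weighted by `n−1` per group; the sign convention is first factor
level minus second and is reported alongside the value. FDR control is
Benjamini–Hochberg step-up via `stats::p.adjust` plus an explicit rejection
scan; the test suite pins it to an independently coded step-up oracle on a
thousand random vectors. Spearman correlations use midranks with pairwise
deletion (at least 4 complete pairs per cell) and the t approximation for p.

Regional effect sizes aggregate into the seven canonical resting-state
networks (VIS, SM, DA, VA, FP, DMN, LIM) by majority vote over a supplied
label-count table, ties broken by the fixed network order and flagged. The
percentage contribution of a network is the sum of |d| over its significant
regions divided by the sum over all significant regions. Absolute values are
used deliberately: single-band effect maps are typically one-signed, but the
statistic must stay well-defined when signs mix, and |d| keeps it invariant
to uniform rescaling.

CAQ composites: cCAQ is the mean item response at current age, pCAQ the mean
over ages 6, 12, 18 and 40; missing items are dropped from the means with
counts recorded.

## PLSC

Both blocks are z-scored per column before the cross-product, so the
decomposed matrix is a cross-*correlation* matrix. This is deliberate: the
blocks mix units (Hz, points, seconds, years), loadings are themselves
defined as correlations, and unscaled covariance would let high-variance
columns dominate the saliences. The SVD gives block-wise orthonormal salience
pairs; latent scores are projections of the standardized blocks; loadings are
correlations of the original columns with their own block's scores; r² per
component is the squared correlation of the paired latent scores.

- **Permutation test**: rows of the cognitive block permuted, rank-matched
  singular values compared, `p = (1 + #exceed)/(1 + N)`, FDR over components.
  No Procrustes rotation is applied to the permuted decompositions — the
  rank-matched statistic is the simplest defensible choice and calibrates
  correctly (the permutation p-value is uniform under independence by a
  Kolmogorov–Smirnov check over 200 replicate datasets).
- **Bootstrap**: paired rows resampled with replacement; each resample's
  components are aligned to the original by maximal absolute inner product
  of the stacked saliences with sign matching; the standard score of a
  loading is the original loading divided by its bootstrap SD (the
  bootstrap-ratio convention — the alternative mean/SD standardization is a
  one-line change but bootstrap-ratio is the standard in the PLSC
  literature); |z| > 3 is deemed reliable, with zero-variance loadings capped
  at |z| = 100. Degenerate resamples (a constant column) are skipped and
  counted.
- **Imputation**: 4-nearest-neighbour, done once on the cognitive block
  before PLSC and not re-done inside resamples, matching the stated order of
  operations. Distance is Euclidean over z-scored mutually observed
  variables; neighbours must observe the target variable; distance ties break
  by row order so the result is deterministic.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets: two
groups of 35 and 11 subjects, 80 regions, 1,250 Hz, 300 s, 16,384-sample
epochs; occipital peak frequencies 9.1 ± 0.8 Hz (CN) and 8.7 ± 0.3 Hz (CI);
per-group band-fraction maps chosen so that the between-group theta contrast
is a standardized +1.15 and the beta contrast −1.23 at the default
between-subject fraction jitter of 0.05 — the magnitudes of spectral slowing
the pipeline is built to detect. Demographics follow the same cohort
geometry (ages ~92 ± 2; 19/35 vs 1/11 women).

Each region is a sum of band-limited components: white noise passed through
the same least-squares FIR used by the connectivity module (one filter
dialect everywhere), scaled to the subject's planted fractions. Components
are confined to their band with a small inset guard margin (≤ 0.5 Hz):
without it, neighbour-band noise enters the analysis filters through their
transition bands and both blurs planted fractions and swamps planted envelope
coupling. Occipital regions replace their peak band's noise with an
amplitude-modulated sinusoid at exactly the planted IPF (shallow modulation,
so the sidebands stay in-band and the spectral peak is sharp).

**Envelope coupling** multiplies two constant-envelope in-band carriers
(sinusoids at distinct random frequencies) by correlated lognormal slow
envelopes `exp(depth·g)`, where `g` are Gaussian processes with 4 Hz knots.
Lognormal envelopes are always positive, bursty like real band-limited
amplitude dynamics, and give a closed form
`corr(E₁,E₂) = (exp(ρs²)−1)/(exp(s²)−1)`, which is inverted so the requested
strength *is* the planted envelope correlation. Constant-envelope carriers
matter: broadband carriers would contribute Rayleigh-distributed envelope
fluctuations of their own and attenuate the recoverable correlation by a
factor of ~2 at typical modulation depths, making recovery criteria
ill-posed. The modulation depth defaults to 1 so the planted envelope
variance dominates leakage-induced envelope noise.

**Leakage** is instantaneous symmetric nearest-neighbour mixing `I + εM`,
with `M` the row-normalized chain adjacency (entries 0.5), so ε is the total
leaked amplitude fraction per region — exactly the zero-lag confound AECc is
designed to remove, with no lag structure. **Artifacts** are ±8 robust-SD
half-sine transients of 100 ms in a random region; **drowsiness** halves the
occipital alpha amplitude (the IPF oscillation plus the occipital alpha1
broadband component) for a whole epoch. Both magnitudes are chosen for
separability by the epoch selector, since the acquisition-side thresholds
they emulate are not published.

**Cohort tables** draw cognitive scores as linear functions of named planted
brain features plus Gaussian noise (MMSE and CERAD decreasing in theta
fraction, fluency increasing in beta, TMT-B tied to IPF, CAQ composites tied
to beta/alpha1, education correlated with past cognitive activity), with CAQ
item grids (six activities × ages 6/12/18/40/current, integer responses 1–5)
generated around the latent activity levels, and missingness inserted at a
configurable rate with a recorded mask.

**What the generator does not emulate**: volume-conduction physics beyond
instantaneous mixing, 1/f aperiodic background, non-Gaussian or non-stationary
noise beyond the planted artifacts, phase coupling, and any MRI anatomy.
Passing tests therefore demonstrate the *estimators* are correct and
calibrated on data matching their assumptions — not that real MEG meets those
assumptions.

## Problem sizes and determinism

The test suite and the acceptance script run the generator at reduced scale —
typically 4–8 regions, 250 Hz, 2,048-sample epochs and ~170 s recordings,
which preserves the 20-candidate/8-selected epoch geometry of the full
acquisition while keeping a full run to a couple of minutes; statistical
calibration (type-I error, FDR, effect-size recovery, PLSC permutation
uniformity) runs at the real cohort design of 35 + 11 subjects, where model
fits are cheap. The end-to-end synthetic study reproduces single-cohort
behaviour honestly: at n = 46 the sampling SD of a Cohen's d near 1 is about
0.37, so recovered study-level effect sizes scatter around the planted
values exactly as a real cohort's would.

Every stochastic function takes a seed; the pipeline fans one master seed out
to fixed per-stage streams, so any stage re-run in isolation reproduces its
in-pipeline result, and identical configuration plus seed yields a
bit-identical results bundle (the manifest records the configuration hash).

## Containers and shapes

Recordings, epoch sets and connectivity matrices are matrix-based S3 objects
(as in any time-series package); everything tabular — cohort tables, group
tests, Spearman grids, PLSC loadings, summaries — is a tibble, and every
result type has `tidy()`/`glance()`/`autoplot()` methods, so the analysis
composes with dplyr/ggplot2 idiom. On-disk interchange is plain text: CSV for
matrices and tables (17-significant-digit round-trip), JSON for metadata and
manifests.
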