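# restmeg

Resting-state MEG analysis for cohort studies: source-level spectral
features, leakage-corrected amplitude-envelope connectivity, and
brain–cognition statistics, with a synthetic-data module that makes the
whole pipeline testable end to end.

## The scientific problem

Cortical oscillations slow down in cognitive impairment: relative power
shifts from the beta band toward theta, and the posterior alpha peak drifts
lower. Resting-state MEG can quantify this at the level of individual
cortical regions, and relate spectral and connectivity features to
cognition and cognitive reserve. `restmeg` implements the full analysis
chain such a study needs:

- **Source reconstruction** — a scalar minimum-variance (LCMV-type)
  beamformer. Filter weights for a source with lead field *l* are
  `w = C⁻¹l / (lᵀC⁻¹l)`, where `C` is the broadband (0.5–48 Hz) sensor
  covariance with diagonal loading `C + λ·mean(diag C)·I`; the constraint
  `wᵀl = 1` (unit gain) holds exactly.
- **Epoch selection** — recordings are cut into 16,384-sample epochs
  (13.1 s at 1,250 Hz); epochs with amplitude artifacts (robust |z| > 6),
  outlying epoch peak frequency (median ± 3 MAD), or low occipital alpha1
  power (lowest within-subject quartile, a drowsiness marker) are rejected,
  and the 8 epochs with the highest combined peak frequency and occipital
  alpha1 rank are kept.
- **Spectral features** — raw periodogram PSDs; relative band power (RBP)
  in delta (0.5–4 Hz), theta (4–8), alpha1 (8–10), alpha2 (10–13), beta
  (13–30) and gamma (30–48), i.e. band-integrated PSD normalized by total
  0.5–48 Hz power; and the individual peak frequency (IPF), the maximum of
  the occipital-average PSD in 4–13 Hz.
- **Connectivity** — the corrected amplitude envelope correlation (AECc):
  band-pass (two-pass least-squares FIR, zero phase), pairwise
  orthogonalization in the time domain to remove zero-lag leakage
  (`y⊥x = y − (⟨y,x⟩/⟨x,x⟩)x`), Hilbert envelopes, Pearson correlation,
  averaged over both orthogonalization directions and over epochs.
- **Group statistics** — ANCOVA (nested-GLM F-tests) with age and gender
  covariates, Cohen's *d* between covariate-adjusted residual
  distributions, Benjamini–Hochberg FDR, Spearman correlation grids, and
  aggregation of regional effect sizes into the seven canonical
  resting-state networks by majority-vote labelling.
- **PLSC** — partial least squares correlation between a brain block (six
  whole-brain RBPs + IPF, or connectivity summaries) and a cognitive block
  (MMSE, letter fluency, TMT-B, CERAD, cCAQ/pCAQ cognitive-activity
  composites, education, age): SVD of the cross-block correlation matrix,
  permutation tests on the singular values (p = (1+#exceed)/(1+N), FDR
  over components), bootstrap standard scores for loadings (|z| > 3
  reliable), and 4-nearest-neighbour imputation of missing cognitive
  scores.

Because raw cohort data of this kind are rarely shareable, the package
ships a **synthetic-data generator** (`simulate_sources()`,
`simulate_cohort()`, `simulate_forward()`) that plants recoverable ground
truth: per-group band-power fractions, subject peak frequencies, envelope
coupling with a closed-form planted correlation, instantaneous mixing
(leakage), artifact and drowsiness epochs, and cognitive scores linearly
tied to brain features. Every stage of the pipeline is tested against this
truth.

## Worked example

A small synthetic study (20 cognitively normal, 10 impaired subjects, 6
regions, ~3 minutes of signal at 250 Hz) run end to end:

```r
library(restmeg)

spec <- sim_spec(
  n_subjects_per_group = c(CN = 20L, CI = 10L), n_regions = 6L,
  fs = 250, duration = 170, epoch_len = 2048L, seed = 42L
)
cfg <- pipeline_config(sim = spec, connectivity_bands = "beta",
                       n_perm = 500L, n_boot = 200L, seed = 42L)
bundle <- run_pipeline(cfg)

bundle$group_tests[, c("feature", "F", "p", "cohens_d", "p_adj", "significant")]
#>   feature         F      p cohens_d p_adj significant
#> 1 delta_rbp  0.0128 0.911    0.0426 0.911 FALSE
#> 2 theta_rbp  4.26   0.0491   0.770  0.196 FALSE
#> 5 beta_rbp   5.80   0.0234  -0.895  0.188 FALSE
#> 7 ipf        1.44   0.241   -0.451  0.462 FALSE
#> ...

glance(bundle$plsc)
#>   component singular_value r_squared       p   p_fdr significant
#> 1         1          1.93      0.825 0.00200 0.00699 TRUE
#> 2         2          1.05      0.499 0.00998 0.0175  TRUE
#> ...

dplyr::filter(tidy(bundle$plsc), component == 1, reliable)
#>   block     variable  component salience loading boot_z reliable
#> 1 brain     theta_rbp         1   -0.740  -0.884 -12.2  TRUE
#> 2 cognitive MMSE              1    0.549   0.859   9.34 TRUE
#> 3 cognitive CERAD             1    0.571   0.909  12.0  TRUE
#> 4 cognitive cCAQ              1    0.429   0.600   3.20 TRUE
```

The generator plants cortical slowing in the impaired group (theta up,
*d* ≈ +1.15; beta down, *d* ≈ −1.23) and cognitive scores that depend on
it. In this run the per-feature ANCOVAs show the planted contrast with the
planted signs (theta *d* = +0.77, beta *d* = −0.90; at 30 subjects the
single-feature tests do not survive FDR — effect-size estimates at this
sample size carry a sampling SD of ~0.4), while the first PLSC pattern is
highly significant (p = 0.002, r² = 0.83) and its reliable loadings link
higher theta power to lower MMSE, CERAD and current cognitive activity —
the slowing–cognition pattern the pipeline is designed to detect.

`autoplot()` methods render spectral profiles, connectivity matrices,
Spearman grids and PLSC loading plots; `tidy()`/`glance()` turn every
result object into a tibble.

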