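---
title: "Beamformer source reconstruction and phase-lag connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamformer source reconstruction and phase-lag connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megpli)
```

# The problem

MEG sensors record a linear mixture of all active neuronal sources: a single
dipolar source contributes to many channels (field spread), and after any
linear inverse it also contributes to many reconstructed locations. Any
connectivity estimator that rewards zero-lag co-variation — coherence, phase
coherence, envelope correlation without leakage correction — therefore
reports spurious coupling between regions that merely share a mixed signal.
`megpli` implements an analysis chain designed around that problem:

1. reconstruct one time-series per region of interest (ROI) with a scalar
   minimum-variance beamformer, which suppresses (but cannot eliminate)
   cross-talk between locations;
2. quantify coupling with the Phase Lag Index (PLI), which is blind to
   exactly the zero-lag interactions that mixing creates, alongside the
   classical Phase Coherence (PC) as the mixing-sensitive reference;
3. assess significance of per-ROI mean connectivity (node strength) against
   a phase-randomised surrogate null with max-statistic family-wise
   control.

# Source model and beamformer

## Forward model

The head is a single homogeneous conducting sphere. For MEG this model has
a closed-form magnetic field for a current dipole, and two structural
properties the rest of the chain relies on: a radially oriented dipole
produces no external field, so only the two tangential moment components
are estimated per location (`tangentialBasis()`, `leadField()`); and the
radial field component outside the conductor equals that of the primary
current alone, which the test suite exploits as an independent Biot–Savart
oracle. Units are SI throughout: positions in metres, fields in Tesla,
dipole moments in nAm, beamformer weights in nAm/T.

A multi-shell or realistic conductor would change none of the downstream
equations — the beamformer consumes whatever lead field it is given — but a
sphere is the natural choice for fully synthetic data, where no anatomy
exists to fit a more detailed model to.

## Spatial filtering

For a location with tangential lead field $L$ ($N \times 2$) and
band-limited data covariance $C_b$, the source variance along orientation
$\theta$ is

$$\sigma_\theta^2 = \left(L_\theta^\top C_b^{-1} L_\theta\right)^{-1},$$

the unit-gain weights are $W = \sigma_\theta^2 L_\theta^\top C_b^{-1}$
(so $W L_\theta = 1$ and $W C_b W^\top = \sigma_\theta^2$), and the
reconstructed "virtual electrode" is $V = W B$ for sensor data $B$. The
orientation is the tangential direction maximising the pseudo-Z ratio
$(W C_b W^\top)/(W \Sigma W^\top)$ with $\Sigma$ the sensor noise
covariance; this is solved in closed form as a $2 \times 2$ generalised
eigenproblem (`optimalOrientation()`), with a dense angular grid search
retained in the tests as a brute-force oracle. Source polarity is not
physically observable (a flipped orientation with negated amplitude gives
the same external field), so the sign is fixed by convention: the first
non-negligible orientation component is made positive.

Numerical choices:

* **Covariance inversion** uses a symmetric pseudo-inverse with relative
  eigenvalue truncation at `1e-12`. No Tikhonov regularisation is applied
  by default; `regularize = lambda` adds `lambda * trace(C)/N` to the
  diagonal for users who want the smoother, lower-resolution solution.
* **Noise covariance** defaults to white noise at the smallest eigenvalue
  of the data covariance — the noise floor visible in the quietest spatial
  component. It is overridable (`Sigma =`) for systems where an empty-room
  estimate exists.
* **Covariance band**: weights are computed from broadband (0.5–48 Hz)
  data. Narrowband covariance windows carry fewer effective samples and
  correspondingly noisier weights; `covarianceWindowBias()` quantifies the
  resulting downward bias in power estimates for the worst case (3.5 Hz
  bandwidth, 175 s window) and is the basis of the acceptance report.
* **Channel mean** is removed both before and after filtering in
  `computeCovariance()`; a DC offset would otherwise excite an edge
  transient in the zero-phase filter.
* **Degenerate geometry** (source at the sphere center, rank-deficient
  lead field, all-zero weights) raises errors rather than propagating
  non-finite values.

## Depth normalisation

Minimum-variance weights grow with source depth while sensor noise is
constant, so raw virtual electrodes have depth-dependent noise. Each weight
vector is divided by its norm before time-series reconstruction
(`normalizeWeights()`, applied inside `extractROISeries()`). This rescales
each series by a positive constant — irrelevant to every phase-based
quantity — and equalises projected white noise exactly across depth. The
pseudo-Z used for orientation selection is scale-invariant, so the order
(optimise orientation on raw weights, normalise afterwards) does not affect
the result.

# ROI time-series

A parcellation assigns every source-space voxel to exactly one ROI. The
spectrum of every voxel's virtual electrode is split into the five
classical bands — delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–48 Hz — and, per ROI and band independently, the voxel with maximum
band power represents the ROI. Band power is the variance of the
band-passed series (equivalent to integrated PSD). Ties break to the lowest
voxel id. Voxel series are deliberately **not** averaged within a ROI: the
arbitrary per-voxel polarity makes averaging destructive. Voxel selection
operates on the norm-normalised series; because normalisation is a
per-voxel positive scale, this differs from selecting on unnormalised
series only through the depth-equalisation itself, which is intended.

Filtering is a 4th-order Butterworth applied forward and backward
(zero-phase; the pass runs in compiled code). Zero-phase filtering is
essential here: a causal filter would introduce frequency-dependent phase
shifts that a lag-sensitive estimator would score as connectivity. The
4th-order roll-off is gentle; a tone 2 Hz above the gamma edge is
attenuated about five-fold, not annihilated, and one octave outside a band
the attenuation exceeds 20 dB. Relative power is band power divided by
total 0.5–48 Hz power of the same (broadband) series; the five bands
nearly partition it, with a few percent lost to the roll-off.

# Connectivity estimators

Phases come from the analytic signal (frequency-domain Hilbert transform),
computed per 4096-sample epoch; phase differences are stored in
$[-\pi, \pi)$. For a phase-difference series $\Delta\phi(t_k)$, $k = 1
\dots S$:

$$\mathrm{PC} = \left|\frac{1}{S}\sum_k e^{i\Delta\phi(t_k)}\right|,
\qquad
\mathrm{PLI} = \left|\frac{1}{S}\sum_k \operatorname{sign}
\sin \Delta\phi(t_k)\right|.$$

PC is 1 iff the phase difference is constant — including a constant of
zero, which is what mixing produces. PLI is non-zero only when the
phase-difference distribution is asymmetric about 0 (and $\pi$): a
consistent non-zero lag. `sign(0) = 0`, so exactly-zero differences
contribute nothing. Both estimators ignore amplitude entirely. The
convention for the phase-difference interval ($[-\pi,\pi)$ here vs
$[0, 2\pi]$ elsewhere) changes neither estimator, and the modulus in both
definitions matches their stated $[0, 1]$ ranges.

Epochs are the first `n_epochs` non-overlapping windows of `epoch_length`
samples (defaults 5 × 4096; 13.1 s each at 312.5 Hz). Visual epoch
selection has no synthetic analogue, so deterministic segmentation is
used. Averaging is epoch-within-subject first, then across subjects, so
subjects with unequal epoch counts contribute equally; for balanced designs
this equals the pooled mean. Node strength is the off-diagonal row mean of
the adjacency matrix; `degreeThresholded()` additionally binarises at a
fraction (default 20%) of the maximum edge.

The headline methodological property — PC between *independent* simulated
sources correlates with the squared correlation between their beamformer
weight vectors (`weightCorrelationMatrix()`), while PLI does not — is
exercised in the acceptance suite over 20 simulation seeds.

# Surrogate statistics

Null data are built by phase-randomising every ROI series independently:
the Fourier amplitudes are kept bin-for-bin, positive-frequency phases are
replaced by uniform draws, Hermitian symmetry is enforced, and the DC and
Nyquist bins are untouched. This preserves each series' spectrum exactly
while destroying all cross-series coupling. No boundary-jump windowing is
applied; the analysis bands stay at or below 48 Hz, where the resulting
edge artefacts are immaterial. Surrogates are generated from the ROI
series; the beamforming and voxel-selection stages are not re-run per
realisation, since phase randomisation leaves the quantities those stages
depend on (spectra, power) unchanged by construction.

For each of `R` realisations (default 100) the connectivity chain is
re-run and the **maximum** group-mean node strength over ROIs is recorded.
P-values use the rank formula $p_i = (1 + \#\{\text{null} \ge s_i\})/(R+1)$,
which is strictly positive at finite `R`; comparing every ROI against the
null of the maximum controls the family-wise error across ROIs. One
structural property worth knowing: because surrogates inherit the
realisation's jagged periodogram (exponentially distributed bin power),
their effective phase-sample count is roughly half that of a fresh
independent signal, so the null is slightly wide and the test slightly
conservative. The calibration test measures the realised family-wise error
under a global null at about the nominal level or below.

`regressStrengthOnPower()` (OLS of node strength on relative power, F on
$(1, K-2)$ df) and `twoSampleBandContrast()` (pooled-variance t between
two bands' per-ROI values, $K_a + K_b - 2$ df) reproduce the group-level
descriptive analyses; both delegate to `lm()`/`t.test()` and are checked
against explicit textbook formulas in the tests.

# The synthetic-data generator

`simulateSources()` produces unit-variance Gaussian signals band-limited to
a carrier band, per dipole source. A coupling `(i, j, lag, strength)`
rebuilds source *j* as `strength` times the lag-shifted copy of source *i*
plus `(1 - strength)` times fresh same-band noise, restandardised; the lag
is applied by rotating the analytic signal, so at `strength = 1` the
instantaneous phase difference equals the requested lag at every sample.
`projectSources()` superposes the dipolar field patterns and adds white
Gaussian sensor noise. All stochastic steps take one integer seed and are
bit-reproducible.

Default study conditions, chosen once to emulate an eyes-closed
resting-state recording at desk scale:

| quantity | default | rationale |
|---|---|---|
| sampling rate | 312.5 Hz | classical whole-head acquisition rate |
| sensors | 150 radial magnetometers, hemispherical Fibonacci cap, r = 11 cm | echoes a 151-channel axial system |
| head sphere | r = 9 cm at the origin | adult head scale |
| dipole amplitude | 20 nAm | physiological cortical source strength |
| sensor noise | 50 fT (5e-14 T) per sample | sensor-level amplitude SNR ≈ 4–5, matching the regime assumed by the power-bias analysis |
| epochs | 5 × 4096 samples (13.1 s) | the connectivity windowing |
| surrogates | R = 100, α = 0.05 | the significance procedure |
| demo parcellation | 10 ROIs × 2 voxels, 8 mm grid | desk-scale stand-in for a 68-ROI atlas (68 supported) |

The leakage-dissociation fixture uses a denser parcellation (16 ROIs × 4
voxels at 5 mm) and heavier sensor noise (200 fT, in-band SNR ≈ 1.5–2):
field spread between ROI estimates is what that property measures, and it
requires regions close enough to share sensor patterns, with each region's
narrowband activity embedded in the summed background of all the others —
the regime an atlas covering a real brain is in.

What the generator does **not** emulate: 1/f background spectra,
non-stationarity, physiological artefacts (cardiac, ocular, muscle),
gradiometer geometries, realistic conductor shape, and co-registration
error. Passing tests therefore demonstrate the correctness and calibration
of the algorithms under the stated generative model, not robustness to
every property of empirical recordings.

# Problem sizes

The bundled demo and the test suite run at deliberately modest scale: tens
of sensors-to-150, 10–16 ROIs, 66 s recordings, R = 50–100 surrogates,
20-seed property loops. The covariance-window bias simulation is the one
deliberately large computation (150 channels × 1750 s at 312.5 Hz per
seed, 20 seeds); it is the quantity the acceptance script reports.

# Known limitations

* The beamformer assumes sources are linearly uncorrelated; strongly
  zero-lag-correlated sources partially cancel. PLI discards precisely
  those interactions, so the two blind spots coincide — by design, but
  both remain blind spots.
* PLI underestimates genuinely near-zero-lag physiological coupling and
  can underestimate clustering in networks dominated by short-range
  connections.
* The single-sphere forward model is adequate for synthetic data and
  algorithm validation, not for anatomically faithful localisation.
* With few surrogate realisations the smallest attainable p-value is
  `1/(R+1)`; R = 100 bounds it at ~0.0099.
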