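# megpli

Atlas-based MEG beamformer source reconstruction and phase-lag
connectivity, with surrogate-based significance testing.

## The problem

MEG sensors see a linear mixture of all active brain sources (volume
conduction / field spread), and every linear inverse spreads each source
over many reconstructed locations. Estimators that reward zero-lag
co-variation — coherence, phase coherence — therefore report spurious
"connectivity" between regions that merely share mixed signal. `megpli`
implements a pipeline that addresses this end to end:

* **Scalar minimum-variance beamformer** over an analytic spherical head
  model. For a target location with tangential lead field *L* and
  band-limited data covariance *C*, the source variance along orientation
  θ is σθ² = (Lθᵀ C⁻¹ Lθ)⁻¹, the unit-gain spatial filter is
  W = σθ² Lθᵀ C⁻¹, and θ maximises the pseudo-Z ratio
  (W C Wᵀ)/(W Σ Wᵀ) against the sensor noise covariance Σ (closed-form
  2×2 eigensolution). Weights are vector-norm normalised before
  time-series reconstruction to equalise projected noise across depth.
* **ROI time-series**: per ROI and per frequency band (delta 0.5–4,
  theta 4–8, alpha 8–13, beta 13–30, gamma 30–48 Hz), the voxel with
  maximum band power represents the ROI (no within-ROI averaging — voxel
  polarity is arbitrary).
* **Connectivity**: the Phase Lag Index
  PLI = |⟨sign sin Δφ(t)⟩| is non-zero only for a consistent *non-zero*
  phase lag, hence insensitive to mixing; Phase Coherence
  PC = |⟨e^{iΔφ(t)}⟩| is the mixing-sensitive reference estimator. Mean
  connectivity per ROI is the node strength (weighted degree).
* **Statistics**: phase-randomised surrogates (spectra preserved exactly,
  coupling destroyed) re-run through the connectivity chain; the maximum
  node strength over ROIs per realisation forms a null that controls the
  family-wise error across ROIs.

A seeded forward simulator (conducting-sphere dipoles, band-limited
coupled signals with planted phase lags, calibrated sensor noise) supplies
fully synthetic data for every test and the bundled demo.

## Worked example

The bundled demo config simulates one subject: 10 ROIs inside a spherical
head, one 20 nAm alpha-band dipole per ROI, phase-lag couplings planted
between ROIs 1–2 (lag π/4, strength 0.8) and 3–4 (lag π/3, strength 0.8),
projected to 150 sensors with 50 fT noise, then analysed end to end.

```r
library(megpli)
cfg <- jsonlite::read_json(system.file("extdata", "demo_config.json",
                                       package = "megpli"),
                           simplifyVector = TRUE)
cfg$sensors <- system.file("extdata", "sensors.tsv", package = "megpli")
cfg$parcellation <- system.file("extdata", "parcellation.tsv", package = "megpli")
res <- runPipeline(cfg, "demo_out")

round(adjacencyValues(res$adjacency$alpha$pli), 2)
pValues(res$stats$alpha$map)
```

Output from this run (group alpha-band PLI adjacency, abridged, and the
max-statistic p-values):

```
      ROI01 ROI02 ROI03 ROI04 ROI05 ...
ROI01  0.00  0.80  0.11  0.12  0.11
ROI02  0.80  0.00  0.24  0.05  0.11
ROI03  0.11  0.24  0.00  0.82  0.09
ROI04  0.12  0.05  0.82  0.00  0.13
ROI05  0.11  0.11  0.09  0.13  0.00

     ROI01      ROI02      ROI03      ROI04      ROI05      ROI06      ROI07
0.00990099 0.00990099 0.00990099 0.00990099 0.99009901 0.00990099 0.00990099
     ROI08      ROI09      ROI10
1.00000000 1.00000000 0.95049505
```

The planted pairs carry by far the strongest edges (PLI 0.80 and 0.82
against an uncoupled background around 0.1), and all four coupled ROIs are
significant at the smallest attainable p (1/101 with R = 100). Two
additional ROIs (6 and 7) also reach significance: they sit close enough
to the coupled sources that their virtual electrodes sample lagged
mixtures — field spread of a *lagged* pair creates genuinely lagged
third-party coupling, which PLI correctly scores and which localised
significance maps of this kind inherit. The far ROIs (5, 8–10) stay null.
`demo_out/` contains the group adjacency
matrices (TSV), `results.json` (strengths, p-values, significance flags)
and `provenance.json` (config hash, seeds, per-stage timing, output
digests — rerunning with the same config and seed reproduces identical
digests).

The same stages are scriptable from a shell via `exec/megpli`
(`simulate`, `beamform`, `roi-extract`, `connectivity`, `surrogates`,
`pipeline`).

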