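# Full forward-inverse analysis chains used by the calibration and
# dissociation tests.

# Independent-source run: K narrowband sources at ROI centroids, projected,
# beamformed and reduced to alpha-band ROI series; returns the per-pair
# epoch-averaged PLI and PC plus the squared weight correlation of the
# chosen voxels.
dissociationRun <- function(seed, K = 16, voxelsPerRoi = 4, spacing = 5,
                            nSensors = 100, noiseSd = 2e-13,
                            couplings = NULL) {
  hm <- testHead()
  sens <- makeSensorCap(nSensors)
  parc <- makeToyParcellation(hm, K = K, voxelsPerRoi = voxelsPerRoi,
                              spacing = spacing, seed = seed)
  srcs <- lapply(roiLabels(parc), function(l) {
    ctr <- colMeans(parc@positions[parc@voxelLabels == l, , drop = FALSE])
    dipoleSource(hm, ctr)
  })
  prs <- if (is.null(couplings))
    data.frame(i = integer(), j = integer(), lag = numeric(),
               strength = numeric())
  else couplings
  cs <- couplingSpec(prs, carrierBand = c(8, 13))
  sig <- simulateSources(srcs, cs, 66, 312.5, seed = seed)
  rec <- projectSources(hm, sens, srcs, sig, noiseSd = noiseSd,
                        seed = seed + 1L)
  est <- computeSourceEstimates(rec, sens, hm, parc)
  rs <- extractROISeries(rec, est, parc, defaultBands()[3, ])
  Apli <- averageAdjacency(epochAdjacency(rs, "pli", band = "alpha"))
  Apc <- averageAdjacency(epochAdjacency(rs, "pc", band = "alpha"))
  W <- sourceWeights(est)[as.character(rs@chosenVoxel[, "alpha"]), ,
                          drop = FALSE]
  wc <- weightCorrelationMatrix(W)
  list(pli = Apli, pc = Apc, wc = wc, roiSet = rs)
}

# ROI-level global-null run: K independent narrowband sources taken
# directly as ROI series (the statistics operate downstream of
# beamforming), tested against their own surrogate null.
globalNullRun <- function(seed, K = 10, R = 100, alpha = 0.05) {
  hm <- testHead()
  srcs <- lapply(seq_len(K), function(k)
    dipoleSource(hm, c(0.05 * cos(k), 0.05 * sin(k), 0.04)))
  sig <- simulateSources(srcs, couplingSpec(carrierBand = c(8, 13)),
                         66, 312.5, seed = seed)
  M <- sig[, 1:(4096 * 5)]
  strengths <- nodeStrength(averageAdjacency(epochAdjacency(M, "pli")))
  null <- nullDistribution(M, "pli", R = R, seed = seed + 50000L)
  significanceMap(strengths, null, alpha = alpha)
}
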