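# In-memory cohort builders used by clustering/similarity/statistics tests.
# They compose the package's own generator primitives but skip NIfTI I/O so
# replicated simulations stay fast; file-based runs are covered in
# test-pipeline.R.

# Simulate M subjects over one ground truth and return raw SubjectSeries.
# Gains follow the generator's model: 1 + N(0, gainSd^2), truncated at 0.1.
makeSeriesCohort <- function(truth, M, nT, snr, seed, gainSd = 0.2) {
  roi <- thresholdAtlas(array(as.numeric(truth@mask), dim(truth@mask)),
                        threshold = 0.5, geom = truth@geometry)
  sig <- clusterSignals(truth@KTrue, nT, seed = seed)
  set.seed(seed + 1L)
  gains <- pmax(0.1, 1 + rnorm(M, 0, gainSd))
  lapply(seq_len(M), function(s) {
    vol <- simulateSubject(truth, nT, snr = snr, seed = seed + 10L * s,
                           subjectGain = gains[s], signals = sig)
    extractTimeseries(vol, roi, subjectId = sprintf("sub-%02d", s))
  })
}

# Group solution from a list of SubjectSeries.
groupSolve <- function(seriesList, ...) {
  Z <- concatenateSubjects(lapply(seriesList, standardizeSeries))
  optimizeCut(buildDendrogram(pairwiseEuclidean(Z)), Z, ...)
}

# Ground-truth labels in canonical voxel order.
truthLabelVector <- function(truth) {
  truth@labels[truth@mask]
}
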