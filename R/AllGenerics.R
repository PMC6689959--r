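#' @include AllClasses.R
NULL

#' Accessors for prepercept classes
#'
#' Small accessor family in the Bioconductor style; user code should use these
#' rather than reaching into slots.
#'
#' @param object a prepercept S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochsData", function(object) standardGeneric("epochsData"))
#' @rdname accessors
#' @export
setMethod("epochsData", "TrialEpochs", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setMethod("epochTimes", "TrialEpochs", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setMethod("trialLabels", "TrialEpochs", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "TrialEpochs", function(object) object@sampleRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CrossSpectralDensity", function(object) object@sampleRate)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "TrialEpochs", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "ConnectivitySpectrum", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setMethod("nTrials", "TrialEpochs", function(object) dim(object@data)[1L])

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "TrialEpochs", function(object) dim(object@data)[2L])

#' @rdname accessors
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setMethod("subjects", "CohortDataset", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "CohortDataset", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("csdFreqs", function(object) standardGeneric("csdFreqs"))
#' @rdname accessors
#' @export
setMethod("csdFreqs", "CrossSpectralDensity", function(object) object@freqs)

#' @rdname accessors
#' @export
setGeneric("csdMatrix", function(object) standardGeneric("csdMatrix"))
#' @rdname accessors
#' @export
setMethod("csdMatrix", "CrossSpectralDensity", function(object) object@S)

#' @rdname accessors
#' @export
setGeneric("aucScores", function(object) standardGeneric("aucScores"))
#' @rdname accessors
#' @export
setMethod("aucScores", "DecodingResult", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("decodingTimes", function(object) standardGeneric("decodingTimes"))
#' @rdname accessors
#' @export
setMethod("decodingTimes", "DecodingResult", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("classifierWeights", function(object) standardGeneric("classifierWeights"))
#' @rdname accessors
#' @export
setMethod("classifierWeights", "DecodingResult", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("activationPatterns", function(object) standardGeneric("activationPatterns"))
#' @rdname accessors
#' @export
setMethod("activationPatterns", "DecodingResult", function(object) object@patterns)

#' @rdname accessors
#' @export
setGeneric("clusterPValues", function(object) standardGeneric("clusterPValues"))
#' @rdname accessors
#' @export
setMethod("clusterPValues", "ClusterTestResult", function(object) object@pCluster)

setMethod("show", "TrialEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TrialEpochs '%s': %d trials x %d %s channels x %d samples @ %g Hz\n",
    object@subjectId, d[1], d[2], object@channelKind, d[3], object@sampleRate))
  cat(sprintf("  time: [%.3f, %.3f] s; labels: %d face / %d vase\n",
              min(object@time), max(object@time),
              sum(object@labels == "face"), sum(object@labels == "vase")))
})

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf("CohortDataset: %d subjects\n", length(object@subjects)))
  if (length(object@subjects)) show(object@subjects[[1]])
})

setMethod("show", "CrossSpectralDensity", function(object) {
  d <- dim(object@S)
  cat(sprintf(
    "CrossSpectralDensity: %d channels, %d freqs [%.2f, %.2f] Hz, %d estimates\n",
    d[1], d[3], min(object@freqs), max(object@freqs), object@nEstimates))
})

setMethod("show", "ConnectivitySpectrum", function(object) {
  cat(sprintf(
    "ConnectivitySpectrum '%s' (%s): %d freqs [%.1f, %.1f] Hz\n",
    object@subjectId, object@condition, length(object@freqs),
    min(object@freqs), max(object@freqs)))
  cat(sprintf("  peak coherence %.3f; peak Granger fb %.4f / ff %.4f\n",
              max(object@coherence), max(object@grangerFB), max(object@grangerFF)))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d time points, mean AUC %.3f, max AUC %.3f\n",
              length(object@times), mean(object@auc), max(object@auc)))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult (%s-tailed, alpha %.3g, %d permutations): %d cluster(s)\n",
    object@tail, object@clusterAlpha, object@nPermutations,
    length(object@clusters)))
  if (length(object@pCluster))
    cat("  p:", paste(signif(object@pCluster, 4), collapse = ", "), "\n")
})

setMethod("show", "SequenceFit", function(object) {
  cat(sprintf("SequenceFit: R^2 = %.3f, p-hat = %.3f, stochastic = %s\n",
              object@rSquared, object@pHat, object@stochastic))
})
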