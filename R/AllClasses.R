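#' @import methods
NULL

#' Simulation configuration for a synthetic cohort
#'
#' Holds every generative parameter of the synthetic bistable-perception
#' cohort. Construct with [simulationConfig()], which validates VAR stability
#' and window geometry; see that help page for the meaning and defaults of
#' each field.
#'
#' @slot nSubjects,nTrials cohort and per-subject trial counts.
#' @slot sampleRate sampling rate in Hz.
#' @slot epochWindow (start, end) of the epoch in seconds, start < 0 < end.
#' @slot varCoeffsBase list of lag-indexed 2x2 coefficient matrices, channel
#'   order (V1, FFA).
#' @slot couplingFace,couplingVase FFA->V1 coefficient added during the
#'   prestimulus samples (split across the coupling lags), per condition.
#' @slot couplingLags lags receiving the added coupling coefficient.
#' @slot noiseCov 2x2 innovation covariance of the source VAR.
#' @slot gammaBurst list(freq, onset, offset, amplitude): induced gamma burst
#'   added to the FFA source on face trials.
#' @slot evoked list(onset, offset, amplitude): low-frequency evoked deflection
#'   added to the FFA source on face trials (what the 1-33 Hz decoder sees).
#' @slot nSensors sensor count of the synthetic array.
#' @slot sensorNoiseSd additive sensor noise SD.
#' @slot pFace probability of a face report.
#' @slot betweenSubjectSd SD of the log-normal subject-level effect-size factor.
#' @slot burnin seconds of VAR burn-in discarded per trial.
#' @slot seed cohort seed.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    nTrials = "integer",
    sampleRate = "numeric",
    epochWindow = "numeric",
    varCoeffsBase = "list",
    couplingFace = "numeric",
    couplingVase = "numeric",
    couplingLags = "integer",
    noiseCov = "matrix",
    gammaBurst = "list",
    evoked = "list",
    nSensors = "integer",
    sensorNoiseSd = "numeric",
    pFace = "numeric",
    betweenSubjectSd = "numeric",
    burnin = "numeric",
    seed = "integer"
  )
)

#' Trial-epoched multichannel time series
#'
#' Container for one subject's epoched recording: a numeric array of
#' \code{trials x channels x samples}, a time axis in seconds relative to
#' stimulus onset (0 = onset), and one categorical report label per trial
#' (\code{"face"} or \code{"vase"}).
#'
#' @slot data numeric array \code{[trials, channels, samples]}.
#' @slot time numeric vector of sample times in seconds, strictly increasing
#'   with uniform spacing \code{1/sampleRate}.
#' @slot labels character vector, one of \code{"face"}/\code{"vase"} per trial.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelKind \code{"sensor"} or \code{"source"}.
#' @slot channelNames character vector, one per channel.
#' @slot subjectId scalar character identifier.
#'
#' @exportClass TrialEpochs
setClass("TrialEpochs",
  representation(
    data = "array",
    time = "numeric",
    labels = "character",
    sampleRate = "numeric",
    channelKind = "character",
    channelNames = "character",
    subjectId = "character"
  )
)

setValidity("TrialEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a trials x channels x samples array")
  if (length(object@time) != d[3L])
    return("time axis length must equal the number of samples")
  dt <- diff(object@time)
  if (any(dt <= 0))
    return("time axis must be strictly increasing")
  if (max(abs(dt - 1 / object@sampleRate)) > 1e-9)
    return("time axis spacing must be uniform and equal to 1/sampleRate")
  if (length(object@labels) != d[1L])
    return("labels length must equal the trial count")
  if (!all(object@labels %in% c("face", "vase")))
    return("labels must be 'face' or 'vase'")
  if (!object@channelKind %in% c("sensor", "source"))
    return("channelKind must be 'sensor' or 'source'")
  if (length(object@channelNames) != d[2L])
    return("channelNames length must equal the channel count")
  TRUE
})

#' Multi-subject cohort with ground truth
#'
#' Ordered collection of [TrialEpochs-class] objects (one per subject) plus a
#' copy of the per-subject realized simulation parameters, so downstream
#' parameter-recovery checks can compare estimates against truth.
#'
#' @slot subjects list of \code{TrialEpochs}.
#' @slot groundTruth list of per-subject realized parameter lists.
#' @slot mixing numeric sensors x sources forward matrix used for projection
#'   (empty matrix when the cohort is source-level).
#'
#' @exportClass CohortDataset
setClass("CohortDataset",
  representation(
    subjects = "list",
    groundTruth = "list",
    mixing = "matrix"
  )
)

setValidity("CohortDataset", function(object) {
  ids <- vapply(object@subjects, function(s) s@subjectId, character(1))
  if (anyDuplicated(ids)) return("subject ids must be unique")
  if (length(object@groundTruth) != length(object@subjects))
    return("groundTruth must have one entry per subject")
  TRUE
})

#' Discrete prolate spheroidal (Slepian) taper set
#'
#' @slot tapers numeric matrix \code{[nTapers, nSamples]}; rows orthonormal,
#'   ordered by decreasing spectral concentration.
#' @slot concentrations eigenvalues of the spectral concentration problem,
#'   in (0, 1].
#' @slot timeBandwidth time-bandwidth product NW.
#'
#' @exportClass TaperSet
setClass("TaperSet",
  representation(
    tapers = "matrix",
    concentrations = "numeric",
    timeBandwidth = "numeric"
  )
)

setValidity("TaperSet", function(object) {
  k <- nrow(object@tapers)
  if (length(object@concentrations) != k)
    return("one concentration per taper required")
  if (k > floor(2 * object@timeBandwidth) - 1)
    return("nTapers must be <= floor(2*NW) - 1")
  g <- tcrossprod(object@tapers)
  if (max(abs(g - diag(k))) > 1e-8)
    return("taper rows must be orthonormal")
  TRUE
})

#' Cross-spectral density
#'
#' Trial- and taper-averaged complex cross-spectral matrix per frequency,
#' scaled as density per Hz. \code{nEstimates} records how many independent
#' trial x taper estimates entered the average; coherence is undefined for a
#' single estimate.
#'
#' @slot freqs frequency grid in Hz.
#' @slot S complex array \code{[channels, channels, freqs]}, Hermitian at each
#'   frequency with real nonnegative diagonal.
#' @slot nEstimates number of trial x taper estimates averaged.
#' @slot window analyzed time window (start, end) in seconds.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelNames character vector.
#'
#' @exportClass CrossSpectralDensity
setClass("CrossSpectralDensity",
  representation(
    freqs = "numeric",
    S = "array",
    nEstimates = "numeric",
    window = "numeric",
    sampleRate = "numeric",
    channelNames = "character"
  )
)

setValidity("CrossSpectralDensity", function(object) {
  d <- dim(object@S)
  if (length(d) != 3L || d[1L] != d[2L])
    return("S must be channels x channels x freqs")
  if (d[3L] != length(object@freqs))
    return("third dimension of S must match the frequency grid")
  for (i in seq_len(d[3L])) {
    Sf <- object@S[, , i]
    if (max(abs(Sf - Conj(t(Sf)))) > 1e-8 * (1 + max(abs(Sf))))
      return("S must be Hermitian at every frequency")
    if (any(Re(diag(Sf)) < -1e-12))
      return("auto-spectra must be nonnegative")
  }
  TRUE
})

#' Sliding-window time-frequency power map
#'
#' @slot power numeric array \code{[trials, channels, freqs, times]},
#'   nonnegative.
#' @slot freqs frequency grid in Hz.
#' @slot times window-center times in seconds (inside the epoch).
#' @slot windowWidth analysis window width in seconds.
#' @slot channelNames character vector.
#'
#' @exportClass TimeFrequencyMap
setClass("TimeFrequencyMap",
  representation(
    power = "array",
    freqs = "numeric",
    times = "numeric",
    windowWidth = "numeric",
    channelNames = "character"
  )
)

setValidity("TimeFrequencyMap", function(object) {
  d <- dim(object@power)
  if (length(d) != 4L) return("power must be trials x channels x freqs x times")
  if (d[3L] != length(object@freqs)) return("freqs mismatch")
  if (d[4L] != length(object@times)) return("times mismatch")
  if (any(object@power < 0)) return("power must be nonnegative")
  TRUE
})

#' Wilson spectral-matrix factorization result
#'
#' Minimum-phase factorization S(f) = H(f) Sigma H(f)* of a cross-spectral
#' density, the engine behind nonparametric spectral Granger causality.
#'
#' @slot H complex transfer-function array \code{[channels, channels, freqs]}.
#' @slot Sigma real innovation covariance (symmetric positive definite).
#' @slot freqs frequency grid in Hz (uniform, 0 to Nyquist).
#' @slot converged logical convergence flag.
#' @slot nIter iterations used.
#' @slot residual final maximum relative Frobenius reconstruction error.
#'
#' @exportClass SpectralFactorization
setClass("SpectralFactorization",
  representation(
    H = "array",
    Sigma = "matrix",
    freqs = "numeric",
    converged = "logical",
    nIter = "integer",
    residual = "numeric"
  )
)

#' Frequency-resolved connectivity estimates for one subject and condition
#'
#' Channel order is fixed package-wide as (V1, FFA): \code{grangerFB} is the
#' feedback direction FFA to V1, \code{grangerFF} the feedforward V1 to FFA.
#'
#' @slot freqs frequency grid in Hz.
#' @slot coherence magnitude coherence, in [0, 1].
#' @slot imagCoherency imaginary part of coherency, in [-1, 1].
#' @slot grangerFF feedforward (V1 -> FFA) Granger spectrum, nonnegative.
#' @slot grangerFB feedback (FFA -> V1) Granger spectrum, nonnegative.
#' @slot condition condition label.
#' @slot subjectId subject identifier.
#'
#' @exportClass ConnectivitySpectrum
setClass("ConnectivitySpectrum",
  representation(
    freqs = "numeric",
    coherence = "numeric",
    imagCoherency = "numeric",
    grangerFF = "numeric",
    grangerFB = "numeric",
    condition = "character",
    subjectId = "character"
  )
)

setValidity("ConnectivitySpectrum", function(object) {
  n <- length(object@freqs)
  for (sl in c("coherence", "imagCoherency", "grangerFF", "grangerFB")) {
    v <- slot(object, sl)
    if (length(v) != n) return(sprintf("%s length must match freqs", sl))
  }
  if (any(object@coherence < -1e-12 | object@coherence > 1 + 1e-9))
    return("coherence must lie in [0, 1]")
  if (any(abs(object@imagCoherency) > 1 + 1e-9))
    return("imaginary coherency must lie in [-1, 1]")
  if (any(object@grangerFF < 0) || any(object@grangerFB < 0))
    return("Granger spectra must be nonnegative")
  TRUE
})

#' Per-timepoint decoding result
#'
#' @slot times decoded time points in seconds.
#' @slot auc area under the ROC curve per time point, in [0, 1], from pooled
#'   held-out decision values.
#' @slot weights fold-averaged classifier weights \code{[times, channels]}.
#' @slot patterns activation patterns \code{[times, channels]} (filled by
#'   [haufePatterns()]; zero rows until then).
#' @slot foldAssignment integer fold index per trial.
#' @slot channelNames character vector.
#'
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(
    times = "numeric",
    auc = "numeric",
    weights = "matrix",
    patterns = "matrix",
    foldAssignment = "integer",
    channelNames = "character"
  )
)

setValidity("DecodingResult", function(object) {
  if (length(object@auc) != length(object@times))
    return("one AUC per time point required")
  if (any(object@auc < 0 | object@auc > 1))
    return("AUC must lie in [0, 1]")
  fs <- tabulate(object@foldAssignment)
  if (length(fs) > 1 && diff(range(fs)) > 1)
    return("fold sizes must differ by at most 1")
  TRUE
})

#' Source-level activation map (arbitrary units)
#'
#' @slot values numeric matrix \code{[grid points, times]}; finite.
#' @slot gridIds character identifiers of the grid points.
#' @slot times time axis in seconds.
#'
#' @exportClass SourceMap
setClass("SourceMap",
  representation(
    values = "matrix",
    gridIds = "character",
    times = "numeric"
  )
)

setValidity("SourceMap", function(object) {
  if (!all(is.finite(object@values))) return("map values must be finite")
  if (nrow(object@values) != length(object@gridIds))
    return("one grid id per row required")
  if (ncol(object@values) != length(object@times))
    return("one column per time point required")
  TRUE
})

#' Cluster-based permutation test result
#'
#' @slot statMap cell-wise paired t statistics over the tested grid; for a
#'   2-D (freq x time) grid the array keeps its dim attribute.
#' @slot clusters list; each element has \code{cells} (integer indices into
#'   statMap), \code{mass} (summed statistic) and \code{p} (Monte-Carlo p).
#' @slot pCluster numeric vector of cluster p-values, in (0, 1].
#' @slot nPermutations number of random sign permutations.
#' @slot tail \code{"two"}, \code{"greater"} or \code{"less"}.
#' @slot clusterAlpha cluster-forming cell-wise alpha.
#' @slot threshold t threshold implied by clusterAlpha and tail.
#'
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(
    statMap = "array",
    clusters = "list",
    pCluster = "numeric",
    nPermutations = "integer",
    tail = "character",
    clusterAlpha = "numeric",
    threshold = "numeric"
  )
)

setValidity("ClusterTestResult", function(object) {
  if (length(object@pCluster) &&
      (any(object@pCluster <= 0) || any(object@pCluster > 1)))
    return("cluster p-values must lie in (0, 1]")
  if (length(object@pCluster) &&
      min(object@pCluster) < 1 / (object@nPermutations + 1) - 1e-12)
    return("p-values cannot undercut 1/(nPermutations + 1)")
  TRUE
})

#' Run-length binomial fit of report sequences
#'
#' @slot binCounts mean count per repetition bin (0-10 repetitions, 11 bins),
#'   averaged across subjects.
#' @slot fitted expected counts under the fitted binomial law.
#' @slot rSquared goodness of fit, 1 - SS_res/SS_tot.
#' @slot pHat fitted binomial success probability.
#' @slot stochastic heuristic flag: FALSE when the mass piles into the top bin
#'   (perseverative, non-stochastic reporting).
#'
#' @exportClass SequenceFit
setClass("SequenceFit",
  representation(
    binCounts = "numeric",
    fitted = "numeric",
    rSquared = "numeric",
    pHat = "numeric",
    stochastic = "logical"
  )
)

setValidity("SequenceFit", function(object) {
  if (length(object@binCounts) != 11L) return("exactly 11 bins required")
  if (any(object@binCounts < 0)) return("bin counts must be nonnegative")
  TRUE
})
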