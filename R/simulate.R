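#' @include AllClasses.R
NULL

# run code under a temporary RNG state so callers' streams are untouched
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spectral radius of the companion matrix of a VAR model
#'
#' A vector-autoregressive process is stable (stationary) iff the spectral
#' radius of its companion matrix is below 1.
#'
#' @param coeffs list of lag-indexed k x k coefficient matrices.
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
varSpectralRadius <- function(coeffs) {
  p <- length(coeffs)
  k <- nrow(coeffs[[1]])
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[seq_len(k), (j - 1) * k + seq_len(k)] <- coeffs[[j]]
  if (p > 1)
    comp[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

.checkStable <- function(coeffs, what = "VAR coefficients") {
  rho <- varSpectralRadius(coeffs)
  if (rho >= 1)
    stop(sprintf("%s define an unstable process (companion spectral radius %.4f >= 1)",
                 what, rho))
  invisible(rho)
}

# default 2x2 VAR(5): each channel an AR(2) resonator at resFreq Hz
.defaultVarCoeffs <- function(sampleRate = 250, resFreq = 10, poleRadius = 0.85,
                              order = 5) {
  a1 <- 2 * poleRadius * cos(2 * pi * resFreq / sampleRate)
  a2 <- -poleRadius^2
  coeffs <- replicate(order, matrix(0, 2, 2), simplify = FALSE)
  coeffs[[1]] <- diag(c(a1, a1))
  coeffs[[2]] <- diag(c(a2, a2))
  coeffs
}

# add an FFA->V1 (row 1, col 2) coefficient, split equally across lags
.addCoupling <- function(coeffs, coupling, lags) {
  for (l in lags) coeffs[[l]][1, 2] <- coeffs[[l]][1, 2] + coupling / length(lags)
  coeffs
}

#' Build a validated simulation configuration
#'
#' Defaults define the reference synthetic cohort: 20 subjects, 400 trials
#' each, 250 Hz, epochs from -1 to +0.5 s around stimulus onset. The two
#' sources (V1-like, FFA-like) follow a bivariate VAR(5) whose channels are
#' 10-Hz resonators; during the prestimulus samples an FFA->V1 coupling
#' coefficient is added at lags 2-3 (the lag makes the cross-spectrum complex,
#' so imaginary coherency is nonzero), stronger before face reports. After
#' stimulus onset the VAR reverts to its base coefficients, so post-stimulus
#' connectivity is uninformative by construction. Face trials additionally
#' receive a random-phase 60-Hz burst (0-0.35 s, induced gamma) and a
#' low-frequency evoked deflection on the FFA source. One log-normal factor
#' per subject scales couplings, gamma and evoked amplitudes jointly, giving
#' the subject-level effect-size spread that drives cross-subject
#' correlations.
#'
#' @param nSubjects,nTrials cohort size and trials per subject.
#' @param sampleRate sampling rate, Hz.
#' @param epochWindow c(start, end) seconds relative to onset; start < 0 < end.
#' @param varCoeffsBase lag-indexed list of 2x2 matrices; default VAR(5) with
#'   10-Hz resonant channels (pole radius 0.85).
#' @param couplingFace,couplingVase prestimulus FFA->V1 coefficient added on
#'   face / vase trials.
#' @param couplingLags lags carrying the coupling (default 2:3).
#' @param noiseCov innovation covariance (default identity).
#' @param gammaBurst list(freq, onset, offset, amplitude) for the induced
#'   FFA gamma burst on face trials.
#' @param evoked list(onset, offset, amplitude) for the FFA evoked deflection
#'   on face trials.
#' @param nSensors sensors in the synthetic array.
#' @param sensorNoiseSd additive sensor noise SD.
#' @param pFace probability of a face report.
#' @param betweenSubjectSd SD of log subject effect-size factor.
#' @param burnin seconds of VAR burn-in discarded before each epoch.
#' @param seed cohort seed; spawns per-subject seeds deterministically.
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nSubjects = 20L,
                             nTrials = 400L,
                             sampleRate = 250,
                             epochWindow = c(-1.0, 0.5),
                             varCoeffsBase = .defaultVarCoeffs(sampleRate),
                             couplingFace = 0.04,
                             couplingVase = 0.015,
                             couplingLags = 2:3,
                             noiseCov = diag(2),
                             gammaBurst = list(freq = 60, onset = 0,
                                               offset = 0.35, amplitude = 2),
                             evoked = list(onset = 0.05, offset = 0.30,
                                           amplitude = 1.5),
                             nSensors = 30L,
                             sensorNoiseSd = 0.5,
                             pFace = 0.5,
                             betweenSubjectSd = 0.3,
                             burnin = 1.0,
                             seed = 1L) {
  stopifnot(length(epochWindow) == 2)
  if (!(epochWindow[1] < 0 && 0 < epochWindow[2]))
    stop("epochWindow must satisfy start < 0 < end")
  if (pFace < 0 || pFace > 1) stop("pFace must lie in [0, 1]")
  allPar <- c(unlist(varCoeffsBase), couplingFace, couplingVase,
              unlist(noiseCov), gammaBurst$amplitude, evoked$amplitude,
              sensorNoiseSd, betweenSubjectSd)
  if (!all(is.finite(allPar))) stop("non-finite simulation parameters")
  # the stricter condition-specific models must both be stable
  .checkStable(.addCoupling(varCoeffsBase, couplingFace, couplingLags),
               "face-condition VAR coefficients")
  .checkStable(.addCoupling(varCoeffsBase, couplingVase, couplingLags),
               "vase-condition VAR coefficients")
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), nTrials = as.integer(nTrials),
      sampleRate = sampleRate, epochWindow = epochWindow,
      varCoeffsBase = varCoeffsBase, couplingFace = couplingFace,
      couplingVase = couplingVase, couplingLags = as.integer(couplingLags),
      noiseCov = noiseCov, gammaBurst = gammaBurst, evoked = evoked,
      nSensors = as.integer(nSensors), sensorNoiseSd = sensorNoiseSd,
      pFace = pFace, betweenSubjectSd = betweenSubjectSd,
      burnin = burnin, seed = as.integer(seed))
}

# core vectorized VAR recursion; coefficient set may switch at a sample index.
# returns [nTrials, k, nKeep] keeping the trailing nKeep samples.
.varRecur <- function(coeffsA, coeffsB = NULL, switchAt = NULL,
                      noiseCov, nKeep, nBurn, nTrials) {
  p <- length(coeffsA)
  k <- nrow(coeffsA[[1]])
  tot <- nBurn + nKeep + p
  U <- chol(noiseCov)
  E <- array(stats::rnorm(nTrials * k * tot), dim = c(nTrials, k, tot))
  for (t in seq_len(tot)) E[, , t] <- E[, , t, drop = FALSE][, , 1] %*% U
  Y <- array(0, dim = c(nTrials, k, tot))
  tA <- lapply(coeffsA, t)
  tB <- if (is.null(coeffsB)) NULL else lapply(coeffsB, t)
  # sample index (into the kept segment) at which coeffsB take over
  swAbs <- if (is.null(switchAt)) Inf else nBurn + p + switchAt
  for (t in (p + 1):tot) {
    acc <- E[, , t, drop = FALSE][, , 1]
    useB <- !is.null(tB) && t >= swAbs
    tC <- if (useB) tB else tA
    for (j in seq_len(p))
      acc <- acc + Y[, , t - j, drop = FALSE][, , 1] %*% tC[[j]]
    Y[, , t] <- acc
  }
  Y[, , (nBurn + p + 1):tot, drop = FALSE]
}

#' Simulate a stationary vector-autoregressive process
#'
#' Generates (after discarding a burn-in) realizations of the VAR process
#' \eqn{y_t = \sum_k A_k y_{t-k} + \epsilon_t} with Gaussian innovations.
#'
#' @param coeffs list of lag-indexed k x k coefficient matrices; must define a
#'   stable process.
#' @param noiseCov innovation covariance, symmetric positive definite.
#' @param nSamples samples to return per trial.
#' @param seed RNG seed.
#' @param nTrials number of independent realizations (default 1).
#' @param burninSamples burn-in samples discarded before the kept segment
#'   (default 250, about 13 time constants of the default pole radius 0.95).
#' @return numeric array \code{[nTrials, channels, nSamples]}.
#' @export
varGenerate <- function(coeffs, noiseCov, nSamples, seed, nTrials = 1L,
                        burninSamples = 250L) {
  .checkStable(coeffs)
  ev <- eigen(noiseCov, symmetric = TRUE, only.values = TRUE)$values
  if (!isSymmetric(unname(noiseCov)) || any(ev <= 0))
    stop("noiseCov must be symmetric positive definite")
  .withSeed(seed,
    .varRecur(coeffs, noiseCov = noiseCov, nKeep = nSamples,
              nBurn = burninSamples, nTrials = as.integer(nTrials)))
}

#' Draw a stochastic report-label sequence
#'
#' Trial-by-trial reports are modelled as i.i.d. Bernoulli draws: the
#' probability of a face report does not depend on the previous trial,
#' matching the stochastic reporting the run-length analysis tests for.
#'
#' @param nTrials number of trials.
#' @param pFace probability of a face report.
#' @param seed RNG seed.
#' @return character vector of \code{"face"}/\code{"vase"} labels.
#' @export
generateReports <- function(nTrials, pFace, seed) {
  if (pFace < 0 || pFace > 1) stop("pFace must lie in [0, 1]")
  .withSeed(seed, ifelse(stats::rbinom(nTrials, 1L, pFace) == 1L, "face", "vase"))
}

# Hann-windowed additive components on the FFA source of face trials
.addFaceComponents <- function(dat, faceIdx, times, gamma, evoked, factor) {
  if (length(faceIdx) == 0) return(dat)
  if (gamma$amplitude > 0) {
    sel <- which(times >= gamma$onset & times <= gamma$offset)
    if (length(sel) > 1) {
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(sel)))
      phi <- stats::runif(length(faceIdx), 0, 2 * pi)
      carrier <- outer(phi, 2 * pi * gamma$freq * times[sel], `+`)
      dat[faceIdx, 2, sel] <- dat[faceIdx, 2, sel] +
        factor * gamma$amplitude * sin(carrier) *
        matrix(env, length(faceIdx), length(sel), byrow = TRUE)
    }
  }
  if (evoked$amplitude > 0) {
    sel <- which(times >= evoked$onset & times <= evoked$offset)
    if (length(sel) > 1) {
      bump <- sin(pi * seq(0, 1, length.out = length(sel)))
      dat[faceIdx, 2, sel] <- dat[faceIdx, 2, sel] +
        matrix(factor * evoked$amplitude * bump,
               length(faceIdx), length(sel), byrow = TRUE)
    }
  }
  dat
}

#' Simulate one subject's source-level epochs
#'
#' Draws the trial labels, generates prestimulus-coupled VAR epochs per
#' condition (the FFA->V1 coupling coefficient applies to samples before
#' stimulus onset and reverts to baseline afterwards), and adds the face-trial
#' gamma burst and evoked deflection. A single log-normal subject factor
#' scales both couplings and both amplitudes.
#'
#' @param config a [SimulationConfig-class].
#' @param subjectSeed integer seed for this subject.
#' @param subjectId identifier string.
#' @return list with \code{epochs} (source-level [TrialEpochs-class]) and
#'   \code{truth} (realized per-subject parameters).
#' @export
simulateSubject <- function(config, subjectSeed, subjectId = "S01") {
  fs <- config@sampleRate
  times <- seq(config@epochWindow[1], config@epochWindow[2], by = 1 / fs)
  nKeep <- length(times)
  nBurn <- round(config@burnin * fs)
  switchAt <- sum(times < 0) + 1L  # first sample with t >= 0
  .withSeed(subjectSeed, {
    factor <- exp(stats::rnorm(1, 0, config@betweenSubjectSd))
    labels <- ifelse(stats::rbinom(config@nTrials, 1L, config@pFace) == 1L,
                     "face", "vase")
    cf <- config@couplingFace * factor
    cv <- config@couplingVase * factor
    base <- config@varCoeffsBase
    preFace <- .addCoupling(base, cf, config@couplingLags)
    preVase <- .addCoupling(base, cv, config@couplingLags)
    .checkStable(preFace, "subject-jittered face VAR")
    .checkStable(preVase, "subject-jittered vase VAR")
    dat <- array(0, dim = c(config@nTrials, 2L, nKeep))
    for (cond in c("face", "vase")) {
      idx <- which(labels == cond)
      if (!length(idx)) next
      pre <- if (cond == "face") preFace else preVase
      dat[idx, , ] <- .varRecur(pre, base, switchAt, config@noiseCov,
                                nKeep, nBurn, length(idx))
    }
    dat <- .addFaceComponents(dat, which(labels == "face"), times,
                              config@gammaBurst, config@evoked, factor)
    epochs <- new("TrialEpochs", data = dat, time = times, labels = labels,
                  sampleRate = fs, channelKind = "source",
                  channelNames = c("V1", "FFA"), subjectId = subjectId)
    list(epochs = epochs,
         truth = list(subjectSeed = subjectSeed, factor = factor,
                      couplingFace = cf, couplingVase = cv,
                      gammaAmplitude = config@gammaBurst$amplitude * factor,
                      evokedAmplitude = config@evoked$amplitude * factor))
  })
}

#' Project source epochs through a linear forward model
#'
#' Sensor data are \code{mixing \%*\% sources} plus i.i.d. Gaussian noise; the
#' mixing matrix is retained by the cohort object so the decoding module can
#' use its pseudo-inverse as the source-projection stand-in.
#'
#' @param epochs source-level [TrialEpochs-class].
#' @param mixing sensors x sources matrix; columns must match the source
#'   channel count.
#' @param noiseSd sensor noise SD.
#' @param seed RNG seed for the noise.
#' @return sensor-level [TrialEpochs-class].
#' @export
projectToSensors <- function(epochs, mixing, noiseSd, seed) {
  d <- dim(epochs@data)
  if (ncol(mixing) != d[2L])
    stop(sprintf("mixing has %d columns but epochs have %d channels",
                 ncol(mixing), d[2L]))
  nSens <- nrow(mixing)
  # channels live on dim 2: collapse trials x samples, multiply once
  src <- aperm(epochs@data, c(2L, 1L, 3L))
  dim(src) <- c(d[2L], d[1L] * d[3L])
  sens <- mixing %*% src
  out <- .withSeed(seed, {
    if (noiseSd > 0)
      sens <- sens + stats::rnorm(length(sens), 0, noiseSd)
    sens
  })
  dim(out) <- c(nSens, d[1L], d[3L])
  new("TrialEpochs", data = aperm(out, c(2L, 1L, 3L)), time = epochs@time,
      labels = epochs@labels, sampleRate = epochs@sampleRate,
      channelKind = "sensor",
      channelNames = sprintf("MEG%02d", seq_len(nSens)),
      subjectId = epochs@subjectId)
}

# smooth random unit-norm sensor topographies on a ring, one per source;
# source centers are spread apart so columns are well-conditioned
.makeMixing <- function(nSensors, nSources = 2L) {
  pos <- seq(0, 2 * pi, length.out = nSensors + 1L)[seq_len(nSensors)]
  centers <- stats::runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = nSources + 1L)[seq_len(nSources)]
  M <- vapply(seq_len(nSources), function(j) {
    width <- stats::runif(1, 0.5, 0.9)
    dmin <- pmin(abs(pos - centers[j] %% (2 * pi)),
                 2 * pi - abs(pos - centers[j] %% (2 * pi)))
    topo <- exp(-dmin^2 / (2 * width^2)) + 0.05 * stats::rnorm(nSensors)
    topo / sqrt(sum(topo^2))
  }, numeric(nSensors))
  M
}

#' Simulate a full synthetic cohort
#'
#' The cohort seed deterministically spawns one seed per subject (and one for
#' the sensor array), so identical \code{(config)} objects give bit-identical
#' cohorts while subjects remain mutually independent.
#'
#' @param config a [SimulationConfig-class].
#' @param sensorLevel if TRUE (default) project each subject through the
#'   cohort's mixing matrix and additive sensor noise; if FALSE keep
#'   source-level epochs.
#' @return a [CohortDataset-class].
#' @export
simulateCohort <- function(config, sensorLevel = TRUE) {
  seeds <- .withSeed(config@seed,
                     sample.int(.Machine$integer.max - 1L,
                                config@nSubjects + 2L))
  mixing <- if (sensorLevel)
    .withSeed(seeds[config@nSubjects + 1L],
              .makeMixing(config@nSensors)) else matrix(numeric(0), 0, 0)
  subjects <- vector("list", config@nSubjects)
  truth <- vector("list", config@nSubjects)
  for (i in seq_len(config@nSubjects)) {
    sid <- sprintf("S%02d", i)
    sim <- simulateSubject(config, seeds[i], sid)
    ep <- sim$epochs
    if (sensorLevel)
      ep <- projectToSensors(ep, mixing, config@sensorNoiseSd,
                             seed = seeds[config@nSubjects + 2L] %% 100000L + i)
    subjects[[i]] <- ep
    truth[[i]] <- sim$truth
  }
  names(truth) <- vapply(subjects, subjectId, character(1))
  new("CohortDataset", subjects = subjects, groundTruth = truth,
      mixing = mixing)
}

#' Reverse each trial's samples in time
#'
#' Used by the time-reversal Granger control: auto-spectra are invariant under
#' reversal while directed estimates should flip direction.
#'
#' @param epochs a [TrialEpochs-class].
#' @return a [TrialEpochs-class] with the sample axis flipped (the time axis
#'   is kept, so downstream windowing is unchanged).
#' @export
reverseTime <- function(epochs) {
  d <- dim(epochs@data)
  new("TrialEpochs", data = epochs@data[, , d[3L]:1, drop = FALSE],
      time = epochs@time, labels = epochs@labels,
      sampleRate = epochs@sampleRate, channelKind = epochs@channelKind,
      channelNames = epochs@channelNames, subjectId = epochs@subjectId)
}
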