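#' @include AllClasses.R
NULL

#' Assemble and validate a pipeline configuration
#'
#' Plain validated parameter list (printed configs stay human-readable and
#' JSON-serializable, which keeps the results bundle self-describing). The
#' analysis windows and the statistical band mirror the study design:
#' connectivity and power are estimated in the prestimulus second and tested
#' over 5-25 Hz where the sources have appreciable oscillatory power;
#' time-frequency contrasts and decoding significance are tested over the
#' first 350 ms after onset; the time-frequency analysis is run at both a
#' 300-ms and a 100-ms window width (the wide window smears post-stimulus
#' power into prestimulus window centers, the narrow one does not).
#'
#' @param simulation a [SimulationConfig-class].
#' @param prestimWindow,poststimWindow analysis windows in seconds.
#' @param statsBand frequency band (Hz) for connectivity/power statistics.
#' @param tfrWidths time-frequency window widths in seconds.
#' @param tfrStep window-center spacing in seconds.
#' @param gammaRange gamma band (Hz) for the time-frequency contrast.
#' @param nPerm permutations for spectral/TFR cluster tests.
#' @param nPermDecoding permutations for the decoding significance test
#'   (defaults to 10000, giving a p floor of about 1e-4).
#' @param clusterAlpha cluster-forming cell-wise alpha.
#' @param decim decode every decim-th sample.
#' @param seed seed for fold assignment and permutation draws (the cohort
#'   itself is seeded by \code{simulation@seed}).
#' @param stages subset of
#'   \code{c("decode", "tfr", "connectivity", "behavior", "correlations")}.
#' @param outDir optional output directory for [writeBundle()] artifacts.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           prestimWindow = c(-1, 0),
                           poststimWindow = c(0, 0.35),
                           statsBand = c(5, 25),
                           tfrWidths = c(0.3, 0.1),
                           tfrStep = 0.05,
                           gammaRange = c(40, 90),
                           nPerm = 1000L,
                           nPermDecoding = 10000L,
                           clusterAlpha = 0.05,
                           decim = 5L,
                           seed = 1L,
                           stages = c("decode", "tfr", "connectivity",
                                      "behavior", "correlations"),
                           outDir = NULL) {
  stopifnot(is(simulation, "SimulationConfig"))
  ew <- simulation@epochWindow
  if (prestimWindow[1] < ew[1] || poststimWindow[2] > ew[2])
    stop("analysis windows must lie inside the epoch")
  if (statsBand[2] > simulation@sampleRate / 2)
    stop("statistics band exceeds the Nyquist frequency")
  stages <- match.arg(stages, c("decode", "tfr", "connectivity", "behavior",
                                "correlations"), several.ok = TRUE)
  structure(list(simulation = simulation, prestimWindow = prestimWindow,
                 poststimWindow = poststimWindow, statsBand = statsBand,
                 tfrWidths = tfrWidths, tfrStep = tfrStep,
                 gammaRange = gammaRange, nPerm = as.integer(nPerm),
                 nPermDecoding = as.integer(nPermDecoding),
                 clusterAlpha = clusterAlpha, decim = as.integer(decim),
                 seed = as.integer(seed), stages = stages, outDir = outDir),
            class = "PipelineConfig")
}

# reconstruct 2-channel source epochs through the spatial filter
.toSourceEpochs <- function(epochs, spatialFilter) {
  d <- dim(epochs@data)
  sens <- matrix(aperm(epochs@data, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  src <- spatialFilter %*% sens
  new("TrialEpochs",
      data = aperm(array(src, dim = c(nrow(spatialFilter), d[1L], d[3L])),
                   c(2L, 1L, 3L)),
      time = epochs@time, labels = epochs@labels,
      sampleRate = epochs@sampleRate, channelKind = "source",
      channelNames = c("V1", "FFA"), subjectId = epochs@subjectId)
}

# per-subject face-minus-vase mean TFR power for one channel,
# restricted to a frequency band; returns [freqs x times]
.tfrContrast <- function(tfr, labels, channel, freqSel, timeSel) {
  pf <- tfr@power[labels == "face", channel, freqSel, timeSel, drop = FALSE]
  pv <- tfr@power[labels == "vase", channel, freqSel, timeSel, drop = FALSE]
  apply(pf, c(3L, 4L), mean) - apply(pv, c(3L, 4L), mean)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: cohort simulation (or use of a supplied cohort);
#' per-subject temporal decoding with activation patterns, source projection
#' and ROI extraction, plus the group decoding-significance cluster test;
#' time-frequency contrasts in the V1-like and FFA-like sources at both
#' window widths with 2-D cluster tests in the gamma band; prestimulus
#' power, coherence, imaginary coherency and directed Granger contrasts
#' (restricted to the statistics band at the testing stage only) with the
#' time-reversal control; the behavioral run-length analysis; and the
#' cross-subject correlations of per-subject maxima. On synthetic cohorts
#' the source spatial filter is the pseudo-inverse of the known mixing
#' matrix; pass \code{spatialFilter} to analyze real sensor data with a
#' user-supplied inverse operator.
#'
#' A stage failure aborts with the stage name after serializing the partial
#' bundle (when \code{outDir} is set). Identical config and seeds give a
#' byte-identical [writeBundle()] summary.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @param cohort optional precomputed [CohortDataset-class]; default is
#'   simulated from \code{config$simulation}.
#' @param spatialFilter optional grid x channels matrix replacing the
#'   known-mixing pseudo-inverse.
#' @return a results bundle: a list with per-stage entries and provenance.
#' @export
runPipeline <- function(config, cohort = NULL, spatialFilter = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  bundle <- list(provenance = list(
    config = .configAsList(config), packageVersion =
      as.character(utils::packageVersion("prepercept"))))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(config$outDir)) writeBundle(bundle, config$outDir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", {
    if (is.null(cohort)) cohort <- simulateCohort(config$simulation)
    cohort
  })
  subjectsList <- subjects(cohort)
  nSubj <- length(subjectsList)
  ids <- vapply(subjectsList, subjectId, character(1))
  sensorLevel <- nrow(cohort@mixing) > 0
  filt <- if (!is.null(spatialFilter)) spatialFilter
          else if (sensorLevel) pseudoInverse(cohort@mixing)
          else diag(2)
  srcEpochs <- lapply(subjectsList, function(ep)
    if (ep@channelKind == "source") ep else .toSourceEpochs(ep, filt))
  bundle$subjects <- ids

  if ("decode" %in% config$stages) bundle$decoding <- stage("decode", {
    res <- vector("list", nSubj)
    rois <- vector("list", nSubj)
    for (i in seq_len(nSubj)) {
      fep <- bandFilterEpochs(subjectsList[[i]])
      dec <- temporalDecode(fep, nFolds = 4L, seed = config$seed + i,
                            decim = config$decim, prefiltered = TRUE)
      dec <- haufePatterns(dec, fep, prefiltered = TRUE)
      map <- projectToSource(dec, filt, gridIds = c("V1", "FFA"))
      rois[[i]] <- extractROI(map, frac = 0.95, window = c(0.05, 0.20))
      res[[i]] <- dec
    }
    times <- res[[1]]@times
    sel <- which(times >= config$poststimWindow[1] - 1e-9 &
                 times <= config$poststimWindow[2] + 1e-9)
    aucMat <- t(vapply(res, function(r) r@auc[sel], numeric(length(sel))))
    sig <- clusterPermutationTest(
      aucMat, matrix(0.5, nSubj, length(sel)), tail = "greater",
      clusterAlpha = config$clusterAlpha, nPerm = config$nPermDecoding,
      seed = config$seed)
    list(results = res, rois = rois, testedTimes = times[sel],
         significance = sig,
         maxAUC = vapply(seq_len(nSubj), function(i)
           maxInRange(res[[i]]@auc, res[[i]]@times, config$poststimWindow),
           numeric(1)))
  })

  if ("tfr" %in% config$stages) bundle$tfr <- stage("tfr", {
    out <- list()
    for (w in config$tfrWidths) {
      key <- sprintf("width%03.0fms", w * 1000)
      contrasts <- list(V1 = NULL, FFA = NULL)
      freqSel <- timeSel <- NULL
      tfrFreqs <- tfrTimes <- NULL
      for (i in seq_len(nSubj)) {
        tfr <- tfrPower(srcEpochs[[i]], windowWidth = w,
                        step = config$tfrStep,
                        freqRange = c(config$gammaRange[1] - 10,
                                      config$gammaRange[2] + 10))
        if (is.null(freqSel)) {
          freqSel <- which(tfr@freqs >= config$gammaRange[1] &
                           tfr@freqs <= config$gammaRange[2])
          timeSel <- which(tfr@times >= config$poststimWindow[1] - 1e-9 &
                           tfr@times <= config$poststimWindow[2] + 1e-9)
          tfrFreqs <- tfr@freqs[freqSel]
          tfrTimes <- tfr@times[timeSel]
        }
        for (ch in 1:2) {
          cmat <- .tfrContrast(tfr, trialLabels(srcEpochs[[i]]), ch,
                               freqSel, timeSel)
          contrasts[[ch]] <- rbind(contrasts[[ch]], as.vector(cmat))
        }
      }
      gd <- c(length(tfrFreqs), length(tfrTimes))
      tests <- lapply(contrasts, function(cm)
        clusterPermutationTest(cm, matrix(0, nSubj, ncol(cm)), tail = "two",
                               clusterAlpha = config$clusterAlpha,
                               nPerm = config$nPerm, seed = config$seed,
                               gridDim = gd))
      out[[key]] <- list(freqs = tfrFreqs, times = tfrTimes,
                         contrasts = contrasts, tests = tests)
    }
    out
  })

  if ("connectivity" %in% config$stages)
    bundle$connectivity <- stage("connectivity", {
      spectra <- list()
      power <- list()  # power[[cond]][[ch]]: nSubj x band matrix
      for (cond in c("face", "vase"))
        power[[cond]] <- list(matrix(0, nSubj, 0), matrix(0, nSubj, 0))
      freqs <- bandSel <- NULL
      for (i in seq_len(nSubj)) {
        ep <- srcEpochs[[i]]
        for (cond in c("face", "vase")) {
          sub <- new("TrialEpochs",
                     data = ep@data[ep@labels == cond, , , drop = FALSE],
                     time = ep@time, labels = ep@labels[ep@labels == cond],
                     sampleRate = ep@sampleRate, channelKind = "source",
                     channelNames = ep@channelNames, subjectId = ep@subjectId)
          csd <- multitaperCSD(sub, config$prestimWindow)
          if (is.null(freqs)) {
            freqs <- csd@freqs
            bandSel <- which(freqs >= config$statsBand[1] &
                             freqs <= config$statsBand[2])
            for (cond2 in c("face", "vase"))
              power[[cond2]] <- list(matrix(0, nSubj, length(bandSel)),
                                     matrix(0, nSubj, length(bandSel)))
          }
          fact <- wilsonFactorize(csd)
          spectra[[paste(ids[i], cond, sep = ".")]] <-
            new("ConnectivitySpectrum", freqs = freqs,
                coherence = csdCoherence(csd),
                imagCoherency = csdImagCoherency(csd),
                grangerFF = grangerSpectrum(fact, "ff"),
                grangerFB = grangerSpectrum(fact, "fb"),
                condition = cond, subjectId = ids[i])
          pw <- csdPower(csd)
          power[[cond]][[1]][i, ] <- pw[1L, bandSel]
          power[[cond]][[2]][i, ] <- pw[2L, bandSel]
          spectra[[paste(ids[i], cond, "rev", sep = ".")]] <-
            timeReversedGranger(sub, config$prestimWindow,
                                paste0(cond, "_rev"))
        }
      }
      pull <- function(slotName, cond, rev = FALSE) {
        t(vapply(ids, function(id) {
          key <- if (rev) paste(id, cond, "rev", sep = ".")
                 else paste(id, cond, sep = ".")
          slot(spectra[[key]], slotName)[bandSel]
        }, numeric(length(bandSel))))
      }
      tests <- list(
        powerV1 = clusterPermutationTest(
          power$face[[1]], power$vase[[1]], tail = "two",
          clusterAlpha = config$clusterAlpha, nPerm = config$nPerm,
          seed = config$seed),
        powerFFA = clusterPermutationTest(
          power$face[[2]], power$vase[[2]], tail = "two",
          clusterAlpha = config$clusterAlpha, nPerm = config$nPerm,
          seed = config$seed),
        coherence = clusterPermutationTest(
          pull("coherence", "face"), pull("coherence", "vase"),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed),
        imagCoherency = clusterPermutationTest(
          abs(pull("imagCoherency", "face")),
          abs(pull("imagCoherency", "vase")),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed),
        grangerFF = clusterPermutationTest(
          pull("grangerFF", "face"), pull("grangerFF", "vase"),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed),
        grangerFB = clusterPermutationTest(
          pull("grangerFB", "face"), pull("grangerFB", "vase"),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed),
        grangerFFReversed = clusterPermutationTest(
          pull("grangerFF", "face", TRUE), pull("grangerFF", "vase", TRUE),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed),
        grangerFBReversed = clusterPermutationTest(
          pull("grangerFB", "face", TRUE), pull("grangerFB", "vase", TRUE),
          tail = "greater", clusterAlpha = config$clusterAlpha,
          nPerm = config$nPerm, seed = config$seed))
      list(spectra = spectra, bandFreqs = freqs[bandSel], tests = tests,
           maxFeedbackDiff = vapply(ids, function(id)
             max((spectra[[paste(id, "face", sep = ".")]]@grangerFB -
                  spectra[[paste(id, "vase", sep = ".")]]@grangerFB)[bandSel]),
             numeric(1)))
    })

  if ("behavior" %in% config$stages) bundle$behavior <- stage("behavior", {
    seqs <- lapply(subjectsList, trialLabels)
    list(fit = runsBinomialFit(seqs),
         faceProportion = vapply(seqs, function(s) mean(s == "face"),
                                 numeric(1)))
  })

  if ("correlations" %in% config$stages &&
      all(c("decode", "tfr", "connectivity") %in% config$stages))
    bundle$correlations <- stage("correlations", {
      key <- sprintf("width%03.0fms", config$tfrWidths[1] * 1000)
      maxGamma <- vapply(seq_len(nSubj), function(i)
        max(bundle$tfr[[key]]$contrasts$FFA[i, ]), numeric(1))
      maxima <- data.frame(subject = ids,
                           maxAUC = bundle$decoding$maxAUC,
                           maxGamma = maxGamma,
                           maxFeedback = bundle$connectivity$maxFeedbackDiff)
      list(maxima = maxima, table = correlateMaxima(maxima))
    })

  if (!is.null(config$outDir)) writeBundle(bundle, config$outDir)
  bundle
}

#' Cross-subject correlations of per-subject maxima
#'
#' The three pairwise Pearson correlations between maximum prestimulus
#' feedback Granger difference, maximum post-stimulus gamma contrast, and
#' maximum decoding AUC, each with a two-sided p and a 95\% Fisher-z CI.
#'
#' @param maxima data.frame with columns \code{maxAUC}, \code{maxGamma},
#'   \code{maxFeedback} (one row per subject, no missing values).
#' @return data.frame with one row per pair: \code{pair, r, p, ciLo, ciHi}.
#' @export
correlateMaxima <- function(maxima) {
  need <- c("maxAUC", "maxGamma", "maxFeedback")
  if (!all(need %in% names(maxima)))
    stop("maxima must contain maxAUC, maxGamma and maxFeedback")
  if (anyNA(maxima[need]))
    stop("missing per-subject maxima are refused (no silent dropping)")
  pairs <- list(c("maxFeedback", "maxGamma"),
                c("maxFeedback", "maxAUC"),
                c("maxGamma", "maxAUC"))
  do.call(rbind, lapply(pairs, function(p) {
    pc <- pearsonCorr(maxima[[p[1]]], maxima[[p[2]]])
    data.frame(pair = paste(p, collapse = " ~ "), r = pc$r, p = pc$p,
               ciLo = pc$ci[1], ciHi = pc$ci[2])
  }))
}

.configAsList <- function(config) {
  sim <- config$simulation
  simList <- lapply(slotNames(sim), function(s) {
    v <- slot(sim, s)
    if (is.list(v) && length(v) && is.matrix(v[[1]]))
      lapply(v, function(m) as.vector(m)) else v
  })
  names(simList) <- slotNames(sim)
  c(list(simulation = simList),
    config[setdiff(names(config), c("simulation", "outDir"))])
}

# JSON-serializable summary of a cluster test
.testSummary <- function(tst) {
  list(tail = tst@tail, nPermutations = tst@nPermutations,
       threshold = tst@threshold,
       pCluster = if (length(tst@pCluster)) tst@pCluster else numeric(0),
       nClusters = length(tst@clusters))
}

#' Serialize a results bundle to disk
#'
#' Writes \code{summary.json} (config, seeds, subject list, every cluster
#' test's settings and p-values, correlation table, behavioral fit) at the
#' bundle root plus tidy CSVs per stage (AUC curves, connectivity spectra,
#' maxima). Arrays that are cheap to regenerate (raw TFR contrasts) are not
#' serialized.
#'
#' @param bundle a results bundle from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(provenance = bundle$provenance, subjects = bundle$subjects)
  if (!is.null(bundle$decoding)) {
    summary$decoding <- list(
      significance = .testSummary(bundle$decoding$significance),
      maxAUC = bundle$decoding$maxAUC,
      rois = lapply(bundle$decoding$rois, as.integer))
    auc <- data.table::rbindlist(lapply(seq_along(bundle$decoding$results),
      function(i) {
        r <- bundle$decoding$results[[i]]
        data.table::data.table(subject = bundle$subjects[i],
                               time_s = r@times, auc = r@auc)
      }))
    data.table::fwrite(auc, file.path(dir, "decoding_auc.csv"))
  }
  if (!is.null(bundle$tfr))
    summary$tfr <- lapply(bundle$tfr, function(w)
      list(freqs = w$freqs, times = w$times,
           tests = lapply(w$tests, .testSummary)))
  if (!is.null(bundle$connectivity)) {
    summary$connectivity <- list(
      bandFreqs = bundle$connectivity$bandFreqs,
      tests = lapply(bundle$connectivity$tests, .testSummary),
      maxFeedbackDiff = bundle$connectivity$maxFeedbackDiff)
    writeConnectivityCSV(bundle$connectivity$spectra,
                         file.path(dir, "connectivity.csv"))
  }
  if (!is.null(bundle$behavior))
    summary$behavior <- list(
      rSquared = bundle$behavior$fit@rSquared,
      pHat = bundle$behavior$fit@pHat,
      binCounts = bundle$behavior$fit@binCounts,
      stochastic = bundle$behavior$fit@stochastic,
      faceProportion = bundle$behavior$faceProportion)
  if (!is.null(bundle$correlations)) {
    summary$correlations <- bundle$correlations$table
    data.table::fwrite(bundle$correlations$maxima,
                       file.path(dir, "maxima.csv"))
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
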