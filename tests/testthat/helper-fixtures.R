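# fixtures are built in code at test time; nothing is stored on disk

# wrap a [trials x channels x samples] array into TrialEpochs
makeEpochs <- function(dat, fs = 250, t0 = -1, labels = NULL,
                       kind = "source", id = "S01") {
  d <- dim(dat)
  if (is.null(labels)) labels <- rep(c("face", "vase"), length.out = d[1])
  chn <- if (d[2] == 2 && kind == "source") c("V1", "FFA")
         else sprintf("CH%02d", seq_len(d[2]))
  new("TrialEpochs", data = dat, time = t0 + (seq_len(d[3]) - 1) / fs,
      labels = labels, sampleRate = fs, channelKind = kind,
      channelNames = chn, subjectId = id)
}

# epochs drawn from a stable VAR, one condition
varEpochs <- function(coeffs, nTrials, nSamples = 250, seed = 1,
                      noiseCov = diag(2), fs = 250, t0 = -1,
                      label = "face") {
  dat <- varGenerate(coeffs, noiseCov, nSamples, seed = seed,
                     nTrials = nTrials)
  makeEpochs(dat, fs = fs, t0 = t0, labels = rep(label, nTrials))
}

# a separable decoding problem: mean shift on two channels from 0.1 s
separableEpochs <- function(nTrials = 80, nCh = 8, shift = 3, seed = 2) {
  set.seed(seed)
  fs <- 100
  tt <- seq(-0.5, 0.5 - 1 / fs, by = 1 / fs)
  dat <- array(rnorm(nTrials * nCh * length(tt)),
               dim = c(nTrials, nCh, length(tt)))
  labels <- rep(c("face", "vase"), nTrials / 2)
  on <- tt >= 0.1
  dat[labels == "face", 1, on] <- dat[labels == "face", 1, on] + shift
  dat[labels == "face", 2, on] <- dat[labels == "face", 2, on] + shift / 2
  makeEpochs(dat, fs = fs, t0 = -0.5, labels = labels)
}

# small simulation config for fast tests
smallConfig <- function(...) {
  simulationConfig(nSubjects = 2L, nTrials = 40L, nSensors = 12L, ...)
}
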