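#' @include AllClasses.R
NULL

#' Write trial epochs to the package's text container
#'
#' The container is deliberately plain text: `<stem>_data.csv` holds the
#' array in wide form (one row per trial x channel, one column per sample),
#' `<stem>_labels.csv` the per-trial labels (`trial,label`), and
#' `<stem>_meta.json` the attributes (sample rate, subject id, channel kind
#' and names, epoch start). [readEpochs()] inverts it exactly (up to double
#' round-trip through decimal text, 15 significant digits).
#'
#' @param epochs a [TrialEpochs-class].
#' @param stem path stem (directory must exist); three files are written.
#' @return the stem, invisibly.
#' @export
writeEpochs <- function(epochs, stem) {
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
  dt <- data.table::data.table(
    trial = rep(seq_len(d[1L]), each = d[2L]),
    channel = rep(epochs@channelNames, d[1L]))
  data.table::fwrite(cbind(dt, data.table::as.data.table(flat)),
                     paste0(stem, "_data.csv"))
  data.table::fwrite(data.table::data.table(trial = seq_len(d[1L]),
                                            label = epochs@labels),
                     paste0(stem, "_labels.csv"))
  jsonlite::write_json(
    list(sampleRate = epochs@sampleRate, subjectId = epochs@subjectId,
         channelKind = epochs@channelKind, channelNames = epochs@channelNames,
         timeStart = epochs@time[1L], nTrials = d[1L], nChannels = d[2L],
         nSamples = d[3L]),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read trial epochs from the package's text container
#'
#' @param stem path stem previously passed to [writeEpochs()].
#' @return a [TrialEpochs-class].
#' @export
readEpochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  lab <- data.table::fread(paste0(stem, "_labels.csv"))
  raw <- data.table::fread(paste0(stem, "_data.csv"))
  flat <- as.matrix(raw[, -(1:2)])
  dat <- aperm(array(flat, dim = c(meta$nChannels, meta$nTrials,
                                   meta$nSamples)), c(2L, 1L, 3L))
  new("TrialEpochs", data = dat,
      time = meta$timeStart + (seq_len(meta$nSamples) - 1L) / meta$sampleRate,
      labels = lab$label, sampleRate = meta$sampleRate,
      channelKind = meta$channelKind, channelNames = meta$channelNames,
      subjectId = meta$subjectId)
}

#' Tidy CSV export of connectivity spectra
#'
#' One row per subject, condition, frequency and measure
#' (`subject,condition,freq_hz,measure,value`).
#'
#' @param spectra list of [ConnectivitySpectrum-class] objects.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeConnectivityCSV <- function(spectra, file) {
  rows <- lapply(spectra, function(cs) {
    data.table::data.table(
      subject = cs@subjectId, condition = cs@condition,
      freq_hz = rep(cs@freqs, 4L),
      measure = rep(c("coherence", "imag_coherency", "granger_ff",
                      "granger_fb"), each = length(cs@freqs)),
      value = c(cs@coherence, cs@imagCoherency, cs@grangerFF, cs@grangerFB))
  })
  data.table::fwrite(data.table::rbindlist(rows), file)
  invisible(file)
}
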