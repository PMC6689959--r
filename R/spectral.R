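#' @include AllClasses.R
NULL

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Solves the spectral concentration problem via the classical symmetric
#' tridiagonal formulation and returns the \code{nTapers} most concentrated
#' sequences, unit-norm and ordered by decreasing concentration. The
#' concentration eigenvalues are evaluated exactly as the quadratic form of
#' each taper with the sinc kernel of half-bandwidth \code{timeBandwidth/n}.
#'
#' @param nSamples sequence length (>= 8).
#' @param timeBandwidth time-bandwidth product NW.
#' @param nTapers number of tapers; must not exceed \code{floor(2*NW) - 1}.
#' @return a [TaperSet-class].
#' @export
dpssTapers <- function(nSamples, timeBandwidth, nTapers) {
  n <- as.integer(nSamples)
  if (n < 8L) stop("nSamples must be at least 8")
  kmax <- floor(2 * timeBandwidth) - 1
  if (nTapers > kmax)
    stop(sprintf("nTapers = %d exceeds the concentration bound floor(2*NW)-1 = %d",
                 nTapers, kmax))
  W <- timeBandwidth / n
  tt <- 0:(n - 1L)
  Tm <- matrix(0, n, n)
  diag(Tm) <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W)
  off <- tt[-1L] * (n - tt[-1L]) / 2
  Tm[cbind(2:n, 1:(n - 1L))] <- off
  Tm[cbind(1:(n - 1L), 2:n)] <- off
  eg <- eigen(Tm, symmetric = TRUE)
  h <- t(eg$vectors[, seq_len(nTapers), drop = FALSE])
  # polarity convention: positive mean for symmetric tapers, positive
  # leading lobe otherwise (spectra are polarity-blind)
  for (k in seq_len(nTapers)) {
    s <- sum(h[k, ])
    if (abs(s) > 1e-8) {
      if (s < 0) h[k, ] <- -h[k, ]
    } else if (h[k, which.max(abs(h[k, seq_len(n %/% 2)]))] < 0) {
      h[k, ] <- -h[k, ]
    }
  }
  dm <- outer(tt, tt, `-`)
  K <- sin(2 * pi * W * dm) / (pi * dm)
  diag(K) <- 2 * W
  conc <- vapply(seq_len(nTapers),
                 function(k) drop(h[k, ] %*% K %*% h[k, ]), numeric(1))
  new("TaperSet", tapers = h, concentrations = conc,
      timeBandwidth = timeBandwidth)
}

# tapered Fourier coefficients of one windowed segment.
# dat: [trials, channels, samples]; returns X [nfreq, trials, channels, K]
# scaled so that |X|^2/fs is a two-sided density per Hz, plus the freq grid.
.mtFourier <- function(dat, fs, timeBandwidth, nTapers, padTo = NULL) {
  d <- dim(dat)
  n <- d[3L]
  ts <- dpssTapers(n, timeBandwidth, nTapers)
  nfft <- if (is.null(padTo)) n else max(n, as.integer(padTo))
  nfreq <- nfft %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nfft
  D <- matrix(aperm(dat, c(3L, 1L, 2L)), nrow = n)      # samples x (trial*ch)
  D <- sweep(D, 2L, colMeans(D))                         # per-window demean
  X <- array(0i, dim = c(nfreq, d[1L], d[2L], nTapers))
  buf <- matrix(0, nfft, ncol(D))
  for (k in seq_len(nTapers)) {
    buf[seq_len(n), ] <- D * ts@tapers[k, ]
    Xk <- stats::mvfft(buf)[seq_len(nfreq), , drop = FALSE]
    X[, , , k] <- array(Xk, dim = c(nfreq, d[1L], d[2L]))
  }
  list(freqs = freqs, X = X, tapers = ts)
}

.windowIndex <- function(time, window) {
  idx <- which(time >= window[1] - 1e-9 & time < window[2] - 1e-9)
  if (!length(idx))
    stop("analysis window lies outside the epoch")
  if (time[idx[1]] - window[1] > 1e-9 || window[2] - time[idx[length(idx)]] < 0)
    stop("analysis window extends beyond the epoch")
  idx
}

#' Multitaper cross-spectral density
#'
#' Tapered Fourier coefficients are computed per trial and taper over the
#' requested window (per-window mean removal only, no padding unless asked);
#' the cross-spectral matrix is averaged over all trial x taper estimates.
#' Scaling is a two-sided density per Hz: summing an auto-spectrum over the
#' full two-sided grid times the frequency step recovers the time-domain
#' variance (Parseval).
#'
#' @param epochs a [TrialEpochs-class].
#' @param window c(start, end) seconds; samples with \code{start <= t < end}
#'   are used, so a (-1, 0) window at 250 Hz is exactly 250 samples.
#' @param timeBandwidth time-bandwidth product NW (default 2: +/-2 Hz
#'   smoothing for a 1-s window).
#' @param nTapers number of tapers (default \code{floor(2*NW) - 1}).
#' @param freqRange optional c(lo, hi) Hz to subset the returned grid; the hi
#'   edge must respect the Nyquist frequency.
#' @param padTo optional FFT length for zero-padding (default none: the grid
#'   is at the window's Rayleigh resolution).
#' @return a [CrossSpectralDensity-class].
#' @export
multitaperCSD <- function(epochs, window, timeBandwidth = 2, nTapers = NULL,
                          freqRange = NULL, padTo = NULL) {
  if (is.null(nTapers)) nTapers <- floor(2 * timeBandwidth) - 1
  if (!is.null(freqRange)) {
    if (freqRange[2] <= freqRange[1]) stop("empty frequency range")
    if (freqRange[2] > epochs@sampleRate / 2)
      stop("frequency range exceeds the Nyquist frequency")
  }
  idx <- .windowIndex(epochs@time, window)
  dat <- epochs@data[, , idx, drop = FALSE]
  mt <- .mtFourier(dat, epochs@sampleRate, timeBandwidth, nTapers, padTo)
  d <- dim(dat)
  nfreq <- length(mt$freqs)
  nEst <- d[1L] * nTapers
  S <- array(0i, dim = c(d[2L], d[2L], nfreq))
  for (c1 in seq_len(d[2L])) {
    for (c2 in c1:d[2L]) {
      acc <- numeric(nfreq) + 0i
      for (k in seq_len(nTapers)) {
        cross <- mt$X[, , c1, k] * Conj(mt$X[, , c2, k])
        acc <- acc + if (d[1L] > 1L) rowSums(cross) else cross
      }
      S[c1, c2, ] <- acc / (nEst * epochs@sampleRate)
      if (c2 > c1) S[c2, c1, ] <- Conj(S[c1, c2, ])
    }
  }
  # remove imaginary dust from the auto-spectra
  for (c1 in seq_len(d[2L])) S[c1, c1, ] <- Re(S[c1, c1, ]) + 0i
  keep <- if (is.null(freqRange)) seq_len(nfreq) else
    which(mt$freqs >= freqRange[1] & mt$freqs <= freqRange[2])
  new("CrossSpectralDensity", freqs = mt$freqs[keep],
      S = S[, , keep, drop = FALSE], nEstimates = nEst,
      window = as.numeric(window), sampleRate = epochs@sampleRate,
      channelNames = epochs@channelNames)
}

#' Auto-spectral power from a cross-spectral density
#'
#' @param csd a [CrossSpectralDensity-class].
#' @return matrix \code{[channels, freqs]} of real nonnegative power densities.
#' @export
csdPower <- function(csd) {
  d <- dim(csd@S)
  out <- matrix(0, d[1L], d[3L], dimnames = list(csd@channelNames, NULL))
  for (c1 in seq_len(d[1L])) out[c1, ] <- Re(csd@S[c1, c1, ])
  out
}

#' Sliding-window multitaper time-frequency power
#'
#' Multitaper power in windows of fixed width centered on a regular grid of
#' output times; window centers are clipped so every window lies inside the
#' epoch (no padding). The effect of the width is deliberate and testable:
#' a 300-ms window smears a post-stimulus burst into window centers up to
#' 150 ms before onset, while a 100-ms window confines it to post-stimulus
#' centers.
#'
#' @param epochs a [TrialEpochs-class].
#' @param windowWidth analysis window width in seconds.
#' @param step spacing of window centers in seconds.
#' @param timeBandwidth NW; default \code{max(1.5, 10 * windowWidth)} gives
#'   +/-10 Hz smoothing for gamma-range windows and a near-Hann taper for
#'   narrow low-frequency windows.
#' @param freqRange optional c(lo, hi) Hz subset of the window's natural grid.
#' @param padTo optional FFT length per window.
#' @return a [TimeFrequencyMap-class] (\code{trials x channels x freqs x times}).
#' @export
tfrPower <- function(epochs, windowWidth, step,
                     timeBandwidth = max(1.5, 10 * windowWidth),
                     freqRange = NULL, padTo = NULL) {
  fs <- epochs@sampleRate
  n <- round(windowWidth * fs)
  d <- dim(epochs@data)
  if (n > d[3L]) stop("analysis window is longer than the epoch")
  nTapers <- max(1L, floor(2 * timeBandwidth) - 1)
  half <- windowWidth / 2
  t0 <- epochs@time[1L]
  t1 <- epochs@time[d[3L]]
  centers <- seq(ceiling((t0 + half) / step) * step, t1 - half + 1e-9,
                 by = step)
  if (!length(centers)) stop("no window center fits inside the epoch")
  ts <- dpssTapers(n, timeBandwidth, nTapers)
  nfft <- if (is.null(padTo)) n else max(n, as.integer(padTo))
  nfreq <- nfft %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nfft
  keep <- if (is.null(freqRange)) seq_len(nfreq) else
    which(freqs >= freqRange[1] & freqs <= freqRange[2])
  if (!length(keep)) stop("empty frequency range")
  pow <- array(0, dim = c(d[1L], d[2L], length(keep), length(centers)))
  buf <- matrix(0, nfft, d[1L] * d[2L])
  for (ci in seq_along(centers)) {
    i0 <- which.min(abs(epochs@time - (centers[ci] - half)))
    idx <- i0:(i0 + n - 1L)
    D <- matrix(aperm(epochs@data[, , idx, drop = FALSE], c(3L, 1L, 2L)),
                nrow = n)
    D <- sweep(D, 2L, colMeans(D))
    acc <- matrix(0, length(keep), ncol(D))
    for (k in seq_len(nTapers)) {
      buf[seq_len(n), ] <- D * ts@tapers[k, ]
      Xk <- stats::mvfft(buf)[keep, , drop = FALSE]
      acc <- acc + Re(Xk * Conj(Xk))
    }
    pow[, , , ci] <- aperm(array(acc / (nTapers * fs),
                                 dim = c(length(keep), d[1L], d[2L])),
                           c(2L, 3L, 1L))
  }
  new("TimeFrequencyMap", power = pow, freqs = freqs[keep], times = centers,
      windowWidth = windowWidth, channelNames = epochs@channelNames)
}
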