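#' @include AllClasses.R
NULL

# ---- small complex 2x2-per-frequency algebra -------------------------------
# matrices are stored as lists with components a11, a12, a21, a22, each a
# complex vector over frequencies; this keeps the Wilson iteration fully
# vectorized over the frequency grid.

.mat2list <- function(A) list(a11 = A[1, 1, ], a12 = A[1, 2, ],
                              a21 = A[2, 1, ], a22 = A[2, 2, ])

.list2mat <- function(L) {
  out <- array(0i, dim = c(2, 2, length(L$a11)))
  out[1, 1, ] <- L$a11; out[1, 2, ] <- L$a12
  out[2, 1, ] <- L$a21; out[2, 2, ] <- L$a22
  out
}

.mm22 <- function(A, B) list(
  a11 = A$a11 * B$a11 + A$a12 * B$a21,
  a12 = A$a11 * B$a12 + A$a12 * B$a22,
  a21 = A$a21 * B$a11 + A$a22 * B$a21,
  a22 = A$a21 * B$a12 + A$a22 * B$a22)

.inv22 <- function(A) {
  det <- A$a11 * A$a22 - A$a12 * A$a21
  list(a11 = A$a22 / det, a12 = -A$a12 / det,
       a21 = -A$a21 / det, a22 = A$a11 / det)
}

.ctrans22 <- function(A) list(a11 = Conj(A$a11), a12 = Conj(A$a21),
                              a21 = Conj(A$a12), a22 = Conj(A$a22))

# ---- coherence measures ----------------------------------------------------

.checkEstimates <- function(csd) {
  if (csd@nEstimates < 2)
    stop(paste("coherency of a single trial/taper estimate is degenerate",
               "(identically 1); supply a CSD averaged over >= 2 estimates"))
}

#' Magnitude coherence between two channels
#'
#' \code{|mean S_xy| / sqrt(mean S_xx * mean S_yy)} per frequency, the means
#' taken over all trial x taper estimates inside the CSD. Values lie in
#' [0, 1] by Cauchy-Schwarz; for independent signals the squared coherence
#' has a small-sample bias floor of about 1/nEstimates.
#'
#' @param csd a trial/taper-averaged [CrossSpectralDensity-class] built from
#'   at least 2 estimates.
#' @param pair integer pair of channel indices (default 1:2).
#' @return numeric vector over the CSD's frequency grid.
#' @export
csdCoherence <- function(csd, pair = c(1L, 2L)) {
  .checkEstimates(csd)
  sxx <- Re(csd@S[pair[1], pair[1], ])
  syy <- Re(csd@S[pair[2], pair[2], ])
  pmin(1, Mod(csd@S[pair[1], pair[2], ]) / sqrt(pmax(sxx * syy, 1e-300)))
}

#' Imaginary part of coherency
#'
#' Insensitive to zero-lag (volume-conduction-like) mixing: an instantaneous
#' mixture of one common source has a real-valued cross-spectrum, so its
#' imaginary coherency vanishes while magnitude coherence can be near 1.
#'
#' @inheritParams csdCoherence
#' @return numeric vector in [-1, 1] over the CSD's frequency grid.
#' @export
csdImagCoherency <- function(csd, pair = c(1L, 2L)) {
  .checkEstimates(csd)
  sxx <- Re(csd@S[pair[1], pair[1], ])
  syy <- Re(csd@S[pair[2], pair[2], ])
  v <- Im(csd@S[pair[1], pair[2], ]) / sqrt(pmax(sxx * syy, 1e-300))
  pmax(-1, pmin(1, v))
}

# ---- Wilson spectral-matrix factorization ----------------------------------

# causal ("plus") part of a matrix function on the full two-sided grid:
# inverse DFT over frequency to lag coefficients, keep nonnegative lags, DFT
# back. The lag-0 coefficient g0 (Hermitian) is split as B + B^H with B upper
# triangular -- diagonal halved, upper off-diagonal kept in full, lower zeroed
# -- which pins down the arbitrary unitary factor of the factorization; the
# shared half-spectrum lag (n2/2, self-conjugate on an even grid) is halved.
.plusOperator <- function(G, nHalf) {
  n2 <- length(G$a11)
  gam <- lapply(G, function(v) stats::fft(v, inverse = TRUE) / n2)
  keep <- seq_len(nHalf)
  out <- lapply(gam, function(v) { v[-keep] <- 0i; v })
  out$a11[1] <- gam$a11[1] / 2
  out$a22[1] <- gam$a22[1] / 2
  out$a21[1] <- 0i
  for (nm in names(out)) out[[nm]][nHalf] <- out[[nm]][nHalf] / 2
  lapply(out, stats::fft)
}

#' Wilson's spectral-matrix factorization
#'
#' Iteratively factorizes a cross-spectral density \eqn{S(f) = H(f) \Sigma
#' H(f)^*} into a minimum-phase transfer function and an innovation
#' covariance, without fitting an autoregressive model. This is the engine of
#' nonparametric spectral Granger causality. The CSD must cover a uniform
#' frequency grid from 0 to the Nyquist frequency. A ridge of
#' \code{1e-10 x mean auto-spectrum} is added where a frequency's matrix is
#' numerically non-PSD (finite-sample guard; reported via a message).
#'
#' @param csd a trial-averaged 2-channel [CrossSpectralDensity-class] on a
#'   full half-spectrum grid including 0 and Nyquist.
#' @param tol convergence tolerance on the successive-iterate relative change.
#' @param maxIter maximum number of iterations.
#' @return a [SpectralFactorization-class]; if the iteration does not reach
#'   \code{tol}, the result is returned with \code{converged = FALSE} and a
#'   warning.
#' @export
wilsonFactorize <- function(csd, tol = 1e-9, maxIter = 100L) {
  S <- csd@S
  freqs <- csd@freqs
  m <- dim(S)[1L]
  if (m != 2L) stop("the factorization is implemented for 2-channel CSDs")
  M <- length(freqs)
  df <- diff(freqs)
  if (max(abs(df - df[1])) > 1e-9 * df[1] || abs(freqs[1]) > 1e-12)
    stop("factorization requires a uniform frequency grid starting at 0")
  if (abs(freqs[M] - csd@sampleRate / 2) > 1e-6)
    stop("factorization requires the grid to end at the Nyquist frequency")
  # PSD guard
  nRidge <- 0L
  for (i in seq_len(M)) {
    Sf <- S[, , i]
    ev <- eigen((Sf + Conj(t(Sf))) / 2, only.values = TRUE)$values
    if (min(Re(ev)) <= 0) {
      S[, , i] <- Sf + diag(2) * 1e-10 * mean(Re(diag(Sf)))
      nRidge <- nRidge + 1L
      ev <- eigen(S[, , i], only.values = TRUE)$values
      if (min(Re(ev)) <= 0)
        stop(sprintf("CSD is not positive semi-definite at %.3f Hz", freqs[i]))
    }
  }
  if (nRidge > 0)
    message(sprintf("wilsonFactorize: ridge regularization applied at %d of %d frequencies",
                    nRidge, M))
  n2 <- 2L * (M - 1L)
  # full two-sided grid: S(-f) = Conj(S(f)) elementwise for real signals
  Sf <- array(0i, dim = c(2, 2, n2))
  Sf[, , seq_len(M)] <- S
  if (M > 2)
    Sf[, , (M + 1L):n2] <- Conj(S[, , (M - 1L):2])
  SL <- .mat2list(Sf)
  Smean <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2)
    Smean[a, b] <- Re(mean(Sf[a, b, ]))
  R <- chol((Smean + t(Smean)) / 2)
  ones <- rep(1 + 0i, n2)
  psi <- list(a11 = R[1, 1] * ones, a12 = R[1, 2] * ones,
              a21 = R[2, 1] * ones, a22 = R[2, 2] * ones)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    psiInv <- .inv22(psi)
    G <- .mm22(.mm22(psiInv, SL), .ctrans22(psiInv))
    G$a11 <- G$a11 + 1; G$a22 <- G$a22 + 1
    gp <- .plusOperator(G, M)
    psiNew <- .mm22(psi, gp)
    num <- 0; den <- 0
    for (nm in names(psi)) {
      num <- max(num, max(Mod(psiNew[[nm]] - psi[[nm]])))
      den <- max(den, max(Mod(psi[[nm]])))
    }
    psi <- psiNew
    if (num / den < tol) { converged <- TRUE; break }
  }
  A0 <- matrix(c(Re(mean(psi$a11)), Re(mean(psi$a21)),
                 Re(mean(psi$a12)), Re(mean(psi$a22))), 2, 2)
  Sigma <- A0 %*% t(A0)
  A0inv <- solve(A0)
  Hl <- .mm22(psi, list(a11 = A0inv[1, 1] * ones, a12 = A0inv[1, 2] * ones,
                        a21 = A0inv[2, 1] * ones, a22 = A0inv[2, 2] * ones))
  H <- .list2mat(Hl)[, , seq_len(M), drop = FALSE]
  # reconstruction residual on the one-sided grid
  resid <- 0
  for (i in seq_len(M)) {
    Hi <- H[, , i]
    Rec <- Hi %*% Sigma %*% Conj(t(Hi))
    resid <- max(resid, sqrt(sum(Mod(Rec - S[, , i])^2)) /
                          max(sqrt(sum(Mod(S[, , i])^2)), 1e-300))
  }
  if (!converged)
    warning(sprintf("Wilson factorization did not converge in %d iterations (residual %.3g)",
                    maxIter, resid))
  new("SpectralFactorization", H = H, Sigma = Sigma, freqs = freqs,
      converged = converged, nIter = it, residual = resid)
}

# ---- Geweke spectral Granger causality -------------------------------------

# Geweke's frequency-domain measure from (H, Sigma) for direction from -> to,
# with the standard partial conditioning on correlated innovations
.gewekeFromHS <- function(H, Sigma, from, to) {
  M <- dim(H)[3L]
  hTT <- H[to, to, ]
  hTF <- H[to, from, ]
  sTT <- Re(Sigma[to, to])
  sFF <- Re(Sigma[from, from])
  sTF <- Re(Sigma[to, from])
  sPartial <- sFF - sTF^2 / sTT
  Stoto <- Re(hTT * sTT * Conj(hTT) + hTT * sTF * Conj(hTF) +
              hTF * sTF * Conj(hTT) + hTF * sFF * Conj(hTF))
  intrinsic <- Stoto - sPartial * Mod(hTF)^2
  val <- log(Stoto / pmax(intrinsic, 1e-300))
  val
}

#' Nonparametric spectral Granger causality
#'
#' Computes Geweke's frequency-domain directed measure from a Wilson
#' factorization of the trial-averaged cross-spectral density. Channel order
#' is (V1, FFA): \code{direction = "fb"} is feedback FFA -> V1,
#' \code{"ff"} feedforward V1 -> FFA. Tiny negative values arising from
#' finite precision are clipped at zero; clipping is counted and reported
#' through a message when it occurs.
#'
#' @param csd a 2-channel [CrossSpectralDensity-class] on a full 0-Nyquist
#'   grid, or a precomputed [SpectralFactorization-class].
#' @param direction \code{"fb"} (FFA to V1) or \code{"ff"} (V1 to FFA).
#' @param ... passed on to [wilsonFactorize()].
#' @return nonnegative numeric vector over the factorization's grid.
#' @export
grangerSpectrum <- function(csd, direction = c("fb", "ff"), ...) {
  direction <- match.arg(direction)
  fact <- if (is(csd, "SpectralFactorization")) csd else wilsonFactorize(csd, ...)
  if (!fact@converged)
    warning("using a non-converged factorization for the Granger spectrum")
  idx <- if (direction == "fb") c(2L, 1L) else c(1L, 2L)
  val <- .gewekeFromHS(fact@H, fact@Sigma, idx[1], idx[2])
  nClip <- sum(val < 0)
  if (nClip > 0 && min(val) < -1e-8)
    message(sprintf("grangerSpectrum: clipped %d negative value(s) (min %.3g)",
                    nClip, min(val)))
  pmax(val, 0)
}

#' Closed-form Geweke Granger spectrum of a VAR model (parametric oracle)
#'
#' Evaluates the analytic transfer function \eqn{H(f) = (I - \sum_k A_k
#' e^{-2\pi i f k / fs})^{-1}} of a stable VAR and applies Geweke's formula
#' directly. Serves as the independent closed-form reference against which
#' the nonparametric (Wilson) path is validated; the measure is invariant
#' under a common rescaling of the innovation covariance.
#'
#' @param coeffs lag-indexed list of 2x2 coefficient matrices.
#' @param noiseCov 2x2 innovation covariance.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param sampleRate sampling rate in Hz.
#' @return list with \code{freqs}, \code{ff} (1 -> 2), \code{fb} (2 -> 1) and
#'   the analytic spectral matrix \code{S} \code{[2, 2, freqs]}.
#' @export
parametricGrangerVAR <- function(coeffs, noiseCov, freqs, sampleRate) {
  .checkStable(coeffs)
  M <- length(freqs)
  H <- array(0i, dim = c(2, 2, M))
  S <- array(0i, dim = c(2, 2, M))
  for (i in seq_len(M)) {
    A <- diag(2) + 0i
    for (k in seq_along(coeffs))
      A <- A - coeffs[[k]] * exp(-2i * pi * freqs[i] * k / sampleRate)
    Hi <- solve(A)
    H[, , i] <- Hi
    S[, , i] <- Hi %*% noiseCov %*% Conj(t(Hi))
  }
  list(freqs = freqs,
       ff = pmax(.gewekeFromHS(H, noiseCov, 1L, 2L), 0),
       fb = pmax(.gewekeFromHS(H, noiseCov, 2L, 1L), 0),
       S = S)
}

#' Canonical unidirectionally coupled test VAR
#'
#' The package's reference model for validating the nonparametric Granger
#' path against the closed-form oracle: channel 1 (the target, V1-like) is a
#' weak AR(1), channel 2 (the source, FFA-like) a 10-Hz AR(2) resonator with
#' pole radius 0.8, coupled 2 -> 1 at lags 2-3. The asymmetric design keeps
#' the Geweke feedback spectrum peaked well inside the band and broad enough
#' that multitaper smoothing bias is small relative to sampling error.
#'
#' @param coupling total 2 -> 1 coefficient, split over lags 2-3.
#' @param sampleRate sampling rate in Hz.
#' @return list of lag-indexed 2x2 coefficient matrices (order 5).
#' @export
canonicalTestVAR <- function(coupling = 0.3, sampleRate = 250) {
  A <- replicate(5, matrix(0, 2, 2), simplify = FALSE)
  A[[1]][1, 1] <- 0.3
  A[[1]][2, 2] <- 2 * 0.8 * cos(2 * pi * 10 / sampleRate)
  A[[2]][2, 2] <- -0.64
  A[[2]][1, 2] <- coupling / 2
  A[[3]][1, 2] <- coupling / 2
  A
}

#' Full connectivity spectrum for one condition of one subject
#'
#' Prestimulus-window multitaper CSD followed by coherence, imaginary
#' coherency and both directed Granger spectra (via Wilson factorization on
#' the full 0-Nyquist grid; any statistical band restriction happens later,
#' at the statistics stage).
#'
#' @param epochs a 2-channel source-level [TrialEpochs-class] (V1, FFA).
#' @param window analysis window in seconds (default the prestimulus second,
#'   c(-1, 0)).
#' @param condition condition label stored with the result.
#' @param timeBandwidth,nTapers multitaper parameters, see [multitaperCSD()].
#' @param reversed if TRUE, reverse each trial's samples in time first
#'   (the time-reversal control for directed estimates).
#' @return a [ConnectivitySpectrum-class].
#' @export
connectivityAnalysis <- function(epochs, window = c(-1, 0),
                                 condition = "all", timeBandwidth = 2,
                                 nTapers = NULL, reversed = FALSE) {
  if (nChannels(epochs) != 2L)
    stop("connectivityAnalysis expects the 2-channel (V1, FFA) source epochs")
  if (reversed) epochs <- reverseTime(epochs)
  csd <- multitaperCSD(epochs, window, timeBandwidth = timeBandwidth,
                       nTapers = nTapers)
  fact <- wilsonFactorize(csd)
  new("ConnectivitySpectrum",
      freqs = csd@freqs,
      coherence = csdCoherence(csd),
      imagCoherency = csdImagCoherency(csd),
      grangerFF = grangerSpectrum(fact, "ff"),
      grangerFB = grangerSpectrum(fact, "fb"),
      condition = condition, subjectId = epochs@subjectId)
}

#' Granger analysis on time-reversed data
#'
#' Repeats the spectral Granger estimation after flipping every trial's
#' samples in time. For genuinely lagged (directed) interactions the
#' dominance of the two directions is expected to reverse, while auto-spectra
#' are invariant; failure to flip flags spurious directionality.
#'
#' @inheritParams connectivityAnalysis
#' @return a [ConnectivitySpectrum-class] computed on the reversed data.
#' @export
timeReversedGranger <- function(epochs, window = c(-1, 0), condition = "all",
                                timeBandwidth = 2, nTapers = NULL) {
  connectivityAnalysis(epochs, window, condition, timeBandwidth, nTapers,
                       reversed = TRUE)
}
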