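#' @include AllClasses.R
NULL

#' Z-normalize features using training statistics only
#'
#' Per-channel mean and SD are estimated on the training partition and
#' applied to both partitions, so no information leaks from held-out trials
#' into the normalization. Zero-variance channels have their SD floored at
#' 1e-12 (a warning is raised) so degenerate inputs stay finite.
#'
#' @param train numeric matrix trials x channels (>= 2 rows).
#' @param test numeric matrix with the same channel count.
#' @return list with normalized \code{train} and \code{test} plus the
#'   \code{center}/\code{scale} used.
#' @export
zscoreFeatures <- function(train, test) {
  if (nrow(train) < 2) stop("at least 2 training trials required")
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  if (any(sdv < 1e-12)) {
    warning("zero-variance channel(s): SD floored at 1e-12")
    sdv <- pmax(sdv, 1e-12)
  }
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, `/`),
       center = mu, scale = sdv)
}

# zero-phase band-pass: symmetric even-order FIR applied by FFT convolution
# with reflective padding and exact integer group-delay compensation.
# dat: [trials, channels, samples] -> same shape, filtered along samples.
.bandFilter <- function(dat, fs, band, order = NULL) {
  d <- dim(dat)
  n <- d[3L]
  if (is.null(order)) order <- min(160L, 2L * ((n - 1L) %/% 3L))
  if (order %% 2L == 1L) order <- order + 1L
  g <- order %/% 2L
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  D <- matrix(aperm(dat, c(3L, 1L, 2L)), nrow = n)
  P <- rbind(D[(g + 1L):2L, , drop = FALSE], D,
             D[(n - 1L):(n - g), , drop = FALSE])
  nP <- nrow(P)
  nfft <- 2L^ceiling(log2(nP + order))
  Bf <- stats::fft(c(b, rep(0, nfft - length(b))))
  X <- stats::mvfft(rbind(P, matrix(0, nfft - nP, ncol(P))))
  Y <- Re(stats::mvfft(X * Bf, inverse = TRUE)) / nfft
  out <- Y[(2L * g + 1L):(2L * g + n), , drop = FALSE]
  aperm(array(out, dim = c(n, d[1L], d[2L])), c(2L, 3L, 1L))
}

# stratified, seeded fold assignment; fold sizes differ by <= 1 and each
# fold preserves the label ratio within 1 trial
.stratifiedFolds <- function(labels, nFolds, seed) {
  .withSeed(seed, {
    fold <- integer(length(labels))
    offset <- 0L
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
      offset <- offset + length(idx)
    }
    fold
  })
}

# Mann-Whitney AUC of decision values for the positive class
.auc <- function(dv, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(dv)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Band-limit epochs with a zero-phase FIR filter
#'
#' Symmetric even-order FIR (designed with \code{signal::fir1}) applied by
#' FFT convolution with reflective padding and exact integer group-delay
#' compensation, so the filter is zero-phase. The outermost half-filter
#' length at each epoch edge relies on reflected samples and should not be
#' interpreted.
#'
#' @param epochs a [TrialEpochs-class].
#' @param bandHz pass-band edges in Hz.
#' @param order FIR order (even; default scales with the epoch length).
#' @return the band-limited [TrialEpochs-class].
#' @export
bandFilterEpochs <- function(epochs, bandHz = c(1, 33), order = NULL) {
  epochs@data <- .bandFilter(epochs@data, epochs@sampleRate, bandHz, order)
  epochs
}

#' Per-timepoint cross-validated category decoding
#'
#' Band-limits the epochs (zero-phase FIR, default 1-33 Hz), then for every
#' decoded time point trains an L2-regularized logistic regression on the
#' training folds of a stratified fourfold split and scores the held-out
#' fold, Z-normalizing with training-fold statistics only. AUC per time point
#' is computed from the decision values of all held-out trials pooled across
#' folds ("face" is the positive class); weights are averaged across folds.
#' The fold split is drawn once and reused at every time point so the
#' time-resolved AUC curve is comparable across time.
#'
#' @param epochs a [TrialEpochs-class] with both labels present.
#' @param nFolds number of cross-validation folds (default 4).
#' @param bandHz band-pass edges in Hz (default c(1, 33)).
#' @param seed seed for the fold assignment.
#' @param decim decode every \code{decim}-th sample (default 1 = all).
#' @param lambda total L2 penalty strength (default 1; passed to glmnet as
#'   \code{lambda/nTrain}, not tuned per fold, keeping the result
#'   deterministic).
#' @param filterOrder FIR order; default scales with the epoch length.
#' @param aucMode \code{"pooled"} (default) or \code{"perfold"} (mean of
#'   per-fold AUCs).
#' @param prefiltered set TRUE if \code{epochs} have already been through
#'   [bandFilterEpochs()] (skips the internal filter).
#' @return a [DecodingResult-class] (patterns left zero until
#'   [haufePatterns()] fills them).
#' @export
temporalDecode <- function(epochs, nFolds = 4L, bandHz = c(1, 33), seed = 1L,
                           decim = 1L, lambda = 1, filterOrder = NULL,
                           aucMode = c("pooled", "perfold"),
                           prefiltered = FALSE) {
  aucMode <- match.arg(aucMode)
  labels <- epochs@labels
  if (length(unique(labels)) < 2L)
    stop("both report categories must be present")
  d <- dim(epochs@data)
  fold <- .stratifiedFolds(labels, nFolds, seed)
  for (f in seq_len(nFolds))
    if (length(unique(labels[fold != f])) < 2L)
      stop("a training fold is missing a class")
  filt <- if (prefiltered) epochs@data else
    .bandFilter(epochs@data, epochs@sampleRate, bandHz, filterOrder)
  tIdx <- seq(1L, d[3L], by = as.integer(decim))
  pos <- labels == "face"
  y <- factor(labels, levels = c("vase", "face"))
  auc <- numeric(length(tIdx))
  W <- matrix(0, length(tIdx), d[2L])
  for (ti in seq_along(tIdx)) {
    X <- filt[, , tIdx[ti]]
    dv <- numeric(d[1L])
    wAcc <- numeric(d[2L])
    aucFold <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      te <- fold == f
      z <- zscoreFeatures(X[!te, , drop = FALSE], X[te, , drop = FALSE])
      fit <- glmnet::glmnet(z$train, y[!te], family = "binomial", alpha = 0,
                            lambda = lambda / sum(!te), standardize = FALSE)
      beta <- as.numeric(fit$beta)
      dv[te] <- drop(z$test %*% beta) + fit$a0
      wAcc <- wAcc + beta / z$scale   # weights on the original channel scale
      if (aucMode == "perfold") aucFold[f] <- .auc(dv[te], pos[te])
    }
    auc[ti] <- if (aucMode == "pooled") .auc(dv, pos) else mean(aucFold)
    W[ti, ] <- wAcc / nFolds
  }
  new("DecodingResult", times = epochs@time[tIdx], auc = auc, weights = W,
      patterns = matrix(0, length(tIdx), d[2L]),
      foldAssignment = fold, channelNames = epochs@channelNames)
}

#' Activation-pattern (forward-model) transformation of classifier weights
#'
#' Backward-model weights are not interpretable as activity sources; the
#' forward-model transformation multiplies them by the data covariance,
#' \eqn{A = C w}, recovering the pattern of a latent source even when the
#' weight vector itself is dominated by noise-cancellation structure.
#' Covariance is estimated at each decoded time point over all trials of the
#' subject, ridge-stabilized, and each pattern is unit-normalized (arbitrary
#' units) and oriented so its inner product with the weight vector is
#' nonnegative.
#'
#' @param result a [DecodingResult-class] from [temporalDecode()].
#' @param epochs the epochs the result was computed from.
#' @param bandHz band used for decoding (covariance is computed on the same
#'   band-limited data).
#' @param ridge relative ridge added to the covariance diagonal.
#' @param prefiltered set TRUE if \code{epochs} are already band-limited.
#' @param dataCov optional known channel covariance (one matrix, or a list
#'   with one matrix per decoded time point) used instead of the empirical
#'   per-timepoint covariance.
#' @return the [DecodingResult-class] with \code{patterns} filled.
#' @export
haufePatterns <- function(result, epochs = NULL, bandHz = c(1, 33),
                          ridge = 1e-6, prefiltered = FALSE, dataCov = NULL) {
  if (is.null(dataCov) && is.null(epochs))
    stop("either epochs or dataCov must be supplied")
  filt <- if (is.null(dataCov)) {
    if (prefiltered) epochs@data else
      .bandFilter(epochs@data, epochs@sampleRate, bandHz)
  }
  tAll <- if (is.null(dataCov)) epochs@time
  A <- matrix(0, length(result@times), ncol(result@weights))
  for (ti in seq_along(result@times)) {
    C <- if (is.null(dataCov)) {
      X <- filt[, , which.min(abs(tAll - result@times[ti]))]
      stats::cov(X)
    } else if (is.list(dataCov)) dataCov[[ti]] else dataCov
    if (!all(is.finite(C))) stop("non-finite covariance")
    C <- C + diag(ncol(C)) * ridge * mean(diag(C))
    a <- drop(C %*% result@weights[ti, ])
    nrm <- sqrt(sum(a^2))
    if (nrm > 0) a <- a / nrm
    if (sum(a * result@weights[ti, ]) < 0) a <- -a
    A[ti, ] <- a
  }
  result@patterns <- A
  result
}

#' Project activation patterns through a spatial filter into source space
#'
#' On synthetic cohorts the spatial filter is the pseudo-inverse of the known
#' mixing matrix -- the package's declared stand-in for the anatomical
#' source reconstruction used on real recordings. Map magnitudes are in
#' arbitrary units.
#'
#' @param patterns numeric matrix \code{[times, channels]} (or a
#'   [DecodingResult-class], whose patterns are used).
#' @param spatialFilter numeric matrix \code{[grid points, channels]}.
#' @param gridIds optional grid-point identifiers.
#' @param times time axis (taken from the DecodingResult when given one).
#' @return a [SourceMap-class].
#' @export
projectToSource <- function(patterns, spatialFilter, gridIds = NULL,
                            times = NULL) {
  if (is(patterns, "DecodingResult")) {
    times <- patterns@times
    patterns <- patterns@patterns
  }
  if (ncol(spatialFilter) != ncol(patterns))
    stop(sprintf("spatial filter has %d columns but patterns have %d channels",
                 ncol(spatialFilter), ncol(patterns)))
  vals <- spatialFilter %*% t(patterns)   # grid x times
  if (is.null(gridIds)) gridIds <- sprintf("g%03d", seq_len(nrow(vals)))
  if (is.null(times)) times <- seq_len(ncol(vals)) - 1
  new("SourceMap", values = unname(vals), gridIds = gridIds, times = times)
}

#' Moore-Penrose pseudo-inverse
#'
#' @param M numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudo-inverse of \code{M}.
#' @export
pseudoInverse <- function(M, tol = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Extract an ROI by fractional-maximum thresholding
#'
#' Absolute map values are averaged over the requested time window; grid
#' points at or above \code{frac} times the maximum of the averaged map are
#' returned. Ties at the threshold are kept, so a uniform map returns every
#' grid point.
#'
#' @param map a [SourceMap-class].
#' @param frac threshold fraction in [0, 1) (default 0.95).
#' @param window c(start, end) seconds to average over (default: all times).
#' @return integer indices of the grid points in the ROI.
#' @export
extractROI <- function(map, frac = 0.95, window = NULL) {
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)")
  if (nrow(map@values) == 0L) stop("empty source map")
  cols <- if (is.null(window)) seq_along(map@times) else
    which(map@times >= window[1] - 1e-9 & map@times <= window[2] + 1e-9)
  if (!length(cols)) stop("no map time points inside the window")
  avg <- rowMeans(abs(map@values[, cols, drop = FALSE]))
  which(avg >= frac * max(avg))
}
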