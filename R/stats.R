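#' @include AllClasses.R
NULL

# connected components of supra-threshold cells.
# 1-D: neighboring bins; 2-D: 4-connectivity (no diagonals).
.clusterCells <- function(supra, gridDim = NULL) {
  if (is.null(gridDim)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(function(s, e) s:e, starts[r$values], ends[r$values])
  } else {
    nr <- gridDim[1L]; nc <- gridDim[2L]
    lab <- integer(length(supra))
    out <- list()
    for (start in which(supra)) {
      if (lab[start]) next
      comp <- integer(0)
      stack <- start
      lab[start] <- 1L
      while (length(stack)) {
        cell <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, cell)
        r <- (cell - 1L) %% nr + 1L
        cc <- (cell - 1L) %/% nr + 1L
        nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
                if (cc > 1L) cell - nr, if (cc < nc) cell + nr)
        nb <- nb[supra[nb] & lab[nb] == 0L]
        lab[nb] <- 1L
        stack <- c(stack, nb)
      }
      out[[length(out) + 1L]] <- sort(comp)
    }
    out
  }
}

# largest cluster mass (by |sum of t|) given a t map and threshold
.maxClusterMass <- function(tvec, thr, tail, gridDim) {
  mx <- 0
  if (tail != "less") {
    for (cl in .clusterCells(tvec > thr, gridDim))
      mx <- max(mx, sum(tvec[cl]))
  }
  if (tail != "greater") {
    for (cl in .clusterCells(tvec < -thr, gridDim))
      mx <- max(mx, -sum(tvec[cl]))
  }
  mx
}

#' Cluster-based permutation test for paired condition contrasts
#'
#' Cell-wise paired t statistics over a 1-D (frequency) or 2-D
#' (frequency x time) grid are thresholded at the t quantile implied by
#' \code{clusterAlpha} and the declared tail; connected supra-threshold cells
#' (neighboring bins in 1-D, 4-connectivity in 2-D) are summed into cluster
#' masses, and each observed cluster is compared against the Monte-Carlo
#' distribution of the maximum cluster mass under random within-subject
#' condition swaps (sign flips of the paired differences). The p-value is
#' \code{(exceedances + 1) / (nPerm + 1)}, so the smallest attainable p is
#' \code{1/(nPerm + 1)}.
#'
#' @param condA,condB numeric matrices \code{[subjects, cells]}; for a 2-D
#'   grid pass \code{gridDim = c(nFreq, nTime)} with cells in column-major
#'   order (frequency varying fastest).
#' @param paired must be TRUE (the within-subject design implemented here).
#' @param tail \code{"two"}, \code{"greater"} (A > B) or \code{"less"}.
#' @param clusterAlpha cell-wise cluster-forming alpha (default 0.05).
#' @param nPerm number of permutations (>= 100 enforced).
#' @param seed RNG seed for the permutation draws.
#' @param gridDim optional c(rows, cols) marking the grid as 2-D.
#' @return a [ClusterTestResult-class].
#' @export
clusterPermutationTest <- function(condA, condB, paired = TRUE,
                                   tail = c("two", "greater", "less"),
                                   clusterAlpha = 0.05, nPerm = 1000L,
                                   seed = 1L, gridDim = NULL) {
  tail <- match.arg(tail)
  if (!paired) stop("only the paired (within-subject) design is implemented")
  condA <- as.matrix(condA); condB <- as.matrix(condB)
  if (!all(dim(condA) == dim(condB)))
    stop("condition matrices must have identical dimensions")
  n <- nrow(condA)
  if (n < 6L) stop("at least 6 subjects required")
  if (nPerm < 100L) stop("fewer than 100 permutations is refused")
  D <- condA - condB
  m <- ncol(D)
  if (!is.null(gridDim) && prod(gridDim) != m)
    stop("gridDim does not match the number of cells")
  sdD <- apply(D, 2L, stats::sd)
  if (any(sdD == 0))
    stop("degenerate contrast: zero-variance difference in at least one cell")
  tObs <- colMeans(D) / (sdD / sqrt(n))
  thr <- if (tail == "two") stats::qt(1 - clusterAlpha / 2, n - 1L)
         else stats::qt(1 - clusterAlpha, n - 1L)
  obs <- list()
  if (tail != "less")
    for (cl in .clusterCells(tObs > thr, gridDim))
      obs[[length(obs) + 1L]] <- list(cells = cl, mass = sum(tObs[cl]))
  if (tail != "greater")
    for (cl in .clusterCells(tObs < -thr, gridDim))
      obs[[length(obs) + 1L]] <- list(cells = cl, mass = sum(tObs[cl]))
  ssq <- colSums(D^2)
  nullMax <- .withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    mu <- (signs %*% D) / n
    vp <- sweep(-n * mu^2, 2L, ssq, `+`) / (n - 1L)
    tp <- mu / sqrt(vp / n)
    vapply(seq_len(nPerm),
           function(i) .maxClusterMass(tp[i, ], thr, tail, gridDim),
           numeric(1))
  })
  pv <- vapply(obs, function(cl)
    (sum(nullMax >= abs(cl$mass)) + 1) / (nPerm + 1), numeric(1))
  ord <- order(pv)
  obs <- obs[ord]; pv <- pv[ord]
  for (i in seq_along(obs)) obs[[i]]$p <- pv[i]
  statMap <- tObs
  if (!is.null(gridDim)) dim(statMap) <- gridDim
  new("ClusterTestResult", statMap = as.array(statMap), clusters = obs,
      pCluster = pv, nPermutations = as.integer(nPerm), tail = tail,
      clusterAlpha = clusterAlpha, threshold = thr)
}

#' Within-subject (Cousineau-Morey) standard errors
#'
#' Subject means are removed and the grand mean restored before computing
#' the per-condition SEM, which is then multiplied by the Morey bias
#' correction \eqn{\sqrt{C/(C-1)}} for C conditions. Constant between-subject
#' offsets therefore do not inflate the error bars of a within-subject
#' contrast.
#'
#' @param values numeric matrix \code{[subjects, conditions]}, >= 2 of each.
#' @return numeric vector: corrected SEM per condition.
#' @export
withinSubjectSEM <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); C <- ncol(values)
  if (n < 2L) stop("at least 2 subjects required")
  if (C < 2L) stop("the correction is undefined for a single condition")
  centered <- values - rowMeans(values) + mean(values)
  apply(centered, 2L, stats::sd) / sqrt(n) * sqrt(C / (C - 1))
}

#' Run-length binomial analysis of report sequences
#'
#' For each subject, consecutive identical reports are collapsed into runs;
#' a run of length L counts as L - 1 repetitions, capped at 10, giving 11
#' bins (0-10 repetitions). Bin counts are averaged across subjects and fit
#' by least squares to a binomial law \code{s * dbinom(k, 10, p)} with the
#' success probability p and the scale s free. A high R-squared indicates
#' stochastic trial-by-trial reporting (an i.i.d. Bernoulli reporter gives a
#' geometric run-length law that the binomial family tracks closely over
#' these bins); a perseverative reporter piles mass into the top bin and is
#' flagged as non-stochastic.
#'
#' @param sequences list of character vectors of \code{"face"}/\code{"vase"}
#'   labels, one per subject.
#' @return a [SequenceFit-class].
#' @export
runsBinomialFit <- function(sequences) {
  if (!length(sequences) || any(!lengths(sequences)))
    stop("empty report sequences")
  counts <- vapply(sequences, function(s) {
    reps <- pmin(rle(s)$lengths - 1L, 10L)
    tabulate(reps + 1L, nbins = 11L)
  }, numeric(11L))
  binCounts <- rowMeans(counts)
  k <- 0:10
  sse <- function(p) {
    d <- stats::dbinom(k, 10L, p)
    s <- sum(binCounts * d) / sum(d^2)
    sum((binCounts - s * d)^2)
  }
  opt <- stats::optimize(sse, interval = c(1e-6, 1 - 1e-6))
  pHat <- opt$minimum
  d <- stats::dbinom(k, 10L, pHat)
  s <- sum(binCounts * d) / sum(d^2)
  fitted <- s * d
  ssTot <- sum((binCounts - mean(binCounts))^2)
  r2 <- if (ssTot > 0) 1 - opt$objective / ssTot else NA_real_
  new("SequenceFit", binCounts = binCounts, fitted = fitted,
      rSquared = r2, pHat = pHat,
      stochastic = which.max(binCounts) != 11L)
}

#' Pearson correlation with p-value and Fisher-z confidence interval
#'
#' @param x,y per-subject scalar vectors, length >= 3, finite, non-constant.
#' @return list with \code{r}, \code{p} (two-sided, t transform) and
#'   \code{ci} (95\% Fisher-z interval; NA at n = 3 where it is undefined).
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in at least one input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  n <- length(x)
  ci <- if (n > 3L) tanh(atanh(r) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
        else c(NA_real_, NA_real_)
  list(r = r, p = ct$p.value, ci = ci)
}

#' Maximum of a curve or map within a declared search range
#'
#' The per-subject summary statistics feeding the cross-subject correlations
#' (max AUC over the tested time window, max gamma-band contrast, max
#' feedback Granger over the statistical band) are all maxima over declared
#' ranges; this helper makes the range restriction explicit and refuses
#' silent NA propagation.
#'
#' @param values numeric vector.
#' @param axis numeric axis of the same length (time in s or frequency in Hz).
#' @param range optional c(lo, hi) restriction of the axis; default all.
#' @return the maximum of \code{values} inside the range.
#' @export
maxInRange <- function(values, axis, range = NULL) {
  if (length(values) != length(axis)) stop("values/axis length mismatch")
  if (anyNA(values)) stop("missing values in input")
  sel <- if (is.null(range)) seq_along(axis)
         else which(axis >= range[1] - 1e-9 & axis <= range[2] + 1e-9)
  if (!length(sel)) stop("search range contains no samples")
  max(values[sel])
}
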