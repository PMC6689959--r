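test_that("varGenerate rejects unstable or invalid inputs and names the radius", {
  unstable <- list(diag(c(1.05, 0.5)))
  expect_error(varGenerate(unstable, diag(2), 100, seed = 1), "spectral radius")
  expect_error(varGenerate(list(diag(c(0.5, 0.5))), matrix(c(1, 2, 2, 1), 2),
                           100, seed = 1), "positive definite")
  expect_error(
    simulationConfig(varCoeffsBase =
                       prepercept:::.defaultVarCoeffs(250, poleRadius = 1.01)),
    "unstable")
  expect_error(simulationConfig(pFace = 1.2), "pFace")
  expect_error(simulationConfig(epochWindow = c(0.1, 0.5)), "epochWindow")
  expect_error(simulationConfig(sensorNoiseSd = NaN), "non-finite")
})

test_that("zero-coefficient VAR is white noise (vanishing lag-1 autocorrelation)", {
  zero <- list(matrix(0, 2, 2))
  dat <- varGenerate(zero, diag(2), 5000, seed = 3, nTrials = 20)
  ac <- vapply(1:20, function(tr) {
    x <- dat[tr, 1, ]
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(abs(mean(ac)), 0.05)
  expect_lt(abs(stats::cor(dat[1, 1, ], dat[1, 2, ])), 0.05)
})

test_that("AR(2) oscillator spectrum peaks at the closed-form resonance", {
  fs <- 250
  A <- prepercept:::.defaultVarCoeffs(fs, resFreq = 10, poleRadius = 0.9)
  ep <- varEpochs(A, nTrials = 200, nSamples = 250, seed = 5)
  csd <- multitaperCSD(ep, c(-1, 0), timeBandwidth = 1.5, nTapers = 2)
  # closed-form AR transfer-function spectrum on the same grid
  o <- parametricGrangerVAR(A, diag(2), csd@freqs, fs)
  fTheory <- csd@freqs[which.max(Re(o$S[1, 1, ]))]
  fEmp <- csd@freqs[which.max(csdPower(csd)[1, ])]
  expect_lte(abs(fEmp - fTheory), 1)
})

test_that("no cross-coupling means exactly zero parametric Granger", {
  A <- prepercept:::.defaultVarCoeffs(250)
  o <- parametricGrangerVAR(A, diag(2), seq(0, 125, 1), 250)
  expect_equal(max(o$fb), 0)
  expect_equal(max(o$ff), 0)
})

test_that("simulateSubject returns the designed trial count and labels", {
  cfg <- simulationConfig(nTrials = 400L)
  sim <- simulateSubject(cfg, subjectSeed = 7L)
  expect_equal(nTrials(sim$epochs), 400L)
  expect_length(trialLabels(sim$epochs), 400L)
  expect_true(all(trialLabels(sim$epochs) %in% c("face", "vase")))
  expect_true(validObject(sim$epochs))
})

test_that("equal couplings and silent bursts make conditions exchangeable", {
  cfg <- simulationConfig(
    nTrials = 10000L, couplingFace = 0.03, couplingVase = 0.03,
    gammaBurst = list(freq = 60, onset = 0, offset = 0.35, amplitude = 0),
    evoked = list(onset = 0.05, offset = 0.3, amplitude = 0),
    betweenSubjectSd = 0)
  sim <- simulateSubject(cfg, subjectSeed = 11L)
  pre <- epochTimes(sim$epochs) < 0
  v <- apply(epochsData(sim$epochs)[, 1, pre], 1, stats::var)
  ks <- stats::ks.test(v[trialLabels(sim$epochs) == "face"],
                       v[trialLabels(sim$epochs) == "vase"])
  expect_gt(ks$p.value, 0.01)
})

test_that("the gamma burst raises face-minus-vase power only after onset", {
  cfg <- simulationConfig(nTrials = 300L, couplingFace = 0.02,
                          couplingVase = 0.02, betweenSubjectSd = 0,
                          evoked = list(onset = 0, offset = 0, amplitude = 0))
  sim <- simulateSubject(cfg, subjectSeed = 13L)
  ep <- sim$epochs
  bandPower <- function(window) {
    csd <- lapply(c("face", "vase"), function(cond) {
      sel <- trialLabels(ep) == cond
      sub <- makeEpochs(epochsData(ep)[sel, , , drop = FALSE],
                        labels = trialLabels(ep)[sel])
      pw <- csdPower(multitaperCSD(sub, window, timeBandwidth = 3))
      f <- multitaperCSD(sub, window, timeBandwidth = 3)@freqs
      mean(pw[2, f >= 50 & f <= 70])
    })
    csd[[1]] - csd[[2]]
  }
  post <- bandPower(c(0, 0.35))
  pre <- bandPower(c(-1, -0.2))
  expect_gt(post, 5 * abs(pre))
  expect_lt(abs(pre) / post, 0.2)
})

test_that("prestimulus variance is stationary across trial thirds", {
  cfg <- simulationConfig(
    nTrials = 900L, gammaBurst = list(freq = 60, onset = 0, offset = 0.35,
                                      amplitude = 0),
    betweenSubjectSd = 0)
  sim <- simulateSubject(cfg, subjectSeed = 17L)
  pre <- epochTimes(sim$epochs) < 0
  n3 <- sum(pre) %/% 3
  v <- vapply(0:2, function(k)
    stats::var(as.vector(epochsData(sim$epochs)[, 1, which(pre)[k * n3 + 1:n3]])),
    numeric(1))
  expect_lt(diff(range(v)) / mean(v), 0.1)
})

test_that("sensor projection is the exact linear image of the sources", {
  cfg <- smallConfig()
  sim <- simulateSubject(cfg, subjectSeed = 19L)
  # identity mixing, no noise: bit-identical
  ident <- projectToSensors(sim$epochs, diag(2), noiseSd = 0, seed = 1)
  expect_identical(epochsData(ident), epochsData(sim$epochs))
  # rank-2 image into 30 sensors
  set.seed(21); M <- matrix(rnorm(60), 30, 2)
  sens <- projectToSensors(sim$epochs, M, noiseSd = 0, seed = 1)
  X <- matrix(aperm(epochsData(sens), c(2, 1, 3)), 30)
  ev <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)$values
  expect_lt(ev[3] / ev[1], 1e-8)
  # pseudo-inverse reconstruction
  rec <- prepercept:::.toSourceEpochs(sens, pseudoInverse(M))
  expect_lt(max(abs(epochsData(rec) - epochsData(sim$epochs))), 1e-8)
  expect_error(projectToSensors(sim$epochs, matrix(1, 4, 3), 0, 1),
               "columns")
})

test_that("report generation is Bernoulli with the requested rate", {
  expect_true(all(generateReports(50, 1, seed = 1) == "face"))
  props <- vapply(1:1000, function(s)
    mean(generateReports(400, 0.5, seed = s) == "face"), numeric(1))
  expect_lt(abs(mean(props) - 0.5), 0.01)
  # run-length law: repetitions of an i.i.d. Bernoulli(1/2) reporter are
  # geometric(1/2); chi-square GOF on 1e5 trials
  labs <- generateReports(1e5, 0.5, seed = 42)
  reps <- pmin(rle(labs)$lengths - 1L, 10L)
  obs <- tabulate(reps + 1L, 11L)
  p <- c(0.5^(1:10), 0.5^10)  # P(rep = k), top bin pooled
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- simulateCohort(smallConfig(seed = 5L))
  b <- simulateCohort(smallConfig(seed = 5L))
  expect_identical(epochsData(subjects(a)[[1]]), epochsData(subjects(b)[[1]]))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- simulateCohort(smallConfig(seed = 6L))
  expect_false(identical(epochsData(subjects(a)[[1]]),
                         epochsData(subjects(c)[[1]])))
})

test_that("time reversal flips samples and preserves metadata", {
  ep <- varEpochs(canonicalTestVAR(), nTrials = 3, seed = 2)
  rev <- reverseTime(ep)
  expect_identical(epochsData(rev)[, , 1], epochsData(ep)[, , 250])
  expect_identical(epochTimes(rev), epochTimes(ep))
})
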