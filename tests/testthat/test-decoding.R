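test_that("z-normalization uses training statistics only", {
  set.seed(1)
  tr <- matrix(rnorm(100, mean = 5, sd = 2), 20, 5)
  te <- matrix(rnorm(25, mean = 5, sd = 2), 5, 5)
  z <- zscoreFeatures(tr, te)
  expect_lt(max(abs(colMeans(z$train))), 1e-10)
  expect_lt(max(abs(apply(z$train, 2, sd) - 1)), 1e-10)
  # test partition is transformed with the same constants, not its own
  expect_equal(z$test, sweep(sweep(te, 2, z$center), 2, z$scale, `/`))
  expect_error(zscoreFeatures(tr[1, , drop = FALSE], te), "2 training")
  # constant channel takes the floored-SD path without non-finite output
  tr[, 3] <- 7
  expect_warning(z2 <- zscoreFeatures(tr, te), "floored")
  expect_true(all(is.finite(z2$train)))
})

test_that("decoding finds the injected class difference and stays at chance before it", {
  # prefiltered: the injected difference is a DC shift, which the band-pass
  # would (correctly) attenuate; the test isolates the classifier path
  ep <- separableEpochs()
  dec <- temporalDecode(ep, seed = 3, decim = 5L, prefiltered = TRUE)
  expect_true(all(aucScores(dec) >= 0 & aucScores(dec) <= 1))
  post <- decodingTimes(dec) > 0.2 & decodingTimes(dec) < 0.45
  pre <- decodingTimes(dec) < -0.1
  expect_gt(mean(aucScores(dec)[post]), 0.9)
  expect_lt(abs(mean(aucScores(dec)[pre]) - 0.5), 0.1)
})

test_that("permuted labels decode at chance and folds are stratified", {
  set.seed(5)
  fs <- 100
  dat <- array(rnorm(400 * 6 * 30), dim = c(400, 6, 30))
  labels <- sample(rep(c("face", "vase"), 200))
  ep <- makeEpochs(dat, fs = fs, t0 = 0, labels = labels)
  dec <- temporalDecode(ep, bandHz = c(1, 40), seed = 7, decim = 3L)
  expect_gt(mean(aucScores(dec)), 0.45)
  expect_lt(mean(aucScores(dec)), 0.55)
  # 400 trials, 4 folds: sizes exactly 100, label ratio preserved within 1
  f <- dec@foldAssignment
  expect_equal(unname(table(f)), rep(100L, 4), ignore_attr = TRUE)
  for (k in 1:4)
    expect_lte(abs(sum(labels[f == k] == "face") - 50), 1)
})

test_that("affine transforms of the input leave the AUC unchanged", {
  ep <- separableEpochs(nTrials = 40, seed = 11)
  dec1 <- temporalDecode(ep, bandHz = c(1, 40), seed = 1, decim = 10L)
  ep2 <- ep
  ep2@data <- ep2@data * 3.7 + 11
  dec2 <- temporalDecode(ep2, bandHz = c(1, 40), seed = 1, decim = 10L)
  expect_equal(aucScores(dec1), aucScores(dec2), tolerance = 1e-8)
})

test_that("pooled AUC matches the closed-form Mann-Whitney null", {
  # permutation distribution of the rank AUC under label exchange
  set.seed(13)
  dv <- rnorm(400)
  auc <- vapply(1:2000, function(i)
    prepercept:::.auc(dv, sample(rep(c(TRUE, FALSE), 200))), numeric(1))
  expect_lt(abs(mean(auc) - 0.5), 0.005)
  nullSd <- sqrt((400 + 1) / (12 * 200 * 200))
  expect_lt(abs(sd(auc) - nullSd) / nullSd, 0.1)
  # cross-check the rank formula against an independent implementation
  pos <- rep(c(TRUE, FALSE), 200)
  expect_equal(prepercept:::.auc(dv, pos),
               as.numeric(pROC::auc(pROC::roc(pos, dv, quiet = TRUE,
                                              direction = "<"))))
})

test_that("no information leaks from held-out trials (canary artifact)", {
  set.seed(15)
  dat <- array(rnorm(80 * 6 * 20), dim = c(80, 6, 20))
  labels <- rep(c("face", "vase"), 40)
  ep <- makeEpochs(dat, fs = 100, t0 = -0.1, labels = labels)
  dec0 <- temporalDecode(ep, bandHz = c(1, 40), seed = 9, decim = 2L)
  # inject a label-correlated artifact into the trials of fold 1 only;
  # a leak-free pipeline never trains on it, so AUC stays near chance
  f <- dec0@foldAssignment
  ep@data[f == 1 & labels == "face", , ] <-
    ep@data[f == 1 & labels == "face", , ] + 5
  dec <- temporalDecode(ep, bandHz = c(1, 40), seed = 9, decim = 2L)
  expect_lt(abs(mean(aucScores(dec)) - 0.5), 0.12)
})

test_that("the activation-pattern transform recovers the generative mixing", {
  # single latent source mixed into 10 channels plus spatially correlated
  # noise: the classifier weight need not resemble the mixing column, but
  # the pattern A = C w must
  set.seed(17)
  nTr <- 600; nCh <- 10; n <- 12
  a <- rnorm(nCh); a <- a / sqrt(sum(a^2))
  B <- matrix(rnorm(nCh * nCh), nCh) * 0.3
  s <- rep(c(1, -1), nTr / 2)
  dat <- array(0, dim = c(nTr, nCh, n))
  for (t in seq_len(n))
    dat[, , t] <- outer(s, a) + matrix(rnorm(nTr * nCh), nTr) %*% B
  labels <- ifelse(s > 0, "face", "vase")
  ep <- makeEpochs(dat, fs = 100, t0 = 0, labels = labels)
  dec <- temporalDecode(ep, bandHz = c(1, 40), seed = 1, decim = 4L,
                        prefiltered = TRUE)
  # defining recovery property with the constructed (population) covariance:
  # the weight vector is noise-distorted, the pattern is not
  Ctrue <- outer(a, a) + crossprod(B)
  decC <- haufePatterns(dec, dataCov = Ctrue)
  A <- activationPatterns(decC)
  expect_gt(abs(stats::cor(A[2, ], a)), 0.99)
  expect_lt(abs(stats::cor(classifierWeights(dec)[2, ], a)), 0.9)
  # empirical-covariance route recovers it nearly as well
  decE <- haufePatterns(dec, ep, prefiltered = TRUE)
  expect_gt(abs(stats::cor(activationPatterns(decE)[2, ], a)), 0.95)
  # sign convention: pattern not anti-aligned with the weight
  expect_gte(sum(A[2, ] * classifierWeights(decC)[2, ]), 0)
  # identity covariance gives patterns proportional to weights
  W <- matrix(rnorm(6), 2, 3)
  epI <- makeEpochs(array(rnorm(500 * 3 * 2), dim = c(500, 3, 2)), fs = 100,
                    t0 = 0, labels = rep(c("face", "vase"), 250))
  decI <- temporalDecode(epI, bandHz = c(1, 40), seed = 2,
                         prefiltered = TRUE)
  decI <- haufePatterns(decI, epI, prefiltered = TRUE)
  w1 <- classifierWeights(decI)[1, ]
  a1 <- activationPatterns(decI)[1, ]
  expect_gt(abs(stats::cor(w1, a1)), 0.9)
})

test_that("source projection and ROI extraction behave as linear-algebra says", {
  set.seed(19)
  M <- matrix(rnorm(30 * 2), 30, 2)      # mixing: 2 grid points, 30 channels
  pinv <- pseudoInverse(M)
  # pattern equal to a mixing column maps to the indicator of that point
  pat <- t(M[, 2, drop = FALSE])
  map <- projectToSource(pat, pinv, gridIds = c("V1", "FFA"), times = 0)
  expect_lt(abs(map@values[1, 1]), 1e-8)
  expect_equal(map@values[2, 1], 1, tolerance = 1e-8)
  # zero pattern gives a zero map
  map0 <- projectToSource(matrix(0, 1, 30), pinv, times = 0)
  expect_true(all(map0@values == 0))
  expect_error(projectToSource(matrix(0, 1, 4), pinv), "channels")
  # ROI thresholding: dominant point, frac = 0 and tie policies
  vals <- matrix(c(1, 0.8, 0.3, 0.2), 4, 1)
  m <- new("SourceMap", values = vals, gridIds = sprintf("g%d", 1:4),
           times = 0)
  expect_equal(extractROI(m, frac = 0.95), 1L)
  expect_equal(extractROI(m, frac = 0), 1:4)
  uni <- new("SourceMap", values = matrix(1, 5, 1),
             gridIds = sprintf("g%d", 1:5), times = 0)
  expect_equal(extractROI(uni, frac = 0.95), 1:5)
  expect_error(extractROI(m, frac = 1), "frac")
})
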