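# Single-neuron AUC selectivity, shuffle-null calibration, population
# fraction tests, psychometric fitting, optogenetic impairment.

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    contra <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
    if (all(contra) || !any(contra)) next
    vals <- sample(round(rnorm(n), 1))    # ties included
    auc <- neuronAUC(cbind(vals), ifelse(contra, "right", "left"),
                     zscore = FALSE)
    # exhaustive pair counting oracle
    pairs <- expand.grid(i = which(contra), j = which(!contra))
    wins <- sum(vals[pairs$i] > vals[pairs$j]) +
      0.5 * sum(vals[pairs$i] == vals[pairs$j])
    expect_equal(as.numeric(auc), wins / nrow(pairs), tolerance = 1e-12)
  }
})

test_that("AUC hits its trivial anchors and is anti-symmetric", {
  ch <- rep(c("left", "right"), each = 10)
  identicalAct <- cbind(rep(1:10, 2))
  expect_equal(as.numeric(neuronAUC(identicalAct, ch, zscore = FALSE)), 0.5)
  separated <- cbind(c(1:10, 101:110))
  expect_equal(as.numeric(neuronAUC(separated, ch, zscore = FALSE)), 1)
  swapped <- ifelse(ch == "right", "left", "right")
  set.seed(2)
  act <- cbind(rnorm(20))
  expect_equal(as.numeric(neuronAUC(act, ch, zscore = FALSE)),
               1 - as.numeric(neuronAUC(act, swapped, zscore = FALSE)))
  # zero-variance neuron: AUC 0.5 with flag
  flatAUC <- neuronAUC(cbind(rep(2, 20)), ch, zscore = FALSE)
  expect_equal(as.numeric(flatAUC), 0.5)
  expect_true(attr(flatAUC, "flat"))
  # agreement with an established ROC implementation on a random instance
  expect_equal(as.numeric(neuronAUC(act, ch, zscore = FALSE)),
               as.numeric(pROC::auc(pROC::roc(ch == "right", act[, 1],
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the shuffle test is calibrated on untuned populations", {
  tr <- generateTrials(taskConfig(nTrials = 100), seed = 6)
  pop <- generateNeuronPopulation(1000, 0, 0, 0, tr, seed = 3)
  res <- aucShuffleTest(pop$activity, tr$choice, pop$window,
                        nShuffle = 100, seed = 9)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(res$significant), 0.05 + 2 * se)
  expect_true(all(res$p >= 2 / 101))
  expect_error(aucShuffleTest(pop$activity[, , 1:5], tr$choice,
                              pop$window, nShuffle = 10), "at least 20")
})

test_that("type-I error stays at or below alpha across null distributions", {
  set.seed(17)
  n <- 60; nn <- 300
  ch <- rep(c("left", "right"), each = n / 2)
  makeRes <- function(M) mean(aucShuffleTest(M, ch, nShuffle = 60,
                                             seed = 5)$significant)
  gauss <- matrix(rnorm(n * nn), n, nn)
  lnorm <- matrix(rlnorm(n * nn), n, nn)
  zinfl <- matrix(rbinom(n * nn, 1, 0.3) * rexp(n * nn), n, nn)
  for (M in list(gauss, lnorm, zinfl)) {
    fp <- makeRes(M)
    expect_lte(fp, 0.05 + 2 * sqrt(0.05 * 0.95 / nn))
  }
})

test_that("strong tuning is detected at the resolution floor of the null", {
  tr <- generateTrials(taskConfig(nTrials = 120), seed = 2)
  pop <- generateNeuronPopulation(60, 0.5, 0.5, 3, tr, seed = 4)
  res <- aucShuffleTest(pop$activity, tr$choice, pop$window,
                        nShuffle = 100, seed = 1)
  tuned <- pop$label != "untuned"
  expect_gt(mean(res$significant[tuned]), 0.9)
  expect_true(any(res$p[tuned] == 2 / 101))
  # preferred side matches the generative label for significant neurons
  sig <- res$significant & tuned
  expect_true(all(res$preferred[sig] == pop$label[sig]))
})

test_that("detection power increases with effect size", {
  tr <- generateTrials(taskConfig(nTrials = 100), seed = 11)
  frac <- sapply(c(0, 1, 3), function(es) {
    pop <- generateNeuronPopulation(150, 0.3, 0.3, es, tr, seed = 7)
    res <- aucShuffleTest(pop$activity, tr$choice, pop$window,
                          nShuffle = 60, seed = 2)
    mean(res$significant)
  })
  expect_true(all(diff(frac) > 0))
})

test_that("population fraction test matches exact binomial enumeration", {
  eq <- selectiveFractionTest(10, 10, 100)
  expect_gt(eq$pValue, 0.99)
  res <- selectiveFractionTest(9, 3, 50, familySize = 4)
  # exact enumeration oracle for the two-sided binomial p at (9, 3)
  probs <- dbinom(0:12, 12, 0.5)
  pOracle <- sum(probs[probs <= dbinom(9, 12, 0.5) * (1 + 1e-7)])
  expect_equal(res$pValue, pOracle, tolerance = 1e-10)
  expect_equal(res$pBonferroni, min(1, pOracle * 4))
  expect_false(res$significant)          # 0.146 * 4 > 0.01
  expect_equal(res$fractionIpsi, 9 / 50)
  # Clopper-Pearson interval contains the point estimate
  expect_true(res$ciIpsi[1] <= 9 / 50 && 9 / 50 <= res$ciIpsi[2])
  expect_error(selectiveFractionTest(1, 1, 0), "positive")
})

test_that("psychometric parameters are recovered from simulated choices", {
  set.seed(12)
  n <- 5000
  x <- sample(-15:15, n, replace = TRUE)
  truth <- c(bias = 1, slope = 0.5, lapseLow = 0.05, lapseHigh = 0.05)
  pr <- psychometricCurve(x, truth["bias"], truth["slope"],
                          truth["lapseLow"], truth["lapseHigh"])
  fit <- fitPsychometric(x = x, chooseRight = runif(n) < pr)
  expect_lt(abs(fit$par["slope"] - truth["slope"]) / truth["slope"], 0.1)
  expect_lt(abs(fit$par["bias"] - truth["bias"]), 0.5)
  expect_lt(abs(fit$par["lapseLow"] - 0.05), 0.02)
  expect_lt(abs(fit$par["lapseHigh"] - 0.05), 0.02)
})

test_that("side-swapped symmetric choices fit with near-zero bias", {
  set.seed(14)
  x <- rep(c(-12, -6, -2, 2, 6, 12), each = 300)
  pr <- psychometricCurve(x, 0, 0.4, 0.03, 0.03)
  y <- runif(length(x)) < pr
  fit <- fitPsychometric(x = x, chooseRight = y)
  # mirror the stimulus and responses: bias flips sign
  fitM <- fitPsychometric(x = -x, chooseRight = !y)
  expect_lt(abs(fit$par["bias"]), 1)
  expect_equal(unname(fit$par["bias"]), -unname(fitM$par["bias"]),
               tolerance = 0.2)
  # trial-table interface and degenerate single-class responding
  tr <- generateTrials(taskConfig(nTrials = 400), seed = 3)
  ft <- fitPsychometric(tr)
  expect_false(ft$degenerate)
  expect_gt(ft$par["slope"], 0)
  expect_warning(
    bad <- fitPsychometric(x = c(-1, 0, 1, 2), chooseRight = rep(TRUE, 4)),
    "single-class")
  expect_true(bad$degenerate)
})

test_that("optogenetic impairment reproduces the exact binomial arithmetic", {
  ctrl <- data.frame(correct = rep(c(TRUE, FALSE), c(400, 100)))
  opto <- data.frame(correct = rep(c(TRUE, FALSE), c(60, 40)))
  res <- optoImpairment(ctrl, opto)
  expect_equal(res$impairment, 100 * (0.6 - 0.8) / 0.8)   # -25%
  # Clopper-Pearson bounds oracle by direct search over the binomial CDF
  loOracle <- uniroot(function(p) pbinom(60 - 1, 100, p) - 0.975,
                      c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  hiOracle <- uniroot(function(p) pbinom(60, 100, p) - 0.025,
                      c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(res$ciLow, 100 * (loOracle - 0.8) / 0.8, tolerance = 1e-6)
  expect_equal(res$ciHigh, 100 * (hiOracle - 0.8) / 0.8, tolerance = 1e-6)
  expect_lt(res$pBonferroni, 0.01)
  # equal performance: zero impairment
  same <- optoImpairment(ctrl, data.frame(correct = rep(c(TRUE, FALSE),
                                                        c(80, 20))))
  expect_equal(same$impairment, 0)
  # grouped by inhibition epoch with Bonferroni across cells
  opto$epoch <- rep(c("stimEarly", "stimLate", "delay", "response"), 25)
  byEpoch <- optoImpairment(ctrl, opto, by = "epoch")
  expect_equal(nrow(byEpoch), 4)
  expect_equal(byEpoch$pBonferroni, pmin(1, byEpoch$p * 4))
})
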