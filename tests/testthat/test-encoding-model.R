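# Design matrix construction, evidence-optimized ridge, cross-validated and
# unique explained variance, kernel reconstruction.

test_that("an event block is the expected shifted-diagonal pattern", {
  B <- eventDesignBlock(5, 0, 2, nFrames = 10)
  expect_equal(dim(B), c(10, 3))
  expect_equal(which(B[, 1] == 1), 5)
  expect_equal(which(B[, 2] == 1), 6)
  expect_equal(which(B[, 3] == 1), 7)
  expect_true(all(B %in% c(0, 1)))
})

test_that("event-block column sums match a brute-force construction", {
  set.seed(3)
  nFrames <- 120
  ev <- sort(sample(10:110, 8))
  bounds <- cbind(ev - 5, ev + 12)
  B <- eventDesignBlock(ev, 2, 9, nFrames, bounds)
  # naive loop oracle
  lags <- -2:9
  O <- matrix(0, nFrames, length(lags))
  for (e in seq_along(ev)) for (l in seq_along(lags)) {
    f <- ev[e] + lags[l]
    if (f >= 1 && f <= nFrames && f >= bounds[e, 1] && f <= bounds[e, 2])
      O[f, l] <- 1
  }
  expect_equal(unname(B), O, ignore_attr = TRUE)
  expect_equal(colSums(B), colSums(O))
})

test_that("the assembled design matrix has the documented structure", {
  out <- smallSession()
  ses <- out$session
  stk <- smallStack(filtered = TRUE)
  nF <- ncol(stk@Vt)
  X <- buildDesignMatrix(ses@trials, frameRate = 15, nFrames = nF,
                         movement = ses@movement, video = ses@video)
  expect_s4_class(X, "DesignMatrix")
  expect_true(validObject(X))
  # lick spans follow the -1 s / +2 s convention: 15 + 30 + 1 columns
  expect_equal(sum(X@groupIndex == "lickLeft"), 15 + 30 + 1)
  # analog traces enter as single columns
  expect_equal(sum(X@groupIndex == "piezo"), 1)
  expect_equal(sum(X@variableKind == "video-component"), 10)
  # every in-trial frame carries its trial id
  tr <- ses@trials
  f1 <- round(tr$stimOnset[3] * 15) + 1
  expect_equal(X@trialIndex[f1], 3)
})

test_that("evidence-optimized ridge recovers noiseless weights with vanishing penalty", {
  set.seed(4)
  X <- matrix(rnorm(400 * 15), 400, 15)
  beta <- rnorm(15)
  Y <- X %*% beta
  fit <- fitRidgeMLE(X, Y)
  expect_lt(fit@lambda[1], 1e-4)
  expect_lt(sqrt(sum((fit@weights[, 1] - beta)^2)) / sqrt(sum(beta^2)),
            1e-3)
})

test_that("evidence-selected penalties track the cross-validation optimum", {
  set.seed(9)
  n <- 240; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p, 0, 0.15)
  Y <- X %*% beta + rnorm(n, 0, 2)
  fit <- fitRidgeMLE(X, Y)
  # 10-fold CV oracle over a lambda grid
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  fold <- rep_len(1:10, n)
  grid <- 10^seq(-4, 5, by = 0.1)
  cvErr <- sapply(grid, function(l) {
    sum(sapply(1:10, function(f) {
      tr <- fold != f
      w <- solve(crossprod(Xc[tr, ]) + diag(l, p),
                 crossprod(Xc[tr, ], Yc[tr]))
      sum((Yc[!tr] - Xc[!tr, ] %*% w)^2)
    }))
  })
  lamCV <- grid[which.min(cvErr)]
  # agreement within 5% of the searched log-lambda range (12 decades)
  expect_lt(abs(log10(fit@lambda[1]) - log10(lamCV)), 0.6)
  # evidence curve is unimodal in log lambda on this instance
  sv <- svd(Xc)
  r2 <- as.numeric(crossprod(sv$u, Yc))^2
  resid0 <- max(sum(Yc^2) - sum(r2), 0)
  ev <- sapply(log(grid), function(ll)
    mesocortex:::.negLogEvidence(exp(ll), sv$d^2, r2, resid0, n))
  signChanges <- sum(abs(diff(sign(diff(ev)))) > 0)
  expect_lte(signChanges, 1)
})

test_that("penalties are selected per data column", {
  set.seed(6)
  X <- matrix(rnorm(300 * 10), 300, 10)
  beta <- rnorm(10)
  Y <- cbind(clean = X %*% beta + rnorm(300, 0, 0.01),
             noisy = X %*% (0.05 * beta) + rnorm(300, 0, 3))
  fit <- fitRidgeMLE(X, Y)
  expect_equal(length(fit@lambda), 2)
  expect_lt(fit@lambda[1] * 10, fit@lambda[2])
})

test_that("degenerate design columns are screened out with a report", {
  set.seed(2)
  X <- matrix(rnorm(100 * 5), 100, 5)
  X <- cbind(X, X[, 3])                # exact duplicate
  colnames(X) <- paste0("c", 1:6)
  expect_warning(fit <- fitRidgeMLE(X, rnorm(100)), "degenerate")
  expect_equal(nrow(fit@weights), 5)
  expect_length(fit@droppedColumns, 1)
})

test_that("cross-validated R2 is near 1 for noiseless data and <= 0 for noise", {
  set.seed(8)
  X <- matrix(rnorm(300 * 8), 300, 8)
  Y <- X %*% rnorm(8)
  cv <- crossValidatedR2(X, Y, lambda = 1e-8)
  expect_gt(cv$cvR2[1], 0.999)
  expect_equal(eval(formals(crossValidatedR2)$folds), 10)
  nullR2 <- sapply(1:20, function(s) {
    set.seed(100 + s)
    crossValidatedR2(X, matrix(rnorm(300)), lambda = 1)$cvR2
  })
  expect_lt(mean(nullR2), 0)
})

test_that("pixel cvR2 maps follow from the component Gram matrices", {
  set.seed(12)
  X <- matrix(rnorm(200 * 6), 200, 6)
  W <- matrix(rnorm(6 * 3), 6, 3)
  Y <- X %*% W + matrix(rnorm(200 * 3, 0, 0.2), 200, 3)
  cv <- crossValidatedR2(X, Y, lambda = rep(1e-4, 3))
  U <- diag(3)                          # identity basis: pixel = component
  expect_equal(cvR2PixelMap(cv, U), unname(cv$cvR2), tolerance = 1e-10)
})

test_that("within-trial shuffling preserves per-trial regressor content", {
  out <- smallSession()
  stk <- smallStack(filtered = TRUE)
  X <- buildDesignMatrix(out$session@trials, frameRate = 15,
                         nFrames = ncol(stk@Vt))
  Y <- t(temporalComponents(stk))[, 1:5]
  uv <- uniqueVariance(X, Y, "handleTouch", folds = 5, lambda = rep(10, 5),
                       seed = 2)
  expect_length(uv$deltaR2, 5)
  expect_false(uv$zeroEvents)
  # deltaR2 of any group is bounded by the full model's cvR2 (up to
  # cross-validation noise; for near-zero columns both terms are noise)
  expect_true(all(uv$deltaR2 <= pmax(uv$cvR2Full, 0) + 0.05))
})

test_that("irrelevant variables carry no unique variance", {
  set.seed(30)
  nT <- 600
  trialIndex <- rep(1:20, each = 30)
  driver <- matrix(0, nT, 3)
  driver[cbind(sample(nT, 60), sample(3, 60, TRUE))] <- 1
  irrelevant <- matrix(0, nT, 3)
  irrelevant[cbind(sample(nT, 60), sample(3, 60, TRUE))] <- 1
  X <- new("DesignMatrix", X = cbind(driver, irrelevant),
           groupIndex = rep(c("driver", "irrelevant"), each = 3),
           variableKind = c(driver = "binary-event",
                            irrelevant = "binary-event"),
           trialIndex = as.integer(trialIndex), frameRate = 15)
  dR2 <- sapply(1:10, function(s) {
    set.seed(s)
    Y <- driver %*% rnorm(3, 2) + rnorm(nT, 0, 0.5)
    uniqueVariance(X, Y, "irrelevant", folds = 5, lambda = 1e-4,
                   seed = s)$deltaR2
  })
  expect_lt(max(abs(dR2)), 0.01)
})

test_that("unique variance of an orthogonal driver matches the closed form", {
  set.seed(31)
  nT <- 2000
  trialIndex <- rep(1:40, each = 50)
  # two orthogonal analog regressors with known variance shares
  x1 <- rnorm(nT); x2 <- rnorm(nT)
  x2 <- residuals(lm(x2 ~ x1))          # exactly orthogonal in sample
  b1 <- 1; b2 <- 0.6; sdN <- 0.8
  Y <- b1 * x1 + b2 * x2 + rnorm(nT, 0, sdN)
  X <- new("DesignMatrix", X = cbind(g1 = x1, g2 = x2),
           groupIndex = c("g1", "g2"),
           variableKind = c(g1 = "analog", g2 = "analog"),
           trialIndex = as.integer(trialIndex), frameRate = 15)
  uv <- uniqueVariance(X, Y, "g2", folds = 10, lambda = 1e-6, seed = 4)
  share <- b2^2 * var(x2) / var(Y)      # unique share for orthogonal design
  expect_lt(abs(uv$deltaR2 - share) / share, 0.2)
})

test_that("kernels map back to pixel space and recover the generative kernels", {
  out <- smallSession()
  ses <- out$session; gt <- out$truth
  stk <- smallStack(filtered = TRUE)
  M <- temporalComponents(stk)
  X <- buildDesignMatrix(ses@trials, frameRate = 15, nFrames = ncol(M),
                         movement = ses@movement)
  fit <- suppressWarnings(fitRidgeMLE(X, t(M)))
  # identity-basis case: kernels equal raw weights
  idFit <- fit
  kr0 <- reconstructKernels(fit, diag(nrow(M)), "clickLeft")
  idx <- which(fit@groupIndex == "clickLeft")
  expect_equal(kr0$kernel, fit@weights[idx, ], tolerance = 1e-12)
  # generative-kernel recovery through U at SNR 10
  U <- spatialBasis(stk)
  rs <- sapply(c(clickLeft = "stimLeft", clickRight = "stimRight"),
               function(e) NA_real_)
  vars <- c(clickLeft = "stimLeft", clickRight = "stimRight")
  for (v in names(vars)) {
    kr <- reconstructKernels(fit, U, v)
    truthK <- t(gt@spatialComponents %*% gt@eventKernels[[vars[[v]]]])
    L <- min(nrow(kr$kernel), nrow(truthK))
    rs[v] <- cor(as.vector(kr$kernel[1:L, ]), as.vector(truthK[1:L, ]))
  }
  expect_gt(median(rs), 0.9)
  # default stimulus display window is 0-200 ms
  expect_equal(eval(formals(reconstructKernels)$window), c(0, 0.2))
})

test_that("scaling the data rescales weights but not penalties or variance shares", {
  set.seed(40)
  X <- matrix(rnorm(250 * 12), 250, 12)
  Y <- X %*% rnorm(12) + rnorm(250)
  f1 <- fitRidgeMLE(X, Y)
  f5 <- fitRidgeMLE(X, 5 * Y)
  expect_equal(f5@weights, 5 * f1@weights, tolerance = 1e-6)
  expect_equal(log(f5@lambda), log(f1@lambda), tolerance = 1e-3)
  cv1 <- crossValidatedR2(X, Y, lambda = f1@lambda)
  cv5 <- crossValidatedR2(X, 5 * Y, lambda = f5@lambda)
  expect_equal(cv1$cvR2, cv5$cvR2, tolerance = 1e-8)
})
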