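# Registration, hemodynamic correction, compression, filtering, landmark
# and trial alignment.

test_that("phase-correlation registration recovers known integer shifts", {
  set.seed(1)
  dims <- c(40, 36)
  ref <- matrix(0, dims[1], dims[2])
  for (i in 1:6)   # textured reference
    ref <- ref + matrix(gaussianBlobFixture(dims), dims[1], dims[2])
  shifted <- ref[pmin(pmax(seq_len(dims[1]) - 3, 1), dims[1]),
                 pmin(pmax(seq_len(dims[2]) + 2, 1), dims[2])]
  frames <- cbind(as.vector(ref), as.vector(shifted))
  r <- registerRigid(frames, dims = dims, reference = ref)
  expect_equal(r$shifts[1, ], c(0, 0))            # identical frame
  expect_equal(r$shifts[2, ], c(-3, 2))           # inverse of applied shift
  # registered interior pixels match the reference
  interior <- as.vector(matrix(seq_len(prod(dims)), dims[1], dims[2])[5:36, 5:32])
  expect_lt(max(abs(r$frames[interior, 2] - frames[interior, 1])), 1e-10)
})

test_that("all-zero frames register with zero shift and a warning", {
  dims <- c(8, 8)
  frames <- cbind(as.vector(matrix(rnorm(64), 8, 8)), rep(0, 64))
  expect_warning(r <- registerRigid(frames, dims = dims,
                                    reference = frames[, 1]),
                 "all-zero")
  expect_equal(r$shifts[2, ], c(0L, 0L))
})

test_that("session registration references the median over first-trial frames", {
  out <- smallSession()
  ses <- out$session
  refIdx <- which(ses@blueTimes >= ses@trials$initTime[1] &
                  ses@blueTimes <= ses@trials$responseTime[1])
  manual <- registerRigid(ses@blue, dims = ses@dims, refIdx = refIdx)
  viaSession <- registerRigid(ses)
  expect_equal(viaSession@blue, manual$frames)
})

test_that("correction with a silent violet channel returns blue dF/F", {
  out <- generateWidefieldSession(
    taskConfig(nTrials = 5),
    sessionSpec(dims = c(16, 14), nSources = 2, hemoAmplitude = 0,
                noiseSd = 0.002), seed = 6)
  ses <- out$session
  ses@violet <- matrix(100, nrow(ses@violet), ncol(ses@violet))
  expect_warning(corr <- correctHemodynamics(ses), "zero-variance")
  blueDff <- ses@blue / rowMeans(ses@blue) - 1
  expect_equal(corr$dff, blueDff, tolerance = 1e-12)
})

test_that("correction removes the artifact and improves truth recovery", {
  out <- smallSession()
  ses <- out$session; gt <- out$truth
  corr <- correctHemodynamics(ses)
  calcium <- gt@spatialComponents %*% gt@temporalLoadings
  rawDff <- ses@blue / rowMeans(ses@blue) - 1
  expect_gt(cor(as.vector(corr$dff), as.vector(calcium)),
            cor(as.vector(rawDff), as.vector(calcium)))
  # residual artifact: compare against the calcium signal as it appears
  # after the dF/F arithmetic (centered per pixel, scaled by the per-pixel
  # baseline), so only genuine artifact leakage remains in the residual
  hemoBlue <- outer(gt@hemoSpatial,
                    gt@hemoTemporal[seq(1, length(gt@hemoTemporal), 2)])
  expected <- (calcium - rowMeans(calcium)) / (1 + rowMeans(calcium))
  resid <- corr$dff - expected
  resid <- resid - rowMeans(resid)
  hemoC <- hemoBlue - rowMeans(hemoBlue)
  expect_lt(abs(cor(as.vector(resid), as.vector(hemoC))), 0.05)
  # output at the per-channel rate (half of 30 fps)
  expect_equal(corr$frameRate, 15)
})

test_that("correction is idempotent on already-corrected data", {
  out <- smallSession()
  corr <- correctHemodynamics(out$session)
  vDff <- out$session@violet / rowMeans(out$session@violet) - 1
  again <- correctHemodynamics(corr$dff, vDff, corr$times,
                               out$session@violetTimes, baseline = "none")
  rmsChange <- sqrt(mean((again$dff - corr$dff)^2)) /
    sqrt(mean(corr$dff^2))
  expect_lt(rmsChange, 0.01)
})

test_that("channel length mismatch beyond one frame is rejected", {
  b <- matrix(rnorm(40), 4, 10); v <- matrix(rnorm(32), 4, 8)
  expect_error(correctHemodynamics(b, v, 1:10, 1:8), "more than one frame")
})

test_that("SVD compression matches a dense-SVD oracle", {
  set.seed(2)
  movie <- matrix(rnorm(50 * 200), 50, 200)
  d <- svd(movie, nu = 0, nv = 0)$d           # dense oracle
  for (k in c(3, 10, 25)) {
    stk <- compressSVD(movie, nComponents = k, frameRate = 15)
    expect_equal(varianceExplained(stk), sum(d[1:k]^2) / sum(d^2),
                 tolerance = 1e-8)
    expect_equal(singularValues(stk), d[1:k], tolerance = 1e-8)
    recon <- spatialBasis(stk) %*% (singularValues(stk) * stk@Vt)
    oracle <- svd(movie)
    reconO <- oracle$u[, 1:k] %*% (oracle$d[1:k] * t(oracle$v[, 1:k]))
    expect_equal(recon, reconO, tolerance = 1e-6)
  }
  expect_equal(eval(formals(compressSVD)$nComponents), 200)
})

test_that("rank-1 movies compress to a single nonzero singular value", {
  movie <- outer(runif(30), rnorm(80))
  stk <- compressSVD(movie, nComponents = 5, frameRate = 15)
  s <- singularValues(stk)
  expect_true(all(s[-1] < 1e-10 * s[1]))
  expect_equal(varianceExplained(stk), 1, tolerance = 1e-12)
})

test_that("non-finite frames are rejected with the frame named", {
  movie <- matrix(1, 4, 6); movie[2, 5] <- NA
  expect_error(compressSVD(movie, frameRate = 1), "frame\\(s\\) 5")
})

test_that("high-pass filter removes DC, passes fast signal, keeps zero phase", {
  fs <- 15
  tt <- seq(0, 400, by = 1 / fs)
  # constant row vanishes
  flat <- highpassFilter(rep(3, 500), frameRate = fs)
  expect_lt(max(abs(flat)), 1e-8 * 3)
  # 0.01 Hz attenuated > 20x, 1 Hz passed > 0.95
  slow <- highpassFilter(sin(2 * pi * 0.01 * tt), frameRate = fs)
  fast <- highpassFilter(sin(2 * pi * 1 * tt), frameRate = fs)
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  expect_lt(sqrt(mean(slow[mid]^2)) / sqrt(0.5), 1 / 20)
  expect_gt(sqrt(mean(fast[mid]^2)) / sqrt(0.5), 0.95)
  # zero phase: cross-correlation with the input peaks at lag 0
  x <- sin(2 * pi * 1 * tt)
  cc <- ccf(fast, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # too-short input is refused
  expect_error(highpassFilter(rnorm(5), frameRate = fs), "warm-up")
})

test_that("compress-filter-align pipeline commutes with input scaling", {
  out <- smallSession()
  corr <- correctHemodynamics(out$session)
  run <- function(m) {
    stk <- highpassFilter(compressSVD(m, nComponents = 10, frameRate = 15,
                                      dims = out$session@dims))
    al <- alignTrials(temporalComponents(stk), out$session@trials,
                      frameRate = 15, times = corr$times)
    list(U = spatialBasis(stk), al = al@data)
  }
  a <- run(corr$dff)
  b <- run(3 * corr$dff)
  # reconstruct in pixel space to factor out basis sign/rotation
  recA <- sapply(seq_len(dim(a$al)[1]), function(i) a$U %*% a$al[i, , ])
  recB <- sapply(seq_len(dim(b$al)[1]), function(i) b$U %*% b$al[i, , ])
  expect_equal(recB, 3 * recA, tolerance = 1e-6)
})

test_that("compressed filtered data still reconstructs the true calcium", {
  out <- generateWidefieldSession(
    taskConfig(nTrials = 10),
    sessionSpec(dims = c(24, 20), nSources = 3, hemoAmplitude = 0,
                noiseSd = 0), seed = 8)
  corr <- suppressWarnings(correctHemodynamics(out$session))
  stk <- compressSVD(corr, nComponents = 10, dims = out$session@dims)
  recon <- spatialBasis(stk) %*% temporalComponents(stk)
  calcium <- out$truth@spatialComponents %*% out$truth@temporalLoadings
  target <- corr$dff          # corrected movie is calcium up to baseline terms
  r2 <- 1 - sum((recon - target)^2) / sum((target - mean(target))^2)
  expect_gt(r2, 0.99)
  # against the truth, up to the per-pixel dF/F baseline constant
  expect_gt(cor(as.vector(recon - rowMeans(recon)),
                as.vector(calcium - rowMeans(calcium))), 0.995)
})

test_that("landmark alignment recovers rigid transforms to numerical precision", {
  lm <- defaultLandmarks()
  expect_equal(nrow(lm), 4)
  idFit <- landmarkAlign(lm, lm)
  expect_equal(idFit$rotation, diag(2), tolerance = 1e-12)
  expect_equal(idFit$translation, c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(idFit$residuals), 1e-12)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- t(R %*% t(lm)) + matrix(c(1.5, -0.7), 4, 2, byrow = TRUE)
  fit <- landmarkAlign(lm, moved)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, c(1.5, -0.7), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(fit$residuals), 1e-9)
  # scaled version
  fitS <- landmarkAlign(lm, 1.3 * moved, scale = TRUE)
  expect_equal(fitS$scale, 1.3, tolerance = 1e-9)
  collinear <- cbind(1:4, 2 * (1:4))
  expect_error(landmarkAlign(collinear, collinear), "collinear")
})

test_that("trial alignment yields fixed 2 s tensors anchored at the four events", {
  out <- smallSession()
  corr <- correctHemodynamics(out$session)
  stk <- smallStack()
  M <- temporalComponents(stk)
  al <- alignTrials(M, out$session@trials, frameRate = 15,
                    times = corr$times)
  expect_s4_class(al, "AlignedTensor")
  expect_equal(dim(al@data)[3], 30)                  # 2 s at 15 fps
  ef <- epochFrames(al)
  expect_equal(sum(lengths(ef)), 30)
  expect_equal(names(ef), c("initiate", "stimulus", "delay", "response"))
  # anchor frame choice equals a brute-force nearest-frame search
  tr <- out$session@trials
  for (i in c(1, 7)) {
    for (anchor in c("initTime", "stimOnset")) {
      bf <- which.min(abs(corr$times - tr[[anchor]][i]))
      win <- if (anchor == "initTime") ef$initiate else ef$stimulus
      expect_equal(al@data[i, , win[1]], M[, bf])
    }
  }
  expect_false(anyNA(al@data))
})

test_that("frames past a short real epoch are flagged in the mask", {
  fr <- 15
  M <- matrix(rnorm(2 * 200), 2, 200)
  t0 <- 2
  tr <- data.frame(initTime = t0, stimOnset = t0 + 0.5,
                   stimOffset = t0 + 1.6, spoutsIn = t0 + 1.65,
                   responseTime = t0 + 2.0)   # real delay 0.05 s < 0.2 s
  al <- alignTrials(M, tr, frameRate = fr)
  ef <- epochFrames(al)
  expect_true(any(al@mask[1, ef$delay]))
  expect_false(any(al@mask[1, ef$stimulus]))
})

test_that("a trial whose real durations equal the windows aligns to the raw slice", {
  # windows chosen to land exactly on frame boundaries at 15 fps
  fr <- 15
  spec <- data.frame(name = c("initiate", "stimulus", "delay", "response"),
                     anchor = c("initTime", "stimOnset", "stimOffset",
                                "spoutsIn"),
                     window = c(0.4, 1.0, 0.2, 0.4))
  M <- matrix(rnorm(2 * 300), 2, 300)
  times <- (0:299) / fr
  t0 <- times[31]
  tr <- data.frame(initTime = t0, stimOnset = t0 + 0.4,
                   stimOffset = t0 + 1.4, spoutsIn = t0 + 1.6,
                   responseTime = t0 + 2.0)
  al <- alignTrials(M, tr, epochSpec = spec, frameRate = fr)
  flat <- matrix(al@data[1, , ], nrow = 2)
  expect_equal(flat, M[, 31:60], ignore_attr = TRUE)
  expect_false(any(al@mask))
})
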