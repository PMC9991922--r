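#' Generate a trial event table for the discrimination task
#'
#' Draws one session of the delayed click-rate discrimination task. Epoch
#' durations are uniform within their configured ranges (handle hold
#' 0.25-0.75 s, stimulus 1-1.5 s, delay 0-1 s by default). Click trains are
#' homogeneous Poisson processes on each side; the rewarded side is the side
#' with more clicks and tie trials are re-drawn. The animal's choice is drawn
#' from a four-parameter psychometric rule (lapse + logistic in the signed
#' click-count difference).
#'
#' @param config a [taskConfig()]
#' @param seed integer seed; identical (config, seed) give identical tables
#' @return a data.frame with one row per trial: timestamps initTime,
#'   stimOnset, stimOffset, spoutsIn, responseTime (seconds, session clock),
#'   list-columns clickTimesLeft/clickTimesRight (absolute click times),
#'   counts nClicksLeft/nClicksRight, choice and rewardedSide
#'   ("left"/"right"), correct (logical) and opto ("none")
#' @examples
#' tr <- generateTrials(taskConfig(nTrials = 10), seed = 1)
#' @export
generateTrials <- function(config, seed) {
  validObject(config)
  set.seed(seed)
  n <- config@nTrials
  hold <- stats::runif(n, config@handleHoldRange[1], config@handleHoldRange[2])
  stimDur <- stats::runif(n, config@stimDurationRange[1], config@stimDurationRange[2])
  delay <- stats::runif(n, 0, config@delayMax)
  latency <- stats::runif(n, 0.1, 0.4)
  iti <- stats::runif(n, 1, 2)

  clicksL <- vector("list", n)
  clicksR <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      nL <- stats::rpois(1, config@clickRateLeft * stimDur[i])
      nR <- stats::rpois(1, config@clickRateRight * stimDur[i])
      if (nL != nR) break           # tie: rewarded side undefined, re-draw
    }
    clicksL[[i]] <- sort(stats::runif(nL, 0, stimDur[i]))
    clicksR[[i]] <- sort(stats::runif(nR, 0, stimDur[i]))
  }
  nL <- lengths(clicksL); nR <- lengths(clicksR)
  rewarded <- ifelse(nR > nL, "right", "left")

  ps <- config@psychometric
  pRight <- psychometricCurve(nR - nL, ps["bias"], ps["slope"],
                              ps["lapseLow"], ps["lapseHigh"])
  choice <- ifelse(stats::runif(n) < pRight, "right", "left")

  initTime <- 2 + cumsum(c(0, (hold + stimDur + delay + latency + iti)[-n]))
  stimOnset <- initTime + hold
  stimOffset <- stimOnset + stimDur
  spoutsIn <- stimOffset + delay
  responseTime <- spoutsIn + latency

  out <- data.frame(
    trial = seq_len(n), initTime = initTime, stimOnset = stimOnset,
    stimOffset = stimOffset, spoutsIn = spoutsIn,
    responseTime = responseTime,
    nClicksLeft = nL, nClicksRight = nR,
    choice = choice, rewardedSide = rewarded,
    correct = choice == rewarded, opto = "none",
    stringsAsFactors = FALSE
  )
  out$clickTimesLeft <- lapply(seq_len(n), function(i) stimOnset[i] + clicksL[[i]])
  out$clickTimesRight <- lapply(seq_len(n), function(i) stimOnset[i] + clicksR[[i]])
  out
}

#' Four-parameter psychometric function
#'
#' P(right) = lapseLow + (1 - lapseLow - lapseHigh) * logistic(slope * (x - bias))
#'
#' @param x signed stimulus strength (e.g. right minus left click count)
#' @param bias,slope,lapseLow,lapseHigh curve parameters
#' @return probability of a rightward choice
#' @export
psychometricCurve <- function(x, bias, slope, lapseLow, lapseHigh) {
  unname(lapseLow + (1 - lapseLow - lapseHigh) * stats::plogis(slope * (x - bias)))
}

#' Specification of a synthetic widefield session's ground truth
#'
#' @param dims image dimensions (rows, cols)
#' @param nSources number of nonnegative latent sources
#' @param hemoAmplitude standard deviation of the shared hemodynamic artifact
#'   as a fraction of baseline fluorescence (0 disables the artifact)
#' @param snr ratio of calcium signal RMS to additive noise SD; ignored when
#'   \code{noiseSd} is given explicitly
#' @param noiseSd additive noise SD as a fraction of baseline, or NULL to
#'   derive it from \code{snr}
#' @param violetGainRange range of the per-pixel violet artifact gain
#' @param calciumAmplitude typical peak dF/F of a single source response
#' @param movementWeight strength of movement-driven source activity
#' @param spontaneousWeight strength of each source's independent
#'   spontaneous (non-task) activity, relative to a unit event response;
#'   spontaneous and movement activity dominating task responses mirrors
#'   real widefield recordings
#' @param nVideo number of latent video feature traces
#' @return a list understood by [generateWidefieldSession()]
#' @export
sessionSpec <- function(dims = c(64, 54), nSources = 5,
                        hemoAmplitude = 0.1, snr = 10, noiseSd = NULL,
                        violetGainRange = c(0.8, 1.2),
                        calciumAmplitude = 0.05, movementWeight = 0.3,
                        spontaneousWeight = 1, nVideo = 10) {
  list(dims = as.integer(dims), nSources = as.integer(nSources),
       hemoAmplitude = hemoAmplitude, snr = snr, noiseSd = noiseSd,
       violetGainRange = violetGainRange,
       calciumAmplitude = calciumAmplitude,
       movementWeight = movementWeight,
       spontaneousWeight = spontaneousWeight, nVideo = as.integer(nVideo))
}

# 2-D Gaussian blob over the pixel grid, flattened column-major, peak 1.
# Compactly supported (zero beyond ~2 sigma): cortical sources are local,
# and compact support keeps distinct sources identifiable.
gaussianBlob <- function(dims, center, sigma, truncate = TRUE) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  g <- exp(-((r - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
  if (truncate) g <- pmax(g - exp(-2), 0) / (1 - exp(-2))
  as.vector(g)
}

# smooth unit-variance random trace: white noise run twice through a causal
# exponential moving average (time constant tauS seconds); the second pass
# makes the trace differentiable at the frame timescale, as physiological
# signals are
smoothTrace <- function(n, rate, tauS) {
  a <- exp(-1 / (rate * tauS))
  x <- stats::rnorm(n)
  for (i in 1:2)
    x <- as.numeric(stats::filter(x, a, method = "recursive"))
  x / stats::sd(x)
}

#' Generate a complete synthetic two-wavelength widefield session
#'
#' Emulates the acquisition: a camera at \code{config@frameRate} (30 fps
#' default) alternates blue and violet excitation so each channel runs at
#' half rate. Blue frames are
#' \code{baseline * (1 + calcium + hemo + noise)}; violet frames are
#' \code{baseline * (1 + gain * hemo + noise)} and carry no calcium. The
#' calcium movie is exactly low-rank: nonnegative Gaussian-blob sources times
#' loadings driven by event kernels convolved with the trial events plus a
#' movement-coupled trace. The hemodynamic artifact is multiplicative and
#' shared across channels up to a stored per-pixel gain, so the
#' rescale-and-subtract correction is exact in the noiseless limit.
#'
#' @param config a [taskConfig()]
#' @param gtSpec a [sessionSpec()]
#' @param seed integer seed
#' @return list with elements \code{session} (a [RawSession-class]) and
#'   \code{truth} (a [GroundTruth-class])
#' @examples
#' out <- generateWidefieldSession(taskConfig(nTrials = 4),
#'                                 sessionSpec(dims = c(16, 14)), seed = 1)
#' @export
generateWidefieldSession <- function(config, gtSpec = sessionSpec(), seed) {
  if (prod(gtSpec$dims) < gtSpec$nSources)
    stop("pixel grid smaller than the number of latent sources")
  trials <- generateTrials(config, seed)
  set.seed(seed + 1L)

  dims <- gtSpec$dims
  npx <- prod(dims)
  k <- gtSpec$nSources
  fullRate <- config@frameRate
  chanRate <- fullRate / 2

  dur <- max(trials$responseTime) + 2
  nFrames <- 2L * ceiling(dur * fullRate / 2)
  frameTimes <- (seq_len(nFrames) - 1) / fullRate
  blueIdx <- seq(1L, nFrames, by = 2L)
  violetIdx <- seq(2L, nFrames, by = 2L)
  tb <- frameTimes[blueIdx]
  tv <- frameTimes[violetIdx]
  nb <- length(tb)

  # nonnegative spatial sources at mutually separated centers; separation
  # exceeds the blob support radius so each source keeps pure peak pixels
  # (distinct cortical areas, not one smeared continuum)
  centers <- matrix(0, k, 2)
  minSep <- 0.35 * min(dims)
  for (i in seq_len(k)) {
    for (try in seq_len(200)) {
      ctr <- c(stats::runif(1, 0.15, 0.85) * dims[1],
               stats::runif(1, 0.15, 0.85) * dims[2])
      if (i == 1 || min(sqrt(rowSums(sweep(centers[seq_len(i - 1), ,
            drop = FALSE], 2, ctr)^2))) >= minSep) break
    }
    centers[i, ] <- ctr
  }
  A <- sapply(seq_len(k), function(i)
    gaussianBlob(dims, centers[i, ], stats::runif(1, 0.07, 0.13) * min(dims)))
  A <- matrix(A, npx, k)

  # event kernels: gamma-shaped responses at the blue-channel rate; lick
  # responses are choice-lateralized so some sources carry choice signal
  eventTypes <- c("stimLeft", "stimRight", "init", "lickLeft", "lickRight")
  lagS <- seq(0, 1, by = 1 / chanRate)
  kern <- lapply(eventTypes, function(e) {
    tau <- stats::runif(k, 0.15, 0.3)
    amp <- stats::runif(k, 0, 1) * stats::rbinom(k, 1, 0.6)
    t(sapply(seq_len(k), function(s)
      amp[s] * (lagS / tau[s]) * exp(1 - lagS / tau[s])))
  })
  names(kern) <- eventTypes
  # licking drives strong, side-preferring activity (movement-related
  # activity dominates cortical variance; frontal sources carry robust
  # choice-lateralized responses)
  lickAmp <- stats::runif(k, 0.5, 1.5)
  lickSide <- sample(c("L", "R"), k, replace = TRUE)
  for (s in seq_len(k)) {
    tau <- stats::runif(1, 0.15, 0.3)
    sh <- (lagS / tau) * exp(1 - lagS / tau)
    aL <- ifelse(lickSide[s] == "L", lickAmp[s], 0.3 * lickAmp[s])
    aR <- ifelse(lickSide[s] == "R", lickAmp[s], 0.3 * lickAmp[s])
    kern$lickLeft[s, ] <- aL * sh
    kern$lickRight[s, ] <- aR * sh
  }
  # guarantee each source responds to something
  for (s in seq_len(k)) {
    if (all(sapply(kern, function(m) all(m[s, ] == 0)))) {
      e <- eventTypes[1 + (s %% length(eventTypes))]
      kern[[e]][s, ] <- (lagS / 0.2) * exp(1 - lagS / 0.2)
    }
  }

  eventTimes <- list(
    stimLeft = unlist(trials$clickTimesLeft),
    stimRight = unlist(trials$clickTimesRight),
    init = trials$initTime,
    lickLeft = trials$spoutsIn[trials$choice == "left"],
    lickRight = trials$spoutsIn[trials$choice == "right"]
  )

  movement <- cbind(piezo = smoothTrace(nb, chanRate, 0.5),
                    whisk = abs(smoothTrace(nb, chanRate, 0.2)))
  video <- sapply(seq_len(gtSpec$nVideo), function(i)
    smoothTrace(nb, chanRate, 0.3))
  video <- matrix(video, nb, gtSpec$nVideo)

  # loadings at blue frame times: event-kernel drive + movement coupling
  loadings <- matrix(0, k, nb)
  for (e in eventTypes) {
    pulses <- numeric(nb)
    fi <- pmin(nb, pmax(1L, round(eventTimes[[e]] * chanRate) + 1L))
    for (f in fi) pulses[f] <- pulses[f] + 1
    km <- kern[[e]]
    for (s in seq_len(k)) {
      conv <- stats::convolve(pulses, rev(km[s, ]), type = "open")
      loadings[s, ] <- loadings[s, ] + conv[seq_len(nb)]
    }
  }
  mw <- stats::runif(k, 0, gtSpec$movementWeight)
  loadings <- loadings + outer(mw, movement[, "piezo"])
  if (gtSpec$spontaneousWeight > 0)
    loadings <- loadings + gtSpec$spontaneousWeight *
      t(sapply(seq_len(k), function(s) smoothTrace(nb, chanRate, 0.5)))
  loadings <- loadings * gtSpec$calciumAmplitude

  calcium <- A %*% loadings
  noiseSd <- if (!is.null(gtSpec$noiseSd)) gtSpec$noiseSd else
    if (gtSpec$snr > 0) stats::sd(calcium) / gtSpec$snr else 0

  hemoSpatial <- 0.5 + 0.5 * (gaussianBlob(dims, dims * 0.4, 0.3 * min(dims)) +
                              gaussianBlob(dims, dims * 0.7, 0.25 * min(dims)))
  hemoSpatial <- hemoSpatial / max(hemoSpatial)
  # the artifact trace is decorrelated in-sample from the source loadings
  # (separately at blue and violet sample times), so the rescale-and-
  # subtract correction is exactly identified in the noiseless limit — the
  # asymptotic regime of hour-long sessions, where chance correlation
  # between calcium and vasculature vanishes
  hemoTemporal <- numeric(nFrames)
  if (gtSpec$hemoAmplitude > 0) {
    raw <- smoothTrace(nFrames, fullRate, 1.5)
    projOut <- function(y, L) qr.resid(qr(cbind(1, t(L))), y)
    hB <- projOut(raw[blueIdx], loadings)
    Lv <- t(apply(loadings, 1, function(r)
      stats::approx(tb, r, xout = tv, rule = 2)$y))
    hV <- projOut(raw[violetIdx], Lv)
    hemoTemporal[blueIdx] <- hB
    hemoTemporal[violetIdx] <- hV
    hemoTemporal <- gtSpec$hemoAmplitude * hemoTemporal / stats::sd(hemoTemporal)
  }
  gain <- stats::runif(npx, gtSpec$violetGainRange[1], gtSpec$violetGainRange[2])

  baseline <- 100 * (0.8 + 0.4 * stats::runif(npx))
  noise <- function(nc) if (noiseSd > 0)
    matrix(stats::rnorm(npx * nc, 0, noiseSd), npx, nc) else 0

  blue <- baseline * (1 + calcium +
                      outer(hemoSpatial, hemoTemporal[blueIdx]) + noise(nb))
  violet <- baseline * (1 + (gain * hemoSpatial) %o% hemoTemporal[violetIdx] +
                        noise(length(tv)))

  session <- new("RawSession", blue = blue, violet = violet,
                 blueTimes = tb, violetTimes = tv,
                 dims = dims, frameRate = fullRate, trials = trials,
                 movement = movement, video = video)
  truth <- new("GroundTruth", spatialComponents = A,
               temporalLoadings = loadings, eventKernels = kern,
               hemoSpatial = hemoSpatial, hemoTemporal = hemoTemporal,
               hemoGain = gain, noiseSd = noiseSd, dims = dims)
  list(session = session, truth = truth)
}

#' Generate a population of deconvolved-like single-neuron traces
#'
#' Emulates two-photon populations with a declared fraction of choice-tuned
#' neurons. Baseline activity is i.i.d. gamma (nonnegative,
#' deconvolved-like); a tuned neuron's activity during the stimulus+delay
#' window is shifted upward on trials of its preferred choice so that the
#' per-trial window mean separates by \code{effectSize} standard deviations.
#'
#' @param nNeurons population size
#' @param fracIpsi,fracContra fractions preferring ipsi(left)/contra(right)
#'   choices; must sum to at most 1
#' @param effectSize separation of preferred vs anti-preferred per-trial
#'   window means, in SD units of the untuned trial-mean distribution
#' @param trials trial table from [generateTrials()] (choices are used)
#' @param seed integer seed
#' @param nTime timepoints per trial (2 s at 15 fps by default)
#' @param window timepoint indices of the stimulus+delay analysis window
#' @return list: \code{activity} (trials x time x neurons, nonnegative),
#'   \code{label} ("ipsi"/"contra"/"untuned" per neuron), \code{tuning}
#'   (signed effect size per neuron, 0 for untuned), \code{window}
#' @export
generateNeuronPopulation <- function(nNeurons, fracIpsi, fracContra,
                                     effectSize, trials, seed,
                                     nTime = 30L, window = 8:25) {
  stopifnot(fracIpsi >= 0, fracContra >= 0, fracIpsi + fracContra <= 1)
  set.seed(seed)
  nTr <- nrow(trials)
  nIpsi <- round(fracIpsi * nNeurons)
  nContra <- round(fracContra * nNeurons)
  label <- c(rep("ipsi", nIpsi), rep("contra", nContra),
             rep("untuned", nNeurons - nIpsi - nContra))
  label <- sample(label)
  tuning <- ifelse(label == "untuned", 0,
                   ifelse(label == "contra", effectSize, -effectSize))

  act <- array(stats::rgamma(nTr * nTime * nNeurons, shape = 1, scale = 1),
               dim = c(nTr, nTime, nNeurons))
  # shift preferred-choice trials: delta on each window frame moves the
  # trial-window mean by delta; sd of that mean is 1/sqrt(|window|)
  delta <- effectSize / sqrt(length(window))
  isContraTrial <- trials$choice == "right"
  for (j in which(label != "untuned")) {
    pref <- if (label[j] == "contra") isContraTrial else !isContraTrial
    act[pref, window, j] <- act[pref, window, j] + delta
  }
  list(activity = act, label = label, tuning = tuning, window = window)
}

#' Synthetic rectangular region atlas
#'
#' A simplified stand-in for a merged-area reference atlas: the pixel grid is
#' tiled into \code{nx * ny} rectangular seed regions.
#'
#' @param dims image dimensions (rows, cols)
#' @param nx,ny number of tiles along each axis
#' @return a [RegionMap-class]
#' @export
makeRegionGrid <- function(dims, nx = 2, ny = 3) {
  rows <- ceiling(seq_len(dims[1]) / (dims[1] / ny))
  cols <- ceiling(seq_len(dims[2]) / (dims[2] / nx))
  lab <- outer(rows, cols, function(r, c) (r - 1L) * nx + c)
  ids <- sort(unique(as.vector(lab)))
  nm <- paste0("region", ids)
  names(nm) <- as.character(ids)
  new("RegionMap", labels = matrix(as.integer(lab), dims[1], dims[2]),
      regionNames = nm)
}

#' Generate labeled families of synthetic spatial components
#'
#' Produces component images of several "cell types" across several animals,
#' for exercising the embedding + leave-one-animal-out type classifier. Each
#' type is a mixture of Gaussian blobs at type-specific locations; animals
#' and sessions add jitter and pixel noise.
#'
#' @param nPerType components per type
#' @param nTypes number of types
#' @param nAnimals number of animals (components are split evenly)
#' @param dims image dimensions of each component
#' @param jitter SD of the blob-center jitter in pixels
#' @param noiseSd pixel noise SD (components are peak-normalized afterwards)
#' @param seed integer seed
#' @return list: \code{images} (components x pixels matrix), \code{label},
#'   \code{animal}, \code{session} (character vectors), \code{dims}
#' @export
generateTypedComponents <- function(nPerType = 200, nTypes = 3, nAnimals = 6,
                                    dims = c(32, 27), jitter = 1.5,
                                    noiseSd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- lapply(seq_len(nTypes), function(ty)
    cbind(stats::runif(2, 0.2, 0.8) * dims[1],
          stats::runif(2, 0.2, 0.8) * dims[2]))
  n <- nPerType * nTypes
  images <- matrix(0, n, prod(dims))
  label <- character(n); animal <- character(n)
  i <- 0L
  for (ty in seq_len(nTypes)) {
    for (j in seq_len(nPerType)) {
      i <- i + 1L
      img <- numeric(prod(dims))
      for (b in seq_len(nrow(centers[[ty]]))) {
        ctr <- centers[[ty]][b, ] + stats::rnorm(2, 0, jitter)
        img <- img + gaussianBlob(dims, ctr, 0.12 * min(dims))
      }
      img <- img + abs(stats::rnorm(prod(dims), 0, noiseSd))
      images[i, ] <- img / max(img)
      label[i] <- paste0("type", ty)
      animal[i] <- paste0("animal", 1 + (j %% nAnimals))
    }
  }
  session <- paste0(animal, "_s", 1)
  list(images = images, label = label, animal = animal,
       session = session, dims = as.integer(dims))
}
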