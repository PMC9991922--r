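# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# small synthetic session with hemodynamic artifact and noise (SNR 10)
smallSession <- function(seed = 3, nTrials = 20, dims = c(32, 28),
                         nSources = 3, ...) {
  key <- paste("ses", seed, nTrials, paste(dims, collapse = "x"), nSources,
               sep = "_")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateWidefieldSession(
      taskConfig(nTrials = nTrials),
      sessionSpec(dims = dims, nSources = nSources, snr = 10, ...),
      seed = seed)
  .fixtures[[key]]
}

# corrected + compressed (and filtered) stack for the small session
smallStack <- function(seed = 3, nComponents = 40, filtered = FALSE) {
  key <- paste("stk", seed, nComponents, filtered, sep = "_")
  if (is.null(.fixtures[[key]])) {
    out <- smallSession(seed = seed)
    corr <- correctHemodynamics(out$session)
    stk <- compressSVD(corr, nComponents = nComponents,
                       dims = out$session@dims)
    if (filtered) stk <- highpassFilter(stk)
    .fixtures[[key]] <- stk
  }
  .fixtures[[key]]
}

# uncentered cosine similarity between two nonnegative maps
cosineSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# greedy best-match cosine of each true source against recovered components
matchSources <- function(Atrue, Arec) {
  sapply(seq_len(ncol(Atrue)), function(j)
    max(sapply(seq_len(ncol(Arec)), function(i)
      cosineSim(Atrue[, j], Arec[, i]))))
}

# flattened random Gaussian blob for building textured reference frames
gaussianBlobFixture <- function(dims) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  ctr <- runif(2, 0.2, 0.8) * dims
  s <- runif(1, 2, 5)
  as.vector(exp(-((r - ctr[1])^2 + (cc - ctr[2])^2) / (2 * s^2)))
}

# trial table with prescribed (choice x correctness) cell counts
cellTrials <- function(nLeftWrong, nLeftRight, nRightWrong, nRightRight) {
  data.frame(
    choice = rep(c("left", "left", "right", "right"),
                 c(nLeftWrong, nLeftRight, nRightWrong, nRightRight)),
    correct = rep(c(FALSE, TRUE, FALSE, TRUE),
                  c(nLeftWrong, nLeftRight, nRightWrong, nRightRight)),
    stringsAsFactors = FALSE)
}
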