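#' Rigid frame registration by phase correlation
#'
#' Estimates a per-frame integer translation against a reference frame using
#' frequency-domain phase correlation and applies it, filling out-of-frame
#' pixels with edge values. For a [RawSession-class] the reference defaults
#' to the median over all frames of the first trial (per channel).
#'
#' @param x pixels x frames matrix (flattened column-major) or a RawSession
#' @param dims image dimensions (matrix input only)
#' @param reference reference image as a matrix or flattened vector; for the
#'   matrix method, NULL means the median over \code{refIdx} frames
#' @param refIdx frame indices defining the default reference
#' @param ... passed to methods
#' @return list with \code{shifts} (frames x 2, the row/col translation
#'   applied to each frame) and \code{frames} (registered matrix); the
#'   RawSession method returns the session with both channels registered and
#'   per-channel shifts in \code{shifts}
#' @export
setGeneric("registerRigid", function(x, ...) standardGeneric("registerRigid"))

#' @rdname registerRigid
#' @export
setMethod("registerRigid", "matrix",
          function(x, dims, reference = NULL, refIdx = NULL, ...) {
  n <- ncol(x)
  if (is.null(reference)) {
    if (is.null(refIdx)) refIdx <- seq_len(n)
    reference <- apply(x[, refIdx, drop = FALSE], 1, stats::median)
  }
  ref <- matrix(reference, dims[1], dims[2])
  fr <- stats::fft(ref)
  shifts <- matrix(0L, n, 2)
  out <- x
  for (i in seq_len(n)) {
    fm <- matrix(x[, i], dims[1], dims[2])
    if (all(fm == 0)) {
      warning("all-zero frame ", i, ": correlation undefined, zero shift")
      next
    }
    sh <- phaseShift(fr, fm, dims)
    shifts[i, ] <- sh
    if (any(sh != 0)) out[, i] <- as.vector(translateEdge(fm, sh))
  }
  list(shifts = shifts, frames = out)
})

#' @rdname registerRigid
#' @export
setMethod("registerRigid", "RawSession", function(x, ...) {
  shifts <- list()
  for (chan in c("blue", "violet")) {
    tms <- slot(x, paste0(chan, "Times"))
    refIdx <- which(tms >= x@trials$initTime[1] &
                    tms <= x@trials$responseTime[1])
    if (!length(refIdx)) refIdx <- seq_len(min(30L, length(tms)))
    r <- registerRigid(slot(x, chan), dims = x@dims, refIdx = refIdx)
    slot(x, chan) <- r$frames
    shifts[[chan]] <- r$shifts
  }
  x@trials$registered <- TRUE
  attr(x, "shifts") <- shifts
  x
})

# shift (row, col) to apply to frame fm so it aligns with the reference
# whose FFT is fr; integer-pixel phase-correlation peak
phaseShift <- function(fr, fm, dims) {
  cp <- fr * Conj(stats::fft(fm))
  # regularized whitening: plain 1/|cp| amplifies numerically empty high
  # frequencies of smooth images into phase noise
  mag <- Mod(cp)
  corr <- Re(stats::fft(cp / (mag + 1e-4 * max(mag)), inverse = TRUE))
  pk <- arrayInd(which.max(corr), dims)
  wrap <- function(v, n) { v <- v - 1L; ifelse(v > n / 2, v - n, v) }
  c(wrap(pk[1], dims[1]), wrap(pk[2], dims[2]))
}

# integer translation with edge replication
translateEdge <- function(img, sh) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H) - sh[1], 1L), H)
  ci <- pmin(pmax(seq_len(W) - sh[2], 1L), W)
  img[ri, ci]
}

#' Hemodynamic correction from interleaved dual-wavelength frames
#'
#' Isolates calcium-dependent signal by rescaling and subtracting the
#' calcium-independent violet-excitation frames from the blue-excitation
#' frames. The violet channel is linearly interpolated to the blue frame
#' times (nearest-frame at the sequence edges), a per-pixel scale factor is
#' fit by least squares over the whole session, and the corrected movie is
#' \code{dFF(blue) - scale * dFF(violet)} at the per-channel rate.
#'
#' @param blue,violet pixels x frames matrices, or a RawSession for the
#'   session method
#' @param blueTimes,violetTimes frame timestamps in seconds
#' @param scaleMode "pixel" (per-pixel least squares, default) or "global"
#'   (one scalar for the whole image)
#' @param baseline "mean" computes dF/F against the per-pixel session mean
#'   before correcting; "none" treats the inputs as dF/F already
#' @param ... passed to methods
#' @return list: \code{dff} (pixels x blue-frames corrected movie),
#'   \code{scale} (per-pixel or scalar), \code{times}, \code{frameRate}
#' @export
setGeneric("correctHemodynamics", function(blue, ...) standardGeneric("correctHemodynamics"))

#' @rdname correctHemodynamics
#' @export
setMethod("correctHemodynamics", "matrix",
          function(blue, violet, blueTimes, violetTimes,
                   scaleMode = c("pixel", "global"),
                   baseline = c("mean", "none"), ...) {
  scaleMode <- match.arg(scaleMode)
  baseline <- match.arg(baseline)
  if (abs(ncol(blue) - ncol(violet)) > 1)
    stop("blue and violet channel lengths differ by more than one frame")
  dff <- function(m) if (baseline == "mean") m / rowMeans(m) - 1 else m
  b <- dff(blue)
  v <- dff(violet)

  # interpolate violet to blue frame times
  nv <- ncol(v)
  j <- findInterval(blueTimes, violetTimes)
  jlo <- pmin(pmax(j, 1L), nv - 1L)
  w <- (blueTimes - violetTimes[jlo]) / (violetTimes[jlo + 1L] - violetTimes[jlo])
  w <- pmin(pmax(w, 0), 1)                 # nearest-frame fallback at edges
  vb <- t(t(v[, jlo, drop = FALSE]) * (1 - w)) +
        t(t(v[, jlo + 1L, drop = FALSE]) * w)

  den <- rowSums(vb^2)
  num <- rowSums(vb * b)
  if (scaleMode == "global") {
    s <- sum(num) / sum(den)
    corrected <- b - s * vb
  } else {
    bad <- den < .Machine$double.eps * ncol(vb)
    if (any(bad))
      warning(sum(bad), " zero-variance violet pixel(s); scale set to 0")
    s <- ifelse(bad, 0, num / pmax(den, .Machine$double.eps))
    corrected <- b - s * vb
  }
  rate <- 1 / stats::median(diff(blueTimes))
  list(dff = corrected, scale = s, times = blueTimes, frameRate = rate)
})

#' @rdname correctHemodynamics
#' @export
setMethod("correctHemodynamics", "RawSession", function(blue, ...) {
  out <- correctHemodynamics(blue@blue, blue@violet,
                             blue@blueTimes, blue@violetTimes, ...)
  out$dims <- blue@dims
  out
})

#' SVD compression of a movie
#'
#' Truncated singular value decomposition keeping the highest-variance
#' components (200 by default). Downstream time-domain analyses use
#' \code{diag(S) Vt}; pixel-space results are recovered by left-multiplying
#' U.
#'
#' @param movie pixels x frames matrix, or the list returned by
#'   [correctHemodynamics()]
#' @param nComponents number of components to keep (default 200, capped at
#'   \code{min(pixels, frames)})
#' @param frameRate sampling rate of the frame axis (taken from the
#'   corrected-movie list when available)
#' @param pixelSize pixel edge length in mm (default 0.02, i.e. ~20 um)
#' @param dims image dimensions
#' @return a [CompressedStack-class]; its \code{varianceExplained} is
#'   \code{sum(S[1:k]^2) / sum(all S^2)}
#' @export
compressSVD <- function(movie, nComponents = 200, frameRate = NULL,
                        pixelSize = 0.02, dims = NULL) {
  if (is.list(movie)) {
    if (is.null(frameRate)) frameRate <- movie$frameRate
    if (is.null(dims)) dims <- movie$dims
    movie <- movie$dff
  }
  badf <- which(!apply(is.finite(movie), 2, all))
  if (length(badf))
    stop("non-finite values in frame(s) ", paste(utils::head(badf, 5), collapse = ", "))
  if (is.null(dims)) dims <- c(nrow(movie), 1L)
  if (is.null(frameRate)) frameRate <- 1

  k <- min(nComponents, nrow(movie), ncol(movie))
  totSS <- sum(movie^2)
  # eigendecompose the Gram matrix on the smaller side; singular values are
  # then recomputed from the data projections, which is accurate for
  # (near-)null directions where sqrt(eigenvalue) loses half the digits
  uFromP <- ncol(movie) <= nrow(movie)
  if (uFromP) {
    e <- eigen(crossprod(movie), symmetric = TRUE)
    V <- e$vectors[, seq_len(k), drop = FALSE]
    P <- movie %*% V
    d <- sqrt(colSums(P^2))
    pos <- d > max(d) * 1e-14
    U <- P
    U[, pos] <- sweep(P[, pos, drop = FALSE], 2, d[pos], "/")
    if (any(!pos)) U[, !pos] <- 0
  } else {
    e <- eigen(tcrossprod(movie), symmetric = TRUE)
    U <- e$vectors[, seq_len(k), drop = FALSE]
    P <- crossprod(movie, U)
    d <- sqrt(colSums(P^2))
    pos <- d > max(d) * 1e-14
    V <- P
    V[, pos] <- sweep(P[, pos, drop = FALSE], 2, d[pos], "/")
    if (any(!pos)) V[, !pos] <- 0
  }
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; U <- U[, ord, drop = FALSE]; V <- V[, ord, drop = FALSE]
  pos <- pos[ord]
  # null-direction columns of U get a deterministic orthonormal completion
  # (only needed when U columns were built from data projections); retained
  # columns are left untouched
  if (uFromP && any(!pos)) {
    filler <- matrix(sin(seq_len(nrow(U) * sum(!pos))), nrow(U))
    q <- qr.Q(qr(cbind(U[, pos, drop = FALSE], filler)))
    U[, !pos] <- q[, (sum(pos) + 1):k, drop = FALSE]
  }
  new("CompressedStack", U = U, S = d, Vt = t(V),
      frameRate = frameRate, pixelSize = pixelSize,
      dims = as.integer(dims),
      varianceExplained = sum(d^2) / totSS)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes slow drift by filtering each row with a forward-backward
#' (zero-phase) second-order Butterworth high-pass, 0.1 Hz cutoff by
#' default. Applied to the temporal components \code{diag(S) Vt} rather
#' than pixels; by linearity the result equals pixel-domain filtering.
#'
#' @param x numeric matrix whose rows are filtered (or a vector), or a
#'   CompressedStack (its Vt rows are filtered)
#' @param frameRate sampling rate in Hz
#' @param cutoff high-pass cutoff in Hz
#' @param ... passed to methods
#' @return the filtered object, same shape/class as the input
#' @export
setGeneric("highpassFilter", function(x, ...) standardGeneric("highpassFilter"))

.hpRows <- function(m, frameRate, cutoff) {
  stopifnot(frameRate > 2 * cutoff)
  n <- ncol(m)
  if (n < 9)
    stop("sequence shorter than the filter warm-up (need >= 9 samples)")
  bf <- signal::butter(2, cutoff / (frameRate / 2), type = "high")
  # odd-reflection padding: filtfilt alone leaves long edge transients at
  # such a low cutoff; the padding absorbs them
  pad <- min(n - 1, ceiling(3 * frameRate / cutoff))
  t(apply(m, 1, function(r) {
    r <- r - mean(r)   # a high-pass removes the mean anyway; this kills it exactly
    xr <- c(2 * r[1] - r[(pad + 1):2], r, 2 * r[n] - r[(n - 1):(n - pad)])
    signal::filtfilt(bf, xr)[(pad + 1):(pad + n)]
  }))
}

#' @rdname highpassFilter
#' @export
setMethod("highpassFilter", "matrix", function(x, frameRate, cutoff = 0.1, ...) {
  .hpRows(x, frameRate, cutoff)
})

#' @rdname highpassFilter
#' @export
setMethod("highpassFilter", "numeric", function(x, frameRate, cutoff = 0.1, ...) {
  as.numeric(.hpRows(matrix(x, 1), frameRate, cutoff))
})

#' @rdname highpassFilter
#' @export
setMethod("highpassFilter", "CompressedStack", function(x, cutoff = 0.1, ...) {
  x@Vt <- .hpRows(x@Vt, x@frameRate, cutoff)
  x
})

#' Least-squares rigid landmark alignment (Procrustes)
#'
#' Fits the rigid transform (rotation + translation, optional isotropic
#' scale) minimizing the summed squared distance between paired landmarks,
#' e.g. for aligning a session to a reference atlas from four anatomical
#' anchor points.
#'
#' @param landmarksSession n x 2 matrix of session-space points
#' @param landmarksAtlas n x 2 matrix of matched atlas-space points
#' @param scale if TRUE, also fit an isotropic scale
#' @return list: \code{rotation} (2 x 2), \code{translation} (length 2),
#'   \code{scale}, \code{residuals} (per-landmark distance after transform)
#'   and \code{transform}, a function mapping session points to atlas space
#' @export
landmarkAlign <- function(landmarksSession, landmarksAtlas, scale = FALSE) {
  src <- as.matrix(landmarksSession)
  dst <- as.matrix(landmarksAtlas)
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 2, ncol(dst) == 2)
  if (nrow(src) < 3) stop("need at least 3 landmark pairs")
  sc <- scale(src, scale = FALSE)
  dc <- scale(dst, scale = FALSE)
  if (qr(sc)$rank < 2) stop("landmarks are collinear")
  H <- crossprod(sc, dc)
  sv <- svd(H)
  D <- diag(c(1, det(sv$v %*% t(sv$u))))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) sum(diag(D) * sv$d) / sum(sc^2) else 1
  t0 <- colMeans(dst) - s * as.vector(R %*% colMeans(src))
  fn <- function(p) t(s * R %*% t(as.matrix(p)) + t0)
  res <- sqrt(rowSums((fn(src) - dst)^2))
  list(rotation = R, translation = t0, scale = s, residuals = res,
       transform = fn)
}

#' Default anatomical landmarks for atlas alignment
#'
#' Four anchor points in atlas coordinates (mm, synthetic stand-in for a
#' reference atlas): the left, center and right points where anterior cortex
#' meets the olfactory bulbs and the medial point at the base of
#' retrosplenial cortex.
#'
#' @return a 4 x 2 matrix with row names
#' @export
defaultLandmarks <- function() {
  m <- rbind(obLeft = c(-3.5, 2.8), obCenter = c(0, 3.4),
             obRight = c(3.5, 2.8), rsBase = c(0, -4.2))
  colnames(m) <- c("ml", "ap")
  m
}

#' Default four-epoch alignment windows
#'
#' Initiate 0.5 s at handle touch, stimulus 1 s at stimulus onset, delay
#' 0.2 s at stimulus offset, response 0.3 s at spouts-in: 2 s total.
#'
#' @return data.frame with columns name, anchor, window
#' @export
defaultEpochSpec <- function() {
  data.frame(
    name = c("initiate", "stimulus", "delay", "response"),
    anchor = c("initTime", "stimOnset", "stimOffset", "spoutsIn"),
    window = c(0.5, 1.0, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Align temporal components to the four trial epochs
#'
#' Trials have randomized epoch durations; for averaging and decoding each
#' trial is re-sliced into fixed windows anchored at the epoch events. Per
#' epoch, the window starts at the frame nearest the anchor and the windows
#' are concatenated, so the output duration is the sum of the windows
#' regardless of the real durations. Frames that fall beyond a trial's real
#' epoch boundary are flagged in the mask (not silently dropped).
#'
#' @param Vt components x frames matrix (e.g. filtered \code{diag(S) Vt})
#' @param trials trial table with the anchor-event columns
#' @param epochSpec epoch definition, see [defaultEpochSpec()]
#' @param frameRate sampling rate of Vt in Hz
#' @param times frame timestamps; default \code{(0:(n-1)) / frameRate}
#' @return an [AlignedTensor-class]
#' @export
alignTrials <- function(Vt, trials, epochSpec = defaultEpochSpec(),
                        frameRate, times = NULL) {
  nFr <- ncol(Vt)
  if (is.null(times)) times <- (seq_len(nFr) - 1) / frameRate
  nWin <- epochWindowFrames(epochSpec$window, frameRate)
  nTot <- sum(nWin)
  nTr <- nrow(trials)
  ends <- c(trials$stimOnset, trials$stimOffset, trials$spoutsIn,
            trials$responseTime)
  endMat <- matrix(ends, nTr, 4)

  dat <- array(NA_real_, dim = c(nTr, nrow(Vt), nTot))
  mask <- matrix(FALSE, nTr, nTot)
  for (i in seq_len(nTr)) {
    off <- 0L
    for (e in seq_len(nrow(epochSpec))) {
      anchor <- trials[[epochSpec$anchor[e]]][i]
      start <- which.min(abs(times - anchor))
      idx <- start:(start + nWin[e] - 1L)
      if (max(idx) > nFr)
        stop("recording does not cover the ", epochSpec$name[e],
             " window of trial ", i)
      dat[i, , off + seq_len(nWin[e])] <- Vt[, idx]
      mask[i, off + seq_len(nWin[e])] <- times[idx] > endMat[i, e]
      off <- off + nWin[e]
    }
  }
  new("AlignedTensor", data = dat, epochSpec = epochSpec,
      frameRate = frameRate, mask = mask)
}
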