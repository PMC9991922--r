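# Trial-based linear encoding model: a design matrix of time-shifted event
# pulses plus analog movement/video regressors, fit to each temporal data
# column by ridge regression whose penalty is chosen per column by
# maximizing the Bayesian marginal likelihood (evidence), then scored by
# contiguous-fold cross-validation and within-trial shuffle unique variance.

#' Time-shifted design block for one event variable
#'
#' One column per lag in \code{-nLagPre .. nLagPost}; the column for lag l
#' carries a unit pulse at frame(event) + l for every event, clipped to the
#' event's trial bounds when given.
#'
#' @param eventFrames integer frame indices of the events
#' @param nLagPre,nLagPost lags before/after the event (frames)
#' @param nFrames total frames in the session
#' @param bounds optional 2-column matrix of per-event first/last admissible
#'   frames (clipping is counted and reported via attribute "clipped")
#' @return nFrames x (nLagPre + nLagPost + 1) binary matrix
#' @export
eventDesignBlock <- function(eventFrames, nLagPre, nLagPost, nFrames,
                             bounds = NULL) {
  lags <- seq(-nLagPre, nLagPost)
  X <- matrix(0, nFrames, length(lags))
  clipped <- 0L
  for (e in seq_along(eventFrames)) {
    f <- eventFrames[e] + lags
    ok <- f >= 1L & f <= nFrames
    if (!is.null(bounds)) {
      okb <- f >= bounds[e, 1] & f <= bounds[e, 2]
      clipped <- clipped + sum(ok & !okb)
      ok <- ok & okb
    }
    X[cbind(f[ok], which(ok))] <- 1
  }
  attr(X, "clipped") <- clipped
  X
}

#' Build the trial design matrix
#'
#' Assembles the encoding model's regressors at the imaging rate. Event
#' variables follow the study's spans: stimulus-onset copies run from onset
#' to the end of the trial, single clicks get a 2 s post-event set, licks a
#' (-1 s, +2 s) set, and whole-trial variables (current and previous choice)
#' span the full trial. Analog movement traces and video components enter
#' as single columns. Spans reaching past trial bounds are clipped.
#'
#' @param trials trial table (see [generateTrials()])
#' @param frameRate imaging rate in Hz (per-channel rate)
#' @param nFrames total frames; defaults to cover the last trial plus 1 s
#' @param movement optional frames x traces matrix (analog regressors)
#' @param video optional frames x components matrix
#' @param spans named list overriding the per-variable (pre, post) spans in
#'   seconds; \code{Inf} post means "until end of trial"
#' @return a [DesignMatrix-class]
#' @export
buildDesignMatrix <- function(trials, frameRate, nFrames = NULL,
                              movement = NULL, video = NULL,
                              spans = list()) {
  defSpans <- list(stimLeft = c(0, Inf), stimRight = c(0, Inf),
                   clickLeft = c(0, 2), clickRight = c(0, 2),
                   handleTouch = c(0, 1),
                   lickLeft = c(1, 2), lickRight = c(1, 2),
                   choice = c(0, Inf), prevChoice = c(0, Inf))
  spans <- utils::modifyList(defSpans, spans)
  if (is.null(nFrames))
    nFrames <- ceiling((max(trials$responseTime) + 1) * frameRate)
  toFrame <- function(t) pmin(nFrames, pmax(1L, round(t * frameRate) + 1L))

  trialStart <- toFrame(trials$initTime)
  trialEnd <- toFrame(trials$responseTime + 0.5)
  trialIndex <- integer(nFrames)
  for (i in seq_len(nrow(trials)))
    trialIndex[trialStart[i]:trialEnd[i]] <- i

  maxTrialFrames <- max(trialEnd - trialStart) + 1L
  lagN <- function(span, anchorToEnd) {
    post <- if (is.infinite(span[2])) maxTrialFrames else round(span[2] * frameRate)
    c(round(span[1] * frameRate), post)
  }

  blocks <- list(); groups <- character(); kinds <- character()
  addEvent <- function(name, times, trialOf) {
    sp <- lagN(spans[[name]])
    bounds <- cbind(trialStart[trialOf], trialEnd[trialOf])
    B <- eventDesignBlock(toFrame(times), sp[1], sp[2], nFrames, bounds)
    if (attr(B, "clipped") > 0)
      message(name, ": ", attr(B, "clipped"), " span frame(s) clipped at trial bounds")
    blocks[[name]] <<- B
    groups <<- c(groups, rep(name, ncol(B)))
    kinds[name] <<- "binary-event"
  }

  left <- trials$rewardedSide == "left"
  addEvent("stimLeft", trials$stimOnset[left], which(left))
  addEvent("stimRight", trials$stimOnset[!left], which(!left))
  addEvent("clickLeft", unlist(trials$clickTimesLeft),
           rep(seq_len(nrow(trials)), lengths(trials$clickTimesLeft)))
  addEvent("clickRight", unlist(trials$clickTimesRight),
           rep(seq_len(nrow(trials)), lengths(trials$clickTimesRight)))
  addEvent("handleTouch", trials$initTime, seq_len(nrow(trials)))
  chL <- trials$choice == "left"
  addEvent("lickLeft", trials$responseTime[chL], which(chL))
  addEvent("lickRight", trials$responseTime[!chL], which(!chL))
  addEvent("choice", trials$initTime[chL], which(chL))
  prevL <- c(FALSE, utils::head(chL, -1))
  addEvent("prevChoice", trials$initTime[prevL], which(prevL))

  if (!is.null(movement)) {
    movement <- as.matrix(movement)
    stopifnot(nrow(movement) == nFrames)
    nm <- colnames(movement)
    if (is.null(nm)) nm <- paste0("movement", seq_len(ncol(movement)))
    for (j in seq_len(ncol(movement))) {
      blocks[[nm[j]]] <- movement[, j, drop = FALSE]
      groups <- c(groups, nm[j])
      kinds[nm[j]] <- "analog"
    }
  }
  if (!is.null(video)) {
    video <- as.matrix(video)
    stopifnot(nrow(video) == nFrames)
    for (j in seq_len(ncol(video))) {
      nm <- paste0("video", j)
      blocks[[nm]] <- video[, j, drop = FALSE]
      groups <- c(groups, nm)
      kinds[nm] <- "video-component"
    }
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0(groups, ".", unlist(lapply(rle(groups)$lengths, seq_len)))
  new("DesignMatrix", X = X, groupIndex = groups, variableKind = kinds,
      trialIndex = trialIndex, frameRate = frameRate)
}

# negative log evidence of the Bayesian ridge model at penalty lam, given
# the economy SVD of the centered design: d singular values, r = Ud' y,
# resid0 = ||y||^2 - ||r||^2, n observations (noise variance profiled out)
.negLogEvidence <- function(lam, d2, r2, resid0, n) {
  quad <- sum(r2 * lam / (lam + d2)) + resid0
  0.5 * (sum(log1p(d2 / lam)) + n * log(quad / n))
}

#' Ridge regression with per-column evidence-optimized penalties
#'
#' Expresses the encoding model as a Bayesian linear model (Gaussian weight
#' prior with variance sigma^2 / lambda) and, for each data column, picks
#' the ridge penalty lambda maximizing the marginal likelihood of the data
#' — a one-dimensional search over log lambda on the economy SVD of the
#' design, replacing penalty cross-validation. Near-collinear design
#' columns are screened out by pivoted QR beforehand.
#'
#' @param design a [DesignMatrix-class] (or plain matrix)
#' @param Y frames x data-columns matrix of temporal components
#' @param lambdaRange search interval for lambda
#' @param qrTol relative pivot threshold for degenerate-column screening
#' @return an [EncodingFit-class]; weights are for centered X and Y
#' @export
fitRidgeMLE <- function(design, Y, lambdaRange = c(1e-6, 1e6),
                        qrTol = 1e-8) {
  X <- if (is(design, "DesignMatrix")) design@X else design
  groups <- if (is(design, "DesignMatrix")) design@groupIndex else
    rep("x", ncol(X))
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), all(is.finite(Y)))
  n <- nrow(X)

  Xc <- scale(X, scale = FALSE)
  qd <- qr(Xc, tol = qrTol)
  dropped <- character(0)
  if (qd$rank < ncol(Xc)) {
    bad <- qd$pivot[(qd$rank + 1L):ncol(Xc)]
    dropped <- colnames(X)[bad]
    warning("dropping ", length(bad), " degenerate design column(s): ",
            paste(utils::head(dropped, 5), collapse = ", "))
    keep <- setdiff(seq_len(ncol(Xc)), bad)
    Xc <- Xc[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  Yc <- scale(Y, scale = FALSE)

  sv <- svd(Xc)
  d2 <- sv$d^2
  R <- crossprod(sv$u, Yc)              # p' x q
  lo <- log(lambdaRange[1]); hi <- log(lambdaRange[2])
  q <- ncol(Yc)
  lambda <- numeric(q); nll <- numeric(q); sig2 <- numeric(q)
  W <- matrix(0, ncol(Xc), q)
  for (j in seq_len(q)) {
    r2 <- R[, j]^2
    resid0 <- max(sum(Yc[, j]^2) - sum(r2), 0)
    opt <- stats::optimize(function(ll) .negLogEvidence(exp(ll), d2, r2, resid0, n),
                           interval = c(lo, hi))
    lam <- exp(opt$minimum)
    lambda[j] <- lam
    nll[j] <- opt$objective
    sig2[j] <- (sum(r2 * lam / (lam + d2)) + resid0) / n
    W[, j] <- sv$v %*% (sv$d / (d2 + lam) * R[, j])
  }
  rownames(W) <- colnames(Xc)
  new("EncodingFit", weights = W, lambda = lambda, logEvidence = -nll,
      noiseVariance = sig2, groupIndex = groups,
      frameRate = if (is(design, "DesignMatrix")) design@frameRate else NA_real_,
      droppedColumns = dropped)
}

# ridge solve for fixed per-column lambda on (already centered) data
.ridgeSolve <- function(Xc, Yc, lambda) {
  sv <- svd(Xc)
  R <- crossprod(sv$u, Yc)
  W <- matrix(0, ncol(Xc), ncol(Yc))
  d2 <- sv$d^2
  for (j in seq_len(ncol(Yc)))
    W[, j] <- sv$v %*% (sv$d / (d2 + lambda[j]) * R[, j])
  W
}

#' Cross-validated explained variance
#'
#' Tenfold cross-validation over contiguous blocks of the recording: model
#' weights are fit to a continuous 90\% section and variance is scored on
#' the held-out 10\%, rotating so every part of the recording is tested
#' once. Per-column penalties default to the evidence-optimized values on
#' the full data.
#'
#' @param design a [DesignMatrix-class] (degenerate columns are screened as
#'   in [fitRidgeMLE()])
#' @param Y frames x data-columns matrix
#' @param folds number of contiguous folds (default 10)
#' @param lambda per-column penalties; NULL runs [fitRidgeMLE()] first
#' @return list: \code{cvR2} per column (1 - SSE/SST pooled over test
#'   segments), \code{residGram} and \code{dataGram} (column-space Gram
#'   matrices for pixel maps, see [cvR2PixelMap()])
#' @export
crossValidatedR2 <- function(design, Y, folds = 10, lambda = NULL) {
  stopifnot(folds >= 2)
  X <- if (is(design, "DesignMatrix")) design@X else design
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(lambda)) {
    fit <- fitRidgeMLE(design, Y)
    lambda <- fit@lambda
    if (length(fit@droppedColumns))
      X <- X[, setdiff(colnames(X), fit@droppedColumns), drop = FALSE]
  }
  breaks <- floor(seq(0, n, length.out = folds + 1))
  resid <- matrix(0, n, ncol(Y))
  for (f in seq_len(folds)) {
    test <- (breaks[f] + 1):breaks[f + 1]
    train <- setdiff(seq_len(n), test)
    mx <- colMeans(X[train, , drop = FALSE])
    my <- colMeans(Y[train, , drop = FALSE])
    Xc <- sweep(X[train, , drop = FALSE], 2, mx)
    Yc <- sweep(Y[train, , drop = FALSE], 2, my)
    W <- .ridgeSolve(Xc, Yc, lambda)
    pred <- sweep(sweep(X[test, , drop = FALSE], 2, mx) %*% W, 2, my, "+")
    resid[test, ] <- Y[test, , drop = FALSE] - pred
  }
  Ycc <- scale(Y, scale = FALSE)
  sse <- colSums(resid^2)
  sst <- colSums(Ycc^2)
  list(cvR2 = 1 - sse / sst,
       residGram = crossprod(resid), dataGram = crossprod(Ycc))
}

#' Pixel map of cross-validated explained variance
#'
#' @param cv result of [crossValidatedR2()] computed on temporal components
#' @param U pixels x components spatial basis of the same session
#' @return per-pixel cvR2 vector
#' @export
cvR2PixelMap <- function(cv, U) {
  ssePix <- rowSums((U %*% cv$residGram) * U)
  sstPix <- rowSums((U %*% cv$dataGram) * U)
  1 - ssePix / pmax(sstPix, .Machine$double.eps)
}

#' Unique explained variance of a variable group
#'
#' Builds a reduced model in which every regressor of the named variable(s)
#' is independently permuted in time within each trial (destroying its
#' information while preserving within-trial statistics), re-scores
#' cross-validated variance with the full model's penalties, and reports
#' deltaR2 = cvR2(full) - cvR2(reduced). Passing several names shuffles
#' them together (group-of-groups).
#'
#' @param design a [DesignMatrix-class]
#' @param Y frames x data-columns matrix
#' @param variableGroup character, variable name(s) from the design's
#'   groupIndex
#' @param folds contiguous folds (default 10)
#' @param lambda per-column penalties; NULL fits them on the full model
#' @param seed shuffle seed (fixed per call for reproducibility)
#' @return list: \code{deltaR2} per data column, \code{cvR2Full},
#'   \code{cvR2Reduced}, \code{zeroEvents} flag
#' @export
uniqueVariance <- function(design, Y, variableGroup, folds = 10,
                           lambda = NULL, seed = 1) {
  stopifnot(is(design, "DesignMatrix"))
  unknown <- setdiff(variableGroup, design@groupIndex)
  if (length(unknown))
    stop("unknown variable group(s): ", paste(unknown, collapse = ", "))
  cols <- which(design@groupIndex %in% variableGroup)
  if (all(design@X[, cols] == 0))
    return(list(deltaR2 = rep(0, ncol(as.matrix(Y))), cvR2Full = NULL,
                cvR2Reduced = NULL, zeroEvents = TRUE))
  if (is.null(lambda)) lambda <- fitRidgeMLE(design, Y)@lambda

  full <- crossValidatedR2(design, Y, folds = folds, lambda = lambda)
  set.seed(seed)
  Xs <- design@X
  for (tr in setdiff(unique(design@trialIndex), 0L)) {
    rows <- which(design@trialIndex == tr)
    for (cc in cols)
      Xs[rows, cc] <- Xs[sample(rows), cc]
  }
  reduced <- design
  reduced@X <- Xs
  red <- crossValidatedR2(reduced, Y, folds = folds, lambda = lambda)
  list(deltaR2 = full$cvR2 - red$cvR2, cvR2Full = full$cvR2,
       cvR2Reduced = red$cvR2, zeroEvents = FALSE)
}

#' Reconstruct spatiotemporal event kernels in pixel space
#'
#' Maps a variable's block of time-shifted weights through the spatial
#' basis U, giving a lags x pixels kernel; optionally averages over a time
#' window (e.g. 0-200 ms after the event) and forms contra-minus-ipsi
#' difference maps.
#'
#' @param fit an [EncodingFit-class] computed on temporal components
#' @param U pixels x components spatial basis of the same session
#' @param variable variable name from the fit's groupIndex
#' @param window optional c(from, to) in seconds relative to the block's
#'   first lag; the kernel is averaged over it (default 0-0.2 s)
#' @return list: \code{kernel} (lags x pixels), \code{lagTimes},
#'   \code{windowMap} (per-pixel average over \code{window})
#' @export
reconstructKernels <- function(fit, U, variable, window = c(0, 0.2)) {
  if (ncol(fit@weights) != ncol(U))
    stop("component count mismatch between fit and U")
  idx <- which(fit@groupIndex == variable)
  if (!length(idx)) stop("variable '", variable, "' not in the fit")
  K <- fit@weights[idx, , drop = FALSE] %*% t(U)   # lags x pixels
  lagTimes <- (seq_along(idx) - 1) / fit@frameRate
  win <- which(lagTimes >= window[1] & lagTimes <= window[2])
  list(kernel = K, lagTimes = lagTimes,
       windowMap = colMeans(K[win, , drop = FALSE]))
}

#' Contra-minus-ipsi stimulus map
#'
#' @param fit,U as in [reconstructKernels()]
#' @param contraVariable,ipsiVariable variable names for the two sides
#' @param window averaging window in seconds
#' @return per-pixel difference map (contra minus ipsi)
#' @export
sideDifferenceMap <- function(fit, U, contraVariable, ipsiVariable,
                              window = c(0, 0.2)) {
  reconstructKernels(fit, U, contraVariable, window)$windowMap -
    reconstructKernels(fit, U, ipsiVariable, window)$windowMap
}
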