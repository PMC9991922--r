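#' @import methods
NULL

#' Task configuration for the auditory discrimination session
#'
#' Holds the behavioral parameters of the delayed spatial click-rate
#' discrimination task: a trial is initiated by continuous handle contact for
#' a variable hold period, followed by bilateral Poisson click trains of
#' variable duration, a variable delay, and a lick response once the spouts
#' move in. Choices are drawn from a four-parameter psychometric rule applied
#' to the signed click-count difference.
#'
#' @slot frameRate camera frame rate in Hz (illumination alternates between
#'   blue and violet, so each channel runs at half this rate)
#' @slot handleHoldRange min/max handle-hold duration in seconds
#' @slot stimDurationRange min/max stimulus duration in seconds
#' @slot delayMax maximum post-stimulus delay in seconds (uniform on 0..max)
#' @slot clickRateLeft,clickRateRight Poisson click rates (Hz) per speaker
#' @slot clickWidth click duration in seconds (events are modeled as times)
#' @slot nTrials number of trials in a session
#' @slot psychometric named numeric: bias, slope, lapseLow, lapseHigh
#' @export
setClass("TaskConfig", representation(
  frameRate = "numeric",
  handleHoldRange = "numeric",
  stimDurationRange = "numeric",
  delayMax = "numeric",
  clickRateLeft = "numeric",
  clickRateRight = "numeric",
  clickWidth = "numeric",
  nTrials = "integer",
  psychometric = "numeric"
))

setValidity("TaskConfig", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(object@handleHoldRange) != 2 ||
      any(object@handleHoldRange <= 0) ||
      diff(object@handleHoldRange) < 0)
    msg <- c(msg, "handleHoldRange must be an ordered positive pair")
  if (length(object@stimDurationRange) != 2 ||
      any(object@stimDurationRange <= 0) ||
      diff(object@stimDurationRange) < 0)
    msg <- c(msg, "stimDurationRange must be an ordered positive pair")
  if (object@delayMax < 0) msg <- c(msg, "delayMax must be non-negative")
  if (object@clickRateLeft < 0 || object@clickRateRight < 0)
    msg <- c(msg, "click rates must be non-negative")
  if (object@clickRateLeft == 0 && object@clickRateRight == 0)
    msg <- c(msg, "at least one click rate must be positive (rewarded side undefined otherwise)")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be at least 1")
  ps <- object@psychometric
  if (length(ps) != 4 || !all(c("bias", "slope", "lapseLow", "lapseHigh") %in% names(ps)))
    msg <- c(msg, "psychometric must be named (bias, slope, lapseLow, lapseHigh)")
  else if (any(ps[c("lapseLow", "lapseHigh")] < 0) ||
           any(ps[c("lapseLow", "lapseHigh")] >= 0.5))
    msg <- c(msg, "lapse rates must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct a TaskConfig
#'
#' Defaults reproduce the study task: 30 fps camera with alternating
#' illumination, handle hold 0.25-0.75 s, stimulus 1-1.5 s, delay up to 1 s,
#' 3-ms Poisson clicks.
#'
#' @param frameRate camera rate in Hz
#' @param handleHoldRange,stimDurationRange ordered pairs in seconds
#' @param delayMax maximum delay in seconds
#' @param clickRateLeft,clickRateRight Poisson click rates in Hz
#' @param clickWidth click duration in seconds
#' @param nTrials trials per session
#' @param psychometric named numeric (bias, slope, lapseLow, lapseHigh)
#' @return a \code{TaskConfig}
#' @examples
#' cfg <- taskConfig(nTrials = 50)
#' @export
taskConfig <- function(frameRate = 30,
                       handleHoldRange = c(0.25, 0.75),
                       stimDurationRange = c(1, 1.5),
                       delayMax = 1,
                       clickRateLeft = 20,
                       clickRateRight = 20,
                       clickWidth = 0.003,
                       nTrials = 200,
                       psychometric = c(bias = 0, slope = 0.3,
                                        lapseLow = 0.05, lapseHigh = 0.05)) {
  new("TaskConfig", frameRate = frameRate,
      handleHoldRange = handleHoldRange,
      stimDurationRange = stimDurationRange,
      delayMax = delayMax, clickRateLeft = clickRateLeft,
      clickRateRight = clickRateRight, clickWidth = clickWidth,
      nTrials = as.integer(nTrials), psychometric = psychometric)
}

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig:", object@nTrials, "trials at", object@frameRate, "fps\n")
  cat("  handle hold", paste(object@handleHoldRange, collapse = "-"),
      "s; stimulus", paste(object@stimDurationRange, collapse = "-"),
      "s; delay <=", object@delayMax, "s\n")
  cat("  click rates L/R:", object@clickRateLeft, "/",
      object@clickRateRight, "Hz\n")
})

#' Ground truth of a synthetic widefield session
#'
#' Stores everything the generator used so recovery can be scored:
#' nonnegative spatial sources, their per-frame loadings (at the blue-channel
#' rate), the event kernels that drove them, and the hemodynamic artifact in
#' factored form (one spatial profile, one temporal trace at the camera rate,
#' and a per-pixel violet gain).
#'
#' @slot spatialComponents pixels x sources, nonnegative
#' @slot temporalLoadings sources x blue frames
#' @slot eventKernels list of per-event-type kernels (source x lag weights)
#' @slot hemoSpatial per-pixel artifact profile
#' @slot hemoTemporal per-camera-frame artifact trace
#' @slot hemoGain per-pixel violet-channel gain on the shared artifact
#' @slot noiseSd additive noise standard deviation (fraction of baseline)
#' @slot dims image dimensions (rows, cols)
#' @export
setClass("GroundTruth", representation(
  spatialComponents = "matrix",
  temporalLoadings = "matrix",
  eventKernels = "list",
  hemoSpatial = "numeric",
  hemoTemporal = "numeric",
  hemoGain = "numeric",
  noiseSd = "numeric",
  dims = "integer"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(object@spatialComponents < 0))
    msg <- c(msg, "spatial components must be nonnegative")
  if (nrow(object@spatialComponents) != prod(object@dims))
    msg <- c(msg, "spatialComponents rows must equal prod(dims)")
  if (ncol(object@spatialComponents) != nrow(object@temporalLoadings))
    msg <- c(msg, "source count mismatch between spatial and temporal parts")
  if (length(msg)) msg else TRUE
})

#' Raw interleaved two-wavelength session
#'
#' Frames are stored flattened as a pixels x frames matrix per channel, with
#' frame timestamps. Blue frames carry calcium + hemodynamic signal; violet
#' frames carry (calcium-independent) hemodynamic signal only.
#'
#' @slot blue,violet pixels x frames matrices of raw fluorescence
#' @slot blueTimes,violetTimes frame timestamps in seconds
#' @slot dims image dimensions (rows, cols)
#' @slot frameRate full camera rate in Hz
#' @slot trials trial event table (see [generateTrials()])
#' @slot movement frames x traces matrix of analog movement measures
#' @slot video frames x components matrix of latent video features
#' @export
setClass("RawSession", representation(
  blue = "matrix", violet = "matrix",
  blueTimes = "numeric", violetTimes = "numeric",
  dims = "integer", frameRate = "numeric",
  trials = "data.frame",
  movement = "matrix", video = "matrix"
))

setValidity("RawSession", function(object) {
  msg <- character()
  if (ncol(object@blue) != length(object@blueTimes))
    msg <- c(msg, "blue frame count must match blueTimes")
  if (ncol(object@violet) != length(object@violetTimes))
    msg <- c(msg, "violet frame count must match violetTimes")
  if (abs(ncol(object@blue) - ncol(object@violet)) > 1)
    msg <- c(msg, "channel lengths differ by more than one frame")
  if (nrow(object@blue) != prod(object@dims))
    msg <- c(msg, "pixel count must equal prod(dims)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RawSession", function(object) {
  cat("RawSession:", object@dims[1], "x", object@dims[2], "px,",
      ncol(object@blue), "blue +", ncol(object@violet), "violet frames at",
      object@frameRate, "fps camera rate;",
      nrow(object@trials), "trials\n")
})

#' SVD-compressed movie
#'
#' Truncated decomposition Y ~ U diag(S) Vt. Time-domain analyses operate on
#' diag(S) Vt; pixel-space results are recovered by left-multiplying U.
#'
#' @slot U pixels x components orthonormal spatial basis
#' @slot S singular values, non-increasing
#' @slot Vt components x frames temporal matrix (rows orthonormal at creation)
#' @slot frameRate temporal sampling rate of the columns of Vt, in Hz
#' @slot pixelSize pixel edge length in mm
#' @slot dims image dimensions
#' @slot varianceExplained fraction of total variance retained at creation
#' @export
setClass("CompressedStack", representation(
  U = "matrix", S = "numeric", Vt = "matrix",
  frameRate = "numeric", pixelSize = "numeric",
  dims = "integer", varianceExplained = "numeric"
))

setValidity("CompressedStack", function(object) {
  msg <- character()
  k <- ncol(object@U)
  if (length(object@S) != k || nrow(object@Vt) != k)
    msg <- c(msg, "component count mismatch between U, S and Vt")
  if (k > 0) {
    g <- crossprod(object@U)
    if (max(abs(g - diag(k))) > 1e-6)
      msg <- c(msg, "columns of U must be orthonormal (tol 1e-6)")
    if (any(diff(object@S) > 1e-8 * max(object@S)))
      msg <- c(msg, "singular values must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CompressedStack", function(object) {
  cat("CompressedStack:", nrow(object@U), "px x", ncol(object@Vt),
      "frames in", ncol(object@U), "components (",
      sprintf("%.2f%%", 100 * object@varianceExplained),
      "variance) at", object@frameRate, "fps\n")
})

#' @describeIn CompressedStack-class spatial basis U
#' @param object a CompressedStack
#' @export
setGeneric("spatialBasis", function(object) standardGeneric("spatialBasis"))
#' @export
setMethod("spatialBasis", "CompressedStack", function(object) object@U)

#' @describeIn CompressedStack-class singular values
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @export
setMethod("singularValues", "CompressedStack", function(object) object@S)

#' Temporal components of a container
#' @param object a CompressedStack (returns diag(S) Vt) or ComponentSet
#'   (returns C)
#' @export
setGeneric("temporalComponents", function(object) standardGeneric("temporalComponents"))
#' @export
setMethod("temporalComponents", "CompressedStack",
          function(object) object@S * object@Vt)

#' Trial-aligned tensor of temporal components
#'
#' Variable-duration trials re-sliced into fixed epoch windows anchored at
#' handle touch, stimulus onset, stimulus offset and spouts-in. Frames drawn
#' past a trial's real epoch boundary are flagged in \code{mask}.
#'
#' @slot data trials x components x frames array
#' @slot epochSpec data.frame with columns name, anchor, window (seconds)
#' @slot frameRate sampling rate of the frame axis, Hz
#' @slot mask trials x frames logical, TRUE where a frame spilled past the
#'   real epoch boundary of that trial
#' @export
setClass("AlignedTensor", representation(
  data = "array", epochSpec = "data.frame",
  frameRate = "numeric", mask = "matrix"
))

# partition epoch windows (seconds) into integer frame counts that sum to
# round(total * rate): floor plus largest-remainder distribution, with an
# epsilon guard against floating-point rate noise
epochWindowFrames <- function(windows, rate) {
  raw <- windows * rate
  nTot <- round(sum(raw) + 1e-6)
  n <- floor(raw + 1e-6)
  rem <- raw - n
  extra <- nTot - sum(n)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    n[give] <- n[give] + 1L
  }
  as.integer(n)
}

setValidity("AlignedTensor", function(object) {
  msg <- character()
  nf <- dim(object@data)[3]
  expect <- sum(epochWindowFrames(object@epochSpec$window, object@frameRate))
  if (nf != expect)
    msg <- c(msg, sprintf("frame axis (%d) must equal the %d frames implied by the epoch windows",
                          nf, expect))
  if (!identical(dim(object@mask), dim(object@data)[c(1, 3)]))
    msg <- c(msg, "mask must be trials x frames")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignedTensor", function(object) {
  d <- dim(object@data)
  cat("AlignedTensor:", d[1], "trials x", d[2], "components x", d[3],
      "frames (", sum(object@epochSpec$window), "s );",
      "epochs:", paste(object@epochSpec$name, collapse = "/"), "\n")
})

#' Epoch frame index ranges of an AlignedTensor
#' @param object an AlignedTensor
#' @return named list of integer frame-index vectors, one per epoch
#' @export
setGeneric("epochFrames", function(object) standardGeneric("epochFrames"))
#' @export
setMethod("epochFrames", "AlignedTensor", function(object) {
  n <- epochWindowFrames(object@epochSpec$window, object@frameRate)
  ends <- cumsum(n)
  starts <- c(1, head(ends, -1) + 1)
  out <- mapply(seq, starts, ends, SIMPLIFY = FALSE)
  names(out) <- object@epochSpec$name
  out
})

#' Region atlas as a label image
#'
#' Simplified stand-in for a reference atlas: every in-brain pixel carries
#' exactly one region id; id 0 marks out-of-brain pixels.
#'
#' @slot labels integer matrix of region ids over the pixel grid
#' @slot regionNames character vector named by region id
#' @export
setClass("RegionMap", representation(
  labels = "matrix", regionNames = "character"
))

setValidity("RegionMap", function(object) {
  ids <- setdiff(sort(unique(as.vector(object@labels))), 0L)
  if (!all(as.character(ids) %in% names(object@regionNames)))
    "every nonzero label must have an entry in regionNames" else TRUE
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap:", nrow(object@labels), "x", ncol(object@labels), "px,",
      length(object@regionNames), "regions\n")
})

#' Nonnegative spatial / unconstrained temporal component set
#'
#' Result of semi-NMF or region-localized NMF: Y ~ A C with A >= 0
#' elementwise and C free in sign (hemodynamic-corrected data are signed).
#'
#' @slot A pixels x k nonnegative spatial components
#' @slot C k x frames temporal components
#' @slot regionId per-component region id ("global" for plain semi-NMF)
#' @slot varianceExplained fraction of (SVD-reconstructed) variance captured
#' @slot typeLabel cell-type label of the session (may be NA)
#' @slot dims image dimensions
#' @slot converged FALSE when the iteration budget was exhausted
#' @export
setClass("ComponentSet", representation(
  A = "matrix", C = "matrix", regionId = "character",
  varianceExplained = "numeric", typeLabel = "character",
  dims = "integer", converged = "logical"
))

setValidity("ComponentSet", function(object) {
  msg <- character()
  if (any(object@A < 0)) msg <- c(msg, "A must be nonnegative")
  if (ncol(object@A) != nrow(object@C))
    msg <- c(msg, "A and C component counts must match")
  if (length(object@regionId) != ncol(object@A))
    msg <- c(msg, "regionId must have one entry per component")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComponentSet", function(object) {
  cat("ComponentSet:", ncol(object@A), "components over", nrow(object@A),
      "px (", sprintf("%.2f%%", 100 * object@varianceExplained),
      "variance );",
      if (all(object@regionId == "global")) "global" else "localized", "\n")
})

#' @describeIn ComponentSet-class spatial components A
#' @param object a ComponentSet
#' @export
setGeneric("spatialComponents", function(object) standardGeneric("spatialComponents"))
#' @export
setMethod("spatialComponents", "ComponentSet", function(object) object@A)
#' @export
setMethod("temporalComponents", "ComponentSet", function(object) object@C)

#' Variance explained accessor
#' @param object a CompressedStack or ComponentSet
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))
#' @export
setMethod("varianceExplained", "ComponentSet", function(object) object@varianceExplained)
#' @export
setMethod("varianceExplained", "CompressedStack", function(object) object@varianceExplained)

#' Trial design matrix for the linear encoding model
#'
#' Event variables occupy contiguous blocks of time-shifted copies of a unit
#' pulse; analog variables enter as single columns.
#'
#' @slot X frames x regressors matrix
#' @slot groupIndex character, variable name per column
#' @slot variableKind named character, one of binary-event, analog,
#'   video-component, per variable
#' @slot trialIndex integer trial id per frame (row)
#' @slot frameRate sampling rate in Hz
#' @export
setClass("DesignMatrix", representation(
  X = "matrix", groupIndex = "character", variableKind = "character",
  trialIndex = "integer", frameRate = "numeric"
))

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (length(object@groupIndex) != ncol(object@X))
    msg <- c(msg, "groupIndex must label every column")
  if (length(object@trialIndex) != nrow(object@X))
    msg <- c(msg, "trialIndex must label every row")
  binvars <- names(object@variableKind)[object@variableKind == "binary-event"]
  if (length(binvars)) {
    bincols <- object@X[, object@groupIndex %in% binvars, drop = FALSE]
    if (!all(bincols %in% c(0, 1)))
      msg <- c(msg, "binary-event regressors must be 0/1")
    # each event variable must occupy one contiguous column block
    for (v in binvars) {
      idx <- which(object@groupIndex == v)
      if (length(idx) && any(diff(idx) != 1L))
        msg <- c(msg, sprintf("columns of variable '%s' are not contiguous", v))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "frames x", ncol(object@X),
      "regressors in", length(unique(object@groupIndex)), "variables\n")
})

#' Ridge encoding-model fit with per-column evidence-optimized penalties
#'
#' @slot weights regressors x data-columns
#' @slot lambda per data-column ridge penalty (maximizer of the marginal
#'   likelihood)
#' @slot logEvidence per-column maximized log marginal likelihood
#' @slot noiseVariance per-column profile estimate of the observation noise
#' @slot groupIndex copy of the design's per-column variable labels
#' @slot frameRate sampling rate in Hz
#' @slot droppedColumns names of design columns removed as degenerate
#' @export
setClass("EncodingFit", representation(
  weights = "matrix", lambda = "numeric", logEvidence = "numeric",
  noiseVariance = "numeric", groupIndex = "character",
  frameRate = "numeric", droppedColumns = "character"
))

setValidity("EncodingFit", function(object) {
  msg <- character()
  if (any(object@lambda <= 0)) msg <- c(msg, "lambda must be positive")
  if (length(object@lambda) != ncol(object@weights))
    msg <- c(msg, "one lambda per data column required")
  if (nrow(object@weights) != length(object@groupIndex))
    msg <- c(msg, "groupIndex must label every weight row")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EncodingFit", function(object) {
  cat("EncodingFit:", nrow(object@weights), "regressors x",
      ncol(object@weights), "data columns; median lambda",
      sprintf("%.3g", stats::median(object@lambda)), "\n")
})
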