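# Per-timepoint choice decoding: balanced trials, L1-penalized logistic
# regression on the temporal components at each aligned frame, and pixel
# maps of the decoder weights through the spatial basis.

#' Balance trials across choice x correctness cells
#'
#' Randomly removes trials until the four (choice, correct) cells have equal
#' counts, so the decoder cannot exploit side bias or reward contingency.
#'
#' @param trials trial table with \code{choice} and \code{correct} columns
#' @param seed integer seed (deterministic subset under a fixed seed)
#' @return sorted integer vector of retained trial indices
#' @export
balanceTrials <- function(trials, seed = 1) {
  cell <- interaction(trials$choice, trials$correct, drop = FALSE)
  lev <- c("left.FALSE", "left.TRUE", "right.FALSE", "right.TRUE")
  counts <- table(factor(cell, levels = lev))
  if (any(counts == 0))
    stop("empty balance cell(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  m <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(lev, function(l) {
    ix <- which(cell == l)
    if (length(ix) > m) sample(ix, m) else ix
  }))
  sort(keep)
}

# stratified fold assignment over the four balance cells
.stratifiedFolds <- function(choices, correct, folds, seed) {
  cell <- interaction(choices, correct, drop = TRUE)
  fold <- integer(length(choices))
  set.seed(seed)
  for (l in levels(cell)) {
    ix <- sample(which(cell == l))
    fold[ix] <- rep_len(seq_len(folds), length(ix))
  }
  fold
}

#' L1 logistic choice decoder at one timepoint
#'
#' Logistic regression with an L1 penalty on the component activity at
#' aligned frame \code{t}, cross-validated over folds stratified by the
#' four (choice, correctness) cells. The penalty strength is the inverse of
#' the number of observations in the test set (the reciprocal convention is
#' available via \code{penaltyMode}). Accuracy pools the held-out
#' predictions of all folds; the reported weights are the mean over fold
#' models.
#'
#' @param aligned an [AlignedTensor-class] restricted to balanced trials
#'   (or any trials x components x frames array)
#' @param choices per-trial choice, "left"/"right"
#' @param t frame index within the aligned trial
#' @param folds cross-validation folds (default 10)
#' @param seed integer seed for fold assignment
#' @param correct per-trial correctness for stratification; default all TRUE
#' @param penaltyMode "strength" sets the L1 penalty to 1/nTest (default);
#'   "inverse" uses nTest
#' @param penalty explicit L1 penalty, overriding \code{penaltyMode}
#' @return list: \code{beta} (per-component weights, fold average),
#'   \code{intercept}, \code{accuracy} (pooled cross-validated),
#'   \code{predictions}, \code{penalty}
#' @export
fitDecoderTimepoint <- function(aligned, choices, t, folds = 10, seed = 1,
                                correct = NULL,
                                penaltyMode = c("strength", "inverse"),
                                penalty = NULL) {
  penaltyMode <- match.arg(penaltyMode)
  dat <- if (is(aligned, "AlignedTensor")) aligned@data else aligned
  stopifnot(t >= 1, t <= dim(dat)[3])
  x <- dat[, , t]
  y <- factor(choices, levels = c("left", "right"))
  stopifnot(nrow(x) == length(y))
  if (is.null(correct)) correct <- rep(TRUE, length(y))
  fold <- .stratifiedFolds(y, correct, folds, seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
    warning("single-class fold after stratification; results may be unstable")
  nTest <- length(y) / folds
  lam <- if (!is.null(penalty)) penalty else
    if (penaltyMode == "strength") 1 / nTest else nTest

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  betas <- matrix(0, ncol(x), folds)
  icpt <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, lambda = lam, standardize = FALSE)
    betas[, f] <- as.numeric(fit$beta)
    icpt[f] <- as.numeric(fit$a0)
    p <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response")
    pred[!tr] <- ifelse(p > 0.5, "right", "left")
  }
  list(beta = rowMeans(betas), intercept = mean(icpt),
       accuracy = mean(pred == y), predictions = pred, penalty = lam)
}

#' Decode choice at every aligned timepoint
#'
#' Runs [fitDecoderTimepoint()] across the frame axis of an aligned tensor.
#'
#' @inheritParams fitDecoderTimepoint
#' @return list: \code{beta} (components x frames), \code{accuracy}
#'   (per frame), \code{penalty}
#' @export
decodeChoiceTimecourse <- function(aligned, choices, folds = 10, seed = 1,
                                   correct = NULL,
                                   penaltyMode = c("strength", "inverse")) {
  dat <- if (is(aligned, "AlignedTensor")) aligned@data else aligned
  nT <- dim(dat)[3]
  beta <- matrix(0, dim(dat)[2], nT)
  accuracy <- numeric(nT)
  for (t in seq_len(nT)) {
    r <- fitDecoderTimepoint(aligned, choices, t, folds = folds,
                             seed = seed, correct = correct,
                             penaltyMode = penaltyMode)
    beta[, t] <- r$beta
    accuracy[t] <- r$accuracy
  }
  list(beta = beta, accuracy = accuracy, penalty = r$penalty)
}

#' Cortical maps of decoder weights
#'
#' Convolves per-timepoint decoder weights with the spatial basis U to give
#' pixel maps, epoch-averaged maps, and (optionally) per-region traces with
#' the initiate-epoch baseline subtracted.
#'
#' @param betaTimecourse components x frames decoder weights
#' @param U pixels x components spatial basis
#' @param epochSpec epoch definition (see [defaultEpochSpec()])
#' @param frameRate frame rate of the aligned axis, Hz
#' @param regionMap optional [RegionMap-class] for region traces
#' @param baselineEpoch epoch whose mean is subtracted from region traces
#' @return list: \code{maps} (pixels x frames), \code{epochMeans} (pixels x
#'   epochs), \code{regionTraces} (regions x frames, baseline-corrected, or
#'   NULL)
#' @export
decoderMaps <- function(betaTimecourse, U, epochSpec = defaultEpochSpec(),
                        frameRate, regionMap = NULL,
                        baselineEpoch = "initiate") {
  if (nrow(betaTimecourse) != ncol(U))
    stop("component count mismatch between beta and U")
  maps <- U %*% betaTimecourse
  nWin <- epochWindowFrames(epochSpec$window, frameRate)
  ends <- cumsum(nWin); starts <- c(1, utils::head(ends, -1) + 1)
  epochMeans <- sapply(seq_len(nrow(epochSpec)), function(e)
    rowMeans(maps[, starts[e]:ends[e], drop = FALSE]))
  colnames(epochMeans) <- epochSpec$name
  regionTraces <- NULL
  if (!is.null(regionMap)) {
    labels <- as.vector(regionMap@labels)
    ids <- setdiff(sort(unique(labels)), 0L)
    regionTraces <- t(sapply(ids, function(r)
      colMeans(maps[labels == r, , drop = FALSE])))
    rownames(regionTraces) <- regionMap@regionNames[as.character(ids)]
    b <- which(epochSpec$name == baselineEpoch)
    base <- rowMeans(regionTraces[, starts[b]:ends[b], drop = FALSE])
    regionTraces <- regionTraces - base
  }
  list(maps = maps, epochMeans = epochMeans, regionTraces = regionTraces)
}
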