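# Semi-nonnegative and region-localized matrix factorization of compressed
# sessions. All arithmetic stays in the SVD-compressed space: with
# Y = U M (M = diag(S) Vt, U orthonormal), every quantity of the alternating
# minimization of ||Y - A C||^2 can be computed from M, U'A and small k x k
# Gram matrices, so the full movie is never reconstructed.

.posPart <- function(x) (abs(x) + x) / 2
.negPart <- function(x) (abs(x) - x) / 2

# one alternating semi-NMF run at fixed rank; A >= 0, C unconstrained.
# U: pixels x r spatial basis, M: r x frames. Start from spatial init A0 or
# temporal init C0 (one of the two). regionMask: optional pixels x k logical
# (TRUE = in-region) enforcing the localization threshold after every A
# update.
.semiNMFcore <- function(U, M, A0 = NULL, C0 = NULL, tol = 1e-6,
                         maxIter = 500, regionMask = NULL,
                         locThreshold = 0.5) {
  k <- if (!is.null(A0)) ncol(A0) else nrow(C0)
  A <- if (!is.null(A0)) A0 else matrix(0, nrow(U), k)
  normM2 <- sum(M^2)
  lossOld <- Inf
  converged <- FALSE
  # solve the nonnegative least-squares subproblem for A (C fixed) by
  # cyclic coordinate descent over components (HALS), iterated to
  # convergence — a single pass would act like marginal regression and mix
  # correlated components
  halsA <- function(A, C, passes = 50, ptol = 1e-4) {
    CCt <- tcrossprod(C)
    YCt <- U %*% tcrossprod(M, C)
    for (p in seq_len(passes)) {
      delta <- 0
      for (j in seq_len(k)) {
        denom <- CCt[j, j]
        if (denom <= .Machine$double.eps) next
        aj <- pmax((YCt[, j] - A %*% CCt[, j] + A[, j] * denom) / denom, 0)
        delta <- max(delta, max(abs(aj - A[, j])))
        A[, j] <- aj
      }
      if (delta <= ptol * max(A, .Machine$double.eps)) break
    }
    A
  }
  if (!is.null(C0)) A <- halsA(A, C0)
  for (it in seq_len(maxIter)) {
    # C update: unconstrained least squares
    AtA <- crossprod(A)
    AtU <- crossprod(A, U)
    C <- solve(AtA + diag(1e-10 * max(diag(AtA)), k), AtU %*% M)

    # A update: HALS, exact nonnegative coordinate descent per component
    A <- halsA(A, C)

    if (!is.null(regionMask)) {
      for (j in seq_len(k)) {
        inM <- sum(A[regionMask[, j], j])
        outM <- sum(A[!regionMask[, j], j])
        if (inM + outM > 0 && inM / (inM + outM) < locThreshold) {
          f <- inM * (1 - locThreshold) / (locThreshold * max(outM, .Machine$double.eps))
          A[!regionMask[, j], j] <- A[!regionMask[, j], j] * f
        }
      }
    }

    # loss ||Y - AC||^2 in compressed space
    AtA <- crossprod(A)
    AtU <- crossprod(A, U)
    loss <- normM2 - 2 * sum((AtU %*% M) * C) + sum(AtA * tcrossprod(C))
    if (is.finite(lossOld) &&
        abs(lossOld - loss) <= tol * max(lossOld, .Machine$double.eps)) {
      converged <- TRUE
      lossOld <- loss
      break
    }
    lossOld <- loss
  }
  # final C re-fit at the final (localized) A
  AtA <- crossprod(A)
  C <- solve(AtA + diag(1e-10 * max(diag(AtA), 1e-300), k),
             crossprod(A, U) %*% M)
  loss <- normM2 - 2 * sum((crossprod(A, U) %*% M) * C) +
    sum(crossprod(A) * tcrossprod(C))
  list(A = A, C = C, loss = max(loss, 0), converged = converged)
}

# successive-projection (anchor pixel) initialization: picks k pixels whose
# time courses are maximally independent — for spatially compact sources
# every source has near-pure pixels, so its anchors seed an unmixed
# solution. Returns the k x frames temporal seed C0.
.spaInit <- function(U, M, k) {
  G <- tcrossprod(M)
  R <- chol(G + diag(1e-12 * max(diag(G)), nrow(G)))
  B <- U %*% t(R)                      # pixel rows in Euclidean coords
  anchors <- integer(k)
  for (j in seq_len(k)) {
    nrm <- rowSums(B^2)
    anchors[j] <- which.max(nrm)
    b <- B[anchors[j], ]
    B <- B - (B %*% b) %*% rbind(b) / sum(b^2)
  }
  U[anchors, , drop = FALSE] %*% M
}

# total mean-removed sum of squares of Y = U M, computed in compressed space
.compressedSST <- function(M) {
  sum(sweep(M, 1, rowMeans(M))^2)
}

.varExp <- function(loss, sst) 1 - loss / sst

#' Semi-nonnegative matrix factorization with variance-criterion rank
#' selection
#'
#' Factorizes the SVD-reconstructed session movie as Y ~ A C with
#' nonnegative spatial components A and unconstrained temporal components C
#' (hemodynamic-corrected data are signed). The number of components is the
#' smallest k whose factorization explains at least \code{varianceTarget}
#' (99\% by default) of the movie's variance, assessed against the SVD
#' reconstruction.
#'
#' @param stack a [CompressedStack-class]
#' @param varianceTarget fraction of variance the factorization must explain
#'   (ignored when \code{k} is given)
#' @param seed integer seed (initialization is deterministic given the stack
#'   and seed)
#' @param k fixed component count; NULL (default) selects k by the variance
#'   criterion via [rankForVariance()]
#' @param tol relative loss-change convergence tolerance
#' @param maxIter iteration cap; non-convergence returns the best iterate
#'   with a warning and \code{converged = FALSE}
#' @return a [ComponentSet-class]
#' @export
semiNMF <- function(stack, varianceTarget = 0.99, seed = 1, k = NULL,
                    tol = 1e-6, maxIter = 500) {
  validObject(stack)
  if (is.null(k))
    return(rankForVariance(stack, factorizer = .semiNMFk,
                           varianceTarget = varianceTarget, seed = seed,
                           tol = tol, maxIter = maxIter)$fit)
  .semiNMFk(stack, k, seed, tol = tol, maxIter = maxIter)
}

# fixed-rank semi-NMF on a stack
.semiNMFk <- function(stack, k, seed = 1, tol = 1e-6, maxIter = 500) {
  set.seed(seed)
  U <- stack@U
  M <- stack@S * stack@Vt
  fit <- .semiNMFcore(U, M, C0 = .spaInit(U, M, k), tol = tol,
                      maxIter = maxIter)
  if (!fit$converged)
    warning("semi-NMF did not converge within ", maxIter,
            " iterations; returning best iterate")
  # note: initialize(new(...), ...) rather than new(..., C = ...): an
  # argument named "C" would partially match new()'s Class parameter
  initialize(new("ComponentSet"), A = fit$A, C = fit$C,
             regionId = rep("global", k),
             varianceExplained = .varExp(fit$loss, .compressedSST(M)),
             typeLabel = NA_character_, dims = stack@dims,
             converged = fit$converged)
}

#' Smallest rank meeting a variance target
#'
#' Incremental search from below: fits the factorizer at k = 1, 2, ... and
#' returns the first k whose component set explains at least the target
#' fraction of the (SVD-reconstructed) variance.
#'
#' @param stack a [CompressedStack-class]
#' @param factorizer function(stack, k, seed, ...) returning a ComponentSet
#' @param varianceTarget target fraction in (0, 1)
#' @param seed integer seed forwarded to the factorizer
#' @param kMax largest admissible rank (defaults to the stack's component
#'   count); an unreachable target raises an error
#' @param ... forwarded to the factorizer
#' @return list with \code{k} and \code{fit} (the ComponentSet at k)
#' @export
rankForVariance <- function(stack, factorizer = .semiNMFk,
                            varianceTarget = 0.99, seed = 1,
                            kMax = NULL, ...) {
  stopifnot(varianceTarget > 0, varianceTarget < 1)
  if (is.null(kMax)) kMax <- min(nrow(stack@U), ncol(stack@Vt), ncol(stack@U))
  for (k in seq_len(kMax)) {
    fit <- factorizer(stack, k, seed, ...)
    if (varianceExplained(fit) >= varianceTarget)
      return(list(k = k, fit = fit))
  }
  stop("variance target ", varianceTarget, " unreachable at k = ", kMax)
}

#' Region-localized semi-NMF
#'
#' Semi-NMF whose spatial components are each tied to a seed region of a
#' label-image atlas: after every update, any component carrying less than
#' \code{localizationThreshold} of its mass inside its region has its
#' out-of-region mass shrunk back to the threshold. Components are added
#' region by region (largest in-region residual first) until the variance
#' target is met.
#'
#' @param stack a [CompressedStack-class]
#' @param regionMap a [RegionMap-class] covering the stack's pixel grid
#' @param localizationThreshold minimum in-region mass fraction (default 0.5)
#' @param varianceTarget stop adding components once this fraction of the
#'   SVD-reconstructed variance is explained
#' @param seed integer seed
#' @param tol,maxIter convergence controls, as in [semiNMF()]
#' @param kMax cap on the total component count
#' @return a [ComponentSet-class] with per-component \code{regionId}
#' @export
locaNMF <- function(stack, regionMap, localizationThreshold = 0.5,
                    varianceTarget = 0.99, seed = 1,
                    tol = 1e-6, maxIter = 500, kMax = NULL) {
  validObject(stack); validObject(regionMap)
  if (!identical(dim(regionMap@labels), as.integer(stack@dims)) &&
      length(regionMap@labels) != nrow(stack@U))
    stop("region map does not cover the stack's pixel grid")
  set.seed(seed)
  U <- stack@U
  M <- stack@S * stack@Vt
  sst <- .compressedSST(M)
  labels <- as.vector(regionMap@labels)
  ids <- setdiff(sort(unique(labels)), 0L)
  active <- vapply(ids, function(r) sum(labels == r) > 0, logical(1))
  if (any(!active))
    warning("region(s) with no active pixels: ",
            paste(ids[!active], collapse = ", "))
  ids <- ids[active]
  if (is.null(kMax)) kMax <- min(ncol(stack@U), 4L * length(ids))

  # in-region mean seed plus a small out-of-region floor so mass may grow
  seedCol <- function(r) {
    m <- as.numeric(labels == r)
    m + 0.05
  }
  regionOf <- ids
  A0 <- sapply(ids, seedCol)
  A0 <- matrix(A0, nrow(U), length(ids))

  repeat {
    k <- ncol(A0)
    mask <- sapply(regionOf, function(r) labels == r)
    fit <- .semiNMFcore(U, M, A0, tol = tol, maxIter = maxIter,
                        regionMask = mask, locThreshold = localizationThreshold)
    ve <- .varExp(fit$loss, sst)
    if (ve >= varianceTarget || k >= kMax) break
    # add a component to the region with the largest in-region residual
    R <- M - crossprod(U, fit$A) %*% fit$C   # residual in compressed coords
    resPix <- rowSums((U %*% R)^2)
    resByRegion <- vapply(ids, function(r) sum(resPix[labels == r]), numeric(1))
    grow <- ids[which.max(resByRegion)]
    A0 <- cbind(fit$A, seedCol(grow) * stats::runif(nrow(U), 0.5, 1))
    regionOf <- c(regionOf, grow)
  }
  if (!fit$converged)
    warning("localized NMF did not converge within ", maxIter, " iterations")
  initialize(new("ComponentSet"), A = fit$A, C = fit$C,
             regionId = as.character(regionOf),
             varianceExplained = ve, typeLabel = NA_character_,
             dims = stack@dims, converged = fit$converged)
}

#' In-region mass fraction of localized components
#'
#' @param comps a [ComponentSet-class] from [locaNMF()]
#' @param regionMap the [RegionMap-class] used for the fit
#' @return numeric vector, per-component fraction of absolute mass inside
#'   the component's own region
#' @export
localizationFraction <- function(comps, regionMap) {
  labels <- as.vector(regionMap@labels)
  vapply(seq_len(ncol(comps@A)), function(j) {
    r <- as.integer(comps@regionId[j])
    tot <- sum(abs(comps@A[, j]))
    if (tot == 0) return(1)
    sum(abs(comps@A[labels == r, j])) / tot
  }, numeric(1))
}
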