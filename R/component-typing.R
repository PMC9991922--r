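# Embedding and cell-type classification of spatial components: components
# from all sessions are preprocessed into small normalized images, embedded
# in 2-D with UMAP, and classified leave-one-animal-out by their nearest
# neighbors in the embedding.

#' Preprocess spatial components for embedding
#'
#' Takes the first \code{nPerSession} components of each session,
#' downsamples by a factor of 2 (block averaging), smooths with a 5 x 5
#' two-dimensional Gaussian (2-pixel SD) and peak-normalizes each image.
#' All-zero components are dropped with a warning.
#'
#' @param A pixels x components matrix (column-major flattened images)
#' @param dims image dimensions of the input components
#' @param animal,session,label per-component metadata (character vectors)
#' @param nPerSession components retained per session (default 20)
#' @return a \code{ComponentImageSet}: list with \code{images} (components x
#'   downsampled-pixels, each row max 1), \code{dims} (downsampled),
#'   \code{animal}, \code{session}, \code{label}
#' @export
preprocessComponents <- function(A, dims, animal, session, label,
                                 nPerSession = 20) {
  stopifnot(ncol(A) == length(animal), length(animal) == length(session),
            length(session) == length(label))
  keep <- unlist(lapply(split(seq_along(session), session),
                        function(ix) ix[seq_len(min(nPerSession, length(ix)))]))
  keep <- sort(keep)
  zero <- keep[colSums(abs(A[, keep, drop = FALSE])) == 0]
  if (length(zero)) {
    warning(length(zero), " all-zero component(s) dropped (peak normalization undefined)")
    keep <- setdiff(keep, zero)
  }
  g <- stats::dnorm(-2:2, 0, 2)
  kernel <- outer(g, g)
  kernel <- kernel / sum(kernel)
  dsDims <- as.integer(dims %/% 2)
  imgs <- t(vapply(keep, function(j) {
    img <- matrix(A[, j], dims[1], dims[2])
    img <- blockAverage(img, 2L)
    img <- EBImage::filter2(img, kernel, boundary = "replicate")
    img <- pmax(img, 0)
    as.vector(img / max(img))
  }, numeric(prod(dsDims))))
  structure(list(images = imgs, dims = dsDims,
                 animal = animal[keep], session = session[keep],
                 label = label[keep]),
            class = "ComponentImageSet")
}

# 2x block mean downsampling (trailing odd row/col dropped)
blockAverage <- function(img, f) {
  H <- (nrow(img) %/% f) * f
  W <- (ncol(img) %/% f) * f
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  ri <- rep(seq_len(H %/% f), each = f)
  ci <- rep(seq_len(W %/% f), each = f)
  t(rowsum(t(rowsum(img, ri)), ci)) / f^2
}

#' 2-D UMAP embedding of component images
#'
#' Each component's flattened image is its feature vector; components are
#' mapped to two dimensions with UMAP (fixed seed). The embedding model can
#' be returned to project held-out components via the transform contract.
#'
#' @param images components x features matrix (or a ComponentImageSet)
#' @param nNeighbors,minDist UMAP hyperparameters (defaults fixed here and
#'   recorded in the result attributes)
#' @param seed integer seed
#' @param retModel return the uwot model for later [uwot::umap_transform()]
#' @return components x 2 coordinate matrix (with attributes), or the uwot
#'   model when \code{retModel = TRUE}
#' @export
embedComponents <- function(images, nNeighbors = 15, minDist = 0.1,
                            seed = 42, retModel = FALSE) {
  if (inherits(images, "ComponentImageSet")) images <- images$images
  if (nrow(images) < 10) stop("need at least 10 components to embed")
  if (nrow(images) <= nNeighbors)
    stop("fewer components than the neighborhood size")
  set.seed(seed)
  out <- uwot::umap(images, n_neighbors = nNeighbors, min_dist = minDist,
                    n_components = 2, ret_model = retModel,
                    n_threads = 1, n_sgd_threads = 0)
  if (!retModel) {
    attr(out, "nNeighbors") <- nNeighbors
    attr(out, "minDist") <- minDist
  }
  out
}

# majority vote over k nearest neighbors with ties broken by the smallest
# summed neighbor distance
.knnVote <- function(d, lab, k) {
  ord <- order(d)[seq_len(min(k, length(d)))]
  votes <- table(lab[ord])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  sums <- vapply(top, function(cl) sum(d[ord][lab[ord] == cl]), numeric(1))
  top[which.min(sums)]
}

#' Leave-one-animal-out type classification of components
#'
#' For each test animal, a UMAP embedding is computed from all other
#' animals' components only, and the test components are projected into it.
#' Per repetition, \code{perType} components per class are sampled from the
#' embedding and each test component is classified by the majority type of
#' its \code{k} nearest neighbors. Session accuracy is the mean
#' repetition-averaged correctness of that session's components.
#'
#' @param images a ComponentImageSet (see [preprocessComponents()]) or a
#'   components x features matrix
#' @param labels,animals,sessions per-component metadata; taken from the
#'   ComponentImageSet when omitted
#' @param k neighbors per vote (default 10)
#' @param reps repetitions of the balanced resampling (default 100)
#' @param perType components sampled per class per repetition (default
#'   1000); classes with fewer available components are sampled with
#'   replacement, with a warning
#' @param seed integer seed
#' @param nNeighbors,minDist UMAP hyperparameters
#' @return a \code{TypingResult}: list with \code{componentAccuracy},
#'   \code{sessionAccuracy}, \code{predicted} (modal prediction),
#'   \code{embedding} (test-fold coordinates per component), \code{labels},
#'   \code{animals}, \code{sessions}
#' @export
classifyTypesLOO <- function(images, labels = NULL, animals = NULL,
                             sessions = NULL, k = 10, reps = 100,
                             perType = 1000, seed = 1,
                             nNeighbors = 15, minDist = 0.1) {
  if (inherits(images, "ComponentImageSet")) {
    if (is.null(labels)) labels <- images$label
    if (is.null(animals)) animals <- images$animal
    if (is.null(sessions)) sessions <- images$session
    images <- images$images
  }
  if (is.null(sessions)) sessions <- animals
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 types")
  n <- nrow(images)
  acc <- numeric(n)
  predicted <- character(n)
  coords <- matrix(NA_real_, n, 2)
  warned <- FALSE
  set.seed(seed)
  for (a in unique(animals)) {
    test <- which(animals == a)
    train <- which(animals != a)
    if (!length(test)) next
    model <- embedComponents(images[train, , drop = FALSE],
                             nNeighbors = nNeighbors, minDist = minDist,
                             seed = seed, retModel = TRUE)
    testEmb <- uwot::umap_transform(images[test, , drop = FALSE], model,
                                    n_threads = 1)
    coords[test, ] <- testEmb
    trainEmb <- model$embedding
    trainLab <- labels[train]
    # full test x train distances once; repetitions subset columns
    d2 <- outer(testEmb[, 1], trainEmb[, 1], "-")^2 +
          outer(testEmb[, 2], trainEmb[, 2], "-")^2
    hits <- matrix(0, length(test), reps)
    predTab <- matrix("", length(test), reps)
    for (r in seq_len(reps)) {
      samp <- unlist(lapply(classes, function(cl) {
        pool <- which(trainLab == cl)
        if (length(pool) < perType && !warned) {
          warning("class '", cl, "' has fewer than perType components; ",
                  "sampling with replacement")
          warned <<- TRUE
        }
        sample(pool, perType, replace = length(pool) < perType)
      }))
      sl <- trainLab[samp]
      for (i in seq_along(test)) {
        p <- .knnVote(d2[i, samp], sl, k)
        predTab[i, r] <- p
        hits[i, r] <- as.numeric(p == labels[test[i]])
      }
    }
    acc[test] <- rowMeans(hits)
    predicted[test] <- apply(predTab, 1, function(p)
      names(sort(table(p), decreasing = TRUE))[1])
  }
  sessionAccuracy <- tapply(acc, sessions, mean)
  structure(list(componentAccuracy = acc,
                 sessionAccuracy = sessionAccuracy,
                 predicted = predicted, embedding = coords,
                 labels = labels, animals = animals, sessions = sessions),
            class = "TypingResult")
}

#' Component size from a thresholded binary image
#'
#' Binarizes a peak-normalized component above \code{binarizeThreshold}
#' (0.2 by default) and reports both the literal square-root-of-pixel-count
#' statistic and the calibrated area (suprathreshold pixel count times the
#' pixel area in mm^2); the area is the headline value.
#'
#' @param component peak-normalized component (vector or matrix)
#' @param binarizeThreshold binarization level
#' @param pixelSize pixel edge length in mm (default 0.02)
#' @return list: \code{areaMm2}, \code{sqrtPixels}, \code{nPixels},
#'   \code{empty} (TRUE when no pixel is suprathreshold)
#' @export
componentSize <- function(component, binarizeThreshold = 0.2,
                          pixelSize = 0.02) {
  n <- sum(component > binarizeThreshold)
  list(areaMm2 = n * pixelSize^2, sqrtPixels = sqrt(n), nPixels = n,
       empty = n == 0L)
}

#' Compare size distributions of predictive vs nonspecific components
#'
#' Components whose classifier accuracy is at least \code{accuracyCutoff}
#' (0.99) count as type-predictive; their sizes are compared to the
#' remaining (nonspecific) components with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param sizesPredictive,sizesNonspecific numeric size vectors (mm^2)
#' @return list: \code{medianPredictive}, \code{medianNonspecific},
#'   \code{statistic}, \code{pValue}
#' @export
compareSizeDistributions <- function(sizesPredictive, sizesNonspecific) {
  if (length(sizesPredictive) < 2 || length(sizesNonspecific) < 2)
    stop("each group needs at least 2 components")
  wt <- stats::wilcox.test(sizesPredictive, sizesNonspecific,
                           alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(medianPredictive = stats::median(sizesPredictive),
       medianNonspecific = stats::median(sizesNonspecific),
       statistic = unname(wt$statistic), pValue = wt$p.value)
}

#' Split component sizes by classifier accuracy
#'
#' Convenience wrapper applying the predictive-component rule (accuracy >=
#' cutoff) to a TypingResult and a matching size vector.
#'
#' @param typing a TypingResult from [classifyTypesLOO()]
#' @param sizes per-component sizes (mm^2)
#' @param accuracyCutoff predictive threshold (default 0.99)
#' @return list with \code{predictive} and \code{nonspecific} size vectors
#' @export
splitByPredictivity <- function(typing, sizes, accuracyCutoff = 0.99) {
  stopifnot(length(sizes) == length(typing$componentAccuracy))
  sel <- typing$componentAccuracy >= accuracyCutoff
  list(predictive = sizes[sel], nonspecific = sizes[!sel])
}
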