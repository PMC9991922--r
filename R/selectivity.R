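# Single-neuron choice selectivity (ROC/AUC with a shuffle null),
# population fractions, psychometric fitting and optogenetic-impairment
# statistics.

# rank-based AUC of values in class2 ("contra") vs class1 ("ipsi");
# equals the Mann-Whitney U statistic divided by n1*n2
.rankAUC <- function(values, isClass2) {
  n2 <- sum(isClass2); n1 <- sum(!isClass2)
  r <- rank(values)
  (sum(r[isClass2]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' Choice-selectivity AUC per neuron
#'
#' Per neuron, activity is z-scored, averaged per trial over the
#' stimulus+delay window, and the area under the ROC curve of contralateral
#' versus ipsilateral choice trials is computed. AUC above 0.5 denotes
#' contralateral choice preference, below 0.5 ipsilateral.
#'
#' @param activity trials x time x neurons array (or trials x neurons
#'   matrix of window means)
#' @param choices per-trial choice, "left" (ipsi) or "right" (contra)
#' @param window timepoint indices of the stimulus+delay window (array
#'   input only)
#' @param zscore z-score each neuron before averaging (default TRUE)
#' @return numeric AUC per neuron; zero-variance neurons get 0.5 and are
#'   flagged in \code{attr(, "flat")}
#' @export
neuronAUC <- function(activity, choices, window = NULL, zscore = TRUE) {
  contra <- choices == "right"
  if (!any(contra) || all(contra))
    stop("both choice classes must be present")
  if (length(dim(activity)) == 3) {
    if (is.null(window)) window <- seq_len(dim(activity)[2])
    nn <- dim(activity)[3]
    M <- sapply(seq_len(nn), function(j) {
      a <- activity[, , j]
      if (zscore) {
        s <- stats::sd(a)
        if (s > 0) a <- (a - mean(a)) / s
      }
      rowMeans(a[, window, drop = FALSE])
    })
  } else {
    M <- as.matrix(activity)
    if (zscore) M <- scale(M)
  }
  flat <- apply(M, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
  auc <- rep(0.5, ncol(M))
  auc[!flat] <- apply(M[, !flat, drop = FALSE], 2, .rankAUC, isClass2 = contra)
  attr(auc, "flat") <- flat
  auc
}

#' Shuffle-null significance test of choice-selectivity AUC
#'
#' Recomputes each neuron's AUC under randomly reassigned choice labels
#' (100 shuffles by default) and flags a neuron as significantly
#' choice-selective when the empirical probability of its observed AUC
#' under the null falls below \code{alpha} (two-sided by default, computed
#' as 2 * min(tail probabilities) with the +1 correction).
#'
#' @inheritParams neuronAUC
#' @param nShuffle label shuffles (default 100; fewer than 20 is refused,
#'   the p-value resolution would be too coarse for alpha = 0.05)
#' @param alpha significance criterion (default 0.05)
#' @param seed integer seed
#' @param alternative "two.sided" (default) or "one.sided" (larger tail)
#' @return a \code{SelectivityResult}: list with \code{auc}, \code{null}
#'   (neurons x nShuffle), \code{p}, \code{significant}, \code{preferred}
#'   ("ipsi"/"contra"), \code{fractionIpsi}/\code{fractionContra} with
#'   Clopper-Pearson 95\% CIs, \code{alpha}, \code{alternative}
#' @export
aucShuffleTest <- function(activity, choices, window = NULL,
                           nShuffle = 100, alpha = 0.05, seed = 1,
                           zscore = TRUE,
                           alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (nShuffle < 20)
    stop("nShuffle must be at least 20 for a usable p-value resolution")
  # reduce to per-trial window means once
  M <- if (length(dim(activity)) == 3) {
    sapply(seq_len(dim(activity)[3]), function(j) {
      a <- activity[, , j]
      if (zscore) {
        s <- stats::sd(a)
        if (s > 0) a <- (a - mean(a)) / s
      }
      rowMeans(a[, if (is.null(window)) seq_len(ncol(a)) else window,
                 drop = FALSE])
    })
  } else as.matrix(activity)
  obs <- neuronAUC(M, choices, zscore = FALSE)
  set.seed(seed)
  null <- sapply(seq_len(nShuffle), function(s)
    neuronAUC(M, sample(choices), zscore = FALSE))
  hi <- rowSums(null >= obs)
  lo <- rowSums(null <= obs)
  p <- if (alternative == "two.sided")
    pmin(1, 2 * pmin(hi + 1, lo + 1) / (nShuffle + 1)) else
    (hi + 1) / (nShuffle + 1)
  significant <- p < alpha
  preferred <- ifelse(obs >= 0.5, "contra", "ipsi")
  n <- length(obs)
  kI <- sum(significant & preferred == "ipsi")
  kC <- sum(significant & preferred == "contra")
  ciI <- stats::binom.test(kI, n)$conf.int
  ciC <- stats::binom.test(kC, n)$conf.int
  structure(list(auc = as.numeric(obs), null = null, p = p,
                 significant = significant, preferred = preferred,
                 fractionIpsi = kI / n, fractionContra = kC / n,
                 ciIpsi = ciI, ciContra = ciC,
                 alpha = alpha, alternative = alternative),
            class = "SelectivityResult")
}

#' Population test of ipsi- vs contra-selective fractions
#'
#' Reports the two selective fractions with Clopper-Pearson 95\% confidence
#' intervals and a two-sided exact binomial test of the ipsi vs contra
#' counts against an equal split, Bonferroni-corrected across the requested
#' family of comparisons.
#'
#' @param nIpsi,nContra counts of significantly ipsi-/contra-selective
#'   neurons
#' @param n population size
#' @param familySize number of comparisons for the Bonferroni correction
#' @param criterion family-wise criterion (default 0.01)
#' @return list: \code{fractionIpsi}, \code{fractionContra}, their CIs,
#'   \code{pValue} (uncorrected), \code{pBonferroni}, \code{significant}
#' @export
selectiveFractionTest <- function(nIpsi, nContra, n, familySize = 1,
                                  criterion = 0.01) {
  if (n == 0) stop("population size n must be positive")
  stopifnot(nIpsi + nContra <= n)
  bt <- stats::binom.test(nIpsi, nIpsi + nContra, p = 0.5,
                          alternative = "two.sided")
  pB <- min(1, bt$p.value * familySize)
  list(fractionIpsi = nIpsi / n, fractionContra = nContra / n,
       ciIpsi = stats::binom.test(nIpsi, n)$conf.int,
       ciContra = stats::binom.test(nContra, n)$conf.int,
       pValue = bt$p.value, pBonferroni = pB,
       significant = pB < criterion)
}

#' Fit a four-parameter psychometric function
#'
#' Maximum-likelihood fit of P(right) = lapseLow + (1 - lapseLow -
#' lapseHigh) * logistic(slope * (x - bias)) to choices versus the signed
#' click-count difference.
#'
#' @param trials trial table (uses nClicksRight - nClicksLeft and choice),
#'   or NULL when \code{x}/\code{chooseRight} are given directly
#' @param x signed stimulus strengths
#' @param chooseRight logical responses
#' @return list: \code{par} (bias, slope, lapseLow, lapseHigh),
#'   \code{curve} (fitted function of x), \code{logLik},
#'   \code{degenerate} (TRUE when all responses are one class, slope
#'   unidentifiable)
#' @export
fitPsychometric <- function(trials = NULL, x = NULL, chooseRight = NULL) {
  if (!is.null(trials)) {
    x <- trials$nClicksRight - trials$nClicksLeft
    chooseRight <- trials$choice == "right"
  }
  if (length(unique(x)) < 2) stop("need at least 2 distinct stimulus strengths")
  if (all(chooseRight) || !any(chooseRight)) {
    warning("single-class responding: slope unidentifiable")
    return(list(par = c(bias = NA, slope = NA, lapseLow = NA, lapseHigh = NA),
                curve = NULL, logLik = NA, degenerate = TRUE))
  }
  nll <- function(p) {
    pr <- psychometricCurve(x, p[1], p[2], p[3], p[4])
    pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
    -sum(log(ifelse(chooseRight, pr, 1 - pr)))
  }
  opt <- stats::optim(c(0, 0.2, 0.02, 0.02), nll, method = "L-BFGS-B",
                      lower = c(-20, 1e-4, 0, 0),
                      upper = c(20, 10, 0.45, 0.45))
  par <- stats::setNames(opt$par, c("bias", "slope", "lapseLow", "lapseHigh"))
  list(par = par,
       curve = function(z) psychometricCurve(z, par[1], par[2], par[3], par[4]),
       logLik = -opt$value, degenerate = FALSE)
}

#' Optogenetic behavioral impairment
#'
#' Percentage change of task performance under optogenetic inhibition
#' relative to control trials, with exact binomial confidence intervals and
#' a two-sided binomial test of the inhibited correct-count against the
#' control rate, Bonferroni-corrected across cells. Cells are defined by
#' the optional grouping columns (e.g. inhibition epoch, area, cell type)
#' of the opto trial table.
#'
#' @param trialsControl,trialsOpto trial tables with a \code{correct}
#'   column; \code{trialsOpto} may carry grouping columns named in
#'   \code{by}
#' @param by character vector of grouping column names (NULL = one cell)
#' @param conf confidence level (default 0.95, Clopper-Pearson)
#' @return data.frame, one row per cell: control/opto performance,
#'   impairment (percent change from control), CI bounds, p,
#'   Bonferroni-corrected p
#' @export
optoImpairment <- function(trialsControl, trialsOpto, by = NULL,
                           conf = 0.95) {
  if (!nrow(trialsControl) || !nrow(trialsOpto))
    stop("both control and opto arms must be non-empty")
  perfC <- mean(trialsControl$correct)
  groups <- if (is.null(by)) list(seq_len(nrow(trialsOpto))) else
    split(seq_len(nrow(trialsOpto)),
          interaction(trialsOpto[by], drop = TRUE))
  rows <- lapply(names(groups) %||% "all", function(g) {
    ix <- groups[[if (is.null(by)) 1 else g]]
    kO <- sum(trialsOpto$correct[ix]); nO <- length(ix)
    perfO <- kO / nO
    if (perfC == 0)
      return(data.frame(cell = g, controlPerf = perfC, optoPerf = perfO,
                        impairment = NA, ciLow = NA, ciHigh = NA,
                        p = NA, undefined = TRUE))
    bt <- stats::binom.test(kO, nO, p = perfC, conf.level = conf)
    data.frame(cell = g, controlPerf = perfC, optoPerf = perfO,
               impairment = 100 * (perfO - perfC) / perfC,
               ciLow = 100 * (bt$conf.int[1] - perfC) / perfC,
               ciHigh = 100 * (bt$conf.int[2] - perfC) / perfC,
               p = bt$p.value, undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pBonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
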