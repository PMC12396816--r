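#' Area under the ROC curve (all-pairs form)
#'
#' Computed as the probability that a randomly chosen positive outranks a
#' randomly chosen negative, with ties counted 1/2 -- via the rank-sum
#' identity, which is exactly the all-pairs statistic.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical or 0/1 labels.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uninterpolated average precision: the mean, over positives taken in
#' descending score order, of the precision at each positive's rank. Ties
#' are broken deterministically by (pair index, site index) so results are
#' reproducible. For a random classifier the expected value is the
#' prevalence rho, which forms the baseline minimum of this metric.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels.
#' @param pairIdx,siteIdx optional tie-breaking indices (defaults to input
#'   order).
#' @return average precision in [0, 1].
#' @export
auprcScore <- function(scores, labels, pairIdx = seq_along(scores),
                       siteIdx = seq_along(scores)) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("AUPRC needs at least one positive")
  ord <- order(-scores, pairIdx, siteIdx)
  lab <- labels[ord]
  hits <- cumsum(lab)
  prec <- hits / seq_along(lab)
  mean(prec[lab])
}

#' R-precision, micro-averaged over pairs
#'
#' For each pair with R >= 1 observed mutations, counts true mutations
#' among its R highest-scored informative sites (ties broken by site
#' index); the micro-average is total hits / total R. A random classifier
#' has expectation rho.
#'
#' @param scoresByPair list of per-pair score vectors.
#' @param labelsByPair list of per-pair logical label vectors.
#' @return micro-averaged R-precision in [0, 1].
#' @export
rPrecisionScore <- function(scoresByPair, labelsByPair) {
  stopifnot(length(scoresByPair) == length(labelsByPair))
  hits <- 0L; total <- 0L
  for (i in seq_along(scoresByPair)) {
    lab <- as.logical(labelsByPair[[i]])
    R <- sum(lab)
    if (R == 0L) next
    ord <- order(-scoresByPair[[i]], seq_along(lab))
    hits <- hits + sum(lab[ord[seq_len(R)]])
    total <- total + R
  }
  if (total == 0L) stop("R-precision undefined: all pairs have zero mutations")
  hits / total
}

#' Substitution accuracy of the CSP head
#'
#' Fraction of mutated informative sites at which the argmax of the CSP row
#' equals the observed child base (argmax ties broken alphabetically).
#'
#' @param cspRows matrix of CSP rows (columns A, C, G, T) at mutated sites.
#' @param childBases observed child bases at those sites.
#' @return accuracy in [0, 1].
#' @export
substitutionAccuracyScore <- function(cspRows, childBases) {
  if (NROW(cspRows) == 0L) stop("no mutated sites; accuracy undefined")
  pred <- apply(cspRows, 1L, which.max) # first max = alphabetical tie-break
  mean(.NUC[pred] == childBases)
}

#' Binned observed/expected fit and overlap statistic
#'
#' Pools per-site predicted substitution probabilities, bins them (equal
#' width in log10 probability across the pooled score range by default),
#' and compares per-bin observed mutation counts O_b with expected counts
#' E_b (the sum of predicted probabilities in the bin). The overlap is
#' `sum_b min(O_b, E_b) / ((sum_b O_b + sum_b E_b) / 2)`: the intersection
#' of the two histograms divided by their average area, 1 for a perfectly
#' calibrated fit. Zero scores are placed in the lowest bin.
#'
#' @param scores pooled predicted substitution probabilities.
#' @param labels pooled mutation indicators.
#' @param nBins number of bins.
#' @param edges optional explicit bin edges on the probability scale.
#' @return list with `edges`, `observed`, `expected`, and `overlap`.
#' @export
binnedFit <- function(scores, labels, nBins = 20L, edges = NULL) {
  .checkScalar(nBins, "nBins", function(v) v >= 1, "must be >= 1")
  labels <- as.logical(labels)
  if (is.null(edges)) {
    pos <- scores[scores > 0]
    if (!length(pos)) stop("all scores are zero; cannot bin")
    lo <- log10(min(pos)); hi <- log10(max(pos))
    if (hi - lo < 1e-9) hi <- lo + 1e-9
    edges <- 10^seq(lo, hi, length.out = nBins + 1L)
  }
  bin <- findInterval(scores, edges, rightmost.closed = TRUE, all.inside = TRUE)
  O <- tabulate(bin[labels], nbins = length(edges) - 1L)
  E <- vapply(seq_len(length(edges) - 1L),
              function(b) sum(scores[bin == b]), numeric(1))
  denom <- (sum(O) + sum(E)) / 2
  list(edges = edges, observed = O, expected = E,
       overlap = if (denom > 0) sum(pmin(O, E)) / denom else NA_real_)
}

#' Overlap of two binned histograms
#'
#' @param observed,expected nonnegative per-bin masses.
#' @return `sum min(O, E) / mean(total O, total E)`.
#' @export
overlapStatistic <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  denom <- (sum(observed) + sum(expected)) / 2
  sum(pmin(observed, expected)) / denom
}

#' Evaluate a model on a PcpSet
#'
#' Computes all assessment metrics on the informative sites whose 0-based
#' index lies in `siteWindow` (inclusive). Scores are per-site substitution
#' probabilities `p = 1 - exp(-t* lambda)` using per-pair branch lengths
#' re-optimized to maximize the placement likelihood, so scores are
#' comparable across pairs. The mean log-likelihood is the summed placement
#' log-likelihood plus CSP log-likelihood at mutated sites, divided by the
#' number of evaluated sites. The default window (80-319) restricts to a
#' region well covered by typical bulk IgH repertoire reads.
#'
#' @param model a trained model.
#' @param pcps a [PcpSet-class].
#' @param siteWindow 0-based inclusive site range, e.g. `c(80, 319)`.
#' @param nBins histogram bins for the overlap statistic.
#' @param optimizeT re-optimize branch lengths per pair (TRUE, default) or
#'   use the stored offsets.
#' @return a [MetricReport-class].
#' @export
evaluateModel <- function(model, pcps, siteWindow = c(80L, 319L),
                          nBins = 20L, optimizeT = TRUE) {
  stopifnot(is(pcps, "PcpSet"))
  if (length(pcps) == 0L) stop("empty dataset")
  preps <- .prepSet(pcps)
  scoresByPair <- labelsByPair <- vector("list", length(preps))
  cspRows <- list(); childBases <- character(0)
  logLik <- 0
  for (i in seq_along(preps)) {
    prep <- preps[[i]]
    pred <- predictRates(model, prep$parent)
    lam <- pred@rates
    tStar <- if (optimizeT) .optimalT(lam, prep) else prep$t
    sites0 <- seq_len(prep$L) - 1L
    sel <- prep$mask & sites0 >= siteWindow[1] & sites0 <= siteWindow[2]
    if (!any(sel)) {
      scoresByPair[[i]] <- numeric(0)
      labelsByPair[[i]] <- logical(0)
      next
    }
    p <- substitutionProbability(lam, tStar)
    m <- prep$m & sel
    scoresByPair[[i]] <- p[sel]
    labelsByPair[[i]] <- m[sel]
    # log-likelihood restricted to the window
    lt <- tStar * lam
    logLik <- logLik - sum(lt[sel & !m]) + sum(log(-expm1(-lt[m])))
    mutIdx <- which(m)
    if (length(mutIdx)) {
      logLik <- logLik + sum(log(pred@csp[cbind(mutIdx, prep$childIdx[mutIdx])]))
      cspRows[[length(cspRows) + 1L]] <- pred@csp[mutIdx, , drop = FALSE]
      childBases <- c(childBases, .NUC[prep$childIdx[mutIdx]])
    }
  }
  scores <- unlist(scoresByPair)
  labels <- unlist(labelsByPair)
  if (!length(scores)) stop("evaluation window is empty after masking")
  pairIdx <- rep(seq_along(scoresByPair), lengths(scoresByPair))
  siteIdx <- unlist(lapply(scoresByPair, seq_along))
  bf <- binnedFit(scores, labels, nBins = nBins)
  cspAll <- if (length(cspRows)) do.call(rbind, cspRows) else matrix(0, 0, 4)
  new("MetricReport",
    auroc = aurocScore(scores, labels),
    auprc = auprcScore(scores, labels, pairIdx, siteIdx),
    rPrecision = rPrecisionScore(scoresByPair, labelsByPair),
    substitutionAccuracy = if (nrow(cspAll))
      substitutionAccuracyScore(cspAll, childBases) else NA_real_,
    overlap = bf$overlap,
    meanLogLik = logLik / length(scores),
    prevalence = mean(labels),
    binned = bf[c("edges", "observed", "expected")],
    nSites = length(scores), nMutated = sum(labels)
  )
}

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  sites evaluated: %d (%d mutated, prevalence rho = %.4g)\n",
              object@nSites, object@nMutated, object@prevalence))
  cat(sprintf("  AUROC:                 %.4f\n", object@auroc))
  cat(sprintf("  AUPRC:                 %.4f\n", object@auprc))
  cat(sprintf("  R-precision:           %.4f\n", object@rPrecision))
  cat(sprintf("  substitution accuracy: %.4f\n", object@substitutionAccuracy))
  cat(sprintf("  overlap:               %.4f\n", object@overlap))
  cat(sprintf("  mean per-site loglik:  %.5f\n", object@meanLogLik))
})

#' Write a MetricReport as delimited text and key-value pairs
#'
#' @param report a [MetricReport-class].
#' @param prefix output path prefix; writes `<prefix>_metrics.tsv`,
#'   `<prefix>_metrics.txt` (key=value), and `<prefix>_binned.tsv`.
#' @return invisibly, the written paths.
#' @export
writeMetricReport <- function(report, prefix) {
  vals <- c(
    auroc = report@auroc, auprc = report@auprc,
    r_precision = report@rPrecision,
    substitution_accuracy = report@substitutionAccuracy,
    overlap = report@overlap, mean_log_lik = report@meanLogLik,
    prevalence = report@prevalence,
    n_sites = report@nSites, n_mutated = report@nMutated
  )
  tsv <- paste0(prefix, "_metrics.tsv")
  utils::write.table(
    data.frame(metric = names(vals), value = .fmtNum(vals)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  kv <- paste0(prefix, "_metrics.txt")
  writeLines(paste0(names(vals), "=", .fmtNum(vals)), kv)
  bn <- paste0(prefix, "_binned.tsv")
  utils::write.table(
    data.frame(
      bin_lo = .fmtNum(report@binned$edges[-length(report@binned$edges)]),
      bin_hi = .fmtNum(report@binned$edges[-1]),
      observed = report@binned$observed,
      expected = .fmtNum(report@binned$expected)
    ),
    bn, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(tsv, kv, bn))
}
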