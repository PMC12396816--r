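#' Probability of substitution under the exponential waiting-time model
#'
#' Each site carries an exponential mutation clock with rate lambda; over a
#' branch of length t the effective parameter is the offset-scaled rate
#' `lambda~ = t * lambda`, and the probability that the clock fires is
#' `p = 1 - exp(-t * lambda)`. Computed with `expm1` so the small-rate
#' limit `p -> t * lambda` is accurate.
#'
#' @param lambda positive per-site rate(s).
#' @param t nonnegative branch length.
#' @return substitution probability/ies in [0, 1).
#' @export
substitutionProbability <- function(lambda, t) {
  if (any(lambda <= 0)) stop("lambda must be strictly positive")
  if (any(t < 0)) stop("t must be nonnegative")
  -expm1(-t * lambda)
}

#' Two-part loss for one parent-child pair
#'
#' The training objective combines (i) a mutation-placement negative
#' log-likelihood: each informative site is an independent censored
#' waiting-time observation, Bernoulli with `p_i = 1 - exp(-t lambda_i)`;
#' and (ii) a categorical cross-entropy over the observed child base at
#' mutated sites, using the model's conditional substitution probabilities.
#' The two are combined as `total = placement + cspWeight * csp`; the
#' default weight 0.01 approximately evens out the two contributions.
#' A mutated site whose CSP assigns zero mass to the observed base yields
#' an explicit infinite CSP loss (never silently clipped).
#'
#' @param pred a [RatePrediction-class] aligned to the pair.
#' @param pcp a length-1 [PcpSet-class] (or list from `.prepPair`).
#' @param cspWeight weight on the cross-entropy term.
#' @param t optional branch length overriding the stored one.
#' @return list with `placement`, `csp`, and `total` (all site sums over
#'   the pair's loss mask).
#' @export
pcpLoss <- function(pred, pcp, cspWeight = 0.01, t = NULL) {
  stopifnot(is(pred, "RatePrediction"))
  if (is(pcp, "PcpSet")) {
    stopifnot(length(pcp) == 1L)
    prep <- .prepPair(pcp@parent[1], pcp@child[1], pcp@lossMask[[1]],
                      pcp@branchLength[1])
  } else {
    prep <- pcp
  }
  if (length(pred@rates) != prep$L)
    stop("prediction and pair lengths differ")
  if (is.null(t)) t <- prep$t
  lam <- pred@rates
  .placementCspLoss(lam, pred@csp, prep, t, cspWeight)
}

# core loss arithmetic shared by pcpLoss and the training loop
.placementCspLoss <- function(lam, csp, prep, t, cspWeight) {
  mask <- prep$mask
  m <- prep$m & mask
  lt <- t * lam
  # log(1-p) = -lt exactly; log p = log(-expm1(-lt))
  nllPlace <- sum(lt[mask & !m]) - sum(log(-expm1(-lt[m])))
  mutIdx <- which(m)
  if (length(mutIdx)) {
    pChild <- csp[cbind(mutIdx, prep$childIdx[mutIdx])]
    nllCsp <- -sum(log(pChild))
  } else {
    nllCsp <- 0
  }
  list(placement = nllPlace, csp = nllCsp,
       total = nllPlace + cspWeight * nllCsp)
}

#' Maximum-likelihood branch length for one pair
#'
#' Holds the model's per-site rates fixed and maximizes the placement
#' likelihood over the branch length t in [0, tMax]. The derivative of the
#' log-likelihood is strictly decreasing from +Inf (when any mutation is
#' observed), so the optimum is found by a root search on the derivative to
#' tolerance 1e-8; pairs with no observed mutation get t* = 0. For uniform
#' rates lambda over L sites with m mutated, the closed form is
#' `t* = -log(1 - m/L) / lambda`.
#'
#' @param model a model, or a [RatePrediction-class] already computed.
#' @param pcp a length-1 [PcpSet-class].
#' @param tMax bracket upper bound (well beyond any per-site scale).
#' @return the optimized branch length t*.
#' @export
optimizeBranchLength <- function(model, pcp, tMax = 5) {
  stopifnot(is(pcp, "PcpSet"), length(pcp) == 1L)
  prep <- .prepPair(pcp@parent[1], pcp@child[1], pcp@lossMask[[1]],
                    pcp@branchLength[1])
  lam <- if (is(model, "RatePrediction")) model@rates
         else predictRates(model, pcp@parent[1])@rates
  .optimalT(lam, prep, tMax)
}

.optimalT <- function(lam, prep, tMax = 5) {
  mask <- prep$mask
  if (!any(mask)) stop("pair has no informative sites")
  m <- prep$m & mask
  if (!any(m)) return(0)
  lamMut <- lam[m]
  lamTot <- sum(lam[mask & !m])
  # d/dt loglik = sum_mut lam e^{-t lam}/(1 - e^{-t lam}) - lamTot
  dldt <- function(t) {
    e <- exp(-t * lamMut)
    sum(lamMut * e / (1 - e)) - lamTot
  }
  if (dldt(tMax) >= 0) return(tMax)
  lo <- 1e-12
  while (dldt(lo) <= 0) lo <- lo / 10 # pathological, tiny rates
  stats::uniroot(dldt, c(lo, tMax), tol = 1e-10)$root
}

#' Training configuration
#'
#' @param epochs full passes over the training set.
#' @param learningRate Adam step size.
#' @param cspWeight weight on the cross-entropy (CSP) loss term.
#' @param batchSize pairs per gradient step.
#' @param seed RNG seed governing shuffling, dropout, and initialization of
#'   derived state; fixed seed gives a bit-reproducible run.
#' @param lossSites "all_informative" or "fourfold_synonymous"; the latter
#'   restricts the loss to fourfold-degenerate synonymous sites via
#'   [fourfoldDegenerateMask()] before training.
#' @param jointBranchOpt alternate gradient epochs with per-pair
#'   branch-length re-optimization.
#' @return a list of class "trainingConfig".
#' @export
trainingConfig <- function(epochs = 100L, learningRate = 1e-3,
                           cspWeight = 0.01, batchSize = 32L, seed = 1L,
                           lossSites = c("all_informative", "fourfold_synonymous"),
                           jointBranchOpt = FALSE) {
  lossSites <- match.arg(lossSites)
  stopifnot(epochs >= 1L, cspWeight >= 0, learningRate > 0, batchSize >= 1L)
  structure(list(
    epochs = as.integer(epochs), learningRate = learningRate,
    cspWeight = cspWeight, batchSize = as.integer(batchSize),
    seed = as.integer(seed), lossSites = lossSites,
    jointBranchOpt = isTRUE(jointBranchOpt)
  ), class = "trainingConfig")
}

# per-site gradient of the placement NLL wrt r = log lambda
.placementGradR <- function(lam, prep, t) {
  mask <- prep$mask
  m <- prep$m & mask
  lt <- t * lam
  g <- numeric(prep$L)
  g[mask & !m] <- lt[mask & !m]
  if (any(m)) {
    e <- exp(-lt[m])
    g[m] <- -lt[m] * e / (1 - e)
  }
  g
}

# gradient of cspWeight * CE wrt the 5 logits (masked columns get 0)
.cspGradZ <- function(z, prep, cspWeight) {
  L <- prep$L
  Gz <- matrix(0, L, 5L)
  mut <- which(prep$m & prep$mask)
  if (!length(mut)) return(Gz)
  for (i in mut) {
    zi <- z[i, 1:4]
    zi[prep$parentIdx[i]] <- -Inf
    q <- exp(zi - max(zi))
    q <- q / sum(q)
    gi <- q
    gi[prep$childIdx[i]] <- gi[prep$childIdx[i]] - 1
    gi[prep$parentIdx[i]] <- 0
    Gz[i, 1:4] <- cspWeight * gi
  }
  Gz
}

# total loss and parameter gradients for a list of prepped pairs (summed per
# pair, averaged over pairs); regularization for sitewise models included
.lossAndGrad <- function(model, preps, cspWeight, dropout = 0, rng = FALSE) {
  n <- length(preps)
  grads <- NULL
  place <- cspl <- 0
  F <- if (is(model, "ThriftyModel")) model@config@filters else 0L
  nBranch <- if (is(model, "ThriftyModel") && model@config@wiring != "joined") 2L else 1L
  for (prep in preps) {
    dm <- NULL
    if (dropout > 0 && rng) {
      dm <- lapply(seq_len(nBranch), function(b) {
        matrix((stats::runif(prep$L * F) >= dropout) / (1 - dropout), prep$L, F)
      })
    }
    out <- .forward(model, prep, dropMask = dm)
    lam <- exp(out$r)
    csp <- .cspFromLogits(out$z, prep$parentIdx)
    l <- .placementCspLoss(lam, csp, prep, prep$t, cspWeight)
    place <- place + l$placement
    cspl <- cspl + l$csp
    gr <- .placementGradR(lam, prep, prep$t)
    Gz <- .cspGradZ(out$z, prep, cspWeight)
    g <- .backward(model, prep, out, gr, Gz)
    grads <- if (is.null(grads)) g else Map(`+`, grads, g)
  }
  grads <- lapply(grads, function(g) g / n)
  total <- (place + cspWeight * cspl) / n
  if (is(model, "SitewiseFivemerModel")) {
    total <- total + 1e-4 * sum(model@logSiteFactor^2)
    grads$logSiteFactor <- grads$logSiteFactor + 2e-4 * model@logSiteFactor
  }
  list(loss = total, placement = place / n, csp = cspl / n, grads = grads)
}

# evaluation-mode mean losses on a list of preps
.meanLoss <- function(model, preps, cspWeight) {
  place <- cspl <- 0
  for (prep in preps) {
    out <- .forward(model, prep, dropMask = NULL)
    l <- .placementCspLoss(exp(out$r), .cspFromLogits(out$z, prep$parentIdx),
                           prep, prep$t, cspWeight)
    place <- place + l$placement
    cspl <- cspl + l$csp
  }
  n <- length(preps)
  c(placement = place / n, csp = cspl / n,
    total = (place + cspWeight * cspl) / n)
}

.prepSet <- function(x) {
  lapply(seq_len(length(x)), function(i) {
    .prepPair(x@parent[i], x@child[i], x@lossMask[[i]], x@branchLength[i])
  })
}

#' Train an SHM model
#'
#' Minimizes the mean two-part loss over parent-child pairs by Adam
#' gradient descent: the loss is summed per pair and averaged over the
#' pairs of each mini-batch. Pairs with zero observed substitutions are
#' excluded from training (their branch-length offset is 0, so they carry
#' no gradient). With `jointBranchOpt`, each gradient epoch is followed by
#' per-pair branch-length re-optimization under the current model. Dropout
#' is active only here; all evaluation passes are deterministic. A fixed
#' seed yields a bit-reproducible run.
#'
#' @param model a [ThriftyModel-class], [FivemerModel-class], or
#'   [SitewiseFivemerModel-class].
#' @param trainSet,valSet [PcpSet-class] training and validation data
#'   (`valSet` may be NULL).
#' @param config a [trainingConfig()].
#' @return list with `model` (trained) and `history` (per-epoch data frame
#'   of train/validation placement, CSP, and total losses).
#' @export
trainModel <- function(model, trainSet, valSet = NULL,
                       config = trainingConfig()) {
  stopifnot(is(trainSet, "PcpSet"), inherits(config, "trainingConfig"))
  if (config$lossSites == "fourfold_synonymous") {
    trainSet <- fourfoldDegenerateMask(trainSet)
    if (!is.null(valSet)) valSet <- fourfoldDegenerateMask(valSet)
  }
  keep <- !zeroSubstitutionPairs(trainSet) &
    vapply(trainSet@lossMask, any, logical(1))
  if (!any(keep)) stop("training set is empty after zero-substitution exclusion")
  trainSet <- trainSet[which(keep)]
  preps <- .prepSet(trainSet)
  valPreps <- if (!is.null(valSet) && length(valSet) > 0) .prepSet(valSet) else NULL
  dropout <- if (is(model, "ThriftyModel")) model@config@dropout else 0
  old <- .Random.seed.exists()
  set.seed(config$seed)
  params <- .paramList(model)
  mState <- lapply(params, function(p) p * 0)
  vState <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(preps)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    bounds <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epPlace <- epCsp <- 0
    for (batch in bounds) {
      lg <- .lossAndGrad(model, preps[batch], config$cspWeight,
                         dropout = dropout, rng = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss (%g) at epoch %d; aborting", lg$loss, epoch))
      step <- step + 1L
      for (nm in names(params)) {
        g <- lg$grads[[nm]]
        mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
        vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g^2
        mh <- mState[[nm]] / (1 - b1^step)
        vh <- vState[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - config$learningRate * mh / (sqrt(vh) + eps)
      }
      model <- .setParamList(model, params)
      epPlace <- epPlace + lg$placement * length(batch)
      epCsp <- epCsp + lg$csp * length(batch)
    }
    if (config$jointBranchOpt) {
      for (i in seq_along(preps)) {
        out <- .forward(model, preps[[i]], dropMask = NULL)
        preps[[i]]$t <- .optimalT(exp(out$r), preps[[i]])
      }
    }
    row <- data.frame(
      epoch = epoch,
      trainPlacement = epPlace / n, trainCsp = epCsp / n,
      trainTotal = (epPlace + config$cspWeight * epCsp) / n
    )
    if (!is.null(valPreps)) {
      vl <- .meanLoss(model, valPreps, config$cspWeight)
      row$valPlacement <- vl[["placement"]]
      row$valCsp <- vl[["csp"]]
      row$valTotal <- vl[["total"]]
    }
    hist[[epoch]] <- row
  }
  .restoreSeed(old)
  list(model = model, history = do.call(rbind, hist))
}
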