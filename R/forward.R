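# Internal forward/backward machinery shared by training and prediction.
#
# Every model class implements:
#   .paramList(model)            named list of numeric arrays
#   .setParamList(model, params) replace weights
#   .forward(model, prep, training, dropMask) -> list(r, z, cache)
#       r: per-site rate-head output (log rate), z: L x 5 CSP logits
#   .backward(model, cache, gr, Gz) -> gradient list matching .paramList
#
# prep is the cached per-pair tokenization produced by .prepPair().

.prepPair <- function(parent, child, lossMask, t) {
  pch <- .charMat(parent)
  cch <- .charMat(child)
  m <- pch != cch & pch %in% .NUC & cch %in% .NUC
  list(
    parent = parent,
    tokens = tokenize3mers(parent), # 0..64
    parentIdx = match(pch, .NUC), # 1..4 or NA
    childIdx = match(cch, .NUC),
    m = m, mask = lossMask, t = t,
    L = length(pch)
  )
}

# -- im2col convolution helpers ------------------------------------------------

# X: L x E -> L x (K*E), zero padding (K-1)/2 each side so output length = L
.im2col <- function(X, K) {
  L <- nrow(X); E <- ncol(X)
  pad <- (K - 1L) / 2
  Xp <- rbind(matrix(0, pad, E), X, matrix(0, pad, E))
  out <- matrix(0, L, K * E)
  for (j in seq_len(K)) {
    out[, (j - 1L) * E + seq_len(E)] <- Xp[(j - 1L) + seq_len(L), , drop = FALSE]
  }
  out
}

# fold L x (K*E) column gradients back to L x E input gradients
.col2im <- function(Gcol, K, E) {
  L <- nrow(Gcol)
  pad <- (K - 1L) / 2
  Gp <- matrix(0, L + 2L * pad, E)
  for (j in seq_len(K)) {
    Gp[(j - 1L) + seq_len(L), ] <- Gp[(j - 1L) + seq_len(L), , drop = FALSE] +
      Gcol[, (j - 1L) * E + seq_len(E), drop = FALSE]
  }
  Gp[pad + seq_len(L), , drop = FALSE]
}

# accumulate per-site embedding-row gradients into the 65 x E table
.embGrad <- function(GX, tokens) {
  gsum <- rowsum(GX, group = tokens, reorder = FALSE)
  G <- matrix(0, 65L, ncol(GX))
  G[as.integer(rownames(gsum)) + 1L, ] <- gsum
  G
}

# one stack: tokens -> embeddings -> conv columns -> linear
.stackForward <- function(emb, convW, convB, tokens, K) {
  X <- emb[tokens + 1L, , drop = FALSE]
  Xcol <- .im2col(X, K)
  A <- Xcol %*% convW + matrix(convB, nrow(Xcol), length(convB), byrow = TRUE)
  list(A = A, Xcol = Xcol)
}

.stackBackward <- function(GA, cache, convW, K, E, tokens) {
  list(
    emb = .embGrad(.col2im(GA %*% t(convW), K, E), tokens),
    convW = t(cache$Xcol) %*% GA,
    convB = colSums(GA)
  )
}

# -- ThriftyModel --------------------------------------------------------------

.paramList <- function(model) {
  if (is(model, "ThriftyModel")) return(model@weights)
  if (is(model, "FivemerModel"))
    return(list(logRate = model@logRate, cspLogits = model@cspLogits))
  if (is(model, "SitewiseFivemerModel"))
    return(list(logRate = model@fivemer@logRate,
                cspLogits = model@fivemer@cspLogits,
                logSiteFactor = model@logSiteFactor))
  stop("unknown model class")
}

.setParamList <- function(model, params) {
  if (is(model, "ThriftyModel")) {
    model@weights <- params
    return(model)
  }
  if (is(model, "FivemerModel")) {
    model@logRate <- params$logRate
    model@cspLogits <- params$cspLogits
    return(model)
  }
  if (is(model, "SitewiseFivemerModel")) {
    model@fivemer@logRate <- params$logRate
    model@fivemer@cspLogits <- params$cspLogits
    model@logSiteFactor <- params$logSiteFactor
    return(model)
  }
  stop("unknown model class")
}

# dropMask: NULL (eval mode) or list of L x F 0/1-scaled masks per branch
.forward <- function(model, prep, dropMask = NULL) {
  if (is(model, "ThriftyModel")) return(.forwardThrifty(model, prep, dropMask))
  if (is(model, "FivemerModel")) return(.forwardFivemer(model, prep, NULL))
  if (is(model, "SitewiseFivemerModel")) return(.forwardFivemer(model@fivemer, prep, model))
  stop("unknown model class")
}

.forwardThrifty <- function(model, prep, dropMask) {
  w <- model@weights
  cfg <- model@config
  K <- cfg@kernel; E <- cfg@embed
  tk <- prep$tokens
  cache <- list(dropMask = dropMask)
  if (cfg@wiring == "joined") {
    s <- .stackForward(w$emb, w$convW, w$convB, tk, K)
    H <- .relu(s$A)
    Hd <- if (is.null(dropMask)) H else H * dropMask[[1]]
    r <- drop(Hd %*% w$rateW) + w$rateB
    z <- Hd %*% w$cspW + matrix(w$cspB, prep$L, 5L, byrow = TRUE)
    cache <- c(cache, list(s = s, H = H, Hd = Hd))
  } else if (cfg@wiring == "hybrid") {
    sr <- .stackForward(w$emb, w$convW_r, w$convB_r, tk, K)
    sc <- .stackForward(w$emb, w$convW_c, w$convB_c, tk, K)
    Hr <- .relu(sr$A); Hc <- .relu(sc$A)
    Hrd <- if (is.null(dropMask)) Hr else Hr * dropMask[[1]]
    Hcd <- if (is.null(dropMask)) Hc else Hc * dropMask[[2]]
    r <- drop(Hrd %*% w$rateW) + w$rateB
    z <- Hcd %*% w$cspW + matrix(w$cspB, prep$L, 5L, byrow = TRUE)
    cache <- c(cache, list(sr = sr, sc = sc, Hr = Hr, Hc = Hc, Hrd = Hrd, Hcd = Hcd))
  } else {
    sr <- .stackForward(w$emb_r, w$convW_r, w$convB_r, tk, K)
    s1 <- .stackForward(w$emb_c1, w$convW_c1, w$convB_c1, tk, K)
    s2 <- .stackForward(w$emb_c2, w$convW_c2, w$convB_c2, tk, K)
    Hr <- .relu(sr$A)
    Ac <- s1$A + s2$A
    Hc <- .relu(Ac)
    Hrd <- if (is.null(dropMask)) Hr else Hr * dropMask[[1]]
    Hcd <- if (is.null(dropMask)) Hc else Hc * dropMask[[2]]
    r <- drop(Hrd %*% w$rateW) + w$rateB
    z <- Hcd %*% w$cspW + matrix(w$cspB, prep$L, 5L, byrow = TRUE)
    cache <- c(cache, list(sr = sr, s1 = s1, s2 = s2, Hr = Hr, Ac = Ac, Hc = Hc,
                           Hrd = Hrd, Hcd = Hcd))
  }
  list(r = r, z = z, cache = cache)
}

.backward <- function(model, prep, out, gr, Gz) {
  if (is(model, "ThriftyModel")) return(.backwardThrifty(model, prep, out, gr, Gz))
  if (is(model, "FivemerModel")) return(.backwardFivemer(model, prep, out, gr, Gz, NULL))
  if (is(model, "SitewiseFivemerModel"))
    return(.backwardFivemer(model@fivemer, prep, out, gr, Gz, model))
  stop("unknown model class")
}

.backwardThrifty <- function(model, prep, out, gr, Gz) {
  w <- model@weights
  cfg <- model@config
  K <- cfg@kernel; E <- cfg@embed
  tk <- prep$tokens
  ca <- out$cache
  dm <- ca$dropMask
  if (cfg@wiring == "joined") {
    GHd <- gr %o% w$rateW + Gz %*% t(w$cspW)
    GH <- if (is.null(dm)) GHd else GHd * dm[[1]]
    GA <- GH * (ca$s$A > 0)
    g <- .stackBackward(GA, ca$s, w$convW, K, E, tk)
    list(emb = g$emb, convW = g$convW, convB = g$convB,
         rateW = drop(t(ca$Hd) %*% gr), rateB = sum(gr),
         cspW = t(ca$Hd) %*% Gz, cspB = colSums(Gz))
  } else if (cfg@wiring == "hybrid") {
    GHr <- gr %o% w$rateW
    GHr <- if (is.null(dm)) GHr else GHr * dm[[1]]
    GHc <- Gz %*% t(w$cspW)
    GHc <- if (is.null(dm)) GHc else GHc * dm[[2]]
    GAr <- GHr * (ca$sr$A > 0)
    GAc <- GHc * (ca$sc$A > 0)
    gr_ <- .stackBackward(GAr, ca$sr, w$convW_r, K, E, tk)
    gc_ <- .stackBackward(GAc, ca$sc, w$convW_c, K, E, tk)
    list(emb = gr_$emb + gc_$emb,
         convW_r = gr_$convW, convB_r = gr_$convB,
         convW_c = gc_$convW, convB_c = gc_$convB,
         rateW = drop(t(ca$Hrd) %*% gr), rateB = sum(gr),
         cspW = t(ca$Hcd) %*% Gz, cspB = colSums(Gz))
  } else {
    GHr <- gr %o% w$rateW
    GHr <- if (is.null(dm)) GHr else GHr * dm[[1]]
    GHc <- Gz %*% t(w$cspW)
    GHc <- if (is.null(dm)) GHc else GHc * dm[[2]]
    GAr <- GHr * (ca$sr$A > 0)
    GAc <- GHc * (ca$Ac > 0)
    g_r <- .stackBackward(GAr, ca$sr, w$convW_r, K, E, tk)
    g_1 <- .stackBackward(GAc, ca$s1, w$convW_c1, K, E, tk)
    g_2 <- .stackBackward(GAc, ca$s2, w$convW_c2, K, E, tk)
    list(emb_r = g_r$emb, convW_r = g_r$convW, convB_r = g_r$convB,
         emb_c1 = g_1$emb, convW_c1 = g_1$convW, convB_c1 = g_1$convB,
         emb_c2 = g_2$emb, convW_c2 = g_2$convW, convB_c2 = g_2$convB,
         rateW = drop(t(ca$Hrd) %*% gr), rateB = sum(gr),
         cspW = t(ca$Hcd) %*% Gz, cspB = colSums(Gz))
  }
}

# -- FivemerModel / SitewiseFivemerModel --------------------------------------

.forwardFivemer <- function(fv, prep, sitewise) {
  idx <- .kmerIdx1(prep$parent, 5L)
  r <- fv@logRate[idx]
  if (!is.null(sitewise)) {
    sites0 <- seq_len(prep$L) - 1L
    inR <- sites0 >= sitewise@siteRange[1] & sites0 <= sitewise@siteRange[2]
    r[inR] <- r[inR] + sitewise@logSiteFactor[sites0[inR] - sitewise@siteRange[1] + 1L]
    cache <- list(idx = idx, inR = inR, sites0 = sites0)
  } else {
    cache <- list(idx = idx)
  }
  z <- fv@cspLogits[idx, , drop = FALSE]
  list(r = r, z = z, cache = cache)
}

.backwardFivemer <- function(fv, prep, out, gr, Gz, sitewise) {
  idx <- out$cache$idx
  gLogRate <- numeric(1025L)
  acc <- rowsum(gr, group = idx, reorder = FALSE)
  gLogRate[as.integer(rownames(acc))] <- acc
  gCsp <- matrix(0, 1025L, 5L)
  accZ <- rowsum(Gz, group = idx, reorder = FALSE)
  gCsp[as.integer(rownames(accZ)), ] <- accZ
  g <- list(logRate = gLogRate, cspLogits = gCsp)
  if (!is.null(sitewise)) {
    gs <- numeric(length(sitewise@logSiteFactor))
    inR <- out$cache$inR
    pos <- out$cache$sites0[inR] - sitewise@siteRange[1] + 1L
    gs[pos] <- gr[inR]
    g$logSiteFactor <- gs
  }
  g
}

# -- CSP normalization ---------------------------------------------------------

# logits L x 5 -> L x 4 probabilities with parent base and ambiguity masked out
.cspFromLogits <- function(z, parentIdx) {
  L <- nrow(z)
  z4 <- z[, 1:4, drop = FALSE]
  ok <- !is.na(parentIdx)
  z4[cbind(which(ok), parentIdx[ok])] <- -Inf
  mx <- apply(z4, 1L, max)
  ez <- exp(z4 - mx)
  p <- ez / rowSums(ez)
  p[!ok, ] <- NA_real_
  p
}

#' Predict per-site rates and substitution probabilities
#'
#' Runs a model's deterministic (evaluation-mode) forward pass on one
#' parent sequence: 3-mer (or 5-mer) context lookup, convolution with
#' symmetric zero padding so every site gets a prediction, rectifier
#' nonlinearity, and the two affine heads. Rates are `exp` of the rate-head
#' output; CSP rows are a softmax over the head outputs after forcing the
#' ambiguity column and the parent-base column to `-Inf`, yielding a
#' distribution over the three non-parent bases. Sites with an ambiguous
#' parent base are flagged and carry NA CSP rows.
#'
#' @param model a [ThriftyModel-class], [FivemerModel-class], or
#'   [SitewiseFivemerModel-class].
#' @param parent a parent sequence string.
#' @return a [RatePrediction-class].
#' @export
predictRates <- function(model, parent) {
  ch <- .checkSeq(parent, "parent")
  prep <- .prepPair(parent, parent, rep(TRUE, length(ch)), 0)
  if (is(model, "TrueModel")) {
    idx <- .kmerIdx1(parent, model@k)
    csp <- matrix(NA_real_, prep$L, 4L, dimnames = list(NULL, .NUC))
    for (i in seq_len(prep$L)) {
      if (is.na(prep$parentIdx[i])) next
      if (idx[i] <= nrow(model@csp)) {
        csp[i, ] <- model@csp[idx[i], ]
      } else {
        csp[i, ] <- 1 / 3
        csp[i, prep$parentIdx[i]] <- 0
      }
    }
    return(new("RatePrediction",
      rates = .trueRates(model, parent), csp = csp,
      flagged = is.na(prep$parentIdx)
    ))
  }
  out <- .forward(model, prep, dropMask = NULL)
  new("RatePrediction",
    rates = exp(out$r),
    csp = .cspFromLogits(out$z, prep$parentIdx),
    flagged = is.na(prep$parentIdx)
  )
}

setMethod("show", "RatePrediction", function(object) {
  cat(sprintf("RatePrediction over %d sites (%d flagged ambiguous)\n",
              length(object@rates), sum(object@flagged)))
  cat(sprintf("  rate range: [%.4g, %.4g]\n",
              min(object@rates), max(object@rates)))
})

#' @rdname predictRates
#' @param x a RatePrediction.
#' @export
siteRates <- function(x) x@rates

#' @rdname predictRates
#' @export
cspMatrix <- function(x) x@csp

#' Empirical context width by perturbation scan
#'
#' Measures, rather than derives, a model's effective nucleotide context:
#' on random sequences, every position is perturbed to every alternative
#' base and the widest window around a focal site whose perturbation
#' changes the site's predicted rate or CSP row is recorded. For a thrifty
#' model this equals [receptiveField()] of its configuration.
#'
#' @param model a model with a [predictRates()] method.
#' @param length sequence length for the scan.
#' @param nSeq number of random sequences scanned (max is reported, since a
#'   rectifier can silence individual filters on a particular sequence).
#' @param seed RNG seed for the scan sequences.
#' @param tol absolute change regarded as a real effect.
#' @return integer observed context width in nucleotides.
#' @export
empiricalContextWidth <- function(model, length = 60L, nSeq = 5L, seed = 1L,
                                  tol = 1e-12) {
  old <- .Random.seed.exists()
  set.seed(seed)
  focal <- as.integer(ceiling(length / 2))
  maxOff <- 0L
  for (s in seq_len(nSeq)) {
    ch <- sample(.NUC, length, replace = TRUE)
    base <- predictRates(model, paste0(ch, collapse = ""))
    for (pos in seq_len(length)) {
      for (b in setdiff(.NUC, ch[pos])) {
        ch2 <- ch
        ch2[pos] <- b
        pert <- predictRates(model, paste0(ch2, collapse = ""))
        moved <- abs(pert@rates[focal] - base@rates[focal]) > tol ||
          any(abs(pert@csp[focal, ] - base@csp[focal, ]) > tol, na.rm = TRUE)
        if (moved) maxOff <- max(maxOff, abs(pos - focal))
      }
    }
  }
  .restoreSeed(old)
  2L * maxOff + 1L
}
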