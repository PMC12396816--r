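#' Construct a generative truth model
#'
#' @param k odd context width.
#' @param rate named numeric vector over all 4^k k-mers.
#' @param csp 4^k x 4 matrix of substitution probabilities (zero at the
#'   center base).
#' @return a [TrueModel-class].
#' @export
trueModel <- function(k, rate, csp) {
  kmers <- .allKmers(as.integer(k))
  if (is.null(names(rate)) || !setequal(names(rate), kmers))
    stop("rate must be named by all 4^k k-mers")
  if (is.null(rownames(csp))) rownames(csp) <- names(rate)
  rate <- rate[kmers] # canonical order assumed by context indexing
  csp <- csp[kmers, , drop = FALSE]
  obj <- new("TrueModel", k = as.integer(k), rate = rate, csp = csp)
  validObject(obj)
  obj
}

setMethod("show", "TrueModel", function(object) {
  cat(sprintf("TrueModel: %d-mer context, rate range [%.3g, %.3g]\n",
              object@k, min(object@rate), max(object@rate)))
})

#' Draw a random context-dependent truth model
#'
#' Rates are log-normal across k-mers; with the default `sdLog = 1` the
#' hottest and coldest contexts differ by roughly two orders of magnitude,
#' matching the dynamic range of empirical SHM hot/cold spots. CSP rows are
#' Dirichlet draws over the three non-center bases with a transition-biased
#' base measure (`alpha` ordered as transition, transversion, transversion),
#' reflecting the strong transition preference of SHM spectra.
#'
#' @param k odd context width.
#' @param seed RNG seed.
#' @param meanLog,sdLog log-normal parameters of the rate table.
#' @param alpha length-3 Dirichlet concentration (transition first).
#' @return a [TrueModel-class].
#' @export
randomTrueModel <- function(k = 3L, seed = 1L, meanLog = 0, sdLog = 1,
                            alpha = c(12, 2, 2)) {
  old <- .Random.seed.exists()
  set.seed(seed)
  kmers <- .allKmers(k)
  nk <- length(kmers)
  rate <- stats::setNames(exp(stats::rnorm(nk, meanLog, sdLog)), kmers)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ctr <- substr(kmers, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  csp <- matrix(0, nk, 4L, dimnames = list(kmers, .NUC))
  for (i in seq_len(nk)) {
    others <- setdiff(.NUC, ctr[i])
    # order targets: transition partner first, then transversions
    ord <- c(transition[[ctr[i]]], setdiff(others, transition[[ctr[i]]]))
    g <- stats::rgamma(3L, shape = alpha)
    csp[i, ord] <- g / sum(g)
  }
  .restoreSeed(old)
  trueModel(k, rate, csp)
}

#' Random parent sequence
#'
#' @param length sequence length (>= 1).
#' @param seed RNG seed.
#' @return a sequence string, i.i.d. uniform over A, C, G, T.
#' @export
randomParent <- function(length, seed = 1L) {
  .checkScalar(length, "length", function(v) v >= 1, "must be >= 1")
  old <- .Random.seed.exists()
  set.seed(seed)
  s <- paste0(sample(.NUC, length, replace = TRUE), collapse = "")
  .restoreSeed(old)
  s
}

# per-site rates of a truth model on a parent; boundary/ambiguous contexts
# get the geometric-mean rate of the table (neutral fallback)
.trueRates <- function(tm, parent) {
  idx <- .kmerIdx1(parent, tm@k)
  fallback <- exp(mean(log(tm@rate)))
  r <- c(tm@rate, fallback)[idx]
  unname(r)
}

#' Simulate a child sequence under a truth model
#'
#' Each site of the parent mutates independently with probability
#' `1 - exp(-t * lambda(context))`, the context being read from the parent
#' (mutations are treated as simultaneous, so a site's context never
#' includes another site's new base). Mutated sites draw their new base
#' from the context's CSP row; sites with boundary/ambiguous contexts use
#' the table's geometric-mean rate and a uniform CSP over non-parent bases.
#' Parent N sites are copied unchanged.
#'
#' @param parent parent sequence string.
#' @param tm a [TrueModel-class].
#' @param t nonnegative branch length.
#' @param seed RNG seed.
#' @return the child sequence string.
#' @export
simulateChild <- function(parent, tm, t, seed = 1L) {
  ch <- .checkSeq(parent, "parent")
  .checkScalar(t, "t", function(v) v >= 0, "must be nonnegative")
  old <- .Random.seed.exists()
  set.seed(seed)
  lam <- .trueRates(tm, parent)
  p <- -expm1(-t * lam)
  informative <- ch %in% .NUC
  mut <- stats::runif(length(ch)) < p & informative
  idx <- .kmerIdx1(parent, tm@k)
  out <- ch
  for (i in which(mut)) {
    if (idx[i] <= nrow(tm@csp)) {
      probs <- tm@csp[idx[i], ]
    } else {
      probs <- stats::setNames(rep(1 / 3, 4), .NUC)
      probs[ch[i]] <- 0
    }
    out[i] <- sample(.NUC, 1L, prob = probs)
  }
  .restoreSeed(old)
  paste0(out, collapse = "")
}

#' Simulator configuration
#'
#' @param nPairs number of parent-child pairs.
#' @param length sequence length.
#' @param branchLengths either a single fixed t, a numeric vector recycled
#'   over pairs, or the string "loguniform" for the default law: t
#'   log-uniform on [0.005, 0.1], spanning typical per-pair mutation loads
#'   of clonal-family edges.
#' @param germline optional fixed parent sequence; random uniform per pair
#'   when NULL.
#' @param inFrame generate in-frame productive-style parents (start codon,
#'   no in-frame stop codons) for synonymous-masking fixtures.
#' @param seed RNG seed.
#' @return a list of class "simConfig".
#' @export
simConfig <- function(nPairs, length, branchLengths = "loguniform",
                      germline = NULL, inFrame = FALSE, seed = 1L) {
  stopifnot(nPairs >= 1L, length >= 1L)
  structure(list(
    nPairs = as.integer(nPairs), length = as.integer(length),
    branchLengths = branchLengths, germline = germline,
    inFrame = isTRUE(inFrame), seed = as.integer(seed)
  ), class = "simConfig")
}

.stopCodons <- c("TAA", "TAG", "TGA")

# in-frame parent: ATG then codons drawn uniformly among non-stop codons
.randomInFrameParent <- function(length) {
  codons <- setdiff(.allKmers(3L), .stopCodons)
  nCodon <- ceiling(length / 3)
  s <- paste0(c("ATG", sample(codons, nCodon, replace = TRUE)), collapse = "")
  substr(s, 1L, length)
}

#' Simulate a PcpSet from a truth model
#'
#' Draws parents (random uniform, in-frame, or a provided germline),
#' branch lengths from the configured law, and children via
#' [simulateChild()]. True branch lengths are recorded in the provenance;
#' the stored branch lengths are recomputed as normalized mutation counts,
#' mimicking the offsets of the real data pipeline. Deterministic under
#' the config seed.
#'
#' @param config a [simConfig()].
#' @param tm a [TrueModel-class].
#' @return a [PcpSet-class].
#' @export
simulateDataset <- function(config, tm) {
  stopifnot(inherits(config, "simConfig"), is(tm, "TrueModel"))
  old <- .Random.seed.exists()
  set.seed(config$seed)
  n <- config$nPairs
  t <- if (identical(config$branchLengths, "loguniform")) {
    exp(stats::runif(n, log(0.005), log(0.1)))
  } else {
    rep_len(as.numeric(config$branchLengths), n)
  }
  if (any(t < 0) || any(!is.finite(t))) stop("invalid branch-length specification")
  parents <- children <- character(n)
  childSeeds <- sample.int(.Machine$integer.max %/% 2L, n)
  parentSeeds <- sample.int(.Machine$integer.max %/% 2L, n)
  for (i in seq_len(n)) {
    parents[i] <- if (!is.null(config$germline)) {
      config$germline
    } else if (config$inFrame) {
      set.seed(parentSeeds[i])
      .randomInFrameParent(config$length)
    } else {
      randomParent(config$length, seed = parentSeeds[i])
    }
    children[i] <- simulateChild(parents[i], tm, t[i], seed = childSeeds[i])
  }
  .restoreSeed(old)
  PcpSet(parents, children,
         sampleId = "sim", familyId = sprintf("sim%04d", seq_len(n)),
         provenance = list(trueBranchLengths = t, seed = config$seed))
}

#' Parameter-recovery summary between a truth model and a fitted model
#'
#' Evaluates both models on probe sequences and reports (i) the Spearman
#' rank correlation between fitted and true per-site rates and (ii) the
#' mean total-variation distance between fitted and true CSP rows, over
#' unambiguous interior probe sites.
#'
#' @param tm the generative [TrueModel-class].
#' @param fitted a fitted model accepted by [predictRates()], or a second
#'   [TrueModel-class].
#' @param probes character vector of probe sequences.
#' @return list with `rateRankCorrelation` and `meanCspTV`.
#' @export
parameterRecoveryReport <- function(tm, fitted, probes) {
  if (length(probes) == 0L) stop("empty probe set")
  h <- (tm@k - 1L) / 2
  trueR <- fitR <- numeric(0)
  tvs <- numeric(0)
  for (s in probes) {
    ch <- .charMat(s)
    L <- length(ch)
    interior <- seq_len(L) > h & seq_len(L) <= L - h & ch %in% .NUC
    idx <- .kmerIdx1(s, tm@k)
    interior <- interior & idx <= length(tm@rate)
    tR <- .trueRates(tm, s)
    tC <- tm@csp[pmin(idx, nrow(tm@csp)), , drop = FALSE]
    if (is(fitted, "TrueModel")) {
      fR <- .trueRates(fitted, s)
      fC <- fitted@csp[pmin(.kmerIdx1(s, fitted@k), nrow(fitted@csp)), , drop = FALSE]
    } else {
      pred <- predictRates(fitted, s)
      fR <- pred@rates
      fC <- pred@csp
    }
    trueR <- c(trueR, tR[interior])
    fitR <- c(fitR, fR[interior])
    tvs <- c(tvs, rowSums(abs(tC[interior, , drop = FALSE] -
                              fC[interior, , drop = FALSE])) / 2)
  }
  list(
    rateRankCorrelation = stats::cor(trueR, fitR, method = "spearman"),
    meanCspTV = mean(tvs)
  )
}

#' Read / write truth-model tables
#'
#' Truth models are stored as tab-separated text with columns `kmer`,
#' `rate`, `csp_A`, `csp_C`, `csp_G`, `csp_T` at full precision.
#'
#' @param tm a [TrueModel-class].
#' @param path file path.
#' @return `readTrueModel` returns a [TrueModel-class].
#' @export
writeTrueModel <- function(tm, path) {
  df <- data.frame(
    kmer = names(tm@rate), rate = .fmtNum(tm@rate),
    csp_A = .fmtNum(tm@csp[, 1]), csp_C = .fmtNum(tm@csp[, 2]),
    csp_G = .fmtNum(tm@csp[, 3]), csp_T = .fmtNum(tm@csp[, 4])
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrueModel
#' @export
readTrueModel <- function(path) {
  df <- utils::read.delim(path, colClasses = c(kmer = "character"))
  k <- nchar(df$kmer[1])
  csp <- as.matrix(df[, c("csp_A", "csp_C", "csp_G", "csp_T")])
  dimnames(csp) <- list(df$kmer, .NUC)
  trueModel(k, stats::setNames(df$rate, df$kmer), csp)
}
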