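#' @import methods
NULL

.NUC <- c("A", "C", "G", "T")
.NUC_N <- c("A", "C", "G", "T", "N")

#' PcpSet: a collection of aligned parent-child sequence pairs
#'
#' A `PcpSet` holds parent-child pairs (PCPs): aligned, gap-free nucleotide
#' sequences over the alphabet A, C, G, T, N, where each pair corresponds to
#' one edge of a clonal-family phylogeny. Each pair carries a branch length
#' `t` on the expected-substitutions-per-site scale and a per-site loss mask
#' marking the sites that contribute to likelihoods and metrics. The mask is
#' always FALSE where either sequence carries the ambiguity symbol N.
#'
#' @slot parent character vector of parent sequences.
#' @slot child character vector of child sequences (same lengths as parents).
#' @slot branchLength numeric vector of nonnegative branch lengths.
#' @slot sampleId character vector of sample identifiers.
#' @slot familyId character vector of clonal-family identifiers.
#' @slot lossMask list of logical vectors, one per pair.
#' @slot provenance free-text metadata list.
#'
#' @name PcpSet-class
#' @rdname PcpSet-class
#' @exportClass PcpSet
setClass("PcpSet",
  representation(
    parent = "character",
    child = "character",
    branchLength = "numeric",
    sampleId = "character",
    familyId = "character",
    lossMask = "list",
    provenance = "list"
  )
)

setValidity("PcpSet", function(object) {
  n <- length(object@parent)
  if (length(object@child) != n) return("parent and child differ in length")
  if (length(object@branchLength) != n) return("branchLength wrong length")
  if (length(object@sampleId) != n) return("sampleId wrong length")
  if (length(object@familyId) != n) return("familyId wrong length")
  if (length(object@lossMask) != n) return("lossMask wrong length")
  for (i in seq_len(n)) {
    if (nchar(object@parent[i]) != nchar(object@child[i]))
      return(sprintf("pair %d: parent and child sequences differ in length", i))
    if (nchar(object@parent[i]) < 1L)
      return(sprintf("pair %d: empty sequence", i))
    if (length(object@lossMask[[i]]) != nchar(object@parent[i]))
      return(sprintf("pair %d: loss mask length mismatch", i))
    amb <- .charMat(object@parent[i]) == "N" | .charMat(object@child[i]) == "N"
    if (any(object@lossMask[[i]] & amb))
      return(sprintf("pair %d: loss mask TRUE at an ambiguous (N) site", i))
  }
  if (any(object@branchLength < 0)) return("negative branch length")
  TRUE
})

#' Thrifty model architecture hyperparameters
#'
#' Architecture of a thrifty convolutional SHM model: an odd convolutional
#' kernel width `kernel` applied to trainable `embed`-dimensional embeddings
#' of overlapping 3-mers, producing `filters` feature channels feeding affine
#' rate and conditional-substitution-probability (CSP) heads. Because a
#' 3-mer adds one base on either side of the kernel window, the effective
#' nucleotide context is `kernel + 2`. `wiring` selects how the two outputs
#' share structure: \describe{
#'   \item{joined}{one embedding + convolution stack feeds both heads;}
#'   \item{hybrid}{a shared embedding with one convolution stack per head;}
#'   \item{independent}{a rate sub-model (embedding + stack + rate head) and
#'     a CSP sub-model (two embedding + stack branches combined by
#'     element-wise addition before the CSP head).}
#' }
#'
#' @slot kernel odd positive integer, convolutional kernel width.
#' @slot embed positive integer, 3-mer embedding dimension.
#' @slot filters positive integer, number of convolutional filters.
#' @slot dropout dropout probability in [0, 1), active only in training.
#' @slot wiring one of "joined", "hybrid", "independent".
#'
#' @name ThriftyConfig-class
#' @rdname ThriftyConfig-class
#' @exportClass ThriftyConfig
setClass("ThriftyConfig",
  representation(
    kernel = "integer",
    embed = "integer",
    filters = "integer",
    dropout = "numeric",
    wiring = "character"
  )
)

setValidity("ThriftyConfig", function(object) {
  if (length(object@kernel) != 1L || object@kernel < 1L)
    return("kernel must be a positive integer")
  if (object@kernel %% 2L == 0L)
    return("kernel must be odd (symmetric context)")
  if (object@embed < 1L) return("embed must be >= 1")
  if (object@filters < 1L) return("filters must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (!object@wiring %in% c("joined", "hybrid", "independent"))
    return("wiring must be one of joined, hybrid, independent")
  TRUE
})

#' A thrifty convolutional SHM model
#'
#' Trainable weights plus a [ThriftyConfig-class] architecture. Weights are
#' held as a named list of numeric arrays; their total scalar count always
#' equals [countParams()] of the configuration.
#'
#' @slot config a [ThriftyConfig-class].
#' @slot weights named list of numeric arrays.
#'
#' @name ThriftyModel-class
#' @rdname ThriftyModel-class
#' @exportClass ThriftyModel
setClass("ThriftyModel",
  representation(config = "ThriftyConfig", weights = "list")
)

#' A 5-mer lookup-table SHM model
#'
#' The classical k-mer baseline at k = 5: one log-rate scalar and one row of
#' CSP logits per unambiguous 5-mer (1024 of them) plus one ambiguity token
#' used for any window containing N or truncated by a sequence boundary.
#' The forward pass is a pure table lookup; the effective context width is 5.
#'
#' @slot logRate numeric vector of length 1025.
#' @slot cspLogits numeric 1025 x 5 matrix (columns A, C, G, T, ambiguity).
#'
#' @name FivemerModel-class
#' @rdname FivemerModel-class
#' @exportClass FivemerModel
setClass("FivemerModel",
  representation(logRate = "numeric", cspLogits = "matrix")
)

setValidity("FivemerModel", function(object) {
  if (length(object@logRate) != 1025L) return("logRate must have length 1025")
  if (!all(dim(object@cspLogits) == c(1025L, 5L)))
    return("cspLogits must be 1025 x 5")
  TRUE
})

#' A per-site x 5-mer SHM model
#'
#' A 5-mer mutability table combined multiplicatively with a per-site factor
#' over a fixed site range: rate(i) = exp(log gamma(5-mer at i) + log s_i),
#' with s_i = 1 outside the range. Fitting applies a small squared-magnitude
#' penalty (coefficient 1e-4) on the per-site log factors to keep the
#' per-site component from absorbing context effects.
#'
#' @slot fivemer a [FivemerModel-class] holding the 5-mer component.
#' @slot siteRange integer 0-based inclusive range covered by site factors.
#' @slot logSiteFactor numeric vector, one log factor per site in the range.
#'
#' @name SitewiseFivemerModel-class
#' @rdname SitewiseFivemerModel-class
#' @exportClass SitewiseFivemerModel
setClass("SitewiseFivemerModel",
  representation(
    fivemer = "FivemerModel",
    siteRange = "integer",
    logSiteFactor = "numeric"
  )
)

setValidity("SitewiseFivemerModel", function(object) {
  if (length(object@siteRange) != 2L || object@siteRange[1] > object@siteRange[2])
    return("siteRange must be an ordered pair")
  if (object@siteRange[1] < 0L) return("siteRange must be nonnegative (0-based)")
  if (length(object@logSiteFactor) != diff(object@siteRange) + 1L)
    return("logSiteFactor length must match siteRange")
  TRUE
})

#' Per-site rate and CSP predictions for one parent sequence
#'
#' @slot rates numeric vector of strictly positive per-site rates lambda_i.
#' @slot csp L x 4 matrix of conditional substitution probabilities
#'   (columns A, C, G, T); each unflagged row sums to 1 with zero mass on
#'   the parent base.
#' @slot flagged logical; TRUE where the parent base is ambiguous, in which
#'   case the CSP row is NA.
#'
#' @name RatePrediction-class
#' @rdname RatePrediction-class
#' @exportClass RatePrediction
setClass("RatePrediction",
  representation(rates = "numeric", csp = "matrix", flagged = "logical")
)

#' Generative truth model for the mutation simulator
#'
#' A context-dependent mutation process over k-mers: each k-mer has a
#' strictly positive rate and a CSP row over the three non-center bases.
#' Used to simulate parent-child pairs and as the reference in
#' parameter-recovery experiments.
#'
#' @slot k odd context width.
#' @slot rate named numeric vector of length 4^k (names are k-mers).
#' @slot csp 4^k x 4 matrix, rows summing to 1 with 0 at the center base.
#'
#' @name TrueModel-class
#' @rdname TrueModel-class
#' @exportClass TrueModel
setClass("TrueModel",
  representation(k = "integer", rate = "numeric", csp = "matrix")
)

setValidity("TrueModel", function(object) {
  if (object@k %% 2L == 0L) return("k must be odd")
  nk <- 4L^object@k
  if (length(object@rate) != nk) return("rate table must have 4^k entries")
  if (any(object@rate <= 0)) return("rates must be strictly positive")
  if (!all(dim(object@csp) == c(nk, 4L))) return("csp must be 4^k x 4")
  if (any(abs(rowSums(object@csp) - 1) > 1e-8)) return("csp rows must sum to 1")
  ctr <- substr(names(object@rate), (object@k + 1L) %/% 2L, (object@k + 1L) %/% 2L)
  if (any(object@csp[cbind(seq_len(nk), match(ctr, .NUC))] != 0))
    return("csp must place zero mass on the center base")
  TRUE
})

#' Model evaluation report
#'
#' All SHM model-assessment quantities computed on one dataset: ranking
#' metrics for mutation placement (AUROC, AUPRC, R-precision), substitution
#' accuracy of the CSP head, the binned observed/expected overlap statistic,
#' mean per-site log-likelihood, and the prevalence rho (mutated sites /
#' sites), which is the random-classifier baseline of AUPRC and R-precision.
#'
#' @slot auroc,auprc,rPrecision,substitutionAccuracy,overlap numeric in [0,1].
#' @slot meanLogLik mean per-site log-likelihood (<= 0).
#' @slot prevalence rho = mutated sites / sites.
#' @slot binned list with bin edges, observed counts O and expected counts E.
#' @slot nSites,nMutated integer counts of evaluated and mutated sites.
#'
#' @name MetricReport-class
#' @rdname MetricReport-class
#' @exportClass MetricReport
setClass("MetricReport",
  representation(
    auroc = "numeric", auprc = "numeric", rPrecision = "numeric",
    substitutionAccuracy = "numeric", overlap = "numeric",
    meanLogLik = "numeric", prevalence = "numeric",
    binned = "list", nSites = "integer", nMutated = "integer"
  )
)
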