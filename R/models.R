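#' Create a thrifty model configuration
#'
#' @param kernel odd positive integer kernel width (effective nucleotide
#'   context is `kernel + 2`).
#' @param embed 3-mer embedding dimension.
#' @param filters number of convolutional filters.
#' @param dropout dropout probability in [0, 1).
#' @param wiring "joined", "hybrid", or "independent" (see
#'   [ThriftyConfig-class]).
#' @return a [ThriftyConfig-class].
#' @examples
#' cfg <- thriftyConfig(kernel = 11, embed = 7, filters = 19,
#'                      dropout = 0.3, wiring = "joined")
#' countParams(cfg)  # 2057
#' @export
thriftyConfig <- function(kernel = 11L, embed = 7L, filters = 19L,
                          dropout = 0.3, wiring = "joined") {
  obj <- new("ThriftyConfig",
    kernel = as.integer(kernel), embed = as.integer(embed),
    filters = as.integer(filters), dropout = as.numeric(dropout),
    wiring = as.character(wiring)
  )
  validObject(obj)
  obj
}

setMethod("show", "ThriftyConfig", function(object) {
  cat(sprintf(
    "ThriftyConfig: wiring=%s kernel=%d embed=%d filters=%d dropout=%g (%d params, %d-mer context)\n",
    object@wiring, object@kernel, object@embed, object@filters,
    object@dropout, countParams(object), receptiveField(object)
  ))
})

#' Closed-form trainable-parameter count of a thrifty configuration
#'
#' One embedding + convolution stack costs `65 E + (E F K + F)` scalars
#' (65-token embedding table, biased width-K convolution); the rate head
#' costs `F + 1` and the CSP head `5 F + 5`. The joined wiring uses one
#' stack, the hybrid one embedding and two convolutions, and the
#' independent wiring three full stacks. Because the convolution acts on
#' 3-mer embeddings, parameters grow linearly -- not exponentially -- in
#' the context width. The count always equals an exhaustive enumeration of
#' the scalars in [buildThriftyModel()]'s weights.
#'
#' @param config a [ThriftyConfig-class].
#' @return integer number of trainable scalars.
#' @export
countParams <- function(config) {
  stopifnot(is(config, "ThriftyConfig"))
  validObject(config)
  K <- config@kernel; E <- config@embed; F <- config@filters
  emb <- 65L * E
  conv <- E * F * K + F
  stack <- emb + conv
  heads <- (F + 1L) + (5L * F + 5L)
  switch(config@wiring,
    joined = stack + heads,
    hybrid = emb + 2L * conv + heads,
    independent = 3L * stack + heads
  )
}

#' Effective nucleotide context width
#'
#' A kernel of width K slides over K consecutive 3-mer embeddings; the
#' outermost 3-mers each contribute one base beyond the kernel span, so the
#' model is effectively a (K + 2)-mer model: kernel 9 gives an 11-mer model
#' and kernel 11 a 13-mer model.
#'
#' @param config a [ThriftyConfig-class] or an odd kernel width.
#' @return integer context width in nucleotides.
#' @export
receptiveField <- function(config) {
  K <- if (is(config, "ThriftyConfig")) config@kernel else {
    .checkScalar(config, "kernel", function(v) v >= 1 && v %% 2 == 1,
                 "must be a positive odd integer")
    as.integer(config)
  }
  K + 2L
}

# one embedding (65 x E) + biased conv (K*E x F) stack, seeded draws
.initStack <- function(K, E, F) {
  list(
    emb = matrix(stats::rnorm(65L * E, sd = 0.3), 65L, E),
    convW = matrix(stats::rnorm(K * E * F, sd = sqrt(2 / (K * E))), K * E, F),
    convB = stats::rnorm(F, sd = 0.01)
  )
}

.initHeads <- function(F) {
  list(
    rateW = stats::rnorm(F, sd = sqrt(1 / F)),
    rateB = stats::rnorm(1, sd = 0.01),
    cspW = matrix(stats::rnorm(5L * F, sd = sqrt(1 / F)), F, 5L),
    cspB = stats::rnorm(5, sd = 0.01)
  )
}

#' Build a thrifty model with seeded random initialization
#'
#' Allocates the trainable weights of the configured architecture from
#' seeded pseudo-random draws; the same seed and configuration always
#' produce bit-identical weights. See [ThriftyConfig-class] for the three
#' wirings.
#'
#' @param config a [ThriftyConfig-class].
#' @param seed integer RNG seed for the initial weights.
#' @return a [ThriftyModel-class].
#' @export
buildThriftyModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ThriftyConfig"))
  validObject(config)
  K <- config@kernel; E <- config@embed; F <- config@filters
  old <- .Random.seed.exists()
  set.seed(seed)
  w <- switch(config@wiring,
    joined = {
      s <- .initStack(K, E, F)
      c(list(emb = s$emb, convW = s$convW, convB = s$convB), .initHeads(F))
    },
    hybrid = {
      s <- .initStack(K, E, F)
      s2 <- .initStack(K, E, F) # only conv used; shared embedding
      c(list(emb = s$emb,
             convW_r = s$convW, convB_r = s$convB,
             convW_c = s2$convW, convB_c = s2$convB), .initHeads(F))
    },
    independent = {
      sr <- .initStack(K, E, F)
      sc1 <- .initStack(K, E, F)
      sc2 <- .initStack(K, E, F)
      c(list(emb_r = sr$emb, convW_r = sr$convW, convB_r = sr$convB,
             emb_c1 = sc1$emb, convW_c1 = sc1$convW, convB_c1 = sc1$convB,
             emb_c2 = sc2$emb, convW_c2 = sc2$convW, convB_c2 = sc2$convB),
        .initHeads(F))
    }
  )
  .restoreSeed(old)
  new("ThriftyModel", config = config, weights = w)
}

# preserve caller RNG state around seeded construction
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

setMethod("show", "ThriftyModel", function(object) {
  cat("ThriftyModel\n  ")
  show(object@config)
  cat(sprintf("  trainable scalars: %d\n", nParams(object)))
})

#' Total trainable scalars in a model (exhaustive enumeration)
#'
#' @param model a model object.
#' @return integer count of weight scalars.
#' @export
nParams <- function(model) {
  sum(vapply(.paramList(model), length, integer(1)))
}

#' Build a 5-mer table baseline model
#'
#' @param seed integer RNG seed for the initial tables.
#' @param sdLog spread of the initial log-rates.
#' @return a [FivemerModel-class].
#' @export
buildFivemerModel <- function(seed = 1L, sdLog = 0.01) {
  old <- .Random.seed.exists()
  set.seed(seed)
  m <- new("FivemerModel",
    logRate = stats::rnorm(1025L, sd = sdLog),
    cspLogits = matrix(stats::rnorm(1025L * 5L, sd = sdLog), 1025L, 5L)
  )
  .restoreSeed(old)
  m
}

#' Build a per-site x 5-mer model
#'
#' @param siteRange 0-based inclusive site range covered by per-site factors.
#' @param seed integer RNG seed.
#' @return a [SitewiseFivemerModel-class].
#' @export
buildSitewiseFivemerModel <- function(siteRange = c(0L, 399L), seed = 1L) {
  fv <- buildFivemerModel(seed = seed)
  new("SitewiseFivemerModel",
    fivemer = fv,
    siteRange = as.integer(siteRange),
    logSiteFactor = rep(0, diff(siteRange) + 1L)
  )
}

setMethod("show", "FivemerModel", function(object) {
  cat(sprintf("FivemerModel: 1024 + 1 contexts, %d trainable scalars\n",
              nParams(object)))
})

setMethod("show", "SitewiseFivemerModel", function(object) {
  cat(sprintf(
    "SitewiseFivemerModel: 5-mer table + per-site factors on sites %d-%d (%d scalars)\n",
    object@siteRange[1], object@siteRange[2], nParams(object)
  ))
})
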