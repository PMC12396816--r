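.MODEL_SCHEMA <- "thriftySHM-model/1"

#' Save / load a model as JSON
#'
#' Models are serialized to a versioned JSON container holding the model
#' type, configuration fields, and named flat weight arrays with their
#' dimensions, written at 17 significant digits so that `loadModel(saveModel(m))`
#' reproduces the weights (and therefore all predictions) bit-exactly.
#'
#' @param model a [ThriftyModel-class], [FivemerModel-class], or
#'   [SitewiseFivemerModel-class].
#' @param path output path.
#' @return `saveModel` invisibly returns `path`; `loadModel` returns the
#'   reconstructed model.
#' @export
saveModel <- function(model, path) {
  # doubles stored as %.17g strings: shortest representation that
  # round-trips IEEE doubles bit-exactly through text
  flat <- function(w) list(dim = dim(w) %||% length(w), data = .fmtNum(w))
  obj <- if (is(model, "ThriftyModel")) {
    cfg <- model@config
    list(
      schema = .MODEL_SCHEMA, type = "thrifty",
      config = list(kernel = cfg@kernel, embed = cfg@embed,
                    filters = cfg@filters, dropout = cfg@dropout,
                    wiring = cfg@wiring),
      weights = lapply(model@weights, flat)
    )
  } else if (is(model, "FivemerModel")) {
    list(schema = .MODEL_SCHEMA, type = "fivemer",
         weights = lapply(.paramList(model), flat))
  } else if (is(model, "SitewiseFivemerModel")) {
    list(schema = .MODEL_SCHEMA, type = "sitewise_fivemer",
         config = list(siteRange = model@siteRange),
         weights = lapply(.paramList(model), flat))
  } else {
    stop("unknown model class")
  }
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (!identical(obj$schema, .MODEL_SCHEMA))
    stop("unsupported model schema: ", obj$schema %||% "<missing>")
  unflat <- function(w) {
    d <- w$dim
    v <- as.numeric(w$data)
    if (length(d) > 1L) array(v, dim = d) else v
  }
  weights <- lapply(obj$weights, unflat)
  switch(obj$type,
    thrifty = {
      cfg <- thriftyConfig(obj$config$kernel, obj$config$embed,
                           obj$config$filters, obj$config$dropout,
                           obj$config$wiring)
      new("ThriftyModel", config = cfg, weights = weights)
    },
    fivemer = new("FivemerModel", logRate = weights$logRate,
                  cspLogits = weights$cspLogits),
    sitewise_fivemer = new("SitewiseFivemerModel",
      fivemer = new("FivemerModel", logRate = weights$logRate,
                    cspLogits = weights$cspLogits),
      siteRange = as.integer(obj$config$siteRange),
      logSiteFactor = weights$logSiteFactor
    ),
    stop("unknown model type: ", obj$type)
  )
}
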