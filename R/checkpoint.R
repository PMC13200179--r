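## Self-describing JSON checkpoints: config, provider, basis definition
## and all parameters, so a prediction is reproducible bit-for-bit across
## sessions from the file alone (for the built-in wACSF provider; external
## providers must be re-attached on load).

#' Save a model checkpoint
#'
#' @param model An \linkS4class{AweModel} or \linkS4class{AoModel}.
#' @param path Output file (JSON).
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  enc <- function(p) lapply(p, function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = NULL, data = as.vector(x)))
  obj <- if (is(model, "AweModel")) {
    list(type = "awe",
         config = model@config[setdiff(names(model@config), "nCenters")],
         nCenters = model@config$nCenters,
         provider = list(name = model@provider@name,
                         dim = model@provider@dim),
         basis = list(energy = model@basis@energy,
                      widthGroups = unique(model@basis@widths),
                      stride = model@basis@stride,
                      lambda = model@basis@lambda),
         params = enc(model@params))
  } else {
    list(type = "ao", config = model@config, params = enc(model@params))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the basis from its stored definition and restores every
#' parameter. For the built-in wACSF provider the descriptor pipeline is
#' reconstructed automatically; for external providers pass the provider.
#'
#' @param path Checkpoint file written by \code{\link{saveModel}}.
#' @param provider Optional \linkS4class{DescriptorProvider} overriding
#'   the stored provider name.
#' @return The restored model.
#' @export
readModel <- function(path, provider = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(p) lapply(p, function(x) {
    v <- as.numeric(x$data)
    if (!is.null(x$dim) && length(x$dim) == 2L)
      matrix(v, x$dim[1], x$dim[2]) else v
  })
  if (obj$type == "ao") {
    model <- aoModel(obj$config$dim, obj$config$nGrid, obj$config$hidden,
                     obj$config$energy, seed = obj$config$seed)
    model@params <- dec(obj$params)
    return(model)
  }
  if (is.null(provider)) {
    if (obj$provider$name != "wacsf")
      .stopf("checkpoint uses provider '%s'; pass it explicitly",
             obj$provider$name)
    provider <- wacsfProvider()
    if (provider@dim != obj$provider$dim)
      .stopf("stored wACSF dimension %d differs from default config",
             obj$provider$dim)
  }
  basis <- buildBasis(obj$basis$energy,
                      basisConfig(obj$basis$widthGroups, obj$basis$stride,
                                  obj$basis$lambda))
  cfg <- obj$config
  model <- aweModel(provider, basis, nShells = cfg$S, cutoff = cfg$cutoff,
                    nBlocks = cfg$L, dropout = cfg$dropout,
                    dLatent = cfg$dLatent, dHidden = cfg$dHidden,
                    epsilon = cfg$epsilon, seed = cfg$seed)
  model@params <- dec(obj$params)
  model
}
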