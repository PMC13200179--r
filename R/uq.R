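## Bootstrap-ensemble uncertainty quantification: members trained on
## with-replacement resamples of the training split (never the test set),
## prediction spread as the uncertainty estimate, and its Pearson
## correlation with the realized spectral error.

#' Train a bootstrap ensemble
#'
#' Each member is a fresh copy of the template model initialized and
#' trained with its own derived seed on a with-replacement resample of the
#' training data (resample size = training size). Resample indices are
#' recorded for audit. The same base seed reproduces the ensemble exactly.
#'
#' @param model Template model (untrained \linkS4class{AweModel} or
#'   \linkS4class{AoModel}); each member re-initializes its parameters.
#' @param data Prepared training data (see
#'   \code{\link{prepareTrainingData}}).
#' @param M Number of members (>= 2; default 8).
#' @param baseSeed Integer base seed.
#' @param config A \code{\link{trainConfig}}.
#' @return An \linkS4class{EnsembleModel}.
#' @export
bootstrapTrain <- function(model, data, M = 8L, baseSeed = 1L,
                           config = trainConfig()) {
  if (!.isCount(M) || M < 2L) .stopf("domain error: ensemble needs M >= 2")
  n <- ncol(data$Yraw)
  members <- vector("list", M)
  resampleIndex <- vector("list", M)
  seeds <- vapply(seq_len(M), function(m) .childSeed(baseSeed, m),
                  integer(1))
  for (m in seq_len(M)) {
    idx <- .withSeed(seeds[m], sample(n, n, replace = TRUE))
    resampleIndex[[m]] <- idx
    sub <- .subsetPrepared(data, idx)
    member <- .reinitModel(model, seeds[m])
    cfg <- config
    cfg$seed <- .childSeed(seeds[m], 7L)
    members[[m]] <- trainModel(member, sub, cfg)
  }
  new("EnsembleModel", members = members, resampleIndex = resampleIndex,
      seeds = seeds)
}

## Subset a prepareTrainingData() result by sample index (repeats allowed).
.subsetPrepared <- function(data, idx) {
  list(dsets = data$dsets[idx], inputs = data$inputs[idx],
       X0 = data$X0[, idx, drop = FALSE],
       Yraw = data$Yraw[, idx, drop = FALSE],
       Yrecon = data$Yrecon[, idx, drop = FALSE],
       Cref = data$Cref[, idx, drop = FALSE])
}

## Fresh parameter initialization of the same architecture.
.reinitModel <- function(model, seed) {
  if (is(model, "AweModel")) {
    aweModel(model@provider, model@basis, nShells = model@config$S,
             cutoff = model@config$cutoff, nBlocks = model@config$L,
             dropout = model@config$dropout, dLatent = model@config$dLatent,
             dHidden = model@config$dHidden,
             epsilon = model@config$epsilon, seed = seed)
  } else {
    aoModel(model@config$dim, model@config$nGrid, model@config$hidden,
            model@config$energy, seed = seed)
  }
}

#' Ensemble prediction with uncertainty
#'
#' Pointwise mean and population standard deviation over the member
#' predictions; the scalar spread is the grid-mean of the pointwise
#' standard deviation.
#'
#' @param ensemble An \linkS4class{EnsembleModel}.
#' @param mol A \linkS4class{Molecule} or \linkS4class{DescriptorSet}.
#' @return List with \code{mean} (a \linkS4class{Spectrum} when the grid
#'   is known), \code{sd} (pointwise), and \code{spread} (scalar).
#' @export
ensemblePredict <- function(ensemble, mol) {
  preds <- vapply(ensemble@members, function(m) {
    if (is(m, "AweModel")) drop(.predictOne(m, mol)) else
      aoForward(m, if (is(mol, "Molecule"))
        computeDescriptorSet(mol, attr(m, "provider")) else mol)
  }, numeric(.outputLength(ensemble@members[[1]])))
  mu <- rowMeans(preds)
  sdv <- sqrt(rowMeans(preds^2) - mu^2)
  sdv <- pmax(sdv, 0)
  first <- ensemble@members[[1]]
  spec <- if (is(first, "AweModel"))
    Spectrum(first@basis@energy, mu)
  else if (!is.null(first@config$energy))
    Spectrum(first@config$energy, mu)
  else mu
  list(mean = spec, sd = sdv, spread = mean(sdv))
}

.outputLength <- function(model) {
  if (is(model, "AweModel")) length(model@basis@energy) else
    model@config$nGrid
}

.predictOne <- function(model, mol) {
  ds <- if (is(mol, "DescriptorSet")) mol else
    computeDescriptorSet(mol, model@provider)
  .aweForward(model@params, model@config, model@basis,
              .encoderInputs(list(ds), model@config$cutoff),
              training = FALSE)$Yhat
}

#' @rdname predictSpectrum
#' @export
setMethod("predictSpectrum", "EnsembleModel", function(model, mol, ...) {
  ensemblePredict(model, mol)
})

#' Pearson correlation between ensemble spread and realized error
#'
#' Standard product-moment correlation between the per-sample uncertainty
#' (ensemble spread) and the realized per-sample MS-SSIM loss. With fewer
#' than 3 samples or zero variance in either vector the correlation is
#' undefined and returned as \code{NA} (never silently 0).
#'
#' @param spread Numeric vector of per-sample ensemble spreads.
#' @param loss Numeric vector of per-sample realized losses.
#' @return Scalar correlation in [-1, 1], or \code{NA} when undefined.
#' @export
uncertaintyErrorCorrelation <- function(spread, loss) {
  stopifnot(length(spread) == length(loss))
  if (length(spread) < 3L) return(NA_real_)
  if (stats::sd(spread) == 0 || stats::sd(loss) == 0) return(NA_real_)
  stats::cor(spread, loss)
}

#' Ensemble uncertainty report on a test set
#'
#' Batched ensemble evaluation: per-sample mean prediction, spread
#' (grid-mean of the pointwise ensemble standard deviation), realized
#' MS-SSIM loss of the mean prediction against the reference, the
#' per-member loss summaries, and the Pearson correlation between spread
#' and realized loss.
#'
#' @param ensemble An \linkS4class{EnsembleModel}.
#' @param data Prepared test data.
#' @param ssimConfig An \code{\link{msSsimConfig}}.
#' @return List with \code{spread}, \code{loss} (of the ensemble-mean
#'   prediction), \code{memberMedians} (per-member median losses),
#'   \code{ensembleSummary}, and \code{pearson}.
#' @export
uncertaintyReport <- function(ensemble, data, ssimConfig = msSsimConfig()) {
  n <- ncol(data$Yraw)
  preds <- lapply(ensemble@members, .predictMatrix, data = data)
  Pmean <- Reduce(`+`, preds) / length(preds)
  Psq <- Reduce(`+`, lapply(preds, function(p) p^2)) / length(preds)
  Psd <- sqrt(pmax(Psq - Pmean^2, 0))
  spread <- colMeans(Psd)
  loss <- 1 - .msSsimBatch(Pmean, data$Yraw, ssimConfig)$sim
  memberLosses <- vapply(preds, function(p)
    1 - .msSsimBatch(p, data$Yraw, ssimConfig)$sim, numeric(n))
  list(spread = spread, loss = loss,
       memberMedians = apply(memberLosses, 2, stats::median),
       memberLosses = memberLosses,
       ensembleSummary = summarizeLosses(loss),
       pearson = uncertaintyErrorCorrelation(spread, loss))
}
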