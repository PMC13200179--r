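## Minibatch Adam training with the halving learning-rate schedule,
## held-out evaluation with box statistics, and similarity-regime curves.

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 1000; the
#'   desk-scale experiments in this package use fewer).
#' @param batchSize Minibatch size (default 32).
#' @param lr0 Initial learning rate (default 2e-3).
#' @param lrHalvingPeriod Epochs between halvings of the learning rate
#'   (default 100).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param testFraction Held-out fraction for \code{\link{splitDataset}}
#'   (default 0.2).
#' @param ssimConfig An \code{\link{msSsimConfig}} used by the loss.
#' @return A list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 1000L, batchSize = 32L, lr0 = 2e-3,
                        lrHalvingPeriod = 100L, seed = 1L,
                        testFraction = 0.2, ssimConfig = msSsimConfig()) {
  stopifnot(epochs >= 0, .isCount(batchSize), lr0 > 0,
            .isCount(lrHalvingPeriod), testFraction > 0, testFraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr0 = lr0,
                 lrHalvingPeriod = as.integer(lrHalvingPeriod),
                 seed = as.integer(seed), testFraction = testFraction,
                 ssimConfig = ssimConfig),
            class = "trainConfig")
}

#' Learning rate at a given epoch
#'
#' \code{lr0 * 0.5^floor((epoch - 1) / period)} for 1-based epochs: the
#' rate is halved after every \code{period} completed epochs.
#'
#' @param epoch 1-based epoch number.
#' @param lr0 Initial learning rate.
#' @param period Halving period in epochs.
#' @return The learning rate.
#' @examples
#' lrSchedule(250, 2e-3, 100)  # 5e-4
#' @export
lrSchedule <- function(epoch, lr0 = 2e-3, period = 100L) {
  lr0 * 0.5^((epoch - 1L) %/% period)
}

#' Reproducible train/test split
#'
#' Draws a held-out test set of size \code{round(fraction * n)} uniformly
#' without replacement; the two index sets are disjoint and exhaustive.
#'
#' @param x Number of samples, or a list whose length is used.
#' @param fraction Test fraction in (0, 1) (default 0.2).
#' @param seed Integer seed; the same seed reproduces the same membership.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
splitDataset <- function(x, fraction = 0.2, seed = 1L) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
  if (n < 2L) .stopf("domain error: need at least 2 samples to split")
  stopifnot(fraction > 0, fraction < 1)
  nTest <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  test <- sort(.withSeed(seed, sample(n, nTest)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Precompute everything training needs from raw pairs
#'
#' Computes descriptor sets, encoder inputs under the model cutoff, the
#' raw spectrum matrix, reference coefficients (projected once, not per
#' epoch) and their ridge reconstructions.
#'
#' @param molecules List of \linkS4class{Molecule}.
#' @param spectra List of \linkS4class{Spectrum} on the basis grid.
#' @param provider A \linkS4class{DescriptorProvider}.
#' @param basis A \linkS4class{GaussianBasis}.
#' @param cutoff Environment cutoff (Angstrom).
#' @return List with \code{dsets}, \code{inputs}, \code{X0} (d x n),
#'   \code{Yraw}, \code{Yrecon}, \code{Cref}.
#' @export
prepareTrainingData <- function(molecules, spectra, provider, basis,
                                cutoff = 7.0) {
  stopifnot(length(molecules) == length(spectra))
  dsets <- lapply(molecules, computeDescriptorSet, provider = provider)
  inputs <- .encoderInputs(dsets, cutoff)
  Yraw <- vapply(spectra, intensities, numeric(length(basis@energy)))
  Cref <- basis@ridgeOp %*% Yraw
  list(dsets = dsets, inputs = inputs,
       X0 = vapply(dsets, function(d) d@X[1, ], numeric(provider@dim)),
       Yraw = Yraw, Yrecon = basis@phi %*% Cref, Cref = Cref)
}

#' Subset prepared data by sample index
#'
#' Index into the result of \code{\link{prepareTrainingData}} (repeats
#' allowed, as in bootstrap resamples), keeping all parallel fields
#' aligned. Combine with \code{\link{splitDataset}} to carve out
#' train/test portions without recomputing descriptors.
#'
#' @param data Result of \code{\link{prepareTrainingData}}.
#' @param idx Integer sample indices.
#' @return A prepared-data list restricted to \code{idx}.
#' @export
subsetPrepared <- function(data, idx) .subsetPrepared(data, idx)

## One Adam step over a named gradient list; state held in environment.
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

.zeroLike <- function(params) lapply(params, function(p) p * 0)

#' Train a model on paired geometries and spectra
#'
#' Minibatch Adam on the composite loss (AWE: MS-SSIM between the
#' predicted spectrum and the ridge reconstruction of the reference, plus
#' coefficient MSE) or the plain MS-SSIM loss on the gridded spectrum
#' (AO). The learning rate follows \code{\link{lrSchedule}}. Fixed seeds
#' make shuffling, dropout and hence the loss history reproducible on one
#' machine. A non-finite loss aborts with a diagnostic naming the
#' offending batch.
#'
#' @param model An \linkS4class{AweModel} or \linkS4class{AoModel}.
#' @param data Either the result of \code{\link{prepareTrainingData}} or a
#'   list with \code{molecules} and \code{spectra}.
#' @param config A \code{\link{trainConfig}}.
#' @param provider For AO models trained from raw pairs: the descriptor
#'   provider supplying absorber features.
#' @param basis For AO models trained from raw pairs: basis (only used to
#'   carry the energy grid; AO regresses the raw grid directly).
#' @return The trained model with attribute \code{history} (per-epoch mean
#'   training loss).
#' @export
trainModel <- function(model, data, config = trainConfig(), provider = NULL,
                       basis = NULL) {
  isAwe <- is(model, "AweModel")
  if (isAwe) {
    provider <- model@provider
    basis <- model@basis
  }
  if (is.null(data$inputs)) {
    if (is.null(provider))
      .stopf("AO training from raw pairs needs a provider")
    if (is.null(basis) && isAwe) basis <- model@basis
    data <- prepareTrainingData(data$molecules, data$spectra, provider,
                                if (!is.null(basis)) basis else
                                  .stopf("need a basis to prepare data"),
                                cutoff = if (isAwe) model@config$cutoff else 7.0)
  }
  n <- ncol(data$Yraw)
  params <- model@params
  if (config$epochs == 0L) {
    attr(model, "history") <- numeric(0)
    return(model)
  }
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- .zeroLike(params)
  state$v <- .zeroLike(params)
  history <- numeric(config$epochs)
  .withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lrSchedule(epoch, config$lr0, config$lrHalvingPeriod)
      perm <- sample(n)
      starts <- seq(1L, n, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batchSize - 1L, n)]
        obj <- tryCatch({
          if (isAwe) {
            aweObjective(params, model@config, basis,
                         data$inputs[idx],
                         data$Yrecon[, idx, drop = FALSE],
                         data$Cref[, idx, drop = FALSE],
                         config$ssimConfig, grad = TRUE,
                         training = TRUE)
          } else {
            aoObjective(params, data$X0[, idx, drop = FALSE],
                        data$Yraw[, idx, drop = FALSE],
                        config$ssimConfig, grad = TRUE)
          }
        }, error = function(e) {
          if (grepl("non-finite", conditionMessage(e)))
            .stopf("training aborted: non-finite loss at epoch %d, batch starting sample %d",
                   epoch, s)
          stop(e)
        })
        if (!is.finite(obj$value))
          .stopf("training aborted: non-finite loss at epoch %d, batch starting sample %d",
                 epoch, s)
        params <- .adamStep(params, obj$grads, state, lr)
        epochLoss <- epochLoss + obj$value * length(idx)
      }
      history[epoch] <- epochLoss / n
    }
  })
  model@params <- params
  if (!isAwe) attr(model, "provider") <- provider
  attr(model, "history") <- history
  model
}

## Predicted spectra for a dataset, as an nE x n matrix.
.predictMatrix <- function(model, data) {
  if (is(model, "AweModel")) {
    .aweForward(model@params, model@config, model@basis, data$inputs,
                training = FALSE)$Yhat
  } else {
    .aoForward(model@params, data$X0)$Yhat
  }
}

#' Evaluate a model on a held-out set
#'
#' Per-sample MS-SSIM loss between predictions and the raw reference
#' spectra, summarized by quartiles (linear interpolation) and Tukey
#' whiskers: the most extreme samples within 1.5 IQR of the quartiles
#' (the non-outlier bounds WL1 and WH1).
#'
#' @param model A trained model.
#' @param data Prepared data (see \code{\link{prepareTrainingData}}).
#' @param ssimConfig An \code{\link{msSsimConfig}}.
#' @return List of class \code{evalSummary} with \code{losses},
#'   \code{WL1}, \code{Q1}, \code{median}, \code{Q3}, \code{WH1} and a
#'   \code{bands} table of qualitative agreement labels.
#' @export
evaluateModel <- function(model, data, ssimConfig = msSsimConfig()) {
  n <- ncol(data$Yraw)
  if (n < 1L) .stopf("domain error: empty evaluation set")
  Yhat <- .predictMatrix(model, data)
  losses <- 1 - .msSsimBatch(Yhat, data$Yraw, ssimConfig)$sim
  summarizeLosses(losses)
}

#' Box statistics of a loss vector
#'
#' @param losses Numeric vector of per-sample losses.
#' @return List of class \code{evalSummary}.
#' @export
summarizeLosses <- function(losses) {
  q <- stats::quantile(losses, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  inlier <- losses[losses >= q[1] - 1.5 * iqr & losses <= q[3] + 1.5 * iqr]
  structure(list(losses = losses, WL1 = min(inlier), Q1 = q[1],
                 median = q[2], Q3 = q[3], WH1 = max(inlier),
                 bands = table(qualityBand(losses))),
            class = "evalSummary")
}

#' @export
print.evalSummary <- function(x, ...) {
  cat(sprintf("n = %d  WL1 = %.4g  Q1 = %.4g  median = %.4g  Q3 = %.4g  WH1 = %.4g\n",
              length(x$losses), x$WL1, x$Q1, x$median, x$Q3, x$WH1))
  invisible(x)
}

#' Loss stratified by descriptor-similarity regime
#'
#' Assigns each test sample to a similarity regime from its normalized
#' nearest-neighbour distance to the training absorber descriptors, then
#' summarizes the per-sample losses within each nonempty regime. Empty
#' regimes are absent from the result, not reported as zero.
#'
#' @param model A trained model.
#' @param data Prepared test data.
#' @param trainX Training absorber-descriptor matrix (rows = samples).
#' @param normalizer Distance normalizer; default the mean training
#'   nearest-neighbour distance.
#' @param ssimConfig An \code{\link{msSsimConfig}}.
#' @return List with \code{distance}, \code{regime} and \code{summaries}
#'   (a named list of \code{evalSummary} per nonempty regime).
#' @export
regimeCurve <- function(model, data, trainX,
                        normalizer = meanNNDistance(trainX),
                        ssimConfig = msSsimConfig()) {
  Yhat <- .predictMatrix(model, data)
  losses <- 1 - .msSsimBatch(Yhat, data$Yraw, ssimConfig)$sim
  d <- apply(data$X0, 2, nearestNeighborDistance, trainX = trainX,
             normalizer = normalizer)
  regime <- classifyRegime(d)
  summaries <- lapply(split(losses, regime), function(x)
    if (length(x)) summarizeLosses(x) else NULL)
  summaries <- Filter(Negate(is.null), summaries)
  list(distance = d, regime = regime, losses = losses,
       summaries = summaries)
}
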