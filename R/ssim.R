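## One-dimensional multiscale structural similarity (MS-SSIM): the training
## loss and evaluation metric. Local statistics come from Gaussian-kernel
## convolution at several window widths; the composite objective adds a
## mean-squared error on the basis coefficients. The exact gradient of the
## loss with respect to the predicted spectrum is derived here as well,
## since training uses hand-written reverse-mode differentiation.

#' MS-SSIM configuration
#'
#' @param scaleFractions Window widths as fractions of the spectral length
#'   (default 3\%, 5\%, 7\%, matching typical spectral peak widths).
#' @param scaleWeights Positive per-scale weights; normalized internally
#'   (default uniform).
#' @param c1Prefactor,c2Prefactor Stability-constant prefactors applied to
#'   the global data range R: C1 = (c1 R)^2, C2 = (c2 R)^2.
#' @return A list of class \code{msSsimConfig}.
#' @export
msSsimConfig <- function(scaleFractions = c(0.03, 0.05, 0.07),
                         scaleWeights = NULL,
                         c1Prefactor = 0.01, c2Prefactor = 0.03) {
  stopifnot(all(scaleFractions > 0), all(scaleFractions < 1))
  if (is.null(scaleWeights)) scaleWeights <- rep(1, length(scaleFractions))
  stopifnot(length(scaleWeights) == length(scaleFractions),
            all(scaleWeights > 0))
  structure(list(scaleFractions = scaleFractions,
                 scaleWeights = scaleWeights,
                 weightsNorm = scaleWeights / sum(scaleWeights),
                 c1Prefactor = c1Prefactor, c2Prefactor = c2Prefactor),
            class = "msSsimConfig")
}

## Mirror an index vector into 1..n (reflection about the boundary points).
.reflectIdx <- function(j, n) {
  while (any(bad <- (j < 1L | j > n))) {
    j[j < 1L] <- 2L - j[j < 1L]
    j[j > n] <- 2L * n - j[j > n]
  }
  j
}

## Dense convolution matrix for a Gaussian kernel of sd = width points,
## truncated at 3 sd, reflective padding; rows sum to 1.
.convMatrix <- function(n, width) {
  h <- as.integer(ceiling(3 * width))
  g <- stats::dnorm(seq(-h, h), sd = width)
  g <- g / sum(g)
  C <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in seq(-h, h)) {
    j <- .reflectIdx(i + o, n)
    C[cbind(i, j)] <- C[cbind(i, j)] + g[o + h + 1L]
  }
  C
}

.convEnv <- new.env(parent = emptyenv())

## Cached per (n, fractions) list of convolution matrices and widths.
.convSet <- function(n, config) {
  widths <- pmax(1L, as.integer(round(config$scaleFractions * n)))
  key <- paste(n, paste(widths, collapse = "_"), sep = ":")
  cs <- .convEnv[[key]]
  if (is.null(cs)) {
    cs <- list(widths = widths,
               C = lapply(widths, function(w) .convMatrix(n, w)))
    .convEnv[[key]] <- cs
  }
  cs
}

#' Gaussian-windowed local statistics of two signals
#'
#' Local means, variances and cross-covariance obtained by convolution with
#' a Gaussian kernel (sd = \code{windowWidth} points, truncated at 3 sd,
#' reflective padding). Variances are floored at zero.
#'
#' @param a,b Equal-length numeric vectors.
#' @param windowWidth Kernel standard deviation in grid points (>= 1).
#' @return List with vectors \code{muA}, \code{muB}, \code{varA},
#'   \code{varB}, \code{cov}.
#' @export
gaussianLocalStats <- function(a, b, windowWidth) {
  if (length(a) != length(b)) .stopf("contract error: length mismatch")
  stopifnot(windowWidth >= 1)
  C <- .convMatrix(length(a), windowWidth)
  muA <- drop(C %*% a); muB <- drop(C %*% b)
  list(muA = muA, muB = muB,
       varA = pmax(drop(C %*% a^2) - muA^2, 0),
       varB = pmax(drop(C %*% b^2) - muB^2, 0),
       cov = drop(C %*% (a * b)) - muA * muB)
}

## Core batched MS-SSIM: Yhat, Y are nE x B matrices (columns = samples).
## Returns per-column similarity (and optionally gradient wrt Yhat).
## rangeFrom = "pair": the metric's symmetric global data range
## R = max(yhat, y) - min(yhat, y, 0), with its (sub)gradient included so
## finite differences match the analytic gradient. rangeFrom = "target":
## R = max(y) - min(y, 0), a per-sample constant; this is the training
## objective's stabilization (differentiating through a pair-based R gives
## the optimizer a degenerate direction: inflating R inflates C1/C2 and
## drives SSIM toward 1 regardless of fit).
.msSsimBatch <- function(Yhat, Y, config = msSsimConfig(), grad = FALSE,
                         rangeFrom = c("pair", "target")) {
  rangeFrom <- match.arg(rangeFrom)
  if (!all(is.finite(Yhat)) || !all(is.finite(Y)))
    .stopf("validation error: non-finite values in spectra")
  n <- nrow(Yhat); B <- ncol(Yhat)
  cs <- .convSet(n, config)
  maxA <- apply(Yhat, 2, max); maxB <- apply(Y, 2, max)
  minA <- apply(Yhat, 2, min); minB <- apply(Y, 2, min)
  R <- if (rangeFrom == "pair") pmax(maxA, maxB) - pmin(minA, minB, 0)
  else maxB - pmin(minB, 0)
  degen <- R <= 0          # only when both signals are identically zero
  C1 <- (config$c1Prefactor * R)^2
  C2 <- (config$c2Prefactor * R)^2
  sim <- numeric(B)
  G <- if (grad) matrix(0, n, B) else NULL
  dR <- numeric(B)         # accumulated dLoss/dR (via C1, C2)
  for (k in seq_along(cs$C)) {
    Cm <- cs$C[[k]]
    w <- config$weightsNorm[k]
    muA <- Cm %*% Yhat; muB <- Cm %*% Y
    ea2 <- Cm %*% Yhat^2; eb2 <- Cm %*% Y^2
    rawVarA <- ea2 - muA^2; rawVarB <- eb2 - muB^2
    varA <- pmax(rawVarA, 0); varB <- pmax(rawVarB, 0)
    cov <- Cm %*% (Yhat * Y) - muA * muB
    c1r <- rep(C1, each = n); c2r <- rep(C2, each = n)
    n1 <- 2 * muA * muB + c1r; n2 <- 2 * cov + c2r
    d1 <- muA^2 + muB^2 + c1r; d2 <- varA + varB + c2r
    ssimMap <- (n1 * n2) / (d1 * d2)
    sk <- colMeans(ssimMap)
    sim <- sim + w * ifelse(degen, 1, sk)
    if (grad) {
      inv <- 1 / (d1 * d2)
      gmu <- 2 * (muB * n2 - n1 * n2 * muA / d1) * inv
      gv <- -(n1 * n2) * inv / d2
      gv[rawVarA < 0] <- 0
      gc <- 2 * n1 * inv
      ## chain through mu, E[a^2], E[ab]; scale by w/n for the point mean
      gmuTot <- gmu - 2 * muA * gv - muB * gc
      Gk <- crossprod(Cm, gmuTot) + 2 * Yhat * crossprod(Cm, gv) +
        Y * crossprod(Cm, gc)
      G <- G + (w / n) * Gk
      if (rangeFrom == "pair") {
        gC1 <- n2 * (d1 - n1) * inv / d1
        gC2 <- n1 * (d2 - n2) * inv / d2
        dR <- dR + (w / n) * (colSums(gC1) * 2 * config$c1Prefactor^2 * R +
                                colSums(gC2) * 2 * config$c2Prefactor^2 * R)
      }
    }
  }
  if (grad && rangeFrom == "pair") {
    ## subgradient of R wrt yhat: argmax contributes when yhat attains the
    ## joint max; argmin contributes when yhat attains the joint min (< 0)
    for (b in which(!degen & dR != 0)) {
      if (maxA[b] >= maxB[b]) {
        i <- which.max(Yhat[, b]); G[i, b] <- G[i, b] + dR[b]
      }
      if (minA[b] < min(minB[b], 0)) {
        i <- which.min(Yhat[, b]); G[i, b] <- G[i, b] - dR[b]
      }
    }
  }
  if (grad) G[, degen] <- 0
  list(sim = sim, grad = G)
}

#' Single-scale structural similarity of two spectra
#'
#' SSIM at one window scale, averaged over spectral points. The global data
#' range \code{R = max(yhat, y) - min(yhat, y, 0)} defines the stability
#' constants. Two identically-zero signals (R = 0) are defined as perfectly
#' similar (value 1), keeping the training objective continuous.
#'
#' @param yhat,y Equal-length numeric vectors (or \linkS4class{Spectrum}).
#' @param k Scale index into \code{config$scaleFractions}.
#' @param config An \code{\link{msSsimConfig}}.
#' @return Scalar similarity in [-1, 1].
#' @export
ssimSingleScale <- function(yhat, y, k = 1L, config = msSsimConfig()) {
  yhat <- .asIntensity(yhat); y <- .asIntensity(y)
  cfg1 <- msSsimConfig(scaleFractions = config$scaleFractions[k],
                       scaleWeights = 1,
                       c1Prefactor = config$c1Prefactor,
                       c2Prefactor = config$c2Prefactor)
  .msSsimBatch(matrix(yhat), matrix(y), cfg1)$sim
}

.asIntensity <- function(x) if (is(x, "Spectrum")) intensities(x) else as.numeric(x)

#' Multiscale structural similarity
#'
#' Weighted average of the single-scale similarities; symmetric in its
#' arguments and bounded in [-1, 1].
#'
#' @inheritParams ssimSingleScale
#' @return Scalar similarity.
#' @export
msSsim <- function(yhat, y, config = msSsimConfig()) {
  .msSsimBatch(matrix(.asIntensity(yhat)), matrix(.asIntensity(y)),
               config)$sim
}

#' MS-SSIM loss
#'
#' \code{1 - msSsim(yhat, y)}: zero iff the similarity is perfect, bounded
#' by 2.
#'
#' @inheritParams ssimSingleScale
#' @return Scalar loss in [0, 2].
#' @export
msSsimLoss <- function(yhat, y, config = msSsimConfig()) {
  1 - msSsim(yhat, y, config)
}

#' Composite training loss
#'
#' Spectral MS-SSIM loss plus the mean squared error over the K basis
#' coefficients, with no extra weighting between the two terms.
#'
#' @param yhat,y Predicted and reference spectra (vectors or Spectrum).
#' @param cPred,cRef Predicted and reference coefficient vectors on a
#'   shared basis.
#' @param config An \code{\link{msSsimConfig}}.
#' @return List with \code{ssimTerm}, \code{coeffMse} and \code{total}.
#' @export
compositeLoss <- function(yhat, y, cPred, cRef, config = msSsimConfig()) {
  if (length(cPred) != length(cRef))
    .stopf("contract error: coefficient vectors must share a basis")
  ssim <- msSsimLoss(yhat, y, config)
  mse <- mean((as.numeric(cPred) - as.numeric(cRef))^2)
  list(ssimTerm = ssim, coeffMse = mse, total = ssim + mse)
}

#' Qualitative agreement band for an MS-SSIM loss
#'
#' Labels losses with the conventional interpretation bands: below 0.01
#' excellent, below 0.075 good, 0.075 to 0.125 moderate, above 0.125 poor.
#'
#' @param loss Numeric vector of MS-SSIM losses.
#' @return Factor with levels excellent, good, moderate, poor.
#' @export
qualityBand <- function(loss) {
  cut(loss, breaks = c(-Inf, 0.01, 0.075, 0.125, Inf), right = FALSE,
      labels = c("excellent", "good", "moderate", "poor"))
}
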