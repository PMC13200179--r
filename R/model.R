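## The absorber-with-environment (AWE) network: learnable soft radial
## shells aggregate environment descriptors, the result is fused with the
## absorber descriptor, refined by prelayer-normalized residual MLP blocks,
## and projected by per-width-group heads onto Gaussian basis coefficients.
## Also the absorber-only (AO) baseline MLP that regresses the gridded
## spectrum directly. Forward passes cache intermediates for the
## hand-written backward pass in backprop.R.

.glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' Construct an (untrained) AWE model
#'
#' Shell radii initialize evenly at \code{cutoff * s / S} (s = 1..S) and
#' blur factors at half the shell spacing, both learnable; blurs stay
#' positive through a softplus reparameterization. Hidden linear maps use
#' Glorot uniform initialization and layer norms start at identity; the
#' coefficient heads initialize at zero so the model's first prediction is
#' the zero spectrum. (The MS-SSIM term is nearly flat between
#' uncorrelated signals, so a randomly initialized output layer starts in
#' a plateau the optimizer cannot leave; from zero output, the
#' coefficient-MSE term pulls the prediction along a well-conditioned
#' path until the similarity term engages.)
#'
#' @param provider A \linkS4class{DescriptorProvider}.
#' @param basis A \linkS4class{GaussianBasis}.
#' @param nShells Number of soft radial shells S (default 4).
#' @param cutoff Environment cutoff radius in Angstrom (default 7);
#'   atoms beyond it are hard-masked out before shell weighting.
#' @param nBlocks Number of residual MLP blocks L (default 1).
#' @param dropout Dropout probability inside each block (default 0.1),
#'   active only during training.
#' @param dLatent Latent width (default: descriptor dimension d).
#' @param dHidden Block bottleneck width (default 2d).
#' @param epsilon Shell-normalization guard (default 1e-8).
#' @param seed Integer seed for parameter initialization.
#' @return An \linkS4class{AweModel}.
#' @export
aweModel <- function(provider, basis, nShells = 4L, cutoff = 7.0,
                     nBlocks = 1L, dropout = 0.1, dLatent = NULL,
                     dHidden = NULL, epsilon = 1e-8, seed = 1L) {
  stopifnot(is(provider, "DescriptorProvider"), is(basis, "GaussianBasis"),
            .isCount(nShells), .isCount(nBlocks),
            dropout >= 0, dropout < 1, cutoff > 0)
  d <- provider@dim
  if (is.null(dLatent)) dLatent <- d
  if (is.null(dHidden)) dHidden <- 2L * d
  groups <- sort(unique(basis@groupIndex))
  nCenters <- as.integer(table(basis@groupIndex)[as.character(groups)])
  config <- list(d = d, S = as.integer(nShells), cutoff = cutoff,
                 L = as.integer(nBlocks), dropout = dropout,
                 dLatent = as.integer(dLatent), dHidden = as.integer(dHidden),
                 epsilon = epsilon, lnEps = 1e-5,
                 nGroups = length(groups), nCenters = nCenters,
                 nShellsInit = "even", seed = as.integer(seed))
  spacing <- cutoff / nShells
  params <- .withSeed(seed, {
    p <- list(
      rShell = spacing * seq_len(nShells),
      bRaw = rep(.softplusInv(spacing / 2), nShells),
      Wsf = .glorot(d, d * nShells), bsf = numeric(d),
      Waf = .glorot(dLatent, 2L * d), baf = numeric(dLatent))
    for (l in seq_len(nBlocks)) {
      p[[paste0("lnG_", l)]] <- rep(1, dLatent)
      p[[paste0("lnB_", l)]] <- numeric(dLatent)
      p[[paste0("W1_", l)]] <- .glorot(dHidden, dLatent)
      p[[paste0("b1_", l)]] <- numeric(dHidden)
      p[[paste0("W2_", l)]] <- .glorot(dLatent, dHidden)
      p[[paste0("b2_", l)]] <- numeric(dLatent)
    }
    p$lnFg <- rep(1, dLatent)
    p$lnFb <- numeric(dLatent)
    for (g in seq_along(groups)) {
      p[[paste0("Wh_", g)]] <- matrix(0, nCenters[g], dLatent)
      p[[paste0("bh_", g)]] <- numeric(nCenters[g])
    }
    p
  })
  new("AweModel", provider = provider, basis = basis, params = params,
      config = config)
}

#' Soft radial shell weights
#'
#' Gaussian shell memberships of environment atoms, normalized across atoms
#' per shell: \code{wt = exp(-((r - r_s)/b_s)^2 / 2)},
#' \code{w = wt / (sum(wt) + epsilon)}. With at least one atom within a few
#' blur widths of a shell, the weights of that shell sum to 1 up to the
#' epsilon guard; empty shells degrade smoothly to ~0 weights, never NaN.
#'
#' @param r Distances of environment atoms to the absorber (Angstrom).
#' @param radii Shell radii r_s.
#' @param blurs Positive shell blur factors b_s.
#' @param epsilon Normalization guard (default 1e-8).
#' @return Matrix of weights, \code{length(r)} x \code{length(radii)}.
#' @export
shellWeights <- function(r, radii, blurs, epsilon = 1e-8) {
  stopifnot(all(blurs > 0), length(radii) == length(blurs))
  wt <- exp(-0.5 * (outer(r, radii, "-") / rep(blurs, each = length(r)))^2)
  sweep(wt, 2, colSums(wt) + epsilon, "/")
}

#' Shell summaries: weighted means of environment features
#'
#' \code{m_s = sum_i w_is x_i} per shell, concatenated into a single
#' vector of length d * S. Permutation invariant in the environment atoms.
#'
#' @param Xenv Environment feature matrix, (N-1) x d.
#' @param W Shell weight matrix from \code{\link{shellWeights}}, (N-1) x S.
#' @return Numeric vector of length d * S.
#' @export
shellSummaries <- function(Xenv, W) {
  if (nrow(Xenv) != nrow(W))
    .stopf("contract error: %d feature rows vs %d weight rows",
           nrow(Xenv), nrow(W))
  as.vector(crossprod(Xenv, W))
}

## Column-wise layer norm with cache. H: dl x B.
.layerNorm <- function(H, g, b, eps) {
  mu <- colMeans(H)
  xc <- sweep(H, 2, mu)
  invStd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, invStd, "*")
  list(out = g * xhat + b, xhat = xhat, invStd = invStd)
}

## Backward through layer norm. dOut: dl x B. Returns dH, dg, db.
.layerNormBack <- function(dOut, cache, g) {
  xhat <- cache$xhat
  dxhat <- dOut * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dH <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"),
              2, cache$invStd, "*")
  list(dH = dH, dg = rowSums(dOut * xhat), db = rowSums(dOut))
}

## Precompute, per molecule, what the encoder needs: absorber feature x0,
## in-range environment features and distances (hard cutoff mask).
.encoderInputs <- function(dsets, cutoff) {
  lapply(dsets, function(ds) {
    n <- nrow(ds@X)
    if (n >= 2L) {
      re <- ds@r[-1]
      keep <- re <= cutoff
      Xe <- ds@X[-1, , drop = FALSE][keep, , drop = FALSE]
      re <- re[keep]
    } else {
      Xe <- matrix(0, 0L, ncol(ds@X)); re <- numeric(0)
    }
    list(x0 = ds@X[1, ], Xe = Xe, re = re)
  })
}

## Batched AWE forward. inputs: list from .encoderInputs. Returns Yhat
## (nE x B), C (K x B) and a cache for the backward pass. Dropout is drawn
## from the current RNG stream when training = TRUE.
.aweForward <- function(params, config, basis, inputs, training = FALSE) {
  d <- config$d; S <- config$S; B <- length(inputs)
  bs <- .softplus(params$bRaw)
  rs <- params$rShell
  U <- matrix(0, d * S, B)
  X0 <- matrix(0, d, B)
  shellCache <- vector("list", B)
  for (b in seq_len(B)) {
    inp <- inputs[[b]]
    X0[, b] <- inp$x0
    m <- length(inp$re)
    if (m > 0L) {
      diffs <- outer(inp$re, rs, "-")
      wt <- exp(-0.5 * (diffs / rep(bs, each = m))^2)
      Tn <- colSums(wt) + config$epsilon
      w <- sweep(wt, 2, Tn, "/")
      U[, b] <- as.vector(crossprod(inp$Xe, w))
      shellCache[[b]] <- list(wt = wt, Tn = Tn, w = w, diffs = diffs)
    }
  }
  Z1 <- params$Wsf %*% U + params$bsf
  Zin <- rbind(Z1, X0)
  Z <- params$Waf %*% Zin + params$baf
  H <- Z
  blocks <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    ln <- .layerNorm(H, params[[paste0("lnG_", l)]],
                     params[[paste0("lnB_", l)]], config$lnEps)
    Q <- params[[paste0("W1_", l)]] %*% ln$out + params[[paste0("b1_", l)]]
    Gq <- .gelu(Q)
    if (training && config$dropout > 0) {
      mask <- (matrix(stats::runif(length(Gq)), nrow(Gq)) >=
                 config$dropout) / (1 - config$dropout)
    } else mask <- NULL
    Gd <- if (is.null(mask)) Gq else Gq * mask
    O <- params[[paste0("W2_", l)]] %*% Gd + params[[paste0("b2_", l)]]
    Hnew <- H + O
    blocks[[l]] <- list(ln = ln, Q = Q, Gq = Gq, mask = mask, Gd = Gd,
                        Hin = H)
    H <- Hnew
  }
  lnF <- .layerNorm(H, params$lnFg, params$lnFb, config$lnEps)
  Hout <- lnF$out
  Cparts <- vector("list", config$nGroups)
  for (g in seq_len(config$nGroups))
    Cparts[[g]] <- params[[paste0("Wh_", g)]] %*% Hout +
      params[[paste0("bh_", g)]]
  C <- do.call(rbind, Cparts)
  Yhat <- basis@phi %*% C
  list(Yhat = Yhat, C = C,
       cache = list(U = U, X0 = X0, Zin = Zin, Z = Z, blocks = blocks,
                    lnF = lnF, Hout = Hout, Hfin = H, bs = bs,
                    shell = shellCache, inputs = inputs))
}

#' Run the AWE model on one molecule
#'
#' Composes descriptor computation, shell aggregation, fusion, residual
#' refinement, the coefficient heads and basis reconstruction. Inference
#' is deterministic (dropout off) and inherits the rotation/translation
#' and environment-permutation invariance of the descriptor provider.
#'
#' @param model An \linkS4class{AweModel}.
#' @param mol A \linkS4class{Molecule}, or a precomputed
#'   \linkS4class{DescriptorSet}.
#' @return List with \code{spectrum} (a \linkS4class{Spectrum}) and
#'   \code{coef} (the predicted coefficient vector).
#' @export
forwardSpectrum <- function(model, mol) {
  ds <- if (is(mol, "DescriptorSet")) mol else
    computeDescriptorSet(mol, model@provider)
  inputs <- .encoderInputs(list(ds), model@config$cutoff)
  fw <- .aweForward(model@params, model@config, model@basis, inputs,
                    training = FALSE)
  list(spectrum = Spectrum(model@basis@energy, drop(fw$Yhat)),
       coef = structure(drop(fw$C), basis = model@basis))
}

#' @rdname predictSpectrum
#' @export
setMethod("predictSpectrum", "AweModel", function(model, mol, ...) {
  forwardSpectrum(model, mol)$spectrum
})

#' Construct an (untrained) absorber-only baseline model
#'
#' An MLP from the absorber descriptor through two hidden layers of
#' \code{hidden} units (GeLU) to the discretized spectrum; no basis, no
#' environment information. The output layer initializes at zero (see
#' \code{\link{aweModel}} for the rationale).
#'
#' @param d Input descriptor dimension.
#' @param nGrid Output length (number of energy grid points).
#' @param hidden Hidden width (default 512).
#' @param energy Optional energy grid stored for convenience.
#' @param seed Integer seed for initialization.
#' @return An \linkS4class{AoModel}.
#' @export
aoModel <- function(d, nGrid, hidden = 512L, energy = NULL, seed = 1L) {
  params <- .withSeed(seed, list(
    W1 = .glorot(hidden, d), b1 = numeric(hidden),
    W2 = .glorot(hidden, hidden), b2 = numeric(hidden),
    W3 = matrix(0, nGrid, hidden), b3 = numeric(nGrid)))
  new("AoModel", params = params,
      config = list(dim = as.integer(d), hidden = as.integer(hidden),
                    nGrid = as.integer(nGrid), energy = energy,
                    seed = as.integer(seed)))
}

## Batched AO forward; X0: d x B.
.aoForward <- function(params, X0) {
  Q1 <- params$W1 %*% X0 + params$b1
  A1 <- .gelu(Q1)
  Q2 <- params$W2 %*% A1 + params$b2
  A2 <- .gelu(Q2)
  Y <- params$W3 %*% A2 + params$b3
  list(Yhat = Y, cache = list(X0 = X0, Q1 = Q1, A1 = A1, Q2 = Q2, A2 = A2))
}

#' Run the absorber-only baseline on an absorber descriptor
#'
#' @param model An \linkS4class{AoModel}.
#' @param x0 Absorber feature vector of length d, or a
#'   \linkS4class{Molecule}/\linkS4class{DescriptorSet} together with a
#'   provider stored at training time.
#' @return Numeric predicted spectrum of length \code{nGrid}.
#' @export
aoForward <- function(model, x0) {
  if (is(x0, "DescriptorSet")) x0 <- x0@X[1, ]
  stopifnot(length(x0) == model@config$dim)
  drop(.aoForward(model@params, matrix(x0))$Yhat)
}

#' @rdname predictSpectrum
#' @export
setMethod("predictSpectrum", "AoModel", function(model, mol, ...) {
  provider <- attr(model, "provider")
  if (is(mol, "Molecule")) {
    if (is.null(provider))
      .stopf("AoModel has no attached provider; pass a DescriptorSet")
    mol <- computeDescriptorSet(mol, provider)
  }
  y <- aoForward(model, mol)
  e <- model@config$energy
  if (is.null(e)) e <- seq_len(model@config$nGrid)
  Spectrum(e, y)
})
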