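## Hand-written reverse-mode gradients for the AWE and AO models. The
## architecture is fixed, so the backward pass mirrors the forward cache
## exactly; correctness is pinned by finite-difference tests over all
## parameter groups, including the learnable shell radii and blurs.

## Backward through the AWE network. fw: result of .aweForward (with
## cache). dYhat: nE x B upstream gradient wrt the predicted spectra.
## dCextra: optional K x B gradient added directly on the coefficients
## (the coefficient-MSE term). Returns a list of gradients named like the
## parameters.
.aweBackward <- function(params, config, basis, fw, dYhat, dCextra = NULL) {
  cache <- fw$cache
  grads <- list()
  dC <- crossprod(basis@phi, dYhat)
  if (!is.null(dCextra)) dC <- dC + dCextra
  offs <- cumsum(c(0L, config$nCenters))
  dHout <- matrix(0, config$dLatent, ncol(dC))
  for (g in seq_len(config$nGroups)) {
    idx <- (offs[g] + 1L):offs[g + 1L]
    dCg <- dC[idx, , drop = FALSE]
    grads[[paste0("Wh_", g)]] <- tcrossprod(dCg, cache$Hout)
    grads[[paste0("bh_", g)]] <- rowSums(dCg)
    dHout <- dHout + crossprod(params[[paste0("Wh_", g)]], dCg)
  }
  lbF <- .layerNormBack(dHout, cache$lnF, params$lnFg)
  grads$lnFg <- lbF$dg; grads$lnFb <- lbF$db
  dH <- lbF$dH
  for (l in rev(seq_len(config$L))) {
    blk <- cache$blocks[[l]]
    dO <- dH
    grads[[paste0("W2_", l)]] <- tcrossprod(dO, blk$Gd)
    grads[[paste0("b2_", l)]] <- rowSums(dO)
    dGd <- crossprod(params[[paste0("W2_", l)]], dO)
    dGq <- if (is.null(blk$mask)) dGd else dGd * blk$mask
    dQ <- dGq * .geluGrad(blk$Q)
    grads[[paste0("W1_", l)]] <- tcrossprod(dQ, blk$ln$out)
    grads[[paste0("b1_", l)]] <- rowSums(dQ)
    dA1 <- crossprod(params[[paste0("W1_", l)]], dQ)
    lb1 <- .layerNormBack(dA1, blk$ln, params[[paste0("lnG_", l)]])
    grads[[paste0("lnG_", l)]] <- lb1$dg
    grads[[paste0("lnB_", l)]] <- lb1$db
    dH <- dH + lb1$dH              # residual skip path
  }
  dZ <- dH
  grads$Waf <- tcrossprod(dZ, cache$Zin)
  grads$baf <- rowSums(dZ)
  dZin <- crossprod(params$Waf, dZ)
  dZ1 <- dZin[seq_len(config$d), , drop = FALSE]
  grads$Wsf <- tcrossprod(dZ1, cache$U)
  grads$bsf <- rowSums(dZ1)
  dU <- crossprod(params$Wsf, dZ1)
  drs <- numeric(config$S); dbs <- numeric(config$S)
  bs <- cache$bs
  for (b in seq_along(cache$shell)) {
    sc <- cache$shell[[b]]
    if (is.null(sc)) next
    dM <- matrix(dU[, b], config$d, config$S)
    dw <- cache$inputs[[b]]$Xe %*% dM
    dwt <- sweep(dw, 2, sc$Tn, "/")
    dwt <- sweep(dwt, 2, colSums(dw * sc$w) / sc$Tn, "-")
    core <- dwt * sc$wt
    drs <- drs + colSums(core * sc$diffs) / bs^2
    dbs <- dbs + colSums(core * sc$diffs^2) / bs^3
  }
  grads$rShell <- drs
  grads$bRaw <- dbs * .sigmoid(params$bRaw)
  grads
}

#' Composite objective and gradient of an AWE model on a batch
#'
#' Evaluates the mean composite loss (MS-SSIM spectral term plus
#' coefficient MSE) over a batch and, optionally, its exact gradient with
#' respect to every model parameter via reverse-mode differentiation.
#' Dropout, if requested, draws masks from the current RNG stream.
#'
#' @param params Parameter list of an \linkS4class{AweModel}.
#' @param config Config list of the model.
#' @param basis The model's \linkS4class{GaussianBasis}.
#' @param inputs Encoder inputs (internal form; see
#'   \code{\link{prepareTrainingData}}).
#' @param Yref Reference spectra, nE x B matrix (the ridge reconstructions
#'   during training).
#' @param Cref Reference coefficients, K x B matrix.
#' @param ssimConfig An \code{\link{msSsimConfig}}.
#' @param grad Compute gradients?
#' @param training Apply dropout?
#' @return List with \code{value}, per-sample \code{losses} and (if
#'   requested) \code{grads}.
#' @keywords internal
#' @export
aweObjective <- function(params, config, basis, inputs, Yref, Cref,
                         ssimConfig = msSsimConfig(), grad = TRUE,
                         training = FALSE) {
  B <- length(inputs)
  fw <- .aweForward(params, config, basis, inputs, training = training)
  ms <- .msSsimBatch(fw$Yhat, Yref, ssimConfig, grad = grad,
                     rangeFrom = "target")
  K <- nrow(Cref)
  mse <- colMeans((fw$C - Cref)^2)
  losses <- (1 - ms$sim) + mse
  out <- list(value = mean(losses), losses = losses,
              ssim = mean(1 - ms$sim), mse = mean(mse))
  if (grad) {
    dYhat <- -ms$grad / B
    dCextra <- 2 * (fw$C - Cref) / (K * B)
    out$grads <- .aweBackward(params, config, basis, fw, dYhat, dCextra)
  }
  out
}

#' MS-SSIM objective and gradient of the AO baseline on a batch
#'
#' @param params Parameter list of an \linkS4class{AoModel}.
#' @param X0 Absorber descriptors, d x B matrix.
#' @param Yref Reference spectra (raw gridded), nE x B matrix.
#' @param ssimConfig An \code{\link{msSsimConfig}}.
#' @param grad Compute gradients?
#' @return List with \code{value}, \code{losses} and optionally
#'   \code{grads}.
#' @keywords internal
#' @export
aoObjective <- function(params, X0, Yref, ssimConfig = msSsimConfig(),
                        grad = TRUE) {
  B <- ncol(X0)
  fw <- .aoForward(params, X0)
  ms <- .msSsimBatch(fw$Yhat, Yref, ssimConfig, grad = grad,
                     rangeFrom = "target")
  losses <- 1 - ms$sim
  out <- list(value = mean(losses), losses = losses)
  if (grad) {
    dY <- -ms$grad / B
    cache <- fw$cache
    grads <- list()
    grads$W3 <- tcrossprod(dY, cache$A2); grads$b3 <- rowSums(dY)
    dA2 <- crossprod(params$W3, dY)
    dQ2 <- dA2 * .geluGrad(cache$Q2)
    grads$W2 <- tcrossprod(dQ2, cache$A1); grads$b2 <- rowSums(dQ2)
    dA1 <- crossprod(params$W2, dQ2)
    dQ1 <- dA1 * .geluGrad(cache$Q1)
    grads$W1 <- tcrossprod(dQ1, cache$X0); grads$b1 <- rowSums(dQ1)
    out$grads <- grads
  }
  out
}

#' Finite-difference gradient check
#'
#' Compares analytic gradients against central finite differences of the
#' objective for a random sample of scalar parameters (spanning all
#' parameter groups, including shell radii and blurs when present).
#'
#' @param objective Function(params) returning a list with \code{value}
#'   and \code{grads}.
#' @param params Parameter list.
#' @param nProbe Number of scalar parameters to probe.
#' @param h Central-difference step.
#' @param seed Seed for probe selection.
#' @return Data frame with columns \code{param}, \code{index},
#'   \code{analytic}, \code{numeric}, \code{relErr}.
#' @export
checkGradients <- function(objective, params, nProbe = 20L, h = 1e-5,
                           seed = 1L) {
  base <- objective(params)
  stopifnot(!is.null(base$grads))
  probes <- .withSeed(seed, {
    nm <- names(params)
    ## guarantee coverage of shell parameters when present, then fill
    chosen <- intersect(c("rShell", "bRaw"), nm)
    sel <- lapply(chosen, function(p)
      c(p, sample(length(params[[p]]), 1L)))
    while (length(sel) < nProbe) {
      p <- sample(nm, 1L)
      sel[[length(sel) + 1L]] <- c(p, sample(length(params[[p]]), 1L))
    }
    sel
  })
  res <- lapply(probes, function(pr) {
    p <- pr[1]; i <- as.integer(pr[2])
    pp <- params; pp[[p]][i] <- pp[[p]][i] + h
    up <- objective(pp)$value
    pm <- params; pm[[p]][i] <- pm[[p]][i] - h
    dn <- objective(pm)$value
    num <- (up - dn) / (2 * h)
    ana <- base$grads[[p]][i]
    data.frame(param = p, index = i, analytic = ana, numeric = num,
               relErr = abs(ana - num) / max(abs(num), abs(ana), 1e-8))
  })
  do.call(rbind, res)
}
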