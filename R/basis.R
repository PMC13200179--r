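## Multiscale Gaussian spectral basis and ridge-regularized projection.
## The codec: spectrum -> coefficients (A y) -> spectrum (Phi c).

#' Basis configuration
#'
#' @param widthGroups Gaussian widths in eV, one group per width. Default
#'   \code{c(0.5, 1, 2, 4)}: four scales spanning sharp near-edge features
#'   through broad envelopes.
#' @param stride Center placement stride in grid points. The default (1)
#'   places all width groups at every grid point; coarser strides (e.g. 4,
#'   one center at every fourth point) trade fidelity for compactness.
#' @param lambda Ridge penalty (default 1e-3) stabilizing the projection of
#'   a redundant basis.
#' @return A list of class \code{basisConfig}.
#' @export
basisConfig <- function(widthGroups = c(0.5, 1, 2, 4), stride = 1L,
                        lambda = 1e-3) {
  stopifnot(all(widthGroups > 0), !anyDuplicated(widthGroups),
            .isCount(stride), lambda > 0)
  structure(list(widthGroups = as.numeric(widthGroups),
                 stride = as.integer(stride), lambda = lambda),
            class = "basisConfig")
}

#' Build the Gaussian spectral basis and its ridge projector
#'
#' Centers are placed at grid points \code{1, 1+stride, 1+2*stride, ...};
#' at every center one Gaussian per width group is created, ordered
#' group-major so that each coefficient head of the AWE model owns a
#' contiguous block. \code{phi[i, k] = exp(-((E_i - mu_k)/w_k)^2 / 2)} and
#' the ridge operator \code{A = (Phi'Phi + lambda I)^{-1} Phi'} is computed
#' once and cached in the object.
#'
#' @param energy Strictly increasing energy grid (eV).
#' @param config A \code{\link{basisConfig}}.
#' @return A \linkS4class{GaussianBasis}.
#' @examples
#' b <- buildBasis(seq(0, 40, length.out = 100), basisConfig(stride = 4))
#' dim(b@phi)  # 100 x 100: 25 centers x 4 widths
#' @export
buildBasis <- function(energy, config = basisConfig()) {
  msg <- .checkGrid(energy)
  if (!is.null(msg)) .stopf(msg)
  energy <- as.numeric(energy)
  nE <- length(energy)
  if (config$stride >= nE)
    .stopf("configuration error: stride %d >= grid length %d",
           config$stride, nE)
  centerIdx <- seq(1L, nE, by = config$stride)
  mu <- energy[centerIdx]
  g <- length(config$widthGroups)
  centers <- rep(mu, times = g)
  widths <- rep(config$widthGroups, each = length(mu))
  groupIndex <- rep(seq_len(g), each = length(mu))
  phi <- exp(-0.5 * ((outer(energy, centers, "-")) /
                       rep(widths, each = nE))^2)
  A <- ridgeOperator(phi, config$lambda)
  new("GaussianBasis", energy = energy, centers = centers, widths = widths,
      phi = phi, ridgeOp = A, groupIndex = as.integer(groupIndex),
      lambda = config$lambda, stride = config$stride)
}

#' Ridge-regularized pseudoinverse of a basis matrix
#'
#' Returns \code{A} such that \code{A \%*\% y} minimizes
#' \code{||Phi c - y||^2 + lambda ||c||^2}, computed by a Cholesky solve of
#' the normal equations (no explicit inverse). \code{lambda = 0} is allowed
#' only when \code{Phi'Phi} is well conditioned; a singular system raises an
#' error rather than returning garbage.
#'
#' @param phi Numeric matrix N_E x K.
#' @param lambda Nonnegative ridge penalty.
#' @return Numeric matrix K x N_E.
#' @export
ridgeOperator <- function(phi, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    .stopf("lambda must be a single nonnegative number")
  gram <- crossprod(phi)
  diag(gram) <- diag(gram) + lambda
  ch <- tryCatch(chol(gram), error = function(e)
    .stopf("numerical error: normal equations singular (lambda = %g): %s",
           lambda, conditionMessage(e)))
  backsolve(ch, forwardsolve(t(ch), t(phi)))
}

#' Project a spectrum onto the basis
#'
#' Applies the cached ridge operator: \code{c = A y}. Linear and
#' deterministic in the spectrum.
#'
#' @param spec A \linkS4class{Spectrum} on the basis grid.
#' @param basis A \linkS4class{GaussianBasis}.
#' @return Numeric coefficient vector of length K with attribute
#'   \code{basis} referencing the basis.
#' @export
projectSpectrum <- function(spec, basis) {
  y <- if (is(spec, "Spectrum")) {
    if (length(energies(spec)) != length(basis@energy) ||
        any(abs(energies(spec) - basis@energy) > 1e-9))
      .stopf("validation error: spectrum grid does not match basis grid")
    intensities(spec)
  } else as.numeric(spec)
  if (length(y) != length(basis@energy))
    .stopf("validation error: spectrum length %d != grid length %d",
           length(y), length(basis@energy))
  structure(drop(basis@ridgeOp %*% y), basis = basis)
}

#' Reconstruct a spectrum from basis coefficients
#'
#' @param coef Numeric coefficient vector of length K.
#' @param basis A \linkS4class{GaussianBasis}; taken from the coefficient
#'   attribute when omitted.
#' @return A \linkS4class{Spectrum} on the basis grid.
#' @export
reconstructSpectrum <- function(coef, basis = attr(coef, "basis")) {
  if (is.null(basis)) .stopf("no basis supplied or attached to coefficients")
  if (length(coef) != length(basis@centers))
    .stopf("coefficient length %d != basis K %d",
           length(coef), length(basis@centers))
  Spectrum(basis@energy, drop(basis@phi %*% as.numeric(coef)))
}
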