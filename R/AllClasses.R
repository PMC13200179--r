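#' @import methods
NULL

#' Molecule: a molecular geometry with a designated absorbing atom
#'
#' Holds element symbols, Cartesian coordinates in Angstrom, and the index
#' (1-based within R; the XYZ dialect stores it 0-based) of the absorbing
#' atom whose core-level spectrum is modelled.
#'
#' @slot elements Character vector of element symbols (H..Og).
#' @slot coords Numeric matrix, N x 3, Angstrom.
#' @slot absorberIndex Integer in 1..N.
#' @export
setClass("Molecule",
  representation(elements = "character", coords = "matrix",
                 absorberIndex = "integer"),
  validity = function(object) {
    n <- length(object@elements)
    if (n < 1L) return("molecule must contain at least one atom")
    if (!is.numeric(object@coords) || !all(dim(object@coords) == c(n, 3L)))
      return("coords must be a numeric N x 3 matrix matching elements")
    if (!all(is.finite(object@coords)))
      return("coordinates must be finite")
    if (length(object@absorberIndex) != 1L ||
        is.na(object@absorberIndex) ||
        object@absorberIndex < 1L || object@absorberIndex > n)
      return("absorberIndex out of range")
    z <- match(object@elements, .ELEMENTS)
    if (anyNA(z))
      return(paste("unknown element symbol(s):",
                   paste(unique(object@elements[is.na(z)]), collapse = ", ")))
    TRUE
  })

#' Construct a Molecule
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param absorberIndex 1-based index of the absorbing atom (default 1).
#' @return A \linkS4class{Molecule}.
#' @examples
#' Molecule(c("Fe", "O"), rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
Molecule <- function(elements, coords, absorberIndex = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  new("Molecule", elements = as.character(elements), coords = coords,
      absorberIndex = as.integer(absorberIndex))
}

#' Spectrum: intensities on a strictly increasing energy grid
#'
#' @slot energy Numeric vector of energies (eV), strictly increasing.
#' @slot intensity Numeric vector of intensities (arbitrary units).
#' @export
setClass("Spectrum",
  representation(energy = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- .checkGrid(object@energy)
    if (!is.null(msg)) return(msg)
    if (length(object@intensity) != length(object@energy))
      return("intensity length must match energy grid")
    if (!all(is.finite(object@intensity)))
      return("intensities must be finite")
    TRUE
  })

#' Construct a Spectrum
#'
#' @param energy Strictly increasing numeric energy grid (eV).
#' @param intensity Numeric intensities, same length.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' Spectrum(0:10, sin(0:10))
#' @export
Spectrum <- function(energy, intensity) {
  new("Spectrum", energy = as.numeric(energy), intensity = as.numeric(intensity))
}

#' GaussianBasis: multiscale Gaussian spectral basis with ridge projector
#'
#' Columns of \code{phi} are Gaussian bumps \eqn{exp(-((E - mu_k)/w_k)^2/2)}
#' evaluated on the energy grid; \code{ridgeOp} is the ridge-regularized
#' pseudoinverse \eqn{A = (Phi' Phi + lambda I)^{-1} Phi'} used to project
#' any spectrum on the grid into coefficient space.
#'
#' @slot energy Energy grid (eV).
#' @slot centers Basis centers mu_k (eV), length K.
#' @slot widths Basis widths w_k (eV), length K.
#' @slot phi Basis matrix, N_E x K.
#' @slot ridgeOp Projection operator A, K x N_E.
#' @slot groupIndex Integer vector length K mapping each function to its
#'   width group (1..G); functions are ordered group-major.
#' @slot lambda Ridge penalty used to build \code{ridgeOp}.
#' @slot stride Center placement stride in grid points.
#' @export
setClass("GaussianBasis",
  representation(energy = "numeric", centers = "numeric", widths = "numeric",
                 phi = "matrix", ridgeOp = "matrix", groupIndex = "integer",
                 lambda = "numeric", stride = "integer"),
  validity = function(object) {
    msg <- .checkGrid(object@energy)
    if (!is.null(msg)) return(msg)
    k <- length(object@centers)
    if (length(object@widths) != k || length(object@groupIndex) != k)
      return("centers, widths and groupIndex must share length K")
    if (!all(dim(object@phi) == c(length(object@energy), k)))
      return("phi must be N_E x K")
    if (!all(dim(object@ridgeOp) == c(k, length(object@energy))))
      return("ridgeOp must be K x N_E")
    if (object@lambda < 0) return("lambda must be >= 0")
    TRUE
  })

#' DescriptorSet: per-atom features plus absorber distances
#'
#' Row 1 of \code{X} is the absorbing atom's feature vector; the remaining
#' rows are the environment atoms in their original order. \code{r} holds
#' Euclidean distances to the absorber (r[1] = 0).
#'
#' @slot X Numeric matrix, N x d.
#' @slot r Numeric vector of length N, Angstrom.
#' @slot provider Name of the descriptor provider that produced X.
#' @export
setClass("DescriptorSet",
  representation(X = "matrix", r = "numeric", provider = "character"),
  validity = function(object) {
    if (nrow(object@X) != length(object@r))
      return("X row count must match length of r")
    if (!all(is.finite(object@X))) return("descriptors must be finite")
    if (any(object@r < 0)) return("distances must be nonnegative")
    if (abs(object@r[1]) > 1e-12) return("absorber distance r[1] must be 0")
    TRUE
  })

#' DescriptorProvider: contract for per-atom feature computation
#'
#' A provider maps a \linkS4class{Molecule} to an N x d feature matrix whose
#' row order follows the atom order. Built-in providers: \code{wacsfProvider}
#' (weighted atom-centered symmetry functions) and \code{matrixProvider}
#' (precomputed external features, e.g. from an equivariant message-passing
#' model, loaded from file).
#'
#' @slot name Provider name.
#' @slot dim Feature dimension d.
#' @slot fun Function Molecule -> N x d matrix.
#' @export
setClass("DescriptorProvider",
  representation(name = "character", dim = "integer", fun = "function"),
  validity = function(object) {
    if (object@dim < 1L) return("descriptor dimension must be >= 1")
    TRUE
  })

#' AweModel: absorber-with-environment spectral prediction model
#'
#' Composes a descriptor provider, learnable soft radial shells, the
#' residual-MLP encoder, per-width-group coefficient heads, and the fixed
#' Gaussian spectral basis into the end-to-end map
#' \eqn{yhat = Phi f_head(f_enc(x, r))}.
#'
#' @slot provider A \linkS4class{DescriptorProvider}.
#' @slot basis A \linkS4class{GaussianBasis}.
#' @slot params Named list of parameter arrays (see \code{aweModel}).
#' @slot config Named list of architectural settings.
#' @export
setClass("AweModel",
  representation(provider = "DescriptorProvider", basis = "GaussianBasis",
                 params = "list", config = "list"))

#' AoModel: absorber-only baseline MLP
#'
#' Direct grid regression from the absorber descriptor through two hidden
#' layers of 512 units; no basis, no environment.
#'
#' @slot params Named list of weight matrices and biases.
#' @slot config Named list with input dim, hidden width and output length.
#' @export
setClass("AoModel", representation(params = "list", config = "list"))

#' EnsembleModel: bootstrap ensemble for uncertainty quantification
#'
#' @slot members List of trained models sharing one architecture.
#' @slot resampleIndex List of integer vectors; the with-replacement
#'   training resample used by each member (recorded for audit).
#' @slot seeds Integer vector of member training seeds.
#' @export
setClass("EnsembleModel",
  representation(members = "list", resampleIndex = "list", seeds = "integer"),
  validity = function(object) {
    if (length(object@members) < 2L)
      return("an ensemble needs at least 2 members")
    if (length(object@resampleIndex) != length(object@members) ||
        length(object@seeds) != length(object@members))
      return("members, resampleIndex and seeds must have equal length")
    TRUE
  })

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d atoms [%s], absorber %s (#%d)\n",
              length(object@elements),
              paste(unique(object@elements), collapse = " "),
              object@elements[object@absorberIndex], object@absorberIndex))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points on [%.3g, %.3g] eV, max intensity %.4g\n",
              length(object@energy), min(object@energy), max(object@energy),
              max(object@intensity)))
})

setMethod("show", "GaussianBasis", function(object) {
  cat(sprintf(
    "GaussianBasis: K = %d (%d centers x %d widths {%s} eV), lambda = %g\n",
    length(object@centers), length(unique(object@centers)),
    length(unique(object@widths)),
    paste(format(sort(unique(object@widths))), collapse = ", "),
    object@lambda))
})

setMethod("show", "DescriptorProvider", function(object) {
  cat(sprintf("DescriptorProvider '%s' (d = %d)\n", object@name, object@dim))
})

setMethod("show", "AweModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "AweModel: provider '%s' (d = %d), %d shells, latent %d, K = %d, %d parameters\n",
    object@provider@name, object@provider@dim, object@config$S,
    object@config$dLatent, length(object@basis@centers), np))
})

setMethod("show", "AoModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("AoModel: d = %d -> %d -> %d -> N_E = %d (%d parameters)\n",
              object@config$dim, object@config$hidden, object@config$hidden,
              object@config$nGrid, np))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d bootstrap members (seeds %s...)\n",
              length(object@members),
              paste(utils::head(object@seeds, 3), collapse = ", ")))
})
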