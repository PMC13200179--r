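#' Predict a spectrum from a molecular geometry
#'
#' @param model A trained \linkS4class{AweModel}, \linkS4class{AoModel} or
#'   \linkS4class{EnsembleModel}.
#' @param mol A \linkS4class{Molecule}.
#' @param ... Passed to methods.
#' @return For single models, a \linkS4class{Spectrum}; for ensembles, a
#'   list with the mean spectrum, pointwise standard deviation and the
#'   scalar spread (see \code{\link{ensemblePredict}}).
#' @export
setGeneric("predictSpectrum", function(model, mol, ...)
  standardGeneric("predictSpectrum"))

#' Accessors for spectra and molecules
#'
#' \code{energies} and \code{intensities} extract the grid and values of a
#' \linkS4class{Spectrum}; \code{elements}, \code{coords} and
#' \code{absorberIndex} extract the parts of a \linkS4class{Molecule};
#' \code{nAtoms} counts atoms.
#'
#' @param x The object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("absorberIndex", function(x) standardGeneric("absorberIndex"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setMethod("energies", "Spectrum", function(x) x@energy)
#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("elements", "Molecule", function(x) x@elements)
#' @rdname accessors
#' @export
setMethod("coords", "Molecule", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("absorberIndex", "Molecule", function(x) x@absorberIndex)
#' @rdname accessors
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))
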