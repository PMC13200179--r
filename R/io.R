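## Readers and writers for the two on-disk dialects (XYZ geometries and
## two-column spectra), plus dataset assembly from a manifest.

#' Parse an XYZ geometry
#'
#' Standard XYZ: first line the atom count, second line a free-form comment
#' which may carry an \code{absorber=<i>} key (0-based, matching the file
#' dialect and CLI), then one \code{symbol x y z} line per atom. Without an
#' absorber key the first atom is taken as the absorber.
#'
#' @param x Path to an XYZ file, or a character vector of lines.
#' @return A \linkS4class{Molecule}.
#' @seealso \code{\link{writeXYZ}}
#' @examples
#' parseXYZ(c("1", "", "Fe 0 0 0"))
#' @export
parseXYZ <- function(x) {
  lines <- if (length(x) == 1L) {
    if (!grepl("\n", x) && file.exists(x)) readLines(x)
    else strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)
  if (length(lines) < 1L) .stopf("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) .stopf("XYZ format error: bad atom count '%s'", lines[1])
  if (length(lines) < n + 2L)
    .stopf("XYZ format error: header says %d atoms but only %d atom lines present",
           n, max(0L, length(lines) - 2L))
  body <- lines[seq(3L, n + 2L)]
  extra <- lines[-seq_len(n + 2L)]
  if (any(nzchar(trimws(extra))))
    .stopf("XYZ format error: header says %d atoms but more atom lines follow", n)
  tok <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(tok) < 4L)) .stopf("XYZ format error: atom line with < 4 fields")
  sym <- vapply(tok, `[[`, "", 1L)
  xyz <- suppressWarnings(
    vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) .stopf("XYZ format error: non-numeric coordinate")
  absorber <- 1L
  m <- regmatches(lines[2], regexpr("absorber=([0-9]+)", lines[2]))
  if (length(m) == 1L)
    absorber <- as.integer(sub("absorber=", "", m)) + 1L
  Molecule(sym, t(xyz), absorber)
}

#' Write an XYZ geometry
#'
#' Inverse of \code{\link{parseXYZ}}; records the absorber in the comment
#' line as a 0-based \code{absorber=<i>} key. Round-trips coordinates to
#' better than 1e-6 Angstrom.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param file Path to write, or \code{NULL} to return the lines.
#' @return Invisibly (or visibly for \code{file = NULL}) the lines written.
#' @export
writeXYZ <- function(mol, file = NULL) {
  stopifnot(is(mol, "Molecule"))
  lines <- c(
    as.character(nAtoms(mol)),
    sprintf("absorber=%d", absorberIndex(mol) - 1L),
    sprintf("%s %.10f %.10f %.10f", elements(mol),
            coords(mol)[, 1], coords(mol)[, 2], coords(mol)[, 3]))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Parse a two-column spectrum
#'
#' Whitespace-delimited \code{energy intensity} rows; lines starting with
#' \code{#} are comments. Energies must be strictly increasing.
#'
#' @param x Path to a spectrum file, or a character vector of lines.
#' @return A \linkS4class{Spectrum}.
#' @seealso \code{\link{writeSpectrum}}
#' @examples
#' parseSpectrum(c("0 0", "1 0.5", "2 1.0"))
#' @export
parseSpectrum <- function(x) {
  lines <- if (length(x) == 1L) {
    if (!grepl("\n", x) && file.exists(x)) readLines(x)
    else strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)]
  if (length(lines) < 2L) .stopf("spectrum must have at least 2 rows")
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(tok) != 2L))
    .stopf("spectrum format error: expected exactly 2 columns per row")
  vals <- suppressWarnings(vapply(tok, function(t) as.numeric(t), numeric(2)))
  if (anyNA(vals)) .stopf("spectrum format error: non-numeric value")
  Spectrum(vals[1, ], vals[2, ])
}

#' Write a two-column spectrum
#'
#' @param spec A \linkS4class{Spectrum}.
#' @param file Path to write, or \code{NULL} to return the lines.
#' @return Invisibly (or visibly for \code{file = NULL}) the lines written.
#' @export
writeSpectrum <- function(spec, file = NULL) {
  stopifnot(is(spec, "Spectrum"))
  lines <- sprintf("%.12g %.12g", energies(spec), intensities(spec))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a dataset manifest
#'
#' A manifest is a whitespace- or tab-delimited table with columns
#' \code{geometry} and \code{spectrum} (paths, resolved relative to the
#' manifest location) and an optional \code{absorber} column (0-based
#' index) overriding the XYZ files. An optional first comment line
#' \code{# mode: XAS|XES} records the spectral modality.
#'
#' @param path Manifest file path.
#' @return A data.frame with attributes \code{mode} and \code{dir}.
#' @export
readManifest <- function(path) {
  lines <- readLines(path)
  mode <- "XAS"
  mline <- grep("^#\\s*mode:", lines, value = TRUE)
  if (length(mline)) mode <- toupper(trimws(sub("^#\\s*mode:", "", mline[1])))
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = lines, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("geometry", "spectrum") %in% names(df)))
    .stopf("manifest needs 'geometry' and 'spectrum' columns")
  if (anyDuplicated(df$geometry) || anyDuplicated(df$spectrum))
    .stopf("manifest paths must be unique per record")
  attr(df, "mode") <- mode
  attr(df, "dir") <- dirname(normalizePath(path))
  df
}

#' Load a paired geometry/spectrum dataset
#'
#' Reads every record of a manifest and returns aligned molecule/spectrum
#' pairs on a single common energy grid. Records whose grids differ from
#' \code{targetGrid} are linearly interpolated onto it; extrapolation
#' outside a source grid is an error. If grids differ and no target grid
#' is given, loading fails.
#'
#' @param manifest A manifest data.frame from \code{\link{readManifest}},
#'   or a path to one.
#' @param targetGrid Optional strictly increasing numeric grid (eV).
#' @return A list with elements \code{molecules} (list of Molecule),
#'   \code{spectra} (list of Spectrum, all on one grid) and \code{energy}
#'   (the common grid).
#' @export
loadDataset <- function(manifest, targetGrid = NULL) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  dir <- attr(manifest, "dir")
  resolve <- function(p) if (!is.null(dir) && !file.exists(p))
    file.path(dir, p) else p
  mols <- lapply(manifest$geometry, function(p) parseXYZ(resolve(p)))
  if (!is.null(manifest$absorber)) {
    for (i in seq_along(mols))
      if (!is.na(manifest$absorber[i]))
        mols[[i]]@absorberIndex <- as.integer(manifest$absorber[i]) + 1L
  }
  specs <- lapply(manifest$spectrum, function(p) parseSpectrum(resolve(p)))
  grids <- lapply(specs, energies)
  same <- all(vapply(grids, function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
  if (is.null(targetGrid)) {
    if (!same)
      .stopf("spectra are on different energy grids; supply targetGrid")
    energy <- grids[[1]]
  } else {
    msg <- .checkGrid(targetGrid)
    if (!is.null(msg)) .stopf(msg)
    energy <- as.numeric(targetGrid)
    specs <- lapply(specs, resampleSpectrum, targetGrid = energy)
  }
  list(molecules = mols, spectra = specs, energy = energy)
}

#' Linearly resample a spectrum onto a target grid
#'
#' Exact for affine spectra; extrapolation beyond the source grid is an
#' error (range error), never silently filled.
#'
#' @param spec A \linkS4class{Spectrum}.
#' @param targetGrid Strictly increasing numeric grid within the source range.
#' @return A \linkS4class{Spectrum} on \code{targetGrid}.
#' @export
resampleSpectrum <- function(spec, targetGrid) {
  e <- energies(spec)
  if (min(targetGrid) < min(e) || max(targetGrid) > max(e))
    .stopf("range error: target grid [%g, %g] outside source grid [%g, %g]",
           min(targetGrid), max(targetGrid), min(e), max(e))
  if (length(targetGrid) == length(e) && all(targetGrid == e)) return(spec)
  Spectrum(targetGrid,
           stats::approx(e, intensities(spec), xout = targetGrid)$y)
}
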