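## Weighted atom-centered symmetry functions (wACSF), descriptor sets,
## descriptor-space distances, and similarity-regime classification.

#' wACSF configuration
#'
#' Defines the weighted radial and angular symmetry-function grid. Element
#' weighting uses atomic number by default, so a single descriptor length
#' covers arbitrary compositions. Defaults: 16 radial centers evenly spaced
#' on (0.5, 7] Angstrom with eta = 4 per Angstrom^2, and 8 angular terms
#' (zeta in {1, 4}, sign in {-1, +1}, eta in {0.01, 0.1}); cutoff 7.0
#' Angstrom, matching the environment-encoder cutoff.
#'
#' @param radialEtas Radial Gaussian widths eta (1/Angstrom^2), recycled to
#'   the length of \code{radialCenters}.
#' @param radialCenters Radial shift parameters mu (Angstrom).
#' @param angularEtas,angularZetas,angularSigns Parallel vectors defining
#'   the angular terms (recycled to common length).
#' @param cutoff Cosine cutoff radius (Angstrom).
#' @param weightFn Function mapping element symbols to weights (default
#'   \code{\link{atomicNumber}}).
#' @return A list of class \code{wacsfConfig} with element \code{dim}.
#' @export
wacsfConfig <- function(radialEtas = 4,
                        radialCenters = 0.5 + seq_len(16) * (6.5 / 16),
                        angularEtas = rep(c(0.01, 0.1), each = 4),
                        angularZetas = rep(c(1, 4, 1, 4), 2),
                        angularSigns = rep(c(1, 1, -1, -1), 2),
                        cutoff = 7.0,
                        weightFn = atomicNumber) {
  stopifnot(cutoff > 0, length(radialCenters) >= 1)
  nr <- length(radialCenters)
  radialEtas <- rep_len(radialEtas, nr)
  na <- max(length(angularEtas), length(angularZetas), length(angularSigns))
  cfg <- list(radialEtas = radialEtas, radialCenters = radialCenters,
              angularEtas = rep_len(angularEtas, na),
              angularZetas = rep_len(angularZetas, na),
              angularSigns = rep_len(angularSigns, na),
              cutoff = cutoff, weightFn = weightFn,
              dim = nr + na)
  stopifnot(all(cfg$angularSigns %in% c(-1, 1)))
  structure(cfg, class = "wacsfConfig")
}

## Cosine cutoff: smooth decay to exactly 0 at r = cutoff.
.fcut <- function(r, cutoff) ifelse(r < cutoff, 0.5 * (cos(pi * r / cutoff) + 1), 0)

#' Compute the wACSF vector of one atom
#'
#' Radial terms sum element-weighted Gaussians of neighbour distances;
#' angular terms sum over neighbour pairs with the modified-cosine form
#' \code{2^(1-zeta) * w_j w_k (1 + s cos theta)^zeta *
#' exp(-eta (r_cj^2 + r_ck^2 + r_jk^2))} times the three cutoff factors.
#' Atoms at or beyond the cutoff contribute exactly zero.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param center 1-based index of the central atom.
#' @param config A \code{\link{wacsfConfig}}.
#' @return Numeric vector of length \code{config$dim}.
#' @export
computeWacsfAtom <- function(mol, center, config = wacsfConfig()) {
  stopifnot(is(mol, "Molecule"), center >= 1L, center <= nAtoms(mol))
  n <- nAtoms(mol)
  out <- numeric(config$dim)
  if (n == 1L) return(out)
  xyz <- coords(mol)
  v <- sweep(xyz[-center, , drop = FALSE], 2, xyz[center, ])
  r <- sqrt(rowSums(v * v))
  w <- config$weightFn(elements(mol)[-center])
  keep <- r < config$cutoff
  nr <- length(config$radialCenters)
  if (any(keep)) {
    rk <- r[keep]; wk <- w[keep]; fk <- .fcut(rk, config$cutoff)
    wf <- wk * fk
    out[seq_len(nr)] <- vapply(seq_len(nr), function(t)
      sum(wf * exp(-config$radialEtas[t] *
                     (rk - config$radialCenters[t])^2)), numeric(1))
    ## angular: pairs of in-range neighbours
    m <- sum(keep)
    if (m >= 2L) {
      vk <- v[keep, , drop = FALSE]
      pairs <- utils::combn(m, 2L)
      j <- pairs[1, ]; k <- pairs[2, ]
      rj <- rk[j]; rkk <- rk[k]
      djk <- sqrt(rowSums((vk[j, , drop = FALSE] - vk[k, , drop = FALSE])^2))
      cosang <- rowSums(vk[j, , drop = FALSE] * vk[k, , drop = FALSE]) /
        (rj * rkk)
      cosang <- pmin(1, pmax(-1, cosang))
      fprod <- fk[j] * fk[k] * .fcut(djk, config$cutoff)
      wprod <- wk[j] * wk[k]
      r2 <- rj^2 + rkk^2 + djk^2
      for (a in seq_along(config$angularEtas)) {
        zeta <- config$angularZetas[a]; s <- config$angularSigns[a]
        out[nr + a] <- 2^(1 - zeta) * sum(
          wprod * (1 + s * cosang)^zeta *
            exp(-config$angularEtas[a] * r2) * fprod)
      }
    }
  }
  out
}

#' Built-in wACSF descriptor provider
#'
#' Wraps \code{\link{computeWacsfAtom}} applied from the perspective of
#' every atom into the \linkS4class{DescriptorProvider} contract.
#'
#' @param config A \code{\link{wacsfConfig}}.
#' @return A \linkS4class{DescriptorProvider}.
#' @export
wacsfProvider <- function(config = wacsfConfig()) {
  force(config)
  new("DescriptorProvider", name = "wacsf", dim = as.integer(config$dim),
      fun = function(mol) {
        t(vapply(seq_len(nAtoms(mol)),
                 function(i) computeWacsfAtom(mol, i, config),
                 numeric(config$dim)))
      })
}

#' Descriptor provider backed by a precomputed feature matrix
#'
#' Consumes externally computed per-atom features (for example from an
#' equivariant message-passing model) stored as plain text: a header line
#' with the dimension \code{d}, then N rows of d values aligned to the XYZ
#' atom order. Lookup is by molecule, via a user-supplied keying function.
#'
#' @param features Either a single N x d matrix (applied to every molecule
#'   of matching size) or a function Molecule -> matrix.
#' @param dim Feature dimension d.
#' @param name Provider name (default "external").
#' @return A \linkS4class{DescriptorProvider}.
#' @export
matrixProvider <- function(features, dim, name = "external") {
  fun <- if (is.function(features)) features else function(mol) features
  new("DescriptorProvider", name = name, dim = as.integer(dim), fun = fun)
}

#' Read an external per-atom feature file
#'
#' Format: first non-comment line is the dimension d; each following line
#' holds d whitespace-separated values for one atom, in XYZ atom order.
#'
#' @param path File path.
#' @return An N x d numeric matrix.
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)]
  d <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  if (any(lengths(rows) != d)) .stopf("feature file rows must have %d values", d)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Euclidean distances from every atom to the absorber
#'
#' @param mol A \linkS4class{Molecule}.
#' @return Numeric vector of length N in atom order; the absorber entry is 0.
#' @export
absorberDistances <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  d <- sweep(coords(mol), 2, coords(mol)[absorberIndex(mol), ])
  sqrt(rowSums(d * d))
}

#' Compute a descriptor set for a molecule
#'
#' Runs the provider, checks its output shape, and reorders rows so the
#' absorbing atom comes first, followed by the environment atoms in their
#' original order; distances follow the same ordering.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param provider A \linkS4class{DescriptorProvider}.
#' @return A \linkS4class{DescriptorSet}.
#' @export
computeDescriptorSet <- function(mol, provider = wacsfProvider()) {
  X <- provider@fun(mol)
  n <- nAtoms(mol)
  if (!is.matrix(X) || nrow(X) != n || ncol(X) != provider@dim)
    .stopf("contract violation: provider '%s' returned %s, expected %d x %d",
           provider@name, paste(dim(X), collapse = " x "), n, provider@dim)
  ord <- c(absorberIndex(mol), setdiff(seq_len(n), absorberIndex(mol)))
  r <- absorberDistances(mol)
  new("DescriptorSet", X = X[ord, , drop = FALSE], r = r[ord],
      provider = provider@name)
}

#' Normalized nearest-neighbour descriptor distance
#'
#' Distance from a test descriptor to its nearest neighbour in the training
#' descriptor matrix, divided by a normalizer (conventionally the mean
#' nearest-neighbour distance among training examples, see
#' \code{\link{meanNNDistance}}).
#'
#' @param testX Numeric descriptor vector.
#' @param trainX Numeric matrix, one training descriptor per row.
#' @param normalizer Positive scalar.
#' @return Nonnegative scalar distance.
#' @export
nearestNeighborDistance <- function(testX, trainX, normalizer = 1) {
  if (is.null(dim(trainX))) trainX <- matrix(trainX, nrow = 1)
  if (nrow(trainX) < 1L) .stopf("domain error: empty training set")
  if (!is.numeric(normalizer) || normalizer <= 0)
    .stopf("domain error: normalizer must be positive")
  d2 <- rowSums(sweep(trainX, 2, as.numeric(testX))^2)
  sqrt(min(d2)) / normalizer
}

#' Mean nearest-neighbour distance within a training set
#'
#' For each training descriptor, its distance to the nearest other training
#' descriptor; the mean over examples is the normalizer used by
#' \code{\link{nearestNeighborDistance}}.
#'
#' @param trainX Numeric matrix with at least 2 rows.
#' @return Positive scalar.
#' @export
meanNNDistance <- function(trainX) {
  n <- nrow(trainX)
  if (is.null(n) || n < 2L) .stopf("need at least 2 training descriptors")
  g <- tcrossprod(trainX)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  diag(d2) <- Inf
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Classify a descriptor-similarity regime
#'
#' Partitions the normalized nearest-neighbour distance d into the four
#' similarity regimes: identical (d < 1e-3), familiar (1e-3 <= d <
#' 10^-1.5), unfamiliar (10^-1.5 <= d < 1) and strange (d >= 1).
#'
#' @param d Nonnegative numeric vector of normalized distances.
#' @return Factor with levels identical, familiar, unfamiliar, strange.
#' @examples
#' classifyRegime(c(0, 0.01, 0.5, 1))
#' @export
classifyRegime <- function(d) {
  if (any(d < 0)) .stopf("domain error: distances must be nonnegative")
  cut(d, breaks = c(-Inf, 1e-3, 10^-1.5, 1, Inf), right = FALSE,
      labels = c("identical", "familiar", "unfamiliar", "strange"))
}
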