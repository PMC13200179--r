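## Internal helpers shared across modules.

## Periodic table H..Og; position = atomic number.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Atomic numbers for element symbols
#'
#' Looks up atomic numbers for the full periodic table (H through Og).
#' Used as the default element weight in the wACSF descriptors.
#'
#' @param symbols Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @examples
#' atomicNumber(c("Fe", "O"))
#' @export
atomicNumber <- function(symbols) {
  z <- match(symbols, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  z
}

## Derive a reproducible child seed from (seed, index); kept below 2^31.
.childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %%
               2147483647)
}

## Run `expr` under a local RNG stream without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == as.integer(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Strictly increasing finite numeric grid?
.checkGrid <- function(energies) {
  if (!is.numeric(energies) || length(energies) < 2L)
    return("energy grid must be numeric with at least 2 points")
  if (!all(is.finite(energies)))
    return("energy grid contains non-finite values")
  if (any(diff(energies) <= 0))
    return("energy grid must be strictly increasing")
  NULL
}

## GeLU and its derivative (exact erf form): gelu(x) = x * pnorm(x).
.gelu <- function(x) x * stats::pnorm(x)
.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplusInv <- function(y) ifelse(y > 30, y, log(expm1(y)))
.sigmoid <- function(x) 1 / (1 + exp(-x))
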