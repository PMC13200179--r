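## Shared fixtures and independent oracles. Everything is generated in
## code; heavyweight objects are memoized so several test files can share
## one benchmark dataset and one trained model.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- force(expr)
  .fixtureEnv[[name]]
}

randomSpectrumMatrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m, -0.2, 1.2), n, m)
}

## A small random molecule for invariance tests: absorber plus k atoms in
## a shell between rmin and rmax.
randomMolecule <- function(k = 8, seed = 1, rmin = 1.6, rmax = 6.5,
                           elements = c("C", "N", "O", "S", "Cl")) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * k), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  r <- runif(k, rmin, rmax)
  Molecule(c("Fe", sample(elements, k, replace = TRUE)),
           rbind(c(0, 0, 0), dirs * r), 1L)
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) *
    sign(det(qr.Q(qr(matrix(rnorm(9), 3, 3)))))
}

rigidMotion <- function(mol, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t <- rnorm(3, 0, 5)
  Molecule(elements(mol), sweep(coords(mol) %*% Q, 2, -t),
           absorberIndex(mol))
}

permuteEnvironment <- function(mol, seed = 1) {
  set.seed(seed)
  n <- nAtoms(mol)
  a <- absorberIndex(mol)
  env <- setdiff(seq_len(n), a)
  perm <- sample(env)
  ord <- seq_len(n)
  ord[env] <- perm
  m2 <- Molecule(elements(mol)[ord], coords(mol)[ord, , drop = FALSE],
                 which(ord == a))
  m2
}

## ---- independent MS-SSIM oracle: direct weighted sums with explicit
## index reflection (no convolution matrices) --------------------------

reflectIndex <- function(j, n) {
  while (j < 1 || j > n) {
    if (j < 1) j <- 2 - j
    if (j > n) j <- 2 * n - j
  }
  j
}

ssimOracleScale <- function(a, b, width, c1f = 0.01, c2f = 0.03) {
  n <- length(a)
  h <- as.integer(ceiling(3 * width))
  g <- dnorm(seq(-h, h), sd = width)
  g <- g / sum(g)
  R <- max(a, b) - min(a, b, 0)
  if (R <= 0) return(1)
  C1 <- (c1f * R)^2; C2 <- (c2f * R)^2
  vals <- numeric(n)
  for (i in seq_len(n)) {
    ma <- mb <- ea2 <- eb2 <- eab <- 0
    for (o in seq(-h, h)) {
      j <- reflectIndex(i + o, n)
      w <- g[o + h + 1]
      ma <- ma + w * a[j]; mb <- mb + w * b[j]
      ea2 <- ea2 + w * a[j]^2; eb2 <- eb2 + w * b[j]^2
      eab <- eab + w * a[j] * b[j]
    }
    va <- max(ea2 - ma^2, 0); vb <- max(eb2 - mb^2, 0)
    cab <- eab - ma * mb
    vals[i] <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  mean(vals)
}

msSsimOracle <- function(a, b, fracs = c(0.03, 0.05, 0.07)) {
  widths <- pmax(1, round(fracs * length(a)))
  mean(vapply(widths, function(w) ssimOracleScale(a, b, w), numeric(1)))
}

## ---- independent layer-by-layer AWE forward (loops, no shared code) --

refLayerNorm <- function(x, g, b, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  g * (x - mu) / sqrt(v + eps) + b
}

refGelu <- function(x) x * pnorm(x)

refAweForward <- function(model, ds) {
  p <- model@params; cfg <- model@config
  X <- ds@X; r <- ds@r
  x0 <- X[1, ]
  keep <- which(r[-1] <= cfg$cutoff)
  Xe <- X[-1, , drop = FALSE][keep, , drop = FALSE]
  re <- r[-1][keep]
  S <- cfg$S; d <- cfg$d
  bs <- log1p(exp(p$bRaw))
  u <- numeric(d * S)
  if (length(re) > 0) {
    for (s in seq_len(S)) {
      wt <- exp(-0.5 * ((re - p$rShell[s]) / bs[s])^2)
      w <- wt / (sum(wt) + cfg$epsilon)
      ms <- numeric(d)
      for (i in seq_along(re)) ms <- ms + w[i] * Xe[i, ]
      u[(s - 1) * d + seq_len(d)] <- ms
    }
  }
  z1 <- drop(p$Wsf %*% u) + p$bsf
  z <- drop(p$Waf %*% c(z1, x0)) + p$baf
  h <- z
  for (l in seq_len(cfg$L)) {
    a1 <- refLayerNorm(h, p[[paste0("lnG_", l)]], p[[paste0("lnB_", l)]])
    q <- drop(p[[paste0("W1_", l)]] %*% a1) + p[[paste0("b1_", l)]]
    o <- drop(p[[paste0("W2_", l)]] %*% refGelu(q)) + p[[paste0("b2_", l)]]
    h <- h + o
  }
  hout <- refLayerNorm(h, p$lnFg, p$lnFb)
  cvec <- unlist(lapply(seq_len(cfg$nGroups), function(g)
    drop(p[[paste0("Wh_", g)]] %*% hout) + p[[paste0("bh_", g)]]))
  list(coef = cvec, y = drop(model@basis@phi %*% cvec))
}

## Randomize the (zero-initialized) output heads so gradients flow through
## the whole network in gradient-correctness tests.
randomizeHeads <- function(model, seed = 1, scale = 0.05) {
  set.seed(seed)
  for (g in seq_len(model@config$nGroups)) {
    nm <- paste0("Wh_", g)
    model@params[[nm]][] <- rnorm(length(model@params[[nm]]), 0, scale)
  }
  model
}

## ---- memoized benchmark fixtures ------------------------------------

benchBasis <- function() memoFixture("benchBasis", {
  buildBasis(groundTruthParams()$energy, basisConfig())
})

benchProvider <- function() memoFixture("benchProvider", wacsfProvider())

## The standard synthetic benchmark at its study conditions (n = 600,
## seed 0) with descriptors precomputed; shared across acceptance tests.
benchData <- function() memoFixture("benchData", {
  ds <- generateDataset(syntheticConfig(nSamples = 600, seed = 0))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, benchProvider(),
                             benchBasis())
  split <- splitDataset(600, 0.2, seed = 1)
  list(ds = ds, dat = dat, split = split)
})

## The benchmark-trained AWE model (study conditions of the learnability
## check: 300 epochs, batch 32, lr 2e-3 halved every 100 epochs).
benchModel <- function() memoFixture("benchModel", {
  bd <- benchData()
  tr <- subsetPrepared(bd$dat, bd$split$train)
  trainModel(aweModel(benchProvider(), benchBasis(), seed = 11), tr,
             trainConfig(epochs = 300, seed = 42))
})
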