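test_that("shell weights normalize across atoms as specified", {
  ## single atom sitting on the shell: weight 1/(1 + eps)
  w <- shellWeights(2.0, radii = 2.0, blurs = 0.5)
  expect_equal(w[1, 1], 1 / (1 + 1e-8), tolerance = 1e-12)
  ## two atoms at 2.0 and 3.0 on a shell at 2.0 with blur 0.5
  w2 <- shellWeights(c(2, 3), radii = 2.0, blurs = 0.5)
  wt <- c(1, exp(-2))
  expect_equal(w2[, 1], wt / (sum(wt) + 1e-8), tolerance = 1e-10)
  expect_equal(w2[, 1], c(0.8808, 0.1192), tolerance = 1e-4)
  ## far atoms: weights ~ 0, never NaN
  w3 <- shellWeights(c(50, 60), radii = 2.0, blurs = 0.5)
  expect_false(anyNA(w3))
  expect_lt(max(w3), 1e-6)
})

test_that("per-shell weights sum to 1 when an atom is within reach", {
  set.seed(1)
  for (k in 1:20) {
    r <- runif(6, 0.5, 7)
    radii <- runif(3, 1, 6); blurs <- runif(3, 0.3, 1.5)
    W <- shellWeights(r, radii, blurs)
    inReach <- sapply(seq_along(radii), function(s)
      any(abs(r - radii[s]) < 3 * blurs[s]))
    sums <- colSums(W)
    expect_true(all(sums[inReach] > 1 - 1e-6 & sums[inReach] <= 1))
  }
})

test_that("shell summaries match a loop-based oracle and are permutation invariant", {
  set.seed(2)
  X <- matrix(rnorm(5 * 7), 5, 7)
  W <- shellWeights(runif(5, 1, 6), c(2, 4, 6), c(0.8, 0.8, 0.8))
  got <- shellSummaries(X, W)
  oracle <- numeric(0)
  for (s in 1:3) {
    m <- numeric(7)
    for (i in 1:5) m <- m + W[i, s] * X[i, ]
    oracle <- c(oracle, m)
  }
  expect_lt(max(abs(got - oracle)), 1e-10)
  p <- sample(5)
  expect_lt(max(abs(shellSummaries(X[p, ], W[p, ]) - got)), 1e-12)
  expect_equal(max(abs(shellSummaries(0 * X, W))), 0)
  expect_error(shellSummaries(X, W[1:3, ]), "contract error")
})

test_that("forward pass matches the independent layer-by-layer reference", {
  b <- benchBasis(); prov <- benchProvider()
  model <- randomizeHeads(aweModel(prov, b, seed = 21), seed = 3)
  for (seed in 1:4) {
    mol <- randomMolecule(k = 6, seed = seed)
    ds <- computeDescriptorSet(mol, prov)
    got <- forwardSpectrum(model, ds)
    ref <- refAweForward(model, ds)
    expect_lt(max(abs(got$coef - ref$coef)), 1e-6)
    expect_lt(max(abs(intensities(got$spectrum) - ref$y)), 1e-6)
  }
})

test_that("zero residual weights leave the latent unchanged before final LN", {
  b <- benchBasis(); prov <- benchProvider()
  model <- aweModel(prov, b, seed = 5)
  model@params$W1_1[] <- 0; model@params$W2_1[] <- 0
  model@params$b1_1[] <- 0; model@params$b2_1[] <- 0
  ds <- computeDescriptorSet(randomMolecule(k = 5, seed = 6), prov)
  inputs <- awespec:::.encoderInputs(list(ds), model@config$cutoff)
  fw <- awespec:::.aweForward(model@params, model@config, b, inputs)
  expect_equal(fw$cache$Hfin, fw$cache$Z, tolerance = 1e-12)
})

test_that("inference is deterministic and dropout only acts in training", {
  b <- benchBasis(); prov <- benchProvider()
  model <- randomizeHeads(aweModel(prov, b, seed = 7), seed = 8)
  mol <- randomMolecule(k = 6, seed = 9)
  y1 <- intensities(predictSpectrum(model, mol))
  y2 <- intensities(predictSpectrum(model, mol))
  expect_identical(y1, y2)
  ## training mode with dropout draws masks from the RNG
  ds <- computeDescriptorSet(mol, prov)
  inputs <- awespec:::.encoderInputs(list(ds), model@config$cutoff)
  set.seed(1)
  t1 <- awespec:::.aweForward(model@params, model@config, b, inputs,
                              training = TRUE)$Yhat
  set.seed(2)
  t2 <- awespec:::.aweForward(model@params, model@config, b, inputs,
                              training = TRUE)$Yhat
  expect_gt(max(abs(t1 - t2)), 0)
})

test_that("predictions are invariant to environment permutation and rigid motion", {
  b <- benchBasis(); prov <- benchProvider()
  model <- randomizeHeads(aweModel(prov, b, seed = 11), seed = 12)
  for (seed in 1:6) {
    mol <- randomMolecule(k = 7, seed = seed + 30)
    y0 <- intensities(predictSpectrum(model, mol))
    yP <- intensities(predictSpectrum(model, permuteEnvironment(mol, seed)))
    yR <- intensities(predictSpectrum(model, rigidMotion(mol, seed)))
    expect_lt(max(abs(y0 - yP)), 1e-6)
    expect_lt(max(abs(y0 - yR)), 1e-6)
  }
})

test_that("single-atom molecules flow through the absorber path", {
  b <- benchBasis(); prov <- benchProvider()
  model <- randomizeHeads(aweModel(prov, b, seed = 13), seed = 14)
  out <- forwardSpectrum(model, Molecule("Ni", matrix(0, 1, 3)))
  expect_length(intensities(out$spectrum), length(b@energy))
  expect_true(all(is.finite(intensities(out$spectrum))))
})

test_that("distinct absorber features give distinct latents", {
  b <- benchBasis(); prov <- benchProvider()
  model <- aweModel(prov, b, seed = 15)
  ds1 <- computeDescriptorSet(randomMolecule(k = 5, seed = 1), prov)
  ds2 <- ds1
  ds2@X[1, ] <- ds2@X[1, ] + 1
  inputs <- awespec:::.encoderInputs(list(ds1, ds2), model@config$cutoff)
  fw <- awespec:::.aweForward(model@params, model@config, b, inputs)
  expect_gt(max(abs(fw$cache$Z[, 1] - fw$cache$Z[, 2])), 1e-8)
})

test_that("head output length equals basis K across configurations", {
  prov <- benchProvider()
  for (stride in c(1, 4, 7)) {
    bb <- buildBasis(seq(0, 40, length.out = 100),
                     basisConfig(stride = stride))
    mm <- aweModel(prov, bb, seed = 16)
    out <- forwardSpectrum(mm, randomMolecule(k = 4, seed = 2))
    expect_length(out$coef, length(bb@centers))
  }
})

test_that("the AO baseline regresses the grid directly", {
  prov <- benchProvider()
  m <- aoModel(prov@dim, 100, seed = 17)
  x0 <- computeDescriptorSet(randomMolecule(k = 5, seed = 3), prov)@X[1, ]
  y <- aoForward(m, x0)
  expect_length(y, 100)
  ## zero-initialized output layer: first prediction is the zero spectrum
  expect_equal(max(abs(y)), 0)
  ## against a plain reference computation with a randomized output layer
  set.seed(18)
  m@params$W3[] <- rnorm(length(m@params$W3), 0, 0.05)
  y2 <- aoForward(m, x0)
  a1 <- refGelu(drop(m@params$W1 %*% x0) + m@params$b1)
  a2 <- refGelu(drop(m@params$W2 %*% a1) + m@params$b2)
  ref <- drop(m@params$W3 %*% a2) + m@params$b3
  expect_lt(max(abs(y2 - ref)), 1e-9)
})

test_that("checkpoints restore a model that predicts identically", {
  b <- benchBasis(); prov <- benchProvider()
  model <- randomizeHeads(aweModel(prov, b, seed = 19), seed = 20)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(model, path)
  model2 <- readModel(path)
  mol <- randomMolecule(k = 6, seed = 21)
  expect_equal(intensities(predictSpectrum(model2, mol)),
               intensities(predictSpectrum(model, mol)), tolerance = 1e-12)
  ## AO checkpoint round trip
  ao <- aoModel(prov@dim, 100, energy = b@energy, seed = 22)
  set.seed(23); ao@params$W3[] <- rnorm(length(ao@params$W3), 0, 0.1)
  p2 <- withr::local_tempfile(fileext = ".json")
  saveModel(ao, p2)
  ao2 <- readModel(p2)
  x0 <- computeDescriptorSet(mol, prov)@X[1, ]
  expect_equal(aoForward(ao2, x0), aoForward(ao, x0), tolerance = 1e-12)
})
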