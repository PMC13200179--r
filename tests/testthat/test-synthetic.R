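test_that("complex generation is deterministic in (seed, index)", {
  cfg <- syntheticConfig(seed = 12)
  m1 <- generateComplex(cfg, 5)
  m2 <- generateComplex(cfg, 5)
  expect_identical(elements(m1), elements(m2))
  expect_identical(coords(m1), coords(m2))
  m3 <- generateComplex(cfg, 6)
  expect_false(identical(coords(m1), coords(m3)))
})

test_that("first-shell geometry honours the distance law and angular separation", {
  cfg <- syntheticConfig(seed = 13)
  for (i in 1:100) {
    m <- generateComplex(cfg, i)
    r <- absorberDistances(m)
    first <- which(r > 0 & r <= 2.8)
    expect_gte(length(first), 4); expect_lte(length(first), 6)
    expect_true(all(r[first] >= 2.1 - 0.3 & r[first] <= 2.1 + 0.3))
    ## min pairwise angle between ligand directions >= 40 degrees
    dirs <- coords(m)[first, , drop = FALSE]
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cosmax <- max(tcrossprod(dirs)[upper.tri(diag(length(first)))])
    expect_lte(cosmax, cos(40 * pi / 180) + 1e-9)
    expect_gte(nAtoms(m), 5)
  }
})

test_that("ground-truth spectra match an independent closed-form evaluation", {
  cfg <- syntheticConfig(seed = 14)
  p <- groundTruthParams()
  for (i in 1:10) {
    m <- generateComplex(cfg, i)
    y <- intensities(groundTruthSpectrum(m, p))
    r <- absorberDistances(m)
    first <- r > 0 & r <= 2.8
    e0 <- 10 + 8 * (mean(r[first]) - 2.1)
    a1 <- 0.3 + 0.1 * (sum(first) - 4)
    zsec <- atomicNumber(elements(m)[r > 2.8])
    a2 <- 0.05 * mean(zsec) / 6
    e <- p$energy
    oracle <- 1 / (1 + exp(-(e - e0) / 0.8)) +
      a1 * exp(-0.5 * (e - e0 - 2)^2) +
      a2 * exp(-0.5 * ((e - 25) / 3)^2)
    expect_lt(max(abs(y - oracle)), 1e-12)
    expect_true(all(y >= 0) && max(y) < 1.45)
  }
})

test_that("edge position and white line follow their geometric laws", {
  ## stretch one bond by +0.1 A: the edge shifts by 8 * 0.1 / CN exactly
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mk <- function(d1) Molecule(c("Fe", rep("O", 4), "C"),
                              rbind(c(0, 0, 0), dirs * c(d1, 2.1, 2.1, 2.1),
                                    c(0, 0, 3.5)), 1L)
  p <- groundTruthParams()
  y1 <- intensities(groundTruthSpectrum(mk(2.1), p))
  y2 <- intensities(groundTruthSpectrum(mk(2.2), p))
  e <- p$energy
  shift <- 8 * 0.1 / 4
  oracle2 <- 1 / (1 + exp(-(e - 10 - shift) / 0.8)) +
    0.3 * exp(-0.5 * (e - 12 - shift)^2) +
    (0.05 * 6 / 6) * exp(-0.5 * ((e - 25) / 3)^2)
  expect_lt(max(abs(y2 - oracle2)), 1e-12)
  ## CN 6 vs CN 4 at equal distances: white line amplitude +0.2 exactly
  dirs6 <- rbind(dirs, c(0, 0, 1), c(0, 0, -1))
  m6 <- Molecule(c("Fe", rep("O", 6), "C"),
                 rbind(c(0, 0, 0), dirs6 * 2.1, c(3.5, 0.1, 0.1)), 1L)
  m4 <- Molecule(c("Fe", rep("O", 4), "C"),
                 rbind(c(0, 0, 0), dirs * 2.1, c(3.5, 0.1, 0.1)), 1L)
  y6 <- intensities(groundTruthSpectrum(m6, p))
  y4 <- intensities(groundTruthSpectrum(m4, p))
  diffOracle <- 0.2 * exp(-0.5 * (e - 12)^2)
  expect_lt(max(abs((y6 - y4) - diffOracle)), 1e-12)
})

test_that("datasets are reproducible, share a grid, and match the distance law", {
  cfg <- syntheticConfig(nSamples = 600, seed = 0)
  ds <- generateDataset(cfg)
  expect_length(ds$molecules, 600)
  ds2 <- generateDataset(cfg)
  expect_identical(coords(ds$molecules[[600]]), coords(ds2$molecules[[600]]))
  expect_identical(intensities(ds$spectra[[1]]), intensities(ds2$spectra[[1]]))
  meanFirst <- mean(vapply(ds$molecules, function(m) {
    r <- absorberDistances(m)
    mean(r[r > 0 & r <= 2.8])
  }, numeric(1)))
  expect_lt(abs(meanFirst - 2.1), 0.02)
})

test_that("the structure-to-spectrum map is smooth in the coordinates", {
  cfg <- syntheticConfig(seed = 15)
  m <- generateComplex(cfg, 1)
  y0 <- intensities(groundTruthSpectrum(m))
  h <- 1e-4
  xyz <- coords(m); xyz[2, 1] <- xyz[2, 1] + h
  y1 <- intensities(groundTruthSpectrum(Molecule(elements(m), xyz, 1L)))
  expect_lt(max(abs(y1 - y0)) / h, 10)
})

test_that("generated data round-trips through the file formats", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(syntheticConfig(nSamples = 4, seed = 16))
  loaded <- loadDataset(writeDataset(ds, dir))
  for (i in 1:4) {
    expect_lt(max(abs(coords(loaded$molecules[[i]]) -
                        coords(ds$molecules[[i]]))), 1e-6)
    expect_lt(max(abs(intensities(loaded$spectra[[i]]) -
                        intensities(ds$spectra[[i]]))), 1e-9)
  }
})

test_that("OOD batches land in their intended regimes via the production metric", {
  cfg <- syntheticConfig(nSamples = 120, seed = 0)
  ds <- generateDataset(cfg)
  prov <- benchProvider()
  X <- t(vapply(ds$molecules, function(m)
    computeDescriptorSet(m, prov)@X[1, ], numeric(prov@dim)))
  ood <- generateOodSplit(cfg, ds$molecules, X, prov, nPerRegime = 20)
  expect_true(all(ood$identical$d == 0))
  expect_true(all(classifyRegime(ood$familiar$d) == "familiar"))
  expect_true(all(classifyRegime(ood$unfamiliar$d) == "unfamiliar"))
  expect_gte(median(ood$strange$d), 1)
  ## strange uses ligand elements outside the training set
  els <- unique(unlist(lapply(ood$strange$molecules, function(m) {
    r <- absorberDistances(m)
    elements(m)[r > 0 & r <= max(2.8, min(r[r > 0]) + 0.9)]
  })))
  expect_true(all(els %in% c("P", "Br")))
})

test_that("the second-shell task hides its signal from short-cutoff descriptors", {
  task <- secondShellTask(syntheticConfig(seed = 0), nPerClass = 6)
  provShort <- wacsfProvider(wacsfConfig(cutoff = 3.0))
  for (i in 1:6) {
    a <- computeDescriptorSet(task$molecules[[i]], provShort)@X[1, ]
    b <- computeDescriptorSet(task$molecules[[i + 6]], provShort)@X[1, ]
    expect_lt(max(abs(a - b)), 1e-10)
  }
  ## but the spectra differ by the designed far-feature margin (evaluated
  ## at the grid point nearest the 25 eV feature center)
  yA <- intensities(task$spectra[[1]]); yB <- intensities(task$spectra[[7]])
  e <- groundTruthParams()$energy
  atten <- max(exp(-0.5 * ((e - 25) / 3)^2))
  margin <- 0.05 * (7 - 6) / 6 * atten
  expect_equal(max(abs(yA - yB)), margin, tolerance = 1e-9)
  ## and the full-cutoff descriptors do see the difference
  provFull <- benchProvider()
  a <- computeDescriptorSet(task$molecules[[1]], provFull)@X[1, ]
  b <- computeDescriptorSet(task$molecules[[7]], provFull)@X[1, ]
  expect_gt(max(abs(a - b)), 1e-3)
})
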