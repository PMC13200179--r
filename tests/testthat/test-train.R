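test_that("train/test splits are reproducible, disjoint and exhaustive", {
  s1 <- splitDataset(100, 0.2, seed = 7)
  s2 <- splitDataset(100, 0.2, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$test, 20)
  expect_length(s1$train, 80)
  for (k in 1:10) {
    n <- sample(5:200, 1)
    fr <- runif(1, 0.1, 0.9)
    s <- splitDataset(n, fr, seed = k)
    expect_equal(sort(c(s$train, s$test)), seq_len(n))
    expect_length(intersect(s$train, s$test), 0)
  }
  s3 <- splitDataset(2, 0.5, seed = 1)
  expect_length(s3$train, 1); expect_length(s3$test, 1)
  expect_error(splitDataset(1, 0.5), "at least 2")
})

test_that("the learning rate halves on the stated schedule", {
  expect_equal(lrSchedule(250, 2e-3, 100), 5e-4)
  expect_equal(lrSchedule(1, 2e-3, 100), 2e-3)
  expect_equal(lrSchedule(100, 2e-3, 100), 2e-3)
  expect_equal(lrSchedule(101, 2e-3, 100), 1e-3)
})

test_that("zero epochs returns the model unchanged", {
  b <- benchBasis(); prov <- benchProvider()
  model <- aweModel(prov, b, seed = 1)
  ds <- generateDataset(syntheticConfig(nSamples = 4, seed = 8))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, prov, b)
  out <- trainModel(model, dat, trainConfig(epochs = 0))
  expect_identical(out@params, model@params)
})

test_that("training is reproducible under a fixed seed", {
  b <- benchBasis(); prov <- benchProvider()
  ds <- generateDataset(syntheticConfig(nSamples = 12, seed = 9))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, prov, b)
  cfg <- trainConfig(epochs = 5, batchSize = 4, seed = 99)
  m1 <- trainModel(aweModel(prov, b, seed = 2), dat, cfg)
  m2 <- trainModel(aweModel(prov, b, seed = 2), dat, cfg)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(m1@params, m2@params)
})

test_that("the model memorizes a tiny training set", {
  b <- benchBasis(); prov <- benchProvider()
  ds <- generateDataset(syntheticConfig(nSamples = 10, seed = 3))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, prov, b)
  ## capacity check: dropout off, minibatches of 2 so 500 epochs provide
  ## enough optimizer steps on 10 samples
  model <- aweModel(prov, b, seed = 11, dropout = 0)
  trained <- trainModel(model, dat,
                        trainConfig(epochs = 500, batchSize = 2, seed = 42))
  expect_lt(tail(attr(trained, "history"), 1), 0.005)
})

test_that("evaluation summaries use interpolated quartiles and Tukey whiskers", {
  s <- summarizeLosses((1:8) / 100)
  expect_equal(s$median, 0.045)
  expect_equal(s$Q1, 0.0275)
  expect_equal(s$Q3, 0.0625)
  expect_equal(s$WL1, 0.01)
  expect_equal(s$WH1, 0.08)
  ## an outlier beyond the 1.5 IQR fence is excluded from the whisker
  s2 <- summarizeLosses(c((1:8) / 100, 0.5))
  expect_lt(s2$WH1, 0.5)
  ## all-identical losses collapse the box
  s3 <- summarizeLosses(rep(0.02, 6))
  expect_true(all(c(s3$WL1, s3$Q1, s3$median, s3$Q3, s3$WH1) == 0.02))
  s4 <- summarizeLosses(rep(0, 5))
  expect_equal(s4$median, 0)
})

test_that("regime curves assign training copies to 'identical' and partition the set", {
  bd <- benchData()
  sub <- subsetPrepared(bd$dat, 1:60)
  model <- randomizeHeads(aweModel(benchProvider(), benchBasis(), seed = 5),
                          seed = 6)
  rc <- regimeCurve(model, sub, trainX = t(sub$X0))
  expect_true(all(rc$regime == "identical"))
  expect_equal(length(rc$regime), 60L)
  expect_named(rc$summaries, "identical")
})

test_that("bootstrap ensembles are reproducible with audited resamples", {
  b <- benchBasis(); prov <- benchProvider()
  ds <- generateDataset(syntheticConfig(nSamples = 12, seed = 10))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, prov, b)
  cfg <- trainConfig(epochs = 2, batchSize = 4, seed = 1)
  e1 <- bootstrapTrain(aweModel(prov, b, seed = 3), dat, M = 2,
                       baseSeed = 17, config = cfg)
  e2 <- bootstrapTrain(aweModel(prov, b, seed = 3), dat, M = 2,
                       baseSeed = 17, config = cfg)
  expect_identical(e1@resampleIndex, e2@resampleIndex)
  expect_identical(e1@members[[1]]@params, e2@members[[1]]@params)
  expect_true(all(lengths(e1@resampleIndex) == 12))
  expect_false(identical(sort(e1@resampleIndex[[1]]),
                         sort(e1@resampleIndex[[2]])))
  expect_error(bootstrapTrain(aweModel(prov, b, seed = 3), dat, M = 1,
                              baseSeed = 1, config = cfg), "M >= 2")
})

test_that("ensemble statistics follow two-point member arithmetic", {
  ## two AO members with constant outputs y and y + 2 delta
  mk <- function(shift) {
    m <- aoModel(3, 10, hidden = 4, energy = seq(0, 9), seed = 1)
    m@params$b3[] <- shift
    m
  }
  ens <- new("EnsembleModel", members = list(mk(0.2), mk(0.6)),
             resampleIndex = list(1:3, 1:3), seeds = c(1L, 2L))
  ds <- new("DescriptorSet", X = matrix(0, 1, 3), r = 0, provider = "x")
  out <- ensemblePredict(ens, ds)
  expect_equal(intensities(out$mean), rep(0.4, 10))
  expect_equal(out$sd, rep(0.2, 10))
  expect_equal(out$spread, 0.2)
  ## identical members: zero spread
  ensSame <- new("EnsembleModel", members = list(mk(0.3), mk(0.3)),
                 resampleIndex = list(1:3, 1:3), seeds = c(1L, 2L))
  expect_equal(ensemblePredict(ensSame, ds)$spread, 0)
})

test_that("spread/error correlation follows the direct Pearson formula", {
  expect_equal(uncertaintyErrorCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(1, 2, 3); y <- c(2, 4, 6.5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(uncertaintyErrorCorrelation(x, y), oracle)
  expect_true(is.na(uncertaintyErrorCorrelation(c(1, 1, 1), y)))
  expect_true(is.na(uncertaintyErrorCorrelation(c(1, 2), c(3, 4))))
})

test_that("training aborts with a diagnostic on non-finite loss", {
  b <- benchBasis(); prov <- benchProvider()
  ds <- generateDataset(syntheticConfig(nSamples = 4, seed = 11))
  dat <- prepareTrainingData(ds$molecules, ds$spectra, prov, b)
  model <- aweModel(prov, b, seed = 1)
  model@params$Waf[] <- 1e308   # force overflow
  expect_error(trainModel(model, dat, trainConfig(epochs = 1, seed = 1)),
               "non-finite loss")
})
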