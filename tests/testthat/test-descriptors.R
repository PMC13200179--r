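test_that("wACSF of an isolated atom is the zero vector", {
  m <- Molecule("Fe", matrix(0, 1, 3))
  expect_equal(computeWacsfAtom(m, 1), rep(0, wacsfConfig()$dim))
})

test_that("neighbours at or beyond the cutoff contribute exactly zero", {
  cfg <- wacsfConfig()
  mAt <- Molecule(c("Fe", "O"), rbind(c(0, 0, 0), c(cfg$cutoff, 0, 0)))
  expect_equal(computeWacsfAtom(mAt, 1, cfg), rep(0, cfg$dim))
  ## adding an out-of-range atom changes nothing
  m1 <- randomMolecule(k = 5, seed = 3, rmax = 6.0)
  m2 <- Molecule(c(elements(m1), "Cl"),
                 rbind(coords(m1), c(9, 0, 0)), 1L)
  expect_equal(computeWacsfAtom(m2, 1, cfg), computeWacsfAtom(m1, 1, cfg))
})

test_that("Fe-O diatomic radial term matches the direct-sum oracle", {
  m <- Molecule(c("Fe", "O"), rbind(c(0, 0, 0), c(2, 0, 0)))
  cfg <- wacsfConfig(radialEtas = 1.0, radialCenters = 2.0,
                     angularEtas = numeric(0), angularZetas = numeric(0),
                     angularSigns = numeric(0), cutoff = 7.0)
  g <- computeWacsfAtom(m, 1, cfg)
  oracle <- 8 * exp(-1.0 * (2.0 - 2.0)^2) * 0.5 * (cos(2 * pi / 7) + 1)
  expect_equal(g[1], oracle, tolerance = 1e-10)
  expect_equal(oracle, 6.4939, tolerance = 1e-4)
})

test_that("wACSF components vanish continuously at the cutoff", {
  cfg <- wacsfConfig()
  vals <- sapply(c(0.2, 0.1, 0.05, 0.02, 0.01), function(delta) {
    m <- Molecule(c("Fe", "O", "O"),
                  rbind(c(0, 0, 0), c(cfg$cutoff - delta, 0, 0),
                        c(0, 2, 0)))
    sum(abs(computeWacsfAtom(m, 1, cfg) -
              computeWacsfAtom(Molecule(c("Fe", "O"),
                                        rbind(c(0, 0, 0), c(0, 2, 0))),
                               1, cfg)))
  })
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-3)
})

test_that("descriptor sets are invariant under rigid motion and permutation", {
  prov <- benchProvider()
  for (seed in 1:6) {
    m <- randomMolecule(k = 7, seed = seed)
    d0 <- computeDescriptorSet(m, prov)
    dR <- computeDescriptorSet(rigidMotion(m, seed + 50), prov)
    expect_lt(max(abs(d0@X - dR@X)), 1e-6)
    expect_lt(max(abs(d0@r - dR@r)), 1e-6)
    dP <- computeDescriptorSet(permuteEnvironment(m, seed + 80), prov)
    ## absorber row identical; environment rows a permutation
    expect_lt(max(abs(d0@X[1, ] - dP@X[1, ])), 1e-9)
    o1 <- order(d0@r[-1], d0@X[-1, 1])
    o2 <- order(dP@r[-1], dP@X[-1, 1])
    expect_lt(max(abs(d0@X[-1, , drop = FALSE][o1, ] -
                        dP@X[-1, , drop = FALSE][o2, ])), 1e-9)
  }
})

test_that("single-atom molecules give a 1 x d descriptor set with r = 0", {
  ds <- computeDescriptorSet(Molecule("Zn", matrix(0, 1, 3)),
                             benchProvider())
  expect_equal(dim(ds@X), c(1L, benchProvider()@dim))
  expect_equal(ds@r, 0)
  expect_true(all(ds@X == 0))
})

test_that("provider contract violations are caught", {
  bad <- matrixProvider(function(mol) matrix(0, 2, 3), dim = 3)
  expect_error(computeDescriptorSet(Molecule("Fe", matrix(0, 1, 3)), bad),
               "contract violation")
})

test_that("absorber distances are Euclidean, translation invariant and equivariant", {
  m <- Molecule(c("Fe", "O"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(absorberDistances(m), c(0, 5))
  m2 <- Molecule(elements(m), sweep(coords(m), 2, c(-7, 2, 11)), 1L)
  expect_equal(absorberDistances(m2), c(0, 5))
  m3 <- Molecule(rev(elements(m)), coords(m)[2:1, ], 2L)
  expect_equal(absorberDistances(m3), c(5, 0))
})

test_that("nearest-neighbour distance matches brute force and is scale equivariant", {
  trainX <- rbind(c(0, 0), c(1, 0))
  expect_equal(nearestNeighborDistance(c(0.5, 0), trainX, 1), 0.5)
  expect_equal(nearestNeighborDistance(c(1, 0), trainX, 1), 0)
  set.seed(9)
  X <- matrix(rnorm(40), 10, 4)
  v <- rnorm(4)
  brute <- min(apply(X, 1, function(x) sqrt(sum((x - v)^2))))
  expect_equal(nearestNeighborDistance(v, X, 1), brute, tolerance = 1e-12)
  ## scaling descriptors and normalizer together leaves d unchanged
  n1 <- meanNNDistance(X)
  expect_equal(nearestNeighborDistance(v, X, n1),
               nearestNeighborDistance(10 * v, 10 * X, meanNNDistance(10 * X)),
               tolerance = 1e-9)
  expect_error(nearestNeighborDistance(v, X[0, , drop = FALSE], 1),
               "empty")
  expect_error(nearestNeighborDistance(v, X, 0), "positive")
})

test_that("regime classification partitions [0, Inf) at the stated bounds", {
  expect_equal(as.character(classifyRegime(0)), "identical")
  expect_equal(as.character(classifyRegime(0.01)), "familiar")
  expect_equal(as.character(classifyRegime(0.5)), "unfamiliar")
  expect_equal(as.character(classifyRegime(1.0)), "strange")
  ## boundaries: lower bound inclusive for each regime
  expect_equal(as.character(classifyRegime(c(1e-3, 10^-1.5, 1))),
               c("familiar", "unfamiliar", "strange"))
  expect_error(classifyRegime(-0.1), "nonnegative")
  set.seed(11)
  d <- c(0, 10^runif(200, -5, 1))
  lab <- classifyRegime(d)
  expect_false(anyNA(lab))
  expect_equal(length(lab), 201L)
})
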