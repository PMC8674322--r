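test_that("training configurations are validated", {
  expect_error(trainConfig(epsilon = c(0.01, 0.5)), "epsilon")
  expect_error(trainConfig(iterations = 0), "iterations")
  expect_error(trainConfig(sigma = c(1, -1)), "sigma")
  expect_error(trainConfig(variant = "batch"), "'arg'")
  cfg <- trainConfig()
  expect_s4_class(cfg, "TrainConfig")
  expect_equal(cfg@iterations, 3000L)
  expect_equal(cfg@band, 60)
})

test_that("grid initialization is seeded, bounded and falls back to replacement", {
  X <- matrix(runif(20 * 12), 20, 12)
  cfg <- trainConfig(seed = 5)
  g1 <- initGrid(2, 3, X, cfg)
  expect_identical(somWeights(g1), somWeights(initGrid(2, 3, X, cfg)))
  expect_true(all(somWeights(g1) >= min(X) & somWeights(g1) <= max(X)))
  gr <- initGrid(2, 3, X, trainConfig(init = "random", seed = 5))
  expect_true(all(somWeights(gr) >= min(X) & somWeights(gr) <= max(X)))
  same <- matrix(rep(X[, 1], 4), 20, 4)
  gs <- initGrid(2, 2, same, cfg)
  expect_true(all(apply(somWeights(gs), 1, function(w) all(w == X[, 1]))))
  expect_warning(initGrid(3, 3, X[, 1:4], cfg), "replacement")
})

test_that("the best-matching unit follows the variant's metric with row-major ties", {
  # DTW absorbs the one-step shift; Euclidean prefers the flat neuron
  A <- c(0, 1, 0, 0); B <- rep(0.25, 4); x <- c(0, 0, 1, 0)
  grid <- new("SomGrid", rows = 1L, cols = 2L, weights = rbind(A, B))
  bd <- findBmu(grid, x, variant = "dtw_full", band = 3)
  be <- findBmu(grid, x, variant = "euclidean")
  expect_equal(bd$index, 1); expect_equal(bd$distance, 0)
  expect_equal(be$index, 2)
  expect_equal(be$distance, sqrt(0.75))
  # exact match wins with distance zero; ties break to the lower index
  g2 <- new("SomGrid", rows = 1L, cols = 2L, weights = rbind(x, x))
  expect_equal(findBmu(g2, x, "euclidean")$index, 1)
  expect_equal(findBmu(g2, x, "dtw_match", band = 3)$distance, 0)
  expect_error(findBmu(grid, 1:5, "euclidean"), "length")
})

test_that("the neighborhood kernel is Gaussian in the chosen space", {
  g <- new("SomGrid", rows = 2L, cols = 2L,
           weights = matrix(c(0, 0, 1, 1, 0, 0, 2, 2), 4, 2, byrow = TRUE))
  expect_equal(neighborhoodWeight(g, 2, 2, sigma = 1), 1.0)
  expect_equal(neighborhoodWeight(g, 1, 2, sigma = 1), exp(-0.5))
  expect_lt(neighborhoodWeight(g, 1, 2, sigma = 1e-4), 1e-12)
  # weight-space kernel: neurons 1 and 2 differ by 1 at both timestamps
  d12 <- dtwDistance(c(0, 0), c(1, 1))@distance
  expect_equal(neighborhoodWeight(g, 1, 2, sigma = 1,
                                  kernel_space = "dtw_weightspace"),
               exp(-d12^2 / 2))
})

test_that("the timestamp-aligned update is the convex elementwise rule", {
  W <- c(0, 0); x <- c(1, 1)
  expect_equal(updateEuclidean(W, x, 0), W)
  expect_equal(updateEuclidean(W, x, 1, 1), x)
  expect_equal(updateEuclidean(W, x, 0.5, 1), c(0.5, 0.5))
  expect_error(updateEuclidean(W, 1:3, 0.5), "length")
  expect_error(updateEuclidean(W, x, 2, 1), "\\[0, 1\\]")
})

test_that("the warping-aligned update follows the hand-traced alignment", {
  W <- c(0, 1, 0, 0); x <- c(0, 0, 1, 0)
  expect_equal(updateDtw(W, x, 0, 1), W)                     # identity at 0
  expect_equal(updateDtw(W, x, 1, 1), x)                     # full step lands on x
  # half step: pairs (0,0),(0,1),(1,2),(2,3),(3,3) give points
  # (0,0),(0.5,0),(1.5,1),(2.5,0),(3,0) -> resampled [0, 0.5, 0.5, 0]
  expect_equal(updateDtw(W, x, 0.5, 1), c(0, 0.5, 0.5, 0))
})

test_that("a diagonal alignment path makes both update rules coincide", {
  W <- c(0, 10, 0, 10, 0); x <- c(0.4, 10.4, 0.4, 10.4, 0.4)
  p <- dtwDistance(W, x)@path
  expect_equal(p[, 1], p[, 2])            # the optimal path is the diagonal
  for (eh in c(0.1, 0.5, 0.9))
    expect_equal(updateDtw(W, x, eh, 1), updateEuclidean(W, x, eh, 1),
                 tolerance = 1e-12)
})

test_that("warping-aligned updates never leave the value range of inputs", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      W <- runif(n, -1, 1); x <- runif(n, -1, 1)
      eh <- runif(1)
      u <- updateDtw(W, x, eh, 1)
      expect_gte(min(u), min(c(W, x)) - 1e-12)
      expect_lte(max(u), max(c(W, x)) + 1e-12)
      expect_length(u, n)
    }
  })
})

test_that("training on identical series collapses every neuron onto them", {
  x <- sin(seq(0, 2 * pi, length.out = 40))
  X <- matrix(rep(x, 8), 40, 8)
  for (v in c("euclidean", "dtw_match", "dtw_full")) {
    fit <- trainSom(X, 1, 2, trainConfig(variant = v, iterations = 300,
                                         band = 10, seed = 2))
    expect_lt(quantizationError(somGrid(fit), X, assignmentTable(fit)), 1e-3)
  }
})

test_that("training is deterministic under the seed and rejects empty data", {
  d <- simulatePrototypeDays(n = 20, len = 48, k = 2, warp_magnitude = 3,
                             noise_sd = 0.3, seed = 9)
  cfg <- trainConfig(variant = "dtw_full", iterations = 100, band = 10, seed = 4)
  f1 <- trainSom(d$values, 2, 2, cfg)
  f2 <- trainSom(d$values, 2, 2, cfg)
  expect_identical(somWeights(somGrid(f1)), somWeights(somGrid(f2)))
  expect_identical(assignmentTable(f1), assignmentTable(f2))
  expect_error(trainSom(matrix(numeric(0), 10, 0), 1, 1, cfg), "empty")
})

test_that("on already-aligned data the full-DTW and Euclidean variants coincide", {
  # constant series: every optimal warping path is the diagonal
  withr::with_seed(12, {
    levels <- runif(30, 0, 1)
    X <- matrix(rep(levels, each = 25), 25, 30)
  })
  cfg <- function(v) trainConfig(variant = v, iterations = 200, band = 5,
                                 seed = 8, qe_every = 50)
  fe <- trainSom(X, 2, 2, cfg("euclidean"))
  fd <- trainSom(X, 2, 2, cfg("dtw_full"))
  expect_equal(somWeights(somGrid(fd)), somWeights(somGrid(fe)),
               tolerance = 1e-9)
  expect_equal(assignmentTable(fd)$neuron, assignmentTable(fe)$neuron)
})

test_that("trained weights stay inside the dataset's value range", {
  d <- simulateImpulseDays(n = 15, len = 60, warp_magnitude = 10, seed = 3)
  for (v in c("euclidean", "dtw_full")) {
    fit <- trainSom(d$values, 2, 2, trainConfig(variant = v, iterations = 150,
                                                band = 15, seed = 3))
    W <- somWeights(somGrid(fit))
    expect_gte(min(W), min(d$values) - 1e-12)
    expect_lte(max(W), max(d$values) + 1e-12)
  }
})

test_that("two well-separated constant prototypes are both recovered", {
  X <- cbind(matrix(0.2, 30, 15), matrix(0.8, 30, 15))
  fit <- trainSom(X, 1, 2, trainConfig(variant = "dtw_full", iterations = 300,
                                       band = 5, seed = 11))
  m <- sort(rowMeans(somWeights(somGrid(fit))))
  expect_lt(abs(m[1] - 0.2), 0.05)
  expect_lt(abs(m[2] - 0.8), 0.05)
})
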