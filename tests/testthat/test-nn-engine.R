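# Checks of the training engine itself: analytic gradients against finite
# differences, determinism, and the ability to fit separable data.

test_that("backward pass matches finite-difference gradients", {
  ns <- asNamespace("LabelSweep")
  model <- buildModel(smallReferenceSpec(16, 2), seed = 3)
  set.seed(9)
  N <- 3
  X <- array(runif(16 * 16 * 3 * N), c(256, 3, N))
  y <- c(0L, 1L, 0L)
  A <- ns$.batchMatrix(X, seq_len(N))
  mdl <- ns$.asEnv(model)
  fw <- ns$.nnForward(mdl, A, N, training = TRUE)
  sl <- ns$.softmaxLoss(fw$logits, y)
  grads <- ns$.nnBackward(mdl, fw$caches, sl$dLogits, N)
  lossAt <- function(m2) {
    ns$.softmaxLoss(ns$.nnForward(m2, A, N, training = TRUE)$logits, y)$loss
  }
  eps <- 1e-5
  for (i in seq_along(mdl$params)) {
    p <- mdl$params[[i]]
    if (is.null(p)) next
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      for (j in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
        m2 <- ns$.asEnv(model)
        m2$params[[i]][[nm]][j] <- m2$params[[i]][[nm]][j] + eps
        lp <- lossAt(m2)
        m2 <- ns$.asEnv(model)
        m2$params[[i]][[nm]][j] <- m2$params[[i]][[nm]][j] - eps
        lm <- lossAt(m2)
        num <- (lp - lm) / (2 * eps)
        ana <- grads[[i]][[nm]][j]
        # relative error with an absolute floor: conv weights feeding
        # batch norm have near-zero gradients, where the finite
        # difference itself is pure cancellation noise
        expect_lt(abs(num - ana) / (abs(num) + abs(ana) + 1e-3), 2e-3)
      }
    }
  }
})

test_that("training is deterministic given config and seed", {
  m <- cachedDataset(20, 4, 16, seed = 21)
  cfg <- cleanerConfig(imageSize = 16, epochsPerRound = 2, baseSeed = 5)
  spec <- smallReferenceSpec(16, 2)
  f1 <- trainOneRound(m, spec, cfg, roundIndex = 1)
  f2 <- trainOneRound(m, spec, cfg, roundIndex = 1)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$lossHistory, f2$lossHistory)
  f3 <- trainOneRound(m, spec, cfg, roundIndex = 2)
  expect_false(identical(f1$model@params, f3$model@params))
})

test_that("training fits a clean separable set as well as the centroid oracle", {
  m <- cachedDataset(30, 4, 16, seed = 22)
  cfg <- cleanerConfig(imageSize = 16, epochsPerRound = 10, baseSeed = 3)
  fit <- trainOneRound(m, smallReferenceSpec(16, 2), cfg, roundIndex = 1)
  flagged <- flagMisclassified(fit$model, m)
  expect_length(flagged, 0)   # 100% training accuracy
  feat <- manifestPixelMatrix(m, 16)
  y <- observedIndex(m)
  expect_equal(mean(centroidPredict(feat, y) == y), 1)  # oracle agrees
})

test_that("the loss decreases over training on separable data", {
  m <- cachedDataset(30, 4, 16, seed = 22)
  cfg <- cleanerConfig(imageSize = 16, epochsPerRound = 10, baseSeed = 3)
  fit <- trainOneRound(m, smallReferenceSpec(16, 2), cfg, roundIndex = 1)
  h <- fit$lossHistory
  expect_lt(mean(utils::tail(h, 5)), mean(utils::head(h, 5)))
})

test_that("plateau rule halves the rate exactly when a window stalls", {
  cfg <- cleanerConfig(plateauWindow = 5, initialLearningRate = 1e-3)
  # strictly decreasing: untouched
  expect_equal(updateLearningRate(seq(2, 0.1, length.out = 10), 1e-3, cfg),
               1e-3)
  # two equal constant windows: "not decrease" boundary case halves
  expect_equal(updateLearningRate(rep(1, 10), 1e-3, cfg), 5e-4)
  # fewer than two windows, or off-boundary: no-op
  expect_equal(updateLearningRate(rep(1, 9), 1e-3, cfg), 1e-3)
  expect_equal(updateLearningRate(rep(1, 12), 1e-3, cfg), 1e-3)
  # floor at minLearningRate
  cfg2 <- cleanerConfig(plateauWindow = 5, minLearningRate = 4e-4)
  expect_equal(updateLearningRate(rep(1, 10), 5e-4, cfg2), 4e-4)
})

test_that("a plateau followed by descent triggers exactly one halving", {
  cfg <- cleanerConfig(plateauWindow = 5, initialLearningRate = 1e-3)
  trace <- c(rep(2, 5), rep(2, 5),            # stalled pair of windows
             seq(1.9, 0.2, length.out = 10))  # then steady descent
  # oracle: enumerate consecutive non-overlapping window means
  means <- vapply(seq_len(length(trace) / 5),
                  function(k) mean(trace[(5 * k - 4):(5 * k)]), numeric(1))
  expectHalvings <- sum(diff(means) >= 0)
  lr <- 1e-3
  halvings <- 0L
  for (n in seq_along(trace)) {
    new <- updateLearningRate(trace[seq_len(n)], lr, cfg)
    if (new < lr) halvings <- halvings + 1L
    lr <- new
  }
  expect_equal(halvings, expectHalvings)
  expect_equal(halvings, 1L)
})
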