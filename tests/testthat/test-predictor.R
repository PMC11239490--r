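# Model architecture, losses, augmentation, calibration and training sanity.

tinyCfg <- function(K = 4L) {
  modelConfig(n_classes = K, n_bins = 40L, dilations = c(1L, 2L),
              pool_kernel = 5L, trunk_dim = 8L, embed_dim = 3L, dropout = 0,
              conv_channels = 3L, conv_kernel = 3L, hidden_dim = 6L)
}

tinyInputs <- function(N = 3L, L = 40L, seed = 5) {
  set.seed(seed)
  list(x = matrix(runif(2 * L * N), 2L, L * N),
       scal = matrix(runif(2L * N), 2L, N),
       meta = matrix(sample(0:2, 5L * N, replace = TRUE), 5L, N),
       L = L, N = N)
}

test_that("the forward pass has the contracted shape and determinism", {
  m <- buildModel(tinyCfg(), seed = 3)
  inputs <- tinyInputs()
  fw1 <- glycrunch:::.nnForward(m, inputs, train = FALSE)
  expect_equal(dim(fw1$logits), c(4L, 3L))
  # dropout disabled at evaluation: two eval passes identical
  fw2 <- glycrunch:::.nnForward(m, inputs, train = FALSE)
  expect_identical(fw1$logits, fw2$logits)
  # sensitivity: perturbing one bin changes the scores
  inputs2 <- inputs
  inputs2$x[1L, 7L] <- inputs2$x[1L, 7L] + 0.5
  fw3 <- glycrunch:::.nnForward(m, inputs2, train = FALSE)
  expect_gt(max(abs(fw3$logits[, 1L] - fw1$logits[, 1L])), 0)
  expect_identical(fw3$logits[, 2:3], fw1$logits[, 2:3])
})

test_that("analytic gradients match numerical differentiation", {
  m <- buildModel(tinyCfg(), seed = 3)
  inputs <- tinyInputs()
  y <- c(1L, 3L, 2L)
  tcfg <- trainConfig()
  lib <- generateLibrary(4, seed = 11)
  D <- distanceMatrices(lib)
  fw <- glycrunch:::.nnForward(m, inputs, train = TRUE)  # keeps the cache
  lg <- glycrunch:::.lossGrad(fw$logits, y, tcfg, D$structure, D$composition)
  grads <- glycrunch:::.nnBackward(m, fw$cache, lg$dlogits)
  lossAt <- function(params) {
    m2 <- m; m2$params <- params
    f <- glycrunch:::.nnForward(m2, inputs, train = FALSE)
    glycrunch:::.lossGrad(f$logits, y, tcfg, D$structure, D$composition)$loss
  }
  set.seed(9)
  for (nm in sample(names(grads), 12L)) {
    i <- sample(length(m$params[[nm]]), 1L)
    h <- 1e-5
    p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (lossAt(p1) - lossAt(p2)) / (2 * h)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("distanceLoss is the expected distance under the prediction", {
  expect_equal(distanceLoss(c(1, 0, 0), c(0, 0.4, 0.9)), 0)
  expect_equal(distanceLoss(c(0.2, 0.5, 0.3), rep(0.37, 3)), 0.37)
  expect_equal(distanceLoss(rep(0.25, 4), c(0, 0, 1, 1)), 0.5)
  # bounded in [0,1] for distances in [0,1]
  set.seed(2)
  p <- matrix(runif(12), 4); p <- sweep(p, 2, colSums(p), "/")
  d <- matrix(runif(12), 4)
  expect_true(distanceLoss(p, d) >= 0 && distanceLoss(p, d) <= 1)
  expect_error(distanceLoss(c(0.5, 0.5), c(1, 2, 3)), "same number")
})

test_that("with all-zero distances the total loss reduces to PolyLoss", {
  set.seed(4)
  logits <- matrix(rnorm(20), 5)
  y <- c(1L, 4L, 2L, 5L)
  tcfg <- trainConfig()
  plain <- glycrunch:::.lossGrad(logits, y, tcfg)
  zeroD <- glycrunch:::.lossGrad(logits, y, tcfg,
                                 matrix(0, 5, 5), matrix(0, 5, 5))
  expect_equal(plain$loss, zeroD$loss)
  expect_equal(plain$dlogits, zeroD$dlogits)
  expect_equal(plain$loss, polyLoss(logits, y), tolerance = 1e-12)
})

test_that("augmentation respects its configured bounds", {
  g <- generateLibrary(1, seed = 20)[[1]]
  s <- simulateSpectrum(g, simParams(), seed = 2)
  # all rates zero -> identity
  off <- augmentConfig(peak_drop_frac = 0, intensity_jitter_sd = 0,
                       new_peak_rate = 0, adduct_prob = 0,
                       precursor_jitter = 0, rt_jitter = 0)
  s0 <- augmentSpectrum(s, off, seed = 1)
  expect_equal(s0@mz, s@mz)
  expect_equal(s0@intensity, s@intensity)
  expect_equal(precursorMz(s0), precursorMz(s))
  # fixed seed -> identical output
  a1 <- augmentSpectrum(s, augmentConfig(), seed = 42)
  a2 <- augmentSpectrum(s, augmentConfig(), seed = 42)
  expect_identical(a1@mz, a2@mz)
  # precursor jitter bounded by 0.5 Da without adducts
  acfg <- augmentConfig(adduct_prob = 0)
  deltas <- vapply(seq_len(1e4), function(i) {
    precursorMz(augmentSpectrum(s, acfg)) - precursorMz(s)
  }, numeric(1))
  expect_true(all(abs(deltas) <= 0.5))
})

test_that("Platt scaling calibrates without changing the single-pass argmax", {
  K <- 4L
  m <- buildModel(tinyCfg(K), seed = 3)
  # uniform logits -> uniform probabilities regardless of the factor
  u <- glycrunch:::.softmax(matrix(0, K, 1) / 1.15)
  expect_equal(as.numeric(u), rep(1 / K, K))
  set.seed(6)
  z <- matrix(rnorm(K), K, 1)
  p1 <- glycrunch:::.softmax(z)
  p2 <- glycrunch:::.softmax(z / 1.15)
  expect_equal(which.max(p1), which.max(p2))
  # calibration flattens confident predictions
  expect_lt(max(p2), max(p1))
})

test_that("calibrateAndPredict honors k, TTA settings and clipping", {
  lib <- generateLibrary(4, seed = 22)
  cfg <- modelConfig(n_classes = 4L, conv_channels = 4L, trunk_dim = 16L,
                     hidden_dim = 8L)
  m <- buildModel(cfg, seed = 2)
  b <- binSpectrum(simulateSpectrum(lib[[1]], simParams(), seed = 3))
  res <- calibrateAndPredict(m, b, tta_rounds = 1L, k = 4L)
  expect_equal(nrow(res), 4L)
  expect_equal(sum(res$score), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(-res$score))
  # tta_rounds = 1 equals the plain calibrated softmax
  fw <- glycrunch:::.nnForward(m, glycrunch:::.buildInputs(list(b)),
                               train = FALSE)
  plain <- glycrunch:::.softmax(fw$logits / 1.15)[, 1L]
  expect_equal(res$score, sort(plain, decreasing = TRUE), tolerance = 1e-12)
  expect_warning(calibrateAndPredict(m, b, tta_rounds = 1L, k = 10L),
                 "clipping")
})

test_that("a small model learns separable synthetic data", {
  lib <- generateLibrary(4, seed = 30)
  d <- makeDataset(lib, spectra_per_glycan = 10, params = simParams(),
                   seed = 31)
  binned <- lapply(d$spectra, binSpectrum)
  tr <- d$split == "train"
  cfg <- modelConfig(n_classes = 4L, conv_channels = 8L, hidden_dim = 64L)
  tcfg <- trainConfig(seed = 1, epochs = 5L, lr = 1e-3, batch = 32L)
  m <- trainModel(buildModel(cfg, seed = 1), binned[tr], d$label[tr],
                  binned[!tr], d$label[!tr], tcfg, acfg = NULL)
  h <- m$history
  expect_true(all(is.finite(h$train_loss)))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1L])
})

test_that("the predictor interface returns a full score vector", {
  lib <- generateLibrary(4, seed = 22)
  cfg <- modelConfig(n_classes = 4L, conv_channels = 4L, trunk_dim = 16L,
                     hidden_dim = 8L)
  m <- buildModel(cfg, seed = 2)
  pred <- nnPredictor(m, lib, tta_rounds = 1L)
  b <- binSpectrum(simulateSpectrum(lib[[2]], simParams(), seed = 3))
  sc <- pred$scores(b)
  expect_equal(length(sc), 4L)
  expect_equal(sum(sc), 1, tolerance = 1e-9)
})
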