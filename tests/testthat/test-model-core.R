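# Forward operations against literal brute-force oracles, and exact
# parameter accounting.

test_that("layerNorm matches direct evaluation and its affine identity", {
  expect_equal(layerNorm(c(1, 1, 1), 1, 0), c(0, 0, 0))
  # population variance of (1,2,3) is 2/3
  expect_equal(layerNorm(c(1, 2, 3), 1, 0, eps = 0),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(21)
  for (i in 1:20) {
    C <- sample(2:12, 1)
    x <- rnorm(C, sd = 3)
    g <- runif(C, 0.5, 2); b <- rnorm(C)
    expect_equal(layerNorm(x, g, b), oracle_layer_norm(x, g, b, 1e-5),
                 tolerance = 1e-10)
    expect_equal(layerNorm(x, g, b), g * layerNorm(x, 1, 0) + b,
                 tolerance = 1e-10)
  }
})

test_that("conv blocks reproduce the sliding-window oracle and length bookkeeping", {
  set.seed(22)
  for (i in 1:25) {
    L <- sample(4:14, 1); Cin <- sample(2:6, 1); Cout <- sample(2:6, 1)
    K <- sample(c(1, 3, 5), 1)
    x <- matrix(rnorm(L * Cin), L, Cin)
    W <- array(rnorm(Cout * Cin * K), c(Cout, Cin, K))
    b <- rnorm(Cout); g <- runif(Cout, 0.5, 1.5); be <- rnorm(Cout)
    got <- convBlockForward(x, W, b, g, be, eps = 1e-5, pool = 2)
    expect_equal(got, oracle_conv_block(x, W, b, g, be, 1e-5, 2),
                 tolerance = 1e-10)
  }
  # length chain at the real data's minimum: 18 -> 9 -> 4 -> 2
  x <- matrix(rnorm(18 * 20), 18, 20)
  W <- array(rnorm(20 * 20 * 3, sd = 0.1), c(20, 20, 3))
  ln1 <- convBlockForward(x, W, rnorm(20), rep(1, 20), rep(0, 20))
  ln2 <- convBlockForward(ln1, W, rnorm(20), rep(1, 20), rep(0, 20))
  ln3 <- convBlockForward(ln2, W, rnorm(20), rep(1, 20), rep(0, 20))
  expect_equal(c(nrow(ln1), nrow(ln2), nrow(ln3)), c(9, 4, 2))
  # zero kernel with bias: layer norm collapses the constant, ReLU(0) = 0
  got <- convBlockForward(x, array(0, c(20, 20, 3)), rep(2, 20),
                          rep(1, 20), rep(0, 20))
  expect_equal(got, matrix(0, 9, 20))
  expect_error(convBlockForward(matrix(0, 1, 20), W, rnorm(20),
                                rep(1, 20), rep(0, 20)), "pool")
})

test_that("scaled dot-product attention matches the elementwise oracle", {
  Vy <- matrix(rnorm(8), 1, 8)
  expect_equal(scaledDotProductAttention(matrix(1, 1, 4), matrix(2, 1, 4), Vy),
               Vy)                     # l = 1: softmax of a scalar is 1
  set.seed(23)
  K1 <- matrix(rep(rnorm(4), each = 5), 5, 4)   # identical keys
  V1 <- matrix(rnorm(15), 5, 3)
  got <- scaledDotProductAttention(matrix(rnorm(20), 5, 4), K1, V1)
  expect_equal(got, matrix(rep(colMeans(V1), each = 5), 5, 3),
               tolerance = 1e-12)
  for (i in 1:25) {
    l <- sample(2:8, 1); dk <- sample(2:6, 1); dv <- sample(2:6, 1)
    Q <- matrix(rnorm(l * dk), l, dk); K <- matrix(rnorm(l * dk), l, dk)
    V <- matrix(rnorm(l * dv), l, dv)
    expect_equal(scaledDotProductAttention(Q, K, V), oracle_sdpa(Q, K, V),
                 tolerance = 1e-10)
  }
})

test_that("multi-head attention concatenates per-head attention correctly", {
  set.seed(24)
  d <- 20
  Z <- matrix(rnorm(5 * d), 5, d)
  Ws <- replicate(4, matrix(rnorm(d * d, sd = 0.3), d, d), simplify = FALSE)
  expect_equal(multiHeadAttention(Z, Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]], 5),
               oracle_mha(Z, Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]], 5),
               tolerance = 1e-10)
  # h = 1 reduces to a single scaled dot-product attention + output projection
  expect_equal(multiHeadAttention(Z, Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]], 1),
               scaledDotProductAttention(Z %*% Ws[[1]], Z %*% Ws[[2]],
                                         Z %*% Ws[[3]]) %*% Ws[[4]],
               tolerance = 1e-10)
  expect_equal(dim(multiHeadAttention(matrix(rnorm(d), 1, d),
                                      Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]], 4)),
               c(1L, d))
})

test_that("the encoder layer matches the oracle and is permutation-equivariant", {
  set.seed(25)
  for (i in 1:10) {
    l <- sample(2:7, 1); d <- 20
    Z <- matrix(rnorm(l * d), l, d)
    w <- random_tx_weights(d, 16)
    expect_equal(transformerEncoder(Z, w, 5), oracle_encoder(Z, w, 5, 1e-5),
                 tolerance = 1e-8)
  }
  l <- 6; d <- 20
  Z <- matrix(rnorm(l * d), l, d)
  w <- random_tx_weights(d, 16)
  out <- transformerEncoder(Z, w, 5)
  expect_equal(dim(out), dim(Z))
  perm <- sample(l)
  expect_equal(transformerEncoder(Z[perm, ], w, 5), out[perm, ],
               tolerance = 1e-10)
})

test_that("attention rows are a proper distribution (sum to one)", {
  set.seed(26)
  for (i in 1:10) {
    l <- sample(2:9, 1)
    Q <- matrix(rnorm(l * 4, sd = 2), l, 4)
    K <- matrix(rnorm(l * 4, sd = 2), l, 4)
    A <- scaledDotProductAttention(Q, K, diag(l))  # V = I recovers the rows
    expect_equal(rowSums(A), rep(1, l), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
})

test_that("global average pooling and the head behave at their fixed points", {
  expect_equal(globalAveragePool(matrix(1:20, 1, 20)), as.numeric(1:20))
  cmat <- matrix(rep(3.5, 80), 4, 20)
  expect_equal(globalAveragePool(cmat), rep(3.5, 20))
  set.seed(27)
  m <- matrix(rnorm(7 * 5), 7, 5)
  expect_equal(globalAveragePool(m), colMeans(m), tolerance = 1e-12)

  cfg <- ModelConfig(fcHidden = 8L)
  w0 <- initModelWeights(cfg)
  w0@weights <- lapply(w0@weights, function(x) x * 0)
  expect_equal(classifierHead(rnorm(20), w0), 0.5)  # sigmoid(0)
  w <- initModelWeights(cfg)
  v <- rnorm(20)
  a <- pmax(drop(v %*% weightsList(w)$fc1_W) + weightsList(w)$fc1_b, 0)
  manual <- 1 / (1 + exp(-(drop(a %*% weightsList(w)$fc2_W) +
                           weightsList(w)$fc2_b)))
  expect_equal(classifierHead(v, w), manual, tolerance = 1e-12)
  expect_equal(classifierHead(v, w), classifierHead(v, w))  # eval deterministic
})

test_that("the full forward pass honours its range, determinism and length contract", {
  set.seed(28)
  w <- initModelWeights(ModelConfig())
  for (L in c(8, 18, 301)) {
    x <- matrix(rnorm(L * 20), L, 20)
    p <- modelForward(x, w)
    expect_gt(p, 0); expect_lt(p, 1)
    expect_identical(modelForward(x, w), p)
  }
  expect_silent(modelForward(matrix(rnorm(50000 * 20), 50000, 20), w))
  expect_error(modelForward(matrix(0, 7, 20), w), "minimum of 8")
})

test_that("training-mode dropout perturbs the head while evaluation does not", {
  set.seed(29)
  w <- initModelWeights(ModelConfig())
  x <- matrix(rnorm(30 * 20), 30, 20)
  ps <- replicate(20, modelForward(x, w, training = TRUE))
  expect_gt(length(unique(ps)), 1)
  expect_equal(mean(replicate(200, modelForward(x, w, training = TRUE))),
               modelForward(x, w), tolerance = 0.25)
})

test_that("countParameters equals brute-force enumeration for random configs", {
  set.seed(30)
  for (i in 1:50) {
    blocks <- sample(0:3, 1)
    ch <- sample(c(4L, 8L, 12L, 20L), 1)
    d <- if (blocks > 0) ch else 20L
    heads <- sample(which(d %% seq_len(d) == 0), 1)
    cfg <- ModelConfig(convBlocks = blocks, convChannels = ch,
                       convKernel = sample(c(1L, 3L, 5L), 1),
                       dModel = d, nHeads = heads,
                       dFF = sample(c(7L, 20L, 64L, 128L), 1),
                       fcHidden = sample(c(0L, 5L, 64L), 1),
                       useTransformer = sample(c(TRUE, FALSE), 1))
    w <- initModelWeights(cfg)
    expect_identical(countParameters(cfg),
                     sum(vapply(weightsList(w), length, integer(1))))
  }
  # collapsed head, no conv, no transformer: a single 20 -> 1 affine map
  expect_equal(countParameters(ModelConfig(convBlocks = 0L, fcHidden = 0L,
                                           useTransformer = FALSE)), 21)
})

test_that("ablating the transformer removes exactly its parameter block", {
  full <- countParameters(ModelConfig())
  ablated <- countParameters(ModelConfig(useTransformer = FALSE))
  expect_equal(full - ablated, 6948)
  # and the ablated forward still works
  set.seed(31)
  w <- initModelWeights(ModelConfig(useTransformer = FALSE))
  expect_silent(p <- modelForward(matrix(rnorm(40 * 20), 40, 20), w))
  expect_gt(p, 0); expect_lt(p, 1)
})

test_that("checkpoints round-trip weights, config and predictions", {
  set.seed(32)
  cfg <- ModelConfig(dFF = 16L)
  w <- initModelWeights(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  writeCheckpoint(w, f)
  w2 <- readCheckpoint(f)
  expect_identical(names(weightsList(w2)), names(weightsList(w)))
  expect_equal(weightsList(w2), weightsList(w), tolerance = 1e-14)
  x <- matrix(rnorm(25 * 20), 25, 20)
  expect_equal(modelForward(x, w2), modelForward(x, w), tolerance = 1e-12)
})
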