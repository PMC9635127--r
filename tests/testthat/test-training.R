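# Loss, Adam with gradient accumulation, plateau/early-stop scheduling, and
# the training loop's reproducibility.

test_that("inverse-class-frequency weights match the published counts", {
  expect_equal(round(classWeightsFromCounts(1069, 9695), 2),
               c(pos = 10.07, neg = 1.11))
  expect_equal(classWeightsFromCounts(50, 50), c(pos = 2, neg = 2))
  expect_equal(round(classWeightsFromCounts(100, 900), 2),
               c(pos = 10.00, neg = 1.11))
  expect_error(classWeightsFromCounts(0, 10), "at least 1")
})

test_that("weighted BCE has the right fixed points and rejects bad labels", {
  w <- c(10.07, 1.11)
  expect_lt(weightedBCE(1 - 1e-13, 1, w), 1e-10)
  expect_equal(weightedBCE(0.5, 1, w), 10.07 * log(2), tolerance = 1e-12)
  expect_equal(round(weightedBCE(0.5, 1, w), 4), 6.98)
  expect_equal(weightedBCE(0.5, 0, c(10.07, 1)), log(2), tolerance = 1e-12)
  expect_error(weightedBCE(0.5, 2, w), "labels")
  expect_true(all(weightedBCE(runif(50), rbinom(50, 1, 0.5), w) >= 0))
})

logistic_grad <- function(params, sample) {
  p <- 1 / (1 + exp(-sum(params$w * sample$x)))
  list(w = (p - sample$y) * sample$x)
}

test_that("one accumulated step equals the explicit summed-gradient Adam oracle", {
  set.seed(41)
  params <- list(w = c(0.3, -0.2))
  samples <- lapply(1:24, function(i)
    list(x = c(1, rnorm(1)), y = rbinom(1, 1, 0.5)))
  st <- adamInit(params)
  res <- accumulatedStep(params, samples, logistic_grad, st, lr = 1e-2)
  g_sum <- c(0, 0)
  for (s in samples) g_sum <- g_sum + logistic_grad(params, s)$w
  oracle <- oracle_adam(params$w, g_sum, m = c(0, 0), v = c(0, 0), t = 0,
                        lr = 1e-2)
  expect_equal(unname(res$params$w), unname(oracle$w), tolerance = 1e-6)
  expect_equal(res$state$t, 1)
  # a second accumulated step keeps matching (moment buffers carried over)
  samples2 <- lapply(1:24, function(i) list(x = c(1, rnorm(1)), y = 1))
  res2 <- accumulatedStep(res$params, samples2, logistic_grad, res$state, 1e-2)
  g2 <- Reduce(`+`, lapply(samples2, function(s) logistic_grad(res$params, s)$w))
  oracle2 <- oracle_adam(oracle$w, g2, oracle$m, oracle$v, oracle$t, 1e-2)
  expect_equal(unname(res2$params$w), unname(oracle2$w), tolerance = 1e-6)
})

test_that("accumulation of one reduces to plain per-sample stepping", {
  set.seed(42)
  params <- list(w = rnorm(2))
  s <- list(x = rnorm(2), y = 1)
  a <- accumulatedStep(params, list(s), logistic_grad, adamInit(params), 1e-3)
  b <- adamStep(params, logistic_grad(params, s), adamInit(params), 1e-3)
  expect_equal(a$params, b$params)
})

test_that("the engine's gradients match central finite differences", {
  set.seed(43)
  cfg <- ModelConfig(dFF = 12L, fcHidden = 6L)
  w <- weightsList(initModelWeights(cfg))
  x <- matrix(rnorm(18 * 20), 18, 20)
  mask <- (runif(6) >= 0.5) / 0.5
  for (y in c(1, 0)) {
    lg <- pssmTransformer:::cpp_loss_grad(w, x, y, 10.07, 1.11, cfg@nHeads,
                                          cfg@layerNormEps, cfg@poolKernel,
                                          mask)
    expect_equal(lg$loss,
                 weightedBCE(lg$p, y, c(10.07, 1.11)), tolerance = 1e-10)
    f <- function(wl) {
      p <- pssmTransformer:::cpp_forward(wl, x, cfg@nHeads, cfg@layerNormEps,
                                         cfg@poolKernel, mask)
      weightedBCE(p, y, c(10.07, 1.11))
    }
    eps <- 1e-6
    for (nm in sample(names(w), 8)) {
      i <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (f(wp) - f(wm)) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("the compiled epoch driver equals R-level accumulated Adam steps", {
  set.seed(44)
  cfg <- ModelConfig(dFF = 12L, fcHidden = 6L, dropout = 0)
  w <- weightsList(initModelWeights(cfg))
  xs <- lapply(1:5, function(i) matrix(rnorm(12 * 20), 12, 20))
  ys <- c(1, 0, 0, 1, 0)
  gradFun <- function(params, s) {
    pssmTransformer:::cpp_loss_grad(params, xs[[s]], ys[s], 4, 1.25,
                                    cfg@nHeads, cfg@layerNormEps,
                                    cfg@poolKernel, numeric(0))$grads
  }
  ref <- accumulatedStep(w, 1:5, gradFun, adamInit(w), lr = 1e-3)
  opt <- adamInit(w)
  res <- pssmTransformer:::cpp_train_epoch(
    w, opt$m, opt$v, 0L, xs, ys, 1:5, matrix(0, 0, 0), 1e-3, 24L, 4, 1.25,
    cfg@nHeads, cfg@layerNormEps, cfg@poolKernel, 0.9, 0.999, 1e-8)
  expect_equal(res$t, 1L)
  for (nm in names(w))
    expect_equal(res$weights[[nm]], ref$params[[nm]], tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("an epoch of 25 samples at accumulation 24 performs exactly 2 updates", {
  set.seed(45)
  cfg <- ModelConfig(dFF = 12L, fcHidden = 6L, dropout = 0)
  w <- weightsList(initModelWeights(cfg))
  xs <- lapply(1:25, function(i) matrix(rnorm(10 * 20), 10, 20))
  ys <- rbinom(25, 1, 0.3)
  opt <- adamInit(w)
  res <- pssmTransformer:::cpp_train_epoch(
    w, opt$m, opt$v, 0L, xs, ys, 1:25, matrix(0, 0, 0), 1e-3, 24L, 2, 1,
    cfg@nHeads, cfg@layerNormEps, cfg@poolKernel, 0.9, 0.999, 1e-8)
  expect_equal(res$t, 2L)
})

test_that("plateau halving and early stopping follow the stale-epoch counters", {
  tc <- TrainConfig()
  st <- schedulerInit(tc@lrInit)
  # monotone improvement never touches the learning rate
  for (a in seq(0.5, 0.9, by = 0.05)) st <- lrScheduleStep(st, a, tc)
  expect_equal(st$lr, 5e-4)
  expect_false(earlyStopCheck(st, tc))
  # 6 consecutive stale epochs (ties count as stale) halve the rate
  for (i in 1:6) st <- lrScheduleStep(st, 0.9, tc)
  expect_equal(st$lr, 2.5e-4)
  # 12 stale epochs halve twice
  for (i in 1:6) st <- lrScheduleStep(st, 0.1, tc)
  expect_equal(st$lr, 1.25e-4)
  # early stop fires at exactly 20 stale epochs
  expect_false(earlyStopCheck(st, tc))        # 12 so far
  for (i in 1:7) st <- lrScheduleStep(st, 0.1, tc)
  expect_false(earlyStopCheck(st, tc))        # 19
  st <- lrScheduleStep(st, 0.1, tc)
  expect_true(earlyStopCheck(st, tc))         # 20
  # an improvement resets both counters
  st <- lrScheduleStep(st, 0.95, tc)
  expect_false(earlyStopCheck(st, tc))
  expect_equal(st$bestAuc, 0.95)
})

test_that("training is reproducible, improves AUC, and respects the epoch cap", {
  set.seed(46)
  d <- random_profile_set(15, 45, max_len = 50)
  parts <- kFoldStratified(d, k = 3, seed = 7)
  mc <- ModelConfig(dFF = 16L, fcHidden = 8L)
  tc <- TrainConfig(epochs = 4L, accumulation = 8L, seed = 11L)
  fit1 <- trainModel(parts[[1]]$train, parts[[1]]$validation, mc, tc)
  fit2 <- trainModel(parts[[1]]$train, parts[[1]]$validation, mc, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(weightsList(fit1$weights), weightsList(fit2$weights))
  expect_lte(nrow(fit1$history), 4L)
  expect_named(fit1$history, c("epoch", "loss", "val_auc", "lr"))
  expect_equal(fit1$bestAuc, max(fit1$history$val_auc))
  # auto class weights are the training set's inverse frequencies
  expect_equal(fit1$classWeights,
               unname(classWeightsFromCounts(
                 sum(profileLabels(parts[[1]]$train) == 1L),
                 sum(profileLabels(parts[[1]]$train) == 0L))),
               ignore_attr = TRUE)
  expect_error(trainModel(parts[[1]]$train,
                          parts[[1]]$validation[
                            profileLabels(parts[[1]]$validation) == 0L],
                          mc, tc),
               "single class")
})

test_that("cross-validation yields one fit per fold over a true partition", {
  set.seed(47)
  d <- random_profile_set(12, 36, max_len = 40)
  mc <- ModelConfig(dFF = 16L, fcHidden = 8L)
  tc <- TrainConfig(epochs = 3L, accumulation = 8L, seed = 5L)
  cv <- crossValidate(d, mc, tc, k = 3)
  expect_length(cv$folds, 3)
  val_ids <- unlist(lapply(seq_len(3), function(f)
    names(cv$folds[[f]]$validationMetrics)))
  expect_equal(nrow(cv$summary), 4)
  expect_identical(cv$summary$fold, c("1", "2", "3", "mean"))
  expect_equal(cv$summary$auc[4], mean(cv$summary$auc[1:3]))
  for (m in c("sensitivity", "specificity", "accuracy", "auc", "mcc", "auprc"))
    expect_true(m %in% names(cv$summary))
})
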