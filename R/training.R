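# Loss, optimizer, scheduling and the cross-validation driver.
#
# Conventions: the printed loss lacks its leading minus (it is minimized, so
# the standard negated form is used); both class weights are applied, the
# positive weight on the y term and the negative weight on the (1-y) term;
# accumulated gradients are summed, not averaged, over the group; "improved"
# means a strictly greater validation AUC; Adam uses the conventional
# beta1 = 0.9, beta2 = 0.999, eps = 1e-8.

ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8

#' Inverse-class-frequency loss weights
#'
#' w_pos = (n_pos + n_neg) / n_pos and w_neg = (n_pos + n_neg) / n_neg. The
#' published training counts of 1069 adaptors and 9695 non-adaptors give
#' (10.07, 1.11) at two decimals; weights are used unrounded.
#'
#' @param nPos,nNeg Class counts (both >= 1).
#' @return Named numeric vector \code{c(pos = , neg = )}.
#' @export
#' @examples
#' round(classWeightsFromCounts(1069, 9695), 2)
classWeightsFromCounts <- function(nPos, nNeg) {
  if (nPos < 1 || nNeg < 1)
    stop("both class counts must be at least 1")
  n <- nPos + nNeg
  c(pos = n / nPos, neg = n / nNeg)
}

#' Class-weighted binary cross-entropy
#'
#' L = -(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p)), with p clamped
#' away from 0 and 1 for numerical safety. At p = 0.5 the loss is
#' w_pos * log(2) for a positive and w_neg * log(2) for a negative.
#'
#' @param p Predicted probability(ies) in (0, 1).
#' @param y Binary label(s).
#' @param weights Numeric \code{c(w_pos, w_neg)}.
#' @return Nonnegative loss (vectorized over \code{p}, \code{y}).
#' @export
#' @examples
#' weightedBCE(0.5, 1, c(10.07, 1.11))  # 10.07 * log(2)
weightedBCE <- function(p, y, weights) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(weights[1] * y * log(p) + weights[2] * (1 - y) * log(1 - p))
}

# ---------------------------------------------------------------- optimizer

#' Adam optimizer primitives
#'
#' \code{adamInit} creates zeroed first/second moment buffers matching a
#' parameter list; \code{adamStep} applies one bias-corrected Adam update.
#' Parameters, gradients and moments are parallel named lists of numeric
#' arrays.
#'
#' @param params Named list of numeric arrays.
#' @return \code{adamInit}: list with zeroed \code{m}, \code{v} and step
#'   counter \code{t = 0}.
#' @export
adamInit <- function(params) {
  z <- lapply(params, function(x) x * 0)
  list(m = z, v = z, t = 0L)
}

#' @rdname adamInit
#' @param grads Gradient list matching \code{params}.
#' @param state State from [adamInit()] (or a previous step).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam constants.
#' @return \code{adamStep}: list with updated \code{params} and \code{state}.
#' @export
adamStep <- function(params, grads, state, lr, beta1 = ADAM_BETA1,
                     beta2 = ADAM_BETA2, eps = ADAM_EPS) {
  t <- state$t + 1L
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  state$t <- t
  list(params = params, state = state)
}

#' One gradient-accumulation step
#'
#' Sums the per-sample gradients of a group (normally the accumulation size;
#' the final partial group of an epoch is allowed) and applies exactly one
#' Adam update. With a group of one this reduces to plain per-sample
#' stepping.
#'
#' @param params Named list of numeric arrays.
#' @param samples List of samples, passed one at a time to \code{gradFun}.
#' @param gradFun Function \code{(params, sample)} returning a gradient list
#'   matching \code{params}.
#' @param state Adam state from [adamInit()].
#' @param lr Learning rate.
#' @return List with updated \code{params} and \code{state}.
#' @export
accumulatedStep <- function(params, samples, gradFun, state, lr) {
  stopifnot(length(samples) >= 1L)
  total <- NULL
  for (s in samples) {
    g <- gradFun(params, s)
    total <- if (is.null(total)) g else mapply(`+`, total, g, SIMPLIFY = FALSE)
  }
  adamStep(params, total, state, lr)
}

# ------------------------------------------------------------- scheduling

#' Validation-AUC plateau schedule and early stopping
#'
#' \code{schedulerInit} builds the tracking state; \code{lrScheduleStep}
#' folds in one epoch's validation AUC: a strict improvement updates the
#' best and resets both stale counters, otherwise both increment and the
#' learning rate is multiplied by \code{lrFactor} each time the plateau
#' counter reaches \code{lrPatience}. \code{earlyStopCheck} is TRUE once the
#' epochs since the last improvement reach \code{earlyStopPatience}.
#'
#' @param lrInit Initial learning rate.
#' @return \code{schedulerInit}: state list with \code{bestAuc},
#'   \code{staleLr}, \code{staleStop}, \code{lr}.
#' @export
schedulerInit <- function(lrInit) {
  list(bestAuc = -Inf, staleLr = 0L, staleStop = 0L, lr = lrInit)
}

#' @rdname schedulerInit
#' @param state Scheduler state.
#' @param valAuc This epoch's validation AUC, in [0, 1].
#' @param config A \linkS4class{TrainConfig}.
#' @return \code{lrScheduleStep}: updated state, with \code{improved} set.
#' @export
lrScheduleStep <- function(state, valAuc, config) {
  stopifnot(valAuc >= 0, valAuc <= 1)
  if (valAuc > state$bestAuc) {
    state$bestAuc <- valAuc
    state$staleLr <- 0L
    state$staleStop <- 0L
    state$improved <- TRUE
  } else {
    state$staleLr <- state$staleLr + 1L
    state$staleStop <- state$staleStop + 1L
    state$improved <- FALSE
    if (state$staleLr >= config@lrPatience) {
      state$lr <- state$lr * config@lrFactor
      state$staleLr <- 0L
    }
  }
  state
}

#' @rdname schedulerInit
#' @return \code{earlyStopCheck}: logical.
#' @export
earlyStopCheck <- function(state, config) {
  state$staleStop >= config@earlyStopPatience
}

# ---------------------------------------------------------------- training

resolveClassWeights <- function(config, labels) {
  if (anyNA(config@classWeights)) {
    cw <- classWeightsFromCounts(sum(labels == 1L), sum(labels == 0L))
    c(cw[["pos"]], cw[["neg"]])
  } else {
    config@classWeights
  }
}

#' Train the classifier
#'
#' Runs up to \code{epochs} epochs of batch-size-one training over a seeded
#' shuffle of the training set, summing gradients over groups of
#' \code{accumulation} samples before each Adam update (the final partial
#' group of an epoch still updates). After each epoch the validation AUC is
#' computed in evaluation mode and drives learning-rate halving and early
#' stopping; the checkpoint from the best-validation-AUC epoch is returned.
#' With a fixed seed the run is reproducible.
#'
#' @param trainSet,validationSet Labeled \linkS4class{PSSMSet}s; the
#'   validation set must contain both classes (AUC is undefined otherwise).
#' @param modelConfig A \linkS4class{ModelConfig}.
#' @param trainConfig A \linkS4class{TrainConfig}.
#' @param verbose Print one line per epoch.
#' @return List with \code{weights} (best \linkS4class{ModelWeights}),
#'   \code{history} (data.frame epoch/loss/val_auc/lr), \code{bestEpoch},
#'   \code{bestAuc}, and the resolved \code{classWeights}.
#' @export
trainModel <- function(trainSet, validationSet, modelConfig = ModelConfig(),
                       trainConfig = TrainConfig(), verbose = FALSE) {
  stopifnot(is(trainSet, "PSSMSet"), is(validationSet, "PSSMSet"))
  y <- checkLabeled(trainSet)
  yv <- checkLabeled(validationSet)
  if (length(unique(yv)) < 2L)
    stop("validation set has a single class; AUC is undefined")
  cw <- resolveClassWeights(trainConfig, y)
  xs <- lapply(trainSet@profiles, pssmScores)
  xv <- lapply(validationSet@profiles, pssmScores)
  lmin <- minProfileLength(modelConfig)
  if (min(vapply(c(xs, xv), nrow, integer(1))) < lmin)
    stop(sprintf("profiles shorter than the minimum length %d", lmin))
  n <- length(xs)
  fh <- modelConfig@fcHidden
  use_drop <- modelConfig@dropout > 0 && fh > 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric(), lr = numeric())
  withSeed(trainConfig@seed, {
    weights <- weightsList(initModelWeights(modelConfig))
    opt <- adamInit(weights)
    sched <- schedulerInit(trainConfig@lrInit)
    best <- weights
    bestEpoch <- 0L
    for (epoch in seq_len(trainConfig@epochs)) {
      ord <- sample.int(n)
      masks <- if (use_drop) {
        matrix((runif(n * fh) >= modelConfig@dropout) / (1 - modelConfig@dropout),
               n, fh)
      } else matrix(0, 0L, 0L)
      res <- cpp_train_epoch(weights, opt$m, opt$v, opt$t, xs, as.numeric(y),
                             ord, masks, sched$lr,
                             trainConfig@accumulation, cw[1], cw[2],
                             modelConfig@nHeads, modelConfig@layerNormEps,
                             modelConfig@poolKernel, ADAM_BETA1, ADAM_BETA2,
                             ADAM_EPS)
      weights <- res$weights
      opt$m <- res$m
      opt$v <- res$v
      opt$t <- res$t
      pv <- cpp_predict(weights, xv, modelConfig@nHeads,
                        modelConfig@layerNormEps, modelConfig@poolKernel)
      val_auc <- aucScore(yv, pv)
      history[nrow(history) + 1L, ] <- list(epoch, res$loss_sum / n, val_auc,
                                            sched$lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val AUC %.4f  lr %g",
                        epoch, res$loss_sum / n, val_auc, sched$lr))
      sched <- lrScheduleStep(sched, val_auc, trainConfig)
      if (sched$improved) {
        best <- weights
        bestEpoch <- epoch
      }
      if (earlyStopCheck(sched, trainConfig)) break
    }
    list(weights = new("ModelWeights", weights = best, config = modelConfig),
         history = history, bestEpoch = bestEpoch, bestAuc = sched$bestAuc,
         classWeights = cw)
  })
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per stratified fold (each fold seeded from the base seed
#' plus the fold index) and evaluates the best checkpoint on the held-out
#' fold: sensitivity, specificity and accuracy at the decision threshold,
#' plus AUC, MCC and AUPRC.
#'
#' @param dataset A labeled \linkS4class{PSSMSet}.
#' @param modelConfig A \linkS4class{ModelConfig}.
#' @param trainConfig A \linkS4class{TrainConfig}.
#' @param k Number of folds, default 5.
#' @param verbose Print per-epoch progress.
#' @return List with \code{folds} (per-fold fit + validation metrics) and
#'   \code{summary} (data.frame of per-fold metric rows plus a mean row).
#' @export
crossValidate <- function(dataset, modelConfig = ModelConfig(),
                          trainConfig = TrainConfig(), k = 5L,
                          verbose = FALSE) {
  parts <- kFoldStratified(dataset, k = k, seed = trainConfig@seed)
  folds <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tc <- trainConfig
    tc@seed <- trainConfig@seed + f
    fit <- trainModel(parts[[f]]$train, parts[[f]]$validation,
                      modelConfig, tc, verbose = verbose)
    pv <- predictProbs(fit$weights, parts[[f]]$validation)
    yv <- profileLabels(parts[[f]]$validation)
    cm <- confusionAtThreshold(yv, pv, trainConfig@threshold)
    bm <- basicMetrics(cm)
    rows[[f]] <- data.frame(fold = f,
                            sensitivity = bm[["sensitivity"]],
                            specificity = bm[["specificity"]],
                            accuracy = bm[["accuracy"]],
                            auc = aucScore(yv, pv),
                            mcc = mccScore(cm),
                            auprc = auprcScore(yv, pv))
    fit$validationMetrics <- rows[[f]]
    folds[[f]] <- fit
  }
  per_fold <- do.call(rbind, rows)
  mean_row <- data.frame(fold = NA_integer_,
                         t(colMeans(per_fold[, -1, drop = FALSE])))
  summary <- rbind(per_fold, mean_row)
  summary$fold <- c(as.character(seq_len(k)), "mean")
  list(folds = folds, summary = summary)
}
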