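# Model construction, forward operations and parameter accounting.
#
# Architectural conventions (fixed by reproducing every published model
# size simultaneously): attention projections Wq/Wk/Wv/Wo carry no bias;
# convolution, feed-forward and fully connected layers carry biases; every
# layer norm has per-element gain and shift; a single encoder layer; no
# positional encoding; ReLU activations; dropout only in the head.

# Shape (dim vector) of every trainable tensor implied by a config, in the
# fixed enumeration order shared with the C++ engine.
emptyWeightShapes <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  sh <- list()
  cin <- config@inChannels
  if (config@convBlocks > 0L) {
    for (b in seq_len(config@convBlocks)) {
      p <- sprintf("conv%d", b)
      sh[[paste0(p, "_W")]] <- c(config@convChannels, cin, config@convKernel)
      sh[[paste0(p, "_b")]] <- config@convChannels
      sh[[paste0(p, "_g")]] <- config@convChannels
      sh[[paste0(p, "_beta")]] <- config@convChannels
      cin <- config@convChannels
    }
  }
  d <- config@dModel
  if (config@useTransformer) {
    sh$tx_Wq <- c(d, d); sh$tx_Wk <- c(d, d); sh$tx_Wv <- c(d, d)
    sh$tx_Wo <- c(d, d)
    sh$tx_ln1_g <- d; sh$tx_ln1_b <- d
    sh$tx_ffn_W1 <- c(d, config@dFF); sh$tx_ffn_b1 <- config@dFF
    sh$tx_ffn_W2 <- c(config@dFF, d); sh$tx_ffn_b2 <- d
    sh$tx_ln2_g <- d; sh$tx_ln2_b <- d
  }
  if (config@fcHidden > 0L) {
    sh$fc1_W <- c(d, config@fcHidden); sh$fc1_b <- config@fcHidden
    sh$fc2_W <- c(config@fcHidden, 1L); sh$fc2_b <- 1L
  } else {
    sh$fc1_W <- c(d, 1L); sh$fc1_b <- 1L
  }
  sh
}

#' Count the trainable parameters of a model configuration
#'
#' Sums the sizes of every trainable tensor: per convolutional block a
#' kernel (out x in x width) with bias plus a layer-norm gain/shift pair;
#' for the encoder the four bias-free d x d attention projections, two
#' layer-norm pairs and the biased feed-forward pair; and the biased fully
#' connected head. At the default configuration this is 12,137.
#'
#' @param config A \linkS4class{ModelConfig}.
#' @return Integer number of trainable scalars.
#' @seealso [formatParamCount()] for the reporting format.
#' @export
#' @examples
#' countParameters(ModelConfig())                        # 12137
#' countParameters(ModelConfig(useTransformer = FALSE))  # 12137 - 6948
countParameters <- function(config) {
  sh <- emptyWeightShapes(config)
  as.integer(sum(vapply(sh, prod, numeric(1))))
}

#' Format a parameter count in thousands
#'
#' Truncates (does not round) to one decimal in units of 1000, the
#' convention under which 15,089 reports as "15.0k" and 17,385 as "17.3k".
#'
#' @param n Integer parameter count.
#' @return Character like \code{"12.1k"}.
#' @export
#' @examples
#' formatParamCount(12137)
formatParamCount <- function(n) {
  sprintf("%.1fk", floor(n / 100) / 10)
}

#' Initialize model weights
#'
#' Draws weight matrices from the symmetric uniform Glorot range
#' sqrt(6 / (fan_in + fan_out)); biases and layer-norm shifts start at zero,
#' layer-norm gains at one. Tensors are drawn in the fixed enumeration order
#' using R's current RNG stream, so results are reproducible under
#' \code{set.seed()}.
#'
#' @param config A \linkS4class{ModelConfig}.
#' @return A \linkS4class{ModelWeights}.
#' @export
#' @examples
#' set.seed(1)
#' w <- initModelWeights(ModelConfig())
#' w
initModelWeights <- function(config) {
  sh <- emptyWeightShapes(config)
  w <- vector("list", length(sh))
  names(w) <- names(sh)
  for (nm in names(sh)) {
    dm <- sh[[nm]]
    if (length(dm) == 1L) {
      # vectors: layer-norm gains start at 1, everything else at 0
      w[[nm]] <- if (grepl("_g$", nm)) rep(1, dm) else rep(0, dm)
    } else {
      fan <- if (length(dm) == 3L) c(dm[2] * dm[3], dm[1] * dm[3]) else dm
      r <- sqrt(6 / sum(fan))
      w[[nm]] <- array(runif(prod(dm), -r, r), dim = dm)
    }
  }
  new("ModelWeights", weights = w, config = config)
}

#' Layer normalization
#'
#' Normalizes each position's channel vector to zero mean and unit variance
#' (population variance, guarded by \code{eps}) and applies the learned
#' per-channel gain and shift: y = (x - mean(x)) / sqrt(var(x) + eps) * gamma
#' + beta.
#'
#' @param x Numeric vector of width C, or an L x C matrix normalized
#'   row-wise.
#' @param gamma,beta Per-channel gain and shift (length C, recycled from
#'   scalars).
#' @param eps Variance guard, default 1e-5.
#' @return Same shape as \code{x}.
#' @export
#' @examples
#' layerNorm(c(1, 2, 3), 1, 0, eps = 0)
layerNorm <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  C <- ncol(xm)
  out <- cpp_layer_norm(xm, rep_len(as.numeric(gamma), C),
                        rep_len(as.numeric(beta), C), eps)
  if (vec) drop(out) else out
}

#' Convolutional block forward pass
#'
#' 1-D convolution along the sequence dimension (stride 1, zero
#' same-padding) with bias, layer normalization per position, ReLU, then
#' non-overlapping average pooling (kernel = stride = \code{pool}, floor
#' length division).
#'
#' @param x L x C_in feature map (rows = positions).
#' @param kernel C_out x C_in x K array of convolution kernels.
#' @param bias Length C_out bias.
#' @param gamma,beta Layer-norm gain and shift (length C_out).
#' @param eps Layer-norm variance guard.
#' @param pool Average-pooling kernel, default 2.
#' @return floor(L / pool) x C_out matrix.
#' @export
convBlockForward <- function(x, kernel, bias, gamma, beta, eps = 1e-5,
                             pool = 2L) {
  cpp_conv_block(as.matrix(x), kernel, bias, gamma, beta, eps,
                 as.integer(pool))
}

#' Scaled dot-product attention
#'
#' softmax(Q K' / sqrt(d_k)) V with d_k the column width of Q (the per-head
#' width); every attention row sums to one.
#'
#' @param Q,K,V l x d_k (Q, K) and l x d_v (V) matrices.
#' @return l x d_v matrix.
#' @export
scaledDotProductAttention <- function(Q, K, V) {
  cpp_sdpa(as.matrix(Q), as.matrix(K), as.matrix(V))
}

#' Multi-head self-attention
#'
#' Per head i, Q_i = Z Wq[, i], K_i = Z Wk[, i], V_i = Z Wv[, i] (bias-free,
#' head i using columns (i-1)d/h+1 ... i d/h), scaled dot-product attention
#' per head, heads concatenated and reprojected by Wo (bias-free).
#'
#' @param Z l x d input.
#' @param Wq,Wk,Wv,Wo d x d projection matrices.
#' @param h Number of heads (d divisible by h).
#' @return l x d matrix.
#' @export
multiHeadAttention <- function(Z, Wq, Wk, Wv, Wo, h) {
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) %% h == 0)
  cpp_mha(Z, as.matrix(Wq), as.matrix(Wk), as.matrix(Wv), as.matrix(Wo),
          as.integer(h))
}

#' Transformer encoder layer
#'
#' One post-norm encoder layer: Mid = LayerNorm(Z + MultiHead(Z)); FFN =
#' ReLU(Mid W1 + b1) W2 + b2; Output = LayerNorm(Mid + FFN). With no
#' positional encoding the layer is permutation-equivariant.
#'
#' @param Z l x d input.
#' @param txWeights Named list with elements \code{tx_Wq}, \code{tx_Wk},
#'   \code{tx_Wv}, \code{tx_Wo}, \code{tx_ln1_g}, \code{tx_ln1_b},
#'   \code{tx_ffn_W1}, \code{tx_ffn_b1}, \code{tx_ffn_W2}, \code{tx_ffn_b2},
#'   \code{tx_ln2_g}, \code{tx_ln2_b} (the encoder subset of a
#'   \linkS4class{ModelWeights} list).
#' @param h Number of heads.
#' @param eps Layer-norm variance guard.
#' @return l x d matrix.
#' @export
transformerEncoder <- function(Z, txWeights, h, eps = 1e-5) {
  cpp_encoder(as.matrix(Z), txWeights, as.integer(h), eps)
}

#' Global average pooling
#'
#' Column-wise mean, mapping an l x d feature map of any length to a length
#' d vector.
#'
#' @param features l x d matrix.
#' @return Numeric vector of length d.
#' @export
globalAveragePool <- function(features) {
  colMeans(as.matrix(features))
}

#' Classification head
#'
#' p = sigmoid(FC2(dropout(ReLU(FC1(v))))). Dropout is inverted (masked
#' units are dropped and survivors scaled by 1/(1-rate)) and active only
#' when \code{training = TRUE}; evaluation is deterministic with no
#' rescaling.
#'
#' @param v Feature vector of length d.
#' @param weights A \linkS4class{ModelWeights} (its head tensors are used).
#' @param training Logical; draw and apply a dropout mask from R's RNG.
#' @return Probability in (0, 1).
#' @export
classifierHead <- function(v, weights, training = FALSE) {
  w <- weightsList(weights)
  cfg <- modelConfig(weights)
  a <- drop(v %*% w$fc1_W) + w$fc1_b
  if (is.null(w$fc2_W)) return(1 / (1 + exp(-a)))
  r <- pmax(a, 0)
  if (training && cfg@dropout > 0)
    r <- r * (runif(length(r)) >= cfg@dropout) / (1 - cfg@dropout)
  z <- drop(r %*% w$fc2_W) + w$fc2_b
  1 / (1 + exp(-z))
}

# Minimum admissible profile length for a config (each pooling floors the
# length; pool^blocks guarantees >= 1 position survives).
minProfileLength <- function(config) {
  as.integer(config@poolKernel^config@convBlocks)
}

# Dropout mask for one sample (inverted scaling), numeric(0) = no dropout.
dropoutMask <- function(config) {
  if (config@dropout > 0 && config@fcHidden > 0L)
    (runif(config@fcHidden) >= config@dropout) / (1 - config@dropout)
  else numeric(0)
}

#' Full model forward pass
#'
#' Convolutional blocks, then the transformer encoder (skipped when the
#' config ablates it), global average pooling and the classification head.
#' One profile is one batch: the variable-length regime of real PSSM data
#' forces batch size 1 by construction.
#'
#' @param profile A \linkS4class{PSSMProfile} or an N x 20 score matrix.
#' @param weights A \linkS4class{ModelWeights}.
#' @param training Logical; enables head dropout (drawn from R's RNG).
#' @return Probability that the protein is an adaptor, in (0, 1).
#' @export
#' @examples
#' set.seed(1)
#' w <- initModelWeights(ModelConfig())
#' modelForward(matrix(rnorm(40 * 20), 40, 20), w)
modelForward <- function(profile, weights, training = FALSE) {
  stopifnot(is(weights, "ModelWeights"))
  cfg <- modelConfig(weights)
  x <- if (is(profile, "PSSMProfile")) pssmScores(profile) else as.matrix(profile)
  lmin <- minProfileLength(cfg)
  if (nrow(x) < lmin)
    stop(sprintf("profile length %d is below the minimum of %d required by %d pooling stage(s)",
                 nrow(x), lmin, cfg@convBlocks))
  mask <- if (training) dropoutMask(cfg) else numeric(0)
  cpp_forward(weightsList(weights), x, cfg@nHeads, cfg@layerNormEps,
              cfg@poolKernel, mask)
}

#' Predict adaptor probabilities for a dataset
#'
#' Deterministic evaluation-mode forward passes over every profile.
#'
#' @param weights A \linkS4class{ModelWeights}.
#' @param dataset A \linkS4class{PSSMSet} or list of score matrices.
#' @return Named numeric vector of probabilities.
#' @export
predictProbs <- function(weights, dataset) {
  stopifnot(is(weights, "ModelWeights"))
  cfg <- modelConfig(weights)
  if (is(dataset, "PSSMSet")) {
    xs <- lapply(dataset@profiles, pssmScores)
    nms <- profileIDs(dataset)
  } else {
    xs <- lapply(dataset, as.matrix)
    nms <- names(dataset)
  }
  lens <- vapply(xs, nrow, integer(1))
  lmin <- minProfileLength(cfg)
  if (any(lens < lmin))
    stop(sprintf("profile length %d is below the minimum of %d",
                 min(lens), lmin))
  p <- cpp_predict(weightsList(weights), xs, cfg@nHeads, cfg@layerNormEps,
                   cfg@poolKernel)
  names(p) <- nms
  p
}

# ---------------------------------------------------------------- checkpoints

#' Write a model checkpoint
#'
#' Saves weights and the embedded configuration to a single portable JSON
#' file at full double precision.
#'
#' @param weights A \linkS4class{ModelWeights}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCheckpoint <- function(weights, path) {
  stopifnot(is(weights, "ModelWeights"))
  cfg <- modelConfig(weights)
  cfgl <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgl) <- slotNames(cfg)
  wl <- lapply(weightsList(weights), function(x)
    list(dim = if (is.null(dim(x))) length(x) else dim(x),
         data = as.vector(x)))
  jsonlite::write_json(list(format = "pssmTransformer-checkpoint",
                            config = cfgl, weights = wl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path Path to a file written by [writeCheckpoint()].
#' @return A \linkS4class{ModelWeights}.
#' @export
readCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pssmTransformer-checkpoint"))
    stop("not a pssmTransformer checkpoint: ", path)
  cfg <- do.call(ModelConfig, obj$config[c(
    "inChannels", "convBlocks", "convChannels", "convKernel", "poolKernel",
    "dModel", "nHeads", "dFF", "fcHidden", "dropout", "useTransformer",
    "layerNormEps")])
  w <- lapply(obj$weights, function(e) {
    if (length(e$dim) > 1L) array(e$data, dim = e$dim) else as.numeric(e$data)
  })
  new("ModelWeights", weights = w[names(emptyWeightShapes(cfg))], config = cfg)
}
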