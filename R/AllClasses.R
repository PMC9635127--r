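# S4 container classes. Scores are always stored with columns in the fixed
# PSI-BLAST residue order (see pssmResidueOrder()).

#' PSSMProfile: one protein's PSSM profile
#'
#' A single protein represented by its PSI-BLAST position-specific scoring
#' matrix: an N x 20 matrix of log-odds conservation scores (N = sequence
#' length), the residue string, an identifier, and an optional binary label
#' (1 = adaptor, 0 = non-adaptor).
#'
#' @slot id Character identifier (unique within a \linkS4class{PSSMSet}).
#' @slot residues Character scalar over the 20-letter amino-acid alphabet.
#' @slot scores Numeric matrix with \code{nchar(residues)} rows and 20
#'   columns in the fixed PSI-BLAST residue order.
#' @slot label Integer; 1, 0, or \code{NA} when unlabeled.
#'
#' @aliases PSSMProfile-class
#' @exportClass PSSMProfile
setClass("PSSMProfile",
  representation(id = "character", residues = "character",
                 scores = "matrix", label = "integer"),
  prototype(label = NA_integer_))

setValidity("PSSMProfile", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@residues) != 1L)
    msg <- c(msg, "'residues' must be a single string")
  n <- nchar(object@residues)
  if (n < 1L) msg <- c(msg, "profile must have at least one position")
  if (ncol(object@scores) != 20L)
    msg <- c(msg, "'scores' must have exactly 20 columns")
  if (nrow(object@scores) != n)
    msg <- c(msg, sprintf("'scores' has %d rows but 'residues' has %d letters",
                          nrow(object@scores), n))
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "'scores' must be finite")
  bad <- setdiff(strsplit(object@residues, "")[[1]], pssmResidueOrder())
  if (length(bad))
    msg <- c(msg, sprintf("residue letters outside the 20-letter alphabet: %s",
                          paste(unique(bad), collapse = ", ")))
  if (length(object@label) != 1L || (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    msg <- c(msg, "'label' must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a PSSMProfile
#'
#' @param id Identifier string.
#' @param residues Residue string (length N, 20-letter alphabet).
#' @param scores Numeric N x 20 matrix of log-odds scores, columns in the
#'   PSI-BLAST residue order.
#' @param label Optional binary label (1 = adaptor, 0 = non-adaptor).
#' @return A \linkS4class{PSSMProfile}.
#' @export
#' @examples
#' p <- PSSMProfile("toy", "MK", matrix(0, 2, 20))
#' profileLength(p)
PSSMProfile <- function(id, residues, scores, label = NA_integer_) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) == 20L)
    dimnames(scores) <- list(NULL, pssmResidueOrder())
  new("PSSMProfile", id = as.character(id), residues = toupper(residues),
      scores = scores, label = as.integer(label))
}

#' PSSMSet: an ordered collection of PSSM profiles
#'
#' A labeled (or unlabeled) dataset of \linkS4class{PSSMProfile} objects with
#' unique identifiers.
#'
#' @slot profiles List of \linkS4class{PSSMProfile}.
#' @slot name Dataset name.
#' @aliases PSSMSet-class
#' @exportClass PSSMSet
setClass("PSSMSet",
  representation(profiles = "list", name = "character"),
  prototype(name = ""))

setValidity("PSSMSet", function(object) {
  msg <- character()
  ok <- vapply(object@profiles, function(p) is(p, "PSSMProfile"), logical(1))
  if (!all(ok)) msg <- c(msg, "all elements must be PSSMProfile objects")
  ids <- vapply(object@profiles, function(p) p@id, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "profile identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PSSMSet
#'
#' @param profiles List of \linkS4class{PSSMProfile} objects.
#' @param name Optional dataset name.
#' @return A \linkS4class{PSSMSet}.
#' @export
PSSMSet <- function(profiles = list(), name = "") {
  new("PSSMSet", profiles = profiles, name = name)
}

#' ModelConfig: architecture hyperparameters
#'
#' All sizes of the classifier: three (by default) 1-D convolutional blocks
#' of 20 kernels of width 3 with average pooling of kernel 2, a single
#' transformer encoder layer with model width \code{dModel = 20},
#' \code{nHeads = 5} attention heads and a feed-forward width
#' \code{dFF = 128}, and a two-layer fully connected head with 64 hidden
#' units and dropout 0.5 after the first layer. \code{useTransformer = FALSE}
#' ablates the encoder (the feature map passes straight to pooling).
#' \code{fcHidden = 0} collapses the head to a single affine map.
#'
#' @slot inChannels,convBlocks,convChannels,convKernel,poolKernel integer
#'   sizes of the convolutional stage.
#' @slot dModel,nHeads,dFF integer transformer sizes; \code{dModel} must be
#'   divisible by \code{nHeads} and match the channel count entering the
#'   encoder.
#' @slot fcHidden integer hidden width of the classification head.
#' @slot dropout numeric in [0, 1); applied after the first FC layer.
#' @slot useTransformer logical encoder on/off.
#' @slot layerNormEps numeric variance guard of all layer norms.
#' @aliases ModelConfig-class
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(inChannels = "integer", convBlocks = "integer",
                 convChannels = "integer", convKernel = "integer",
                 poolKernel = "integer", dModel = "integer",
                 nHeads = "integer", dFF = "integer", fcHidden = "integer",
                 dropout = "numeric", useTransformer = "logical",
                 layerNormEps = "numeric"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "'dModel' must be divisible by 'nHeads'")
  pos <- c(inChannels = object@inChannels, convChannels = object@convChannels,
           convKernel = object@convKernel, poolKernel = object@poolKernel,
           dModel = object@dModel, nHeads = object@nHeads, dFF = object@dFF)
  if (any(pos < 1L))
    msg <- c(msg, sprintf("%s must be >= 1",
                          paste(names(pos)[pos < 1L], collapse = ", ")))
  if (object@convBlocks < 0L || object@fcHidden < 0L)
    msg <- c(msg, "'convBlocks' and 'fcHidden' must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "'dropout' must be in [0, 1)")
  d_in <- if (object@convBlocks > 0L) object@convChannels else object@inChannels
  if (object@dModel != d_in)
    msg <- c(msg, "'dModel' must equal the channel count entering the encoder")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults reproduce the published 12.1k-parameter architecture.
#'
#' @param inChannels Input channels (PSSM columns), default 20.
#' @param convBlocks Number of convolutional blocks, default 3.
#' @param convChannels Kernels per convolutional layer, default 20.
#' @param convKernel 1-D convolution kernel width, default 3.
#' @param poolKernel Average-pooling kernel (= stride), default 2.
#' @param dModel Transformer model width, default 20.
#' @param nHeads Attention heads, default 5 (per-head width 4).
#' @param dFF Feed-forward hidden width, default 128.
#' @param fcHidden Classification-head hidden width, default 64; 0 collapses
#'   the head to one affine map.
#' @param dropout Dropout rate after the first FC layer, default 0.5.
#' @param useTransformer Encoder on/off, default TRUE.
#' @param layerNormEps Layer-norm variance guard, default 1e-5.
#' @return A \linkS4class{ModelConfig}.
#' @export
#' @examples
#' countParameters(ModelConfig())          # 12137
#' countParameters(ModelConfig(dFF = 20L)) # 7709
ModelConfig <- function(inChannels = 20L, convBlocks = 3L, convChannels = 20L,
                        convKernel = 3L, poolKernel = 2L, dModel = 20L,
                        nHeads = 5L, dFF = 128L, fcHidden = 64L,
                        dropout = 0.5, useTransformer = TRUE,
                        layerNormEps = 1e-5) {
  new("ModelConfig", inChannels = as.integer(inChannels),
      convBlocks = as.integer(convBlocks),
      convChannels = as.integer(convChannels),
      convKernel = as.integer(convKernel), poolKernel = as.integer(poolKernel),
      dModel = as.integer(dModel), nHeads = as.integer(nHeads),
      dFF = as.integer(dFF), fcHidden = as.integer(fcHidden),
      dropout = dropout, useTransformer = useTransformer,
      layerNormEps = layerNormEps)
}

#' TrainConfig: optimization and scheduling settings
#'
#' Defaults follow the published protocol: at most 50 epochs of Adam at
#' initial learning rate 5e-4 and batch size 1 with gradients accumulated
#' over 24 samples per update; the learning rate is halved after 6
#' consecutive epochs without a strict validation-AUC improvement and
#' training stops after 20; the checkpoint from the best-validation-AUC
#' epoch is kept.
#'
#' @slot epochs,accumulation,lrPatience,earlyStopPatience,seed integers.
#' @slot lrInit,lrFactor,threshold numerics.
#' @slot classWeights Numeric (positive, negative) loss weights; \code{NA}
#'   (the default) computes inverse class frequencies from the training set.
#' @aliases TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", lrInit = "numeric",
                 accumulation = "integer", lrPatience = "integer",
                 lrFactor = "numeric", earlyStopPatience = "integer",
                 classWeights = "numeric", threshold = "numeric",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
  if (object@accumulation < 1L) msg <- c(msg, "'accumulation' must be >= 1")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    msg <- c(msg, "'lrFactor' must be in (0, 1)")
  if (object@lrPatience < 1L || object@earlyStopPatience < 1L)
    msg <- c(msg, "patience values must be >= 1")
  if (length(object@classWeights) != 2L)
    msg <- c(msg, "'classWeights' must have length 2")
  else if (!anyNA(object@classWeights) && any(object@classWeights <= 0))
    msg <- c(msg, "'classWeights' must be positive")
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "'threshold' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs Epoch cap, default 50.
#' @param lrInit Initial Adam learning rate, default 5e-4.
#' @param accumulation Gradient-accumulation group size, default 24.
#' @param lrPatience Non-improving epochs before the learning rate is
#'   multiplied by \code{lrFactor}, default 6.
#' @param lrFactor Learning-rate decay factor, default 0.5.
#' @param earlyStopPatience Non-improving epochs before training stops,
#'   default 20.
#' @param classWeights Loss weights (positive, negative); default \code{NA}
#'   derives inverse class frequencies from the training data.
#' @param threshold Decision threshold for confusion-matrix metrics,
#'   default 0.5.
#' @param seed Seed governing weight init, shuffling and dropout, default 42.
#' @return A \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(epochs = 50L, lrInit = 5e-4, accumulation = 24L,
                        lrPatience = 6L, lrFactor = 0.5,
                        earlyStopPatience = 20L,
                        classWeights = c(NA_real_, NA_real_),
                        threshold = 0.5, seed = 42L) {
  new("TrainConfig", epochs = as.integer(epochs), lrInit = lrInit,
      accumulation = as.integer(accumulation),
      lrPatience = as.integer(lrPatience), lrFactor = lrFactor,
      earlyStopPatience = as.integer(earlyStopPatience),
      classWeights = as.numeric(classWeights), threshold = threshold,
      seed = as.integer(seed))
}

#' GeneratorConfig: synthetic PSSM dataset settings
#'
#' The generator emulates the statistical shape of real adaptor-protein PSSM
#' data: a 1:9 positive:negative imbalance, log-uniform lengths spanning the
#' real minimum of 18 positions, integer log-odds scores, and a
#' class-discriminating block of conserved columns in positives.
#'
#' @slot nPos,nNeg Class sizes (default 200 / 1800, the package's desk-scale
#'   stand-in for the 1:9 imbalance of the curated dataset).
#' @slot minLen,maxLen Length bounds of the log-uniform draw (18 / 500).
#' @slot motifLen Number of consecutive motif positions in positives (9).
#' @slot motifGain Additive log-odds boost on the motif columns (6).
#' @slot noiseSD Background score standard deviation before rounding (2).
#' @slot scoreLow,scoreHigh Integer clip bounds (-16 / 13).
#' @slot seed Generator seed (42).
#' @aliases GeneratorConfig-class
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(nPos = "integer", nNeg = "integer", minLen = "integer",
                 maxLen = "integer", motifLen = "integer",
                 motifGain = "numeric", noiseSD = "numeric",
                 scoreLow = "integer", scoreHigh = "integer",
                 seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@minLen < 8L)
    msg <- c(msg, "'minLen' must be >= 8 so three pooling halvings leave a position")
  if (object@minLen > object@maxLen)
    msg <- c(msg, "'minLen' must be <= 'maxLen'")
  if (object@nPos < 0L || object@nNeg < 0L || object@nPos + object@nNeg < 1L)
    msg <- c(msg, "'nPos' and 'nNeg' must be >= 0 and sum to >= 1")
  if (object@motifLen < 1L || object@motifLen > object@minLen)
    msg <- c(msg, "'motifLen' must be in [1, minLen]")
  if (object@noiseSD <= 0) msg <- c(msg, "'noiseSD' must be positive")
  if (object@scoreLow >= object@scoreHigh)
    msg <- c(msg, "'scoreLow' must be below 'scoreHigh'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneratorConfig
#'
#' @param nPos,nNeg Positive / negative class sizes (200 / 1800).
#' @param minLen,maxLen Sequence-length bounds (18 / 500).
#' @param motifLen Motif length in positions (9).
#' @param motifGain Additive score boost on the motif columns (6).
#' @param noiseSD Background Gaussian standard deviation (2).
#' @param scoreLow,scoreHigh Integer clip bounds (-16 / 13).
#' @param seed Seed for the generator's PRNG stream (42).
#' @return A \linkS4class{GeneratorConfig}.
#' @export
#' @examples
#' cfg <- GeneratorConfig(nPos = 5L, nNeg = 45L)
#' length(generateDataset(cfg))
GeneratorConfig <- function(nPos = 200L, nNeg = 1800L, minLen = 18L,
                            maxLen = 500L, motifLen = 9L, motifGain = 6,
                            noiseSD = 2, scoreLow = -16L, scoreHigh = 13L,
                            seed = 42L) {
  new("GeneratorConfig", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      motifLen = as.integer(motifLen), motifGain = motifGain,
      noiseSD = noiseSD, scoreLow = as.integer(scoreLow),
      scoreHigh = as.integer(scoreHigh), seed = as.integer(seed))
}

#' ModelWeights: the complete set of trainable tensors
#'
#' A named list of numeric arrays (convolution kernels and biases, layer-norm
#' gains/shifts, attention projections, feed-forward and fully connected
#' weights) together with the \linkS4class{ModelConfig} that fixes every
#' shape. Tensors are enumerable in a fixed documented order: convolutional
#' blocks first (kernel, bias, gain, shift per block), then the encoder
#' (Wq, Wk, Wv, Wo, first layer norm, FFN W1/b1/W2/b2, second layer norm),
#' then the head (fc1, fc2).
#'
#' @slot weights Named list of numeric arrays.
#' @slot config The \linkS4class{ModelConfig} the shapes derive from.
#' @aliases ModelWeights-class
#' @exportClass ModelWeights
setClass("ModelWeights",
  representation(weights = "list", config = "ModelConfig"))

setValidity("ModelWeights", function(object) {
  want <- names(emptyWeightShapes(object@config))
  have <- names(object@weights)
  if (!identical(want, have))
    return(sprintf("weight names do not match the config (want: %s)",
                   paste(want, collapse = ", ")))
  TRUE
})
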