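# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for PSSM containers
#' @description Small read accessors: \code{profileID}, \code{residueString},
#'   \code{pssmScores}, \code{profileLabel} and \code{profileLength} read the
#'   slots of a \linkS4class{PSSMProfile}; \code{profileLabels} and
#'   \code{profileIDs} vectorize over a \linkS4class{PSSMSet};
#'   \code{weightsList} and \code{modelConfig} unpack a
#'   \linkS4class{ModelWeights}.
#' @param x Object to access.
#' @return The corresponding slot value (see description).
NULL

#' @rdname accessors
#' @export
setGeneric("profileID", function(x) standardGeneric("profileID"))
#' @rdname accessors
#' @export
setGeneric("residueString", function(x) standardGeneric("residueString"))
#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setGeneric("profileLabel", function(x) standardGeneric("profileLabel"))
#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @rdname accessors
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))
#' @rdname accessors
#' @export
setGeneric("profileIDs", function(x) standardGeneric("profileIDs"))
#' @rdname accessors
#' @export
setGeneric("weightsList", function(x) standardGeneric("weightsList"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
setMethod("profileID", "PSSMProfile", function(x) x@id)
#' @rdname accessors
setMethod("residueString", "PSSMProfile", function(x) x@residues)
#' @rdname accessors
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)
#' @rdname accessors
setMethod("profileLabel", "PSSMProfile", function(x) x@label)
#' @rdname accessors
setMethod("profileLength", "PSSMProfile", function(x) nrow(x@scores))

#' @rdname accessors
setMethod("profileLabels", "PSSMSet", function(x)
  vapply(x@profiles, function(p) p@label, integer(1)))
#' @rdname accessors
setMethod("profileIDs", "PSSMSet", function(x)
  vapply(x@profiles, function(p) p@id, character(1)))

#' @rdname accessors
setMethod("weightsList", "ModelWeights", function(x) x@weights)
#' @rdname accessors
setMethod("modelConfig", "ModelWeights", function(x) x@config)

#' @describeIn PSSMSet Number of profiles.
#' @param x A \linkS4class{PSSMSet}.
#' @export
setMethod("length", "PSSMSet", function(x) length(x@profiles))

#' @describeIn PSSMSet Extract one profile.
#' @param i Index or identifier.
#' @export
setMethod("[[", "PSSMSet", function(x, i) {
  if (is.character(i)) i <- match(i, profileIDs(x))
  x@profiles[[i]]
})

#' @describeIn PSSMSet Subset to a new \linkS4class{PSSMSet}.
#' @param j,...,drop Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "PSSMSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, profileIDs(x))
  PSSMSet(x@profiles[i], name = x@name)
})

#' @describeIn PSSMSet Profile identifiers.
#' @export
setMethod("names", "PSSMSet", function(x) profileIDs(x))

setMethod("show", "PSSMProfile", function(object) {
  lab <- if (is.na(object@label)) "unlabeled"
         else if (object@label == 1L) "adaptor (1)" else "non-adaptor (0)"
  cat(sprintf("PSSMProfile '%s': %d positions x 20 residues, %s\n",
              object@id, nrow(object@scores), lab))
})

setMethod("show", "PSSMSet", function(object) {
  labs <- profileLabels(object)
  cat(sprintf("PSSMSet%s with %d profiles (%d adaptor / %d non-adaptor / %d unlabeled)\n",
              if (nzchar(object@name)) sprintf(" '%s'", object@name) else "",
              length(object), sum(labs == 1L, na.rm = TRUE),
              sum(labs == 0L, na.rm = TRUE), sum(is.na(labs))))
  if (length(object)) {
    lens <- vapply(object@profiles, function(p) nrow(p@scores), integer(1))
    cat(sprintf("  lengths: %d-%d (median %d)\n", min(lens), max(lens),
                as.integer(stats::median(lens))))
  }
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig: %d conv block(s) [%d kernels, width %d, pool %d], ",
    "transformer %s (d=%d, h=%d, dFF=%d), head hidden %d, dropout %.2f\n",
    "  trainable parameters: %d (%s)\n"),
    object@convBlocks, object@convChannels, object@convKernel,
    object@poolKernel, if (object@useTransformer) "on" else "off",
    object@dModel, object@nHeads, object@dFF, object@fcHidden,
    object@dropout, countParameters(object),
    formatParamCount(countParameters(object))))
})

setMethod("show", "TrainConfig", function(object) {
  cw <- if (anyNA(object@classWeights)) "inverse class frequency (auto)"
        else sprintf("[%.2f, %.2f]", object@classWeights[1], object@classWeights[2])
  cat(sprintf(paste0(
    "TrainConfig: <=%d epochs, Adam lr %g, accumulation %d, ",
    "halve after %d stale epochs, stop after %d, class weights %s, seed %d\n"),
    object@epochs, object@lrInit, object@accumulation, object@lrPatience,
    object@earlyStopPatience, cw, object@seed))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0(
    "GeneratorConfig: %d positive / %d negative profiles, lengths %d-%d ",
    "(log-uniform), motif %d x gain %g, noise sd %g, clip [%d, %d], seed %d\n"),
    object@nPos, object@nNeg, object@minLen, object@maxLen, object@motifLen,
    object@motifGain, object@noiseSD, object@scoreLow, object@scoreHigh,
    object@seed))
})

setMethod("show", "ModelWeights", function(object) {
  n <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf("ModelWeights: %d tensors, %d trainable parameters (%s)\n",
              length(object@weights), n, formatParamCount(n)))
})
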