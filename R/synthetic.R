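# Synthetic PSSM profile generator. Stands in for PSI-BLAST output so every
# downstream module is testable without external data: variable lengths
# (log-uniform, min 18 like the real data), ~1:9 class imbalance, integer
# log-odds scores, and a class-discriminating conserved-column motif whose
# signal survives global average pooling.

# Fixed label-specific subset of residue columns boosted in positives:
# C, H, P, W, Y in the PSI-BLAST column order.
motifColumns <- function() c(5L, 9L, 15L, 18L, 19L)

#' Sample one synthetic PSSM profile
#'
#' Length is drawn log-uniformly on [minLen, maxLen]; background scores are
#' Gaussian(0, noiseSD), rounded to integers and clipped to
#' [scoreLow, scoreHigh]; positives additionally receive \code{+motifGain}
#' (before rounding and clipping) on a fixed subset of 5 residue columns
#' over \code{motifLen} consecutive positions at a random offset; residues
#' are drawn uniformly. Uses R's current RNG stream — seed the caller (or
#' use [generateDataset()], which seeds its own stream).
#'
#' @param config A \linkS4class{GeneratorConfig}.
#' @param label Binary class label (1 = motif-bearing positive).
#' @param id Identifier for the profile.
#' @return A labeled \linkS4class{PSSMProfile}.
#' @export
#' @examples
#' set.seed(7)
#' sampleProfile(GeneratorConfig(), label = 1L)
sampleProfile <- function(config, label, id = "synthetic") {
  stopifnot(is(config, "GeneratorConfig"), label %in% c(0L, 1L))
  L <- round(exp(runif(1, log(config@minLen), log(config@maxLen))))
  L <- as.integer(min(max(L, config@minLen), config@maxLen))
  sc <- matrix(rnorm(L * 20L, 0, config@noiseSD), L, 20L)
  res <- paste(sample(pssmResidueOrder(), L, replace = TRUE), collapse = "")
  if (label == 1L) {
    off <- sample.int(L - config@motifLen + 1L, 1L)
    rows <- off:(off + config@motifLen - 1L)
    sc[rows, motifColumns()] <- sc[rows, motifColumns()] + config@motifGain
  }
  sc <- pmin(pmax(round(sc), config@scoreLow), config@scoreHigh)
  PSSMProfile(id, res, sc, label = as.integer(label))
}

#' Generate a labeled synthetic PSSM dataset
#'
#' Draws \code{nPos} positive and \code{nNeg} negative profiles with ids
#' \code{pos_0001...} / \code{neg_0001...} and shuffles their order, all on
#' a single PRNG stream seeded by the config; identical configs give
#' identical datasets.
#'
#' @param config A \linkS4class{GeneratorConfig}.
#' @return A labeled \linkS4class{PSSMSet}.
#' @seealso [writeDatasetDir()] to materialize the set as PSSM files plus a
#'   manifest.
#' @export
#' @examples
#' d <- generateDataset(GeneratorConfig(nPos = 10L, nNeg = 90L))
#' table(profileLabels(d))
generateDataset <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  withSeed(config@seed, {
    pos <- lapply(seq_len(config@nPos), function(i)
      sampleProfile(config, 1L, id = sprintf("pos_%04d", i)))
    neg <- lapply(seq_len(config@nNeg), function(i)
      sampleProfile(config, 0L, id = sprintf("neg_%04d", i)))
    all <- c(pos, neg)
    PSSMSet(all[sample.int(length(all))], name = "synthetic")
  })
}
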