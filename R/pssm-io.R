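# PSI-BLAST ASCII PSSM and FASTA input/output, dataset manifests, and
# stratified partitioning.

#' Parse a PSI-BLAST ASCII PSSM profile
#'
#' Reads the standard PSI-BLAST text dialect: free-form header lines, a
#' residue-order line of 20 (or 40) single letters, then one body row per
#' position carrying the position index, the query residue, 20 integer
#' log-odds scores and 20 weighted observed percentages (real files append
#' two per-row statistics, which are accepted and ignored). Trailing footer
#' lines (K/lambda statistics) are ignored. Only the first 20-column
#' log-odds block is kept. Files whose residue-order line permutes the
#' canonical order are re-mapped to it; a missing residue-order line is an
#' error.
#'
#' @param path Path to (or connection for) the ASCII PSSM file.
#' @param id Profile identifier; defaults to the file name without its
#'   extension.
#' @param label Optional binary label to attach.
#' @return A \linkS4class{PSSMProfile}.
#' @export
#' @examples
#' p <- PSSMProfile("x", "MK", matrix(c(1:20, 20:1), 2, 20, byrow = TRUE))
#' f <- tempfile(fileext = ".pssm")
#' writePSSM(p, f)
#' parsePSSM(f, id = "x")
parsePSSM <- function(path, id = NULL, label = NA_integer_) {
  if (is.null(id)) {
    id <- if (is.character(path)) sub("\\.[^.]*$", "", basename(path)) else "profile"
  }
  lines <- readLines(path, warn = FALSE)
  alpha <- pssmResidueOrder()
  header_i <- 0L
  header <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) %in% c(20L, 40L) && all(nchar(tok) == 1L) &&
        all(toupper(tok) %in% alpha) &&
        length(unique(toupper(tok[1:20]))) == 20L) {
      header_i <- i
      header <- toupper(tok[1:20])
      break
    }
  }
  if (header_i == 0L)
    stop("PSSM format error: missing residue-order header line")
  perm <- match(alpha, header)
  rows <- list()
  res <- character()
  for (i in seq(header_i + 1L, length.out = max(0L, length(lines) - header_i))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) {
      if (length(rows)) break else next
    }
    tok <- strsplit(line, "\\s+")[[1]]
    is_row <- grepl("^[0-9]+$", tok[1]) && length(tok) >= 2L &&
      nchar(tok[2]) == 1L && grepl("^[A-Za-z]$", tok[2])
    if (!is_row) {
      if (length(rows)) break
      stop(sprintf("PSSM format error at line %d: expected a position row", i))
    }
    aa <- toupper(tok[2])
    if (!aa %in% alpha)
      stop(sprintf("PSSM format error at line %d: residue '%s' is outside the 20-letter alphabet",
                   i, tok[2]))
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(nums))
      stop(sprintf("PSSM format error at line %d: non-numeric score field", i))
    if (!length(nums) %in% c(40L, 42L))
      stop(sprintf("PSSM format error at line %d: expected 40 numeric columns, found %d",
                   i, length(nums)))
    rows[[length(rows) + 1L]] <- nums[1:20]
    res <- c(res, aa)
  }
  if (!length(rows))
    stop("PSSM format error: empty profile body")
  scores <- do.call(rbind, rows)[, perm, drop = FALSE]
  if (!all(is.finite(scores)))
    stop("PSSM format error: non-finite score value")
  PSSMProfile(id, paste(res, collapse = ""), scores, label = label)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits a file [parsePSSM()] accepts: two header lines, the canonical
#' residue-order line (printed twice, as PSI-BLAST does for the two 20-column
#' blocks), then one row per position with the index, residue, the 20
#' log-odds scores as given and a 20-column zero percentage block (42
#' whitespace-separated tokens per row). No footer is written.
#'
#' @param profile A \linkS4class{PSSMProfile}.
#' @param path Output file path or connection.
#' @return \code{path}, invisibly.
#' @export
writePSSM <- function(profile, path) {
  stopifnot(is(profile, "PSSMProfile"))
  alpha <- pssmResidueOrder()
  sc <- pssmScores(profile)
  res <- strsplit(residueString(profile), "")[[1]]
  fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  body <- vapply(seq_len(nrow(sc)), function(i) {
    paste(c(sprintf("%5d", i), res[i],
            sprintf("%6s", fmt_num(sc[i, ])), rep("0", 20L)),
          collapse = " ")
  }, character(1))
  lines <- c("",
             "Last position-specific scoring matrix computed",
             paste(c("     ", alpha, alpha), collapse = "  "),
             body)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of protein sequences
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}: record order is
#' preserved, identifiers are truncated at the first whitespace, and
#' sequences are uppercased. A file whose first record content precedes any
#' \code{">"} header is rejected.
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences, in file order.
#' @export
readFasta <- function(path) {
  lines <- readLines(path, warn = FALSE, n = 50L)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first) || !startsWith(trimws(first), ">"))
    stop("FASTA format error: sequence data before the first '>' header")
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  seqs
}

# ---------------------------------------------------------------- manifests

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with columns \code{id,path,label}; paths are
#' interpreted relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return \code{readManifest}: a data.frame with columns id, path, label.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns id, path, label")
  df[need]
}

#' @rdname readManifest
#' @param manifest Data.frame with columns id, path, label.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[c("id", "path", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a labeled PSSM dataset from a manifest
#'
#' @param path A manifest CSV path, or a directory containing
#'   \code{manifest.csv}.
#' @param name Dataset name for the returned set.
#' @return A \linkS4class{PSSMSet}.
#' @export
loadDataset <- function(path, name = "") {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  mf <- readManifest(path)
  base <- dirname(path)
  profiles <- lapply(seq_len(nrow(mf)), function(i) {
    parsePSSM(file.path(base, mf$path[i]), id = mf$id[i],
              label = as.integer(mf$label[i]))
  })
  PSSMSet(profiles, name = name)
}

#' Materialize a PSSM dataset to disk
#'
#' Writes one ASCII PSSM file per profile plus \code{manifest.csv} into
#' \code{dir}.
#'
#' @param dataset A labeled \linkS4class{PSSMSet}.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
writeDatasetDir <- function(dataset, dir) {
  stopifnot(is(dataset, "PSSMSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- profileIDs(dataset)
  files <- paste0(ids, ".pssm")
  for (i in seq_along(ids))
    writePSSM(dataset[[i]], file.path(dir, files[i]))
  mf <- data.frame(id = ids, path = files, label = profileLabels(dataset))
  writeManifest(mf, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

# ---------------------------------------------------------------- partitions

# round half away from zero
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

checkLabeled <- function(dataset) {
  labs <- profileLabels(dataset)
  if (anyNA(labs)) stop("dataset contains unlabeled profiles")
  labs
}

#' Stratified train/test split
#'
#' Per class, round(n_class * testFraction) members (half away from zero)
#' are moved to the test set by a seeded shuffle; the split is a pure
#' function of dataset order and seed, and never duplicates or drops an
#' identifier.
#'
#' @param dataset A labeled \linkS4class{PSSMSet} with both classes present.
#' @param testFraction Fraction per class assigned to the test set,
#'   in (0, 1); default 0.2.
#' @param seed Shuffle seed, default 42.
#' @return List with \code{train} and \code{test} \linkS4class{PSSMSet}s.
#' @export
stratifiedSplit <- function(dataset, testFraction = 0.2, seed = 42L) {
  stopifnot(testFraction > 0, testFraction < 1)
  labs <- checkLabeled(dataset)
  if (!all(c(0L, 1L) %in% labs))
    stop("dataset needs at least one member of each class")
  test_idx <- integer(0)
  withSeed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labs == cl)
      n_test <- roundHalfAway(length(idx) * testFraction)
      if (n_test < 1L || n_test >= length(idx))
        stop(sprintf("testFraction %g leaves an empty class %d split",
                     testFraction, cl))
      test_idx <- c(test_idx, idx[sample.int(length(idx))][seq_len(n_test)])
    }
  })
  test_idx <- sort(test_idx)
  list(train = dataset[setdiff(seq_along(labs), test_idx)],
       test = dataset[test_idx])
}

#' Stratified k-fold partition
#'
#' Validation folds partition the dataset; within each class, fold sizes
#' differ by at most one. A pure function of dataset order and seed.
#'
#' @param dataset A labeled \linkS4class{PSSMSet}.
#' @param k Number of folds (>= 2), default 5.
#' @param seed Shuffle seed, default 42.
#' @return A list of k elements, each a list with \code{train} and
#'   \code{validation} \linkS4class{PSSMSet}s.
#' @export
kFoldStratified <- function(dataset, k = 5L, seed = 42L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  labs <- checkLabeled(dataset)
  for (cl in c(1L, 0L)) {
    if (sum(labs == cl) < k)
      stop(sprintf("class %d has fewer than k = %d members", cl, k))
  }
  fold <- integer(length(labs))
  withSeed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labs == cl)
      shuffled <- idx[sample.int(length(idx))]
      fold[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = dataset[which(fold != f)],
         validation = dataset[which(fold == f)])
  })
}
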