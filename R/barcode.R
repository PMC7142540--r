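#' Percent identity from a global pairwise alignment
#'
#' Aligns two DNA sequences globally (Needleman-Wunsch with affine gaps;
#' match +1, mismatch -1, gap open 2, gap extend 0.5) and returns the
#' percentage of matching columns, with terminal-gap columns excluded from
#' the denominator so that fragment queries are not penalised for being
#' shorter than the reference. Ambiguity bases (N) count as mismatches.
#'
#' @param a,b DNA strings (character or \code{DNAString}).
#' @param match,mismatch,gapOpening,gapExtension Alignment scoring
#'   parameters (penalties as positive numbers, Biostrings convention).
#' @return Percent identity in [0, 100]; symmetric in its arguments.
#' @examples
#' globalIdentity("ACGT", "ACGT")  # 100
#' globalIdentity("ACGT", "ACGA")  # 75
#' @export
globalIdentity <- function(a, b, match = 1, mismatch = -1,
                           gapOpening = 2, gapExtension = 0.5) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != 1L || nchar(a) == 0L || length(b) != 1L || nchar(b) == 0L)
    stop("both sequences must be single non-empty strings")
  ## align the lexicographically smaller sequence as pattern: co-optimal
  ## alignments may differ in column count, so a canonical order makes the
  ## reported identity exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  ## N scores as mismatch against everything, including N
  mat[, "N"] <- mismatch
  mat["N", ] <- mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  alignedIdentity(pc, sc)
}

## identity over aligned columns, terminal gap columns excluded; N = mismatch
alignedIdentity <- function(pc, sc) {
  endGap <- function(ch) {
    e <- logical(length(ch))
    i <- 1L
    while (i <= length(ch) && ch[i] == "-") { e[i] <- TRUE; i <- i + 1L }
    i <- length(ch)
    while (i >= 1L && ch[i] == "-") { e[i] <- TRUE; i <- i - 1L }
    e
  }
  keep <- !(endGap(pc) | endGap(sc))
  if (!any(keep)) return(0)
  matches <- pc[keep] == sc[keep] & pc[keep] %in% DNA_BASES4
  100 * sum(matches) / sum(keep)
}

#' Assign a query to a species by best-hit percent identity
#'
#' Compares the query against every entry of a reference barcode set with
#' \code{\link{globalIdentity}} and reports the best hit; ties are broken by
#' first occurrence in reference order. The hit passes if its identity
#' reaches \code{threshold} (default 98, the conventional acceptance rule
#' for COI barcode identification).
#'
#' @param query A DNA string (character or \code{DNAString}); may be named.
#' @param reference A \code{\link{BarcodeReference}}.
#' @param threshold Percent identity required to accept the assignment.
#' @return A one-row \code{data.frame}: \code{query_id}, \code{accession},
#'   \code{species}, \code{identity}, \code{pass}.
#' @export
assignSpecies <- function(query, reference, threshold = 98) {
  stopifnot(is(reference, "BarcodeReference"))
  if (length(reference@sequences) == 0L)
    stop("reference set is empty")
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  q <- as.character(query)[1]
  ids <- vapply(as.character(reference@sequences),
                function(r) globalIdentity(q, r), numeric(1))
  best <- which.max(ids)  # first max = first occurrence in reference order
  data.frame(
    query_id = qid,
    accession = names(reference@sequences)[best],
    species = reference@species[best],
    identity = unname(ids[best]),
    pass = unname(ids[best]) >= threshold,
    stringsAsFactors = FALSE)
}

#' Assign every query in a set
#'
#' @param queries A named \code{DNAStringSet} or named character vector.
#' @inheritParams assignSpecies
#' @return A \code{data.frame} of hits, one row per query.
#' @export
assignSpeciesSet <- function(queries, reference, threshold = 98) {
  queries <- asNamedCharacter(queries)
  do.call(rbind, lapply(names(queries), function(qn)
    assignSpecies(setNames(queries[qn], qn), reference, threshold)))
}

#' Count hits passing the identity threshold
#'
#' @param hits A \code{data.frame} with an \code{identity} column (percent),
#'   e.g. from \code{\link{assignSpeciesSet}} or
#'   \code{\link{codBarcodingResults}}.
#' @param threshold Percent identity cutoff.
#' @return Number of hits with \code{identity >= threshold}.
#' @export
countPassing <- function(hits, threshold = 98) {
  if (!is.data.frame(hits) || nrow(hits) == 0L)
    stop("'hits' must be a non-empty data.frame")
  sum(hits$identity >= threshold)
}

#' Kimura two-parameter distance
#'
#' Estimates substitutions per site between two aligned sequences from the
#' proportions of transitions (P) and transversions (Q) over non-gap
#' columns: \eqn{d = -\frac{1}{2}\ln((1-2P-Q)\sqrt{1-2Q})}. Sequences of
#' unequal length are globally aligned first. Saturated pairs, where the
#' logarithm's argument is non-positive, yield \code{NA} with a warning
#' (undefined distance).
#'
#' @param a,b DNA strings.
#' @return Estimated substitutions per site (0 for identical sequences), or
#'   \code{NA} if the distance is undefined.
#' @export
k2pDistance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("both sequences must be non-empty")
  if (nchar(a) != nchar(b)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 0.5,
      type = "global")
    ac <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    bc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  } else {
    ac <- strsplit(a, "", fixed = TRUE)[[1]]
    bc <- strsplit(b, "", fixed = TRUE)[[1]]
  }
  keep <- ac %in% DNA_BASES4 & bc %in% DNA_BASES4
  ac <- ac[keep]; bc <- bc[keep]
  n <- length(ac)
  if (n == 0L) stop("no aligned ACGT columns to compare")
  purine <- c("A", "G")
  diff <- ac != bc
  transition <- diff & ((ac %in% purine) == (bc %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance undefined (saturation)")
    return(NA_real_)
  }
  -0.5 * log(arg1 * sqrt(arg2))
}

#' K2P distance matrix for a sequence set
#'
#' @param seqs Named character vector or \code{DNAStringSet} of aligned
#'   equal-length sequences.
#' @return A symmetric \code{dist}-compatible matrix.
#' @export
k2pDistanceMatrix <- function(seqs) {
  seqs <- asNamedCharacter(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2pDistance(seqs[i], seqs[j])
    }
  }
  d
}

#' Species-grouping check on a neighbor-joining tree
#'
#' Builds a neighbor-joining tree from pairwise K2P distances and reports,
#' for each species label, whether its tips form a clade on the unrooted
#' tree (i.e. there is an edge separating exactly that label group from the
#' rest). This is the grouping concordance check used to confirm that
#' barcodes cluster by species.
#'
#' @param seqs Named character vector or \code{DNAStringSet} (>= 4
#'   sequences).
#' @param labels Character species label per sequence (>= 2 distinct).
#' @return Named logical vector, one element per species label; the
#'   \code{phylo} tree is attached as attribute \code{"tree"}.
#' @export
njGroupCheck <- function(seqs, labels) {
  seqs <- asNamedCharacter(seqs)
  if (length(seqs) < 4L)
    stop("need at least 4 sequences to build an NJ tree")
  if (length(labels) != length(seqs))
    stop("'labels' must parallel 'seqs'")
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  tree <- ape::nj(as.dist(k2pDistanceMatrix(seqs)))
  res <- vapply(unique(labels), function(lab) {
    tips <- names(seqs)[labels == lab]
    if (length(tips) == length(seqs) || length(tips) == 1L) return(TRUE)
    out <- names(seqs)[labels != lab][1]
    rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    ape::is.monophyletic(rooted, tips)
  }, logical(1))
  attr(res, "tree") <- tree
  res
}

#' Read a reference barcode FASTA
#'
#' Headers must be of the form \code{accession|species}.
#'
#' @param file Path to a FASTA file.
#' @return A \code{\link{BarcodeReference}}.
#' @export
readBarcodeReference <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("reference headers must be 'accession|species'")
  names(seqs) <- vapply(parts, `[`, character(1), 1L)
  new("BarcodeReference", sequences = seqs,
      species = vapply(parts, function(p) paste(p[-1], collapse = "|"),
                       character(1)))
}

#' Write a barcode reference and query set to FASTA/TSV
#'
#' @param barcodeSet The list returned by \code{\link{simulateBarcodeSet}}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
writeBarcodeSet <- function(barcodeSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- barcodeSet$reference
  refSeqs <- ref@sequences
  names(refSeqs) <- paste0(names(refSeqs), "|", ref@species)
  refPath <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(refSeqs, refPath)
  qPath <- file.path(dir, "queries.fasta")
  Biostrings::writeXStringSet(barcodeSet$queries, qPath)
  tPath <- file.path(dir, "truth_labels.tsv")
  write.table(data.frame(query_id = names(barcodeSet$truth),
                         species = unname(barcodeSet$truth)),
              tPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(reference = refPath, queries = qPath, truth = tPath))
}
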