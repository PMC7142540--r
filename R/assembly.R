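#' Quality-filter RAD reads
#'
#' Drops reads with more than \code{maxLowQualFrac} of bases below
#' \code{minQual}, or more than \code{maxNFrac} ambiguous (N) bases. This is
#' the read-level cleaning applied before stacking.
#'
#' @param reads A \code{\link{RadReads}} object.
#' @param minQual Phred score below which a base counts as low-quality.
#' @param maxLowQualFrac Maximum tolerated fraction of low-quality bases.
#' @param maxNFrac Maximum tolerated fraction of N bases.
#' @return A \code{\link{RadReads}} with failing reads removed.
#' @export
qualityFilter <- function(reads, minQual = 20L, maxLowQualFrac = 0.10,
                          maxNFrac = 0.05) {
  stopifnot(is(reads, "RadReads"))
  n <- length(reads@sequences)
  if (n == 0L) return(reads)
  lowFrac <- rowMeans(reads@qualities < minQual)
  nFrac <- vapply(strsplit(reads@sequences, "", fixed = TRUE),
                  function(ch) mean(!(ch %in% DNA_BASES4)), numeric(1))
  keep <- lowFrac <= maxLowQualFrac & nFrac <= maxNFrac
  new("RadReads",
      sampleId = reads@sampleId, species = reads@species,
      readIds = reads@readIds[keep],
      sequences = reads@sequences[keep],
      qualities = reads@qualities[keep, , drop = FALSE],
      trueLocus = reads@trueLocus[keep])
}

#' Build exact-match stacks within one sample
#'
#' Groups a sample's reads into stacks of exactly identical sequences.
#' Stacks reaching depth \code{m} become primary stacks; all remaining reads
#' form the secondary pool, to be placed onto merged loci later. With
#' \code{rcAware = TRUE} each read is first put into canonical orientation
#' (the lexicographically smaller of the read and its reverse complement,
#' qualities reversed accordingly).
#'
#' @param reads A \code{\link{RadReads}}; all reads must have equal length.
#' @param m Minimum depth for a primary stack (default 2).
#' @param rcAware Canonicalise read orientation before stacking.
#' @return A list with elements \code{reads} (possibly re-oriented),
#'   \code{primary} (list of \code{list(sequence, idx)}, ordered by depth
#'   descending then sequence) and \code{secondary} (integer read indices).
#' @export
buildStacks <- function(reads, m = 2L, rcAware = FALSE) {
  stopifnot(is(reads, "RadReads"), m >= 1L)
  n <- length(reads@sequences)
  if (n > 0L && length(unique(nchar(reads@sequences))) != 1L)
    stop("reads must all have the same length")
  if (rcAware && n > 0L) {
    rc <- vapply(reads@sequences, reverseComplement1, character(1),
                 USE.NAMES = FALSE)
    flip <- rc < reads@sequences
    if (any(flip)) {
      reads@sequences[flip] <- rc[flip]
      reads@qualities[flip, ] <- reads@qualities[flip, ncol(reads@qualities):1,
                                                 drop = FALSE]
    }
  }
  groups <- split(seq_len(n), reads@sequences)
  depths <- lengths(groups)
  isPrimary <- depths >= m
  prim <- groups[isPrimary]
  ord <- order(-lengths(prim), names(prim))
  prim <- prim[ord]
  list(
    reads = reads,
    primary = lapply(names(prim), function(s) list(sequence = s, idx = prim[[s]])),
    secondary = sort(unlist(groups[!isPrimary], use.names = FALSE))
  )
}

#' Merge stacks into sample loci
#'
#' Primary stacks whose sequences lie within Hamming distance \code{M} are
#' merged into one locus by single-linkage clustering; each secondary read
#' is then placed on the unique nearest locus within distance \code{M}
#' (ties, or no locus in range, discard the read). The locus consensus is
#' the per-position modal base over all assigned reads (tie-break
#' alphabetical), so deeper stacks dominate variant positions.
#'
#' @param stacks The list returned by \code{\link{buildStacks}}.
#' @param M Maximum within-sample mismatch for merging (default 2).
#' @return A list with \code{loci} (list of \code{list(consensus, idx,
#'   depth)}, ordered by depth descending then consensus), \code{discarded}
#'   (indices of dropped secondary reads) and \code{reads}.
#' @export
mergeStacks <- function(stacks, M = 2L) {
  stopifnot(M >= 0L)
  reads <- stacks$reads
  prim <- stacks$primary
  if (length(prim) == 0L)
    return(list(loci = list(), discarded = stacks$secondary, reads = reads))
  seqs <- vapply(prim, `[[`, character(1), "sequence")
  comp <- if (length(seqs) > 1L)
    singleLinkageComponents(hammingMatrix(seqs), M)
  else 1L
  loci <- lapply(sort(unique(comp)), function(ci) {
    idx <- sort(unlist(lapply(prim[comp == ci], `[[`, "idx"), use.names = FALSE))
    list(idx = idx)
  })
  ## place secondary reads on a unique nearest locus
  consFor <- function(idx) weightedConsensus(
    seqsToMatrix(reads@sequences[idx]))
  consensus <- vapply(loci, function(l) consFor(l$idx), character(1))
  discarded <- integer(0)
  for (si in stacks$secondary) {
    d <- vapply(consensus, function(cs)
      hammingDistance(reads@sequences[si], cs), numeric(1))
    dmin <- min(d)
    if (dmin <= M && sum(d == dmin) == 1L) {
      li <- which.min(d)
      loci[[li]]$idx <- c(loci[[li]]$idx, si)
    } else {
      discarded <- c(discarded, si)
    }
  }
  ## final consensus over the full pileup; deterministic ordering
  loci <- lapply(loci, function(l) {
    l$idx <- sort(l$idx)
    l$consensus <- consFor(l$idx)
    l$depth <- length(l$idx)
    l
  })
  ord <- order(-vapply(loci, `[[`, numeric(1), "depth"),
               vapply(loci, `[[`, character(1), "consensus"))
  list(loci = loci[ord], discarded = sort(discarded), reads = reads)
}

#' Build the cross-sample catalog
#'
#' Single-linkage merges the consensus sequences of all samples' loci at
#' Hamming distance \code{n}; this is the step that places homologous loci
#' of different species into one catalog entry, making cross-species
#' diagnostic sites comparable. The catalog consensus is the depth-weighted
#' modal base per position.
#'
#' @param samples Named list (by sample id) of \code{\link{mergeStacks}}
#'   results.
#' @param n Maximum between-sample mismatch for merging (default 3).
#' @return A list with \code{consensus} (named character of catalog
#'   consensuses, ordered by total depth descending then sequence) and
#'   \code{members} (\code{data.frame}: sample, sample_locus,
#'   catalog_locus).
#' @export
buildCatalog <- function(samples, n = 3L) {
  stopifnot(n >= 0L, length(samples) > 0L)
  tab <- do.call(rbind, lapply(names(samples), function(sid) {
    loci <- samples[[sid]]$loci
    if (length(loci) == 0L) return(NULL)
    data.frame(sample = sid,
               sample_locus = seq_along(loci),
               consensus = vapply(loci, `[[`, character(1), "consensus"),
               depth = vapply(loci, `[[`, numeric(1), "depth"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || nrow(tab) == 0L)
    return(list(consensus = character(0),
                members = data.frame(sample = character(0),
                                     sample_locus = integer(0),
                                     catalog_locus = character(0))))
  if (length(unique(nchar(tab$consensus))) != 1L)
    stop("sample loci have mixed lengths; cannot build catalog")
  comp <- if (nrow(tab) > 1L)
    singleLinkageComponents(hammingMatrix(tab$consensus), n)
  else 1L
  comps <- sort(unique(comp))
  cons <- vapply(comps, function(ci) {
    rows <- comp == ci
    weightedConsensus(seqsToMatrix(tab$consensus[rows]), tab$depth[rows])
  }, character(1))
  totDepth <- vapply(comps, function(ci) sum(tab$depth[comp == ci]), numeric(1))
  ord <- order(-totDepth, cons)
  rank <- integer(length(comps))
  rank[ord] <- seq_along(comps)
  ids <- sprintf("CL%04d", rank)  # one id per component, by (depth desc, seq)
  names(cons) <- ids
  tab$catalog_locus <- ids[comp]
  cons <- cons[order(names(cons))]
  list(consensus = cons, members = tab[, c("sample", "sample_locus",
                                           "catalog_locus")])
}

#' Match sample loci against the catalog
#'
#' Places every sample locus on the nearest catalog locus within Hamming
#' distance \code{n}; ties leave the locus unmatched (reported, not fatal).
#' Emits per-sample, per-catalog-locus read pileups in catalog coordinates.
#'
#' @param catalog The list returned by \code{\link{buildCatalog}}.
#' @param samples Named list of \code{\link{mergeStacks}} results.
#' @param n Maximum mismatch for matching (default 3).
#' @return A list with \code{matches} (\code{data.frame}: sample,
#'   catalog_locus, distance, depth), \code{unmatched} and \code{pileups}
#'   (\code{[[catalog_locus]][[sample]] = list(bases, quals)}).
#' @export
matchSamples <- function(catalog, samples, n = 3L) {
  cons <- catalog$consensus
  matches <- list(); unmatched <- list()
  pileups <- setNames(vector("list", length(cons)), names(cons))
  for (sid in names(samples)) {
    ms <- samples[[sid]]
    for (li in seq_along(ms$loci)) {
      loc <- ms$loci[[li]]
      d <- vapply(cons, function(cs) hammingDistance(loc$consensus, cs),
                  numeric(1))
      dmin <- if (length(d)) min(d) else Inf
      if (is.finite(dmin) && dmin <= n && sum(d == dmin) == 1L) {
        cl <- names(cons)[which.min(d)]
        matches[[length(matches) + 1L]] <-
          data.frame(sample = sid, catalog_locus = cl,
                     distance = dmin, depth = loc$depth,
                     stringsAsFactors = FALSE)
        bases <- seqsToMatrix(ms$reads@sequences[loc$idx])
        quals <- ms$reads@qualities[loc$idx, , drop = FALSE]
        if (is.null(pileups[[cl]][[sid]])) {
          pileups[[cl]][[sid]] <- list(bases = bases, quals = quals)
        } else {
          pileups[[cl]][[sid]]$bases <- rbind(pileups[[cl]][[sid]]$bases, bases)
          pileups[[cl]][[sid]]$quals <- rbind(pileups[[cl]][[sid]]$quals, quals)
        }
      } else {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(sample = sid, sample_locus = li,
                     consensus = loc$consensus, distance = dmin,
                     stringsAsFactors = FALSE)
      }
    }
  }
  bindRows <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(
    matches = bindRows(matches, data.frame(
      sample = character(0), catalog_locus = character(0),
      distance = numeric(0), depth = numeric(0))),
    unmatched = bindRows(unmatched, data.frame(
      sample = character(0), sample_locus = integer(0),
      consensus = character(0), distance = numeric(0))),
    pileups = pileups
  )
}

#' Assemble per-sample reads into a cross-sample catalog
#'
#' Runs the full de novo assembly for a set of samples: quality filtering
#' (optional), exact stacking, within-sample merging, catalog construction
#' and sample-to-catalog matching, with the stage counts recorded.
#'
#' @param readsList Named list of \code{\link{RadReads}}, one per sample.
#' @param m,M,n Assembly parameters: minimum stack depth, within-sample
#'   mismatch bound and catalog mismatch bound (defaults 2, 2, 3).
#' @param rcAware Canonicalise read orientation (default FALSE).
#' @param filter Apply \code{\link{qualityFilter}} first (default TRUE).
#' @return A \code{\link{RadCatalog}}.
#' @export
assembleSamples <- function(readsList, m = 2L, M = 2L, n = 3L,
                            rcAware = FALSE, filter = TRUE) {
  stopifnot(length(readsList) > 0L)
  readsIn <- sum(vapply(readsList, function(r) length(r@sequences), numeric(1)))
  if (filter)
    readsList <- lapply(readsList, qualityFilter)
  retained <- sum(vapply(readsList, function(r) length(r@sequences), numeric(1)))
  merged <- lapply(readsList, function(r) mergeStacks(buildStacks(r, m = m,
                                                                  rcAware = rcAware), M = M))
  names(merged) <- names(readsList)
  cat0 <- buildCatalog(merged, n = n)
  mm <- matchSamples(cat0, merged, n = n)
  assigned <- sum(vapply(merged, function(ms)
    sum(vapply(ms$loci, `[[`, numeric(1), "depth")), numeric(1)))
  discarded <- sum(vapply(merged, function(ms) length(ms$discarded), numeric(1)))
  new("RadCatalog",
      consensus = Biostrings::DNAStringSet(cat0$consensus),
      pileups = mm$pileups,
      matches = mm$matches,
      unmatched = mm$unmatched,
      params = list(m = as.integer(m), M = as.integer(M), n = as.integer(n),
                    rcAware = rcAware,
                    samples = names(readsList),
                    species = vapply(readsList, function(r) r@species,
                                     character(1))),
      log = c(reads_in = readsIn, reads_retained = retained,
              reads_assigned = assigned, reads_discarded = discarded,
              sample_loci = sum(vapply(merged, function(ms) length(ms$loci),
                                       numeric(1))),
              catalog_loci = length(cat0$consensus)))
}

#' Write catalog outputs to plain-text files
#'
#' Writes the catalog consensus FASTA and the sample-to-catalog match TSV.
#'
#' @param catalog A \code{\link{RadCatalog}}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
writeCatalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "catalog.fasta")
  Biostrings::writeXStringSet(catalog@consensus, fa)
  tsv <- file.path(dir, "matches.tsv")
  write.table(catalog@matches, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, matches = tsv))
}
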