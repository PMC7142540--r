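#' In-silico restriction digest
#'
#' Scan a sequence for exact occurrences of a restriction-site motif on the
#' forward strand. RAD loci are anchored at these cut sites; the default
#' motif is the TaqI recognition site 5'-TCGA-3'. Overlapping occurrences are
#' all reported.
#'
#' @param sequence A DNA string (character or \code{DNAString}).
#' @param site Recognition motif, plain ACGT (no ambiguity codes).
#' @return Integer vector of 1-based start positions of the motif, ascending.
#' @examples
#' inSilicoDigest("AATCGATT")          # 3
#' inSilicoDigest("TCGATCGA")          # 1 5
#' @export
inSilicoDigest <- function(sequence, site = "TCGA") {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("'sequence' must be a single non-empty DNA string")
  if (length(site) != 1L || nchar(site) == 0L || !grepl("^[ACGT]+$", site))
    stop("'site' must be a non-empty string over A, C, G, T")
  as.integer(Biostrings::start(
    Biostrings::matchPattern(site, Biostrings::DNAString(sequence))
  ))
}

#' Simulate a set of RAD loci for diverged species
#'
#' Generates the ground truth of a multi-species RAD experiment. Ancestral
#' loci are drawn uniformly over ACGT and each begins with the TaqI remnant
#' \code{TCGA} so loci are digest-anchored. Non-diagnostic loci receive
#' independent per-species substitutions at rate \code{divergence};
#' diagnostic loci instead carry, at one recorded position, a planted allele
#' per species chosen so that all species differ pairwise and every
#' individual of a species is fixed for its allele.
#'
#' Background substitutions never create a column where all species are
#' pairwise distinct: such chance columns are reverted so that the planted
#' diagnostic set is, by construction, exactly the set of species-diagnostic
#' sites and recovery can be scored as precision/recall against the truth.
#'
#' @param nLoci Number of loci.
#' @param locusLength Locus length in bases (>= 20; default 100, the read
#'   length of the emulated study design).
#' @param nSpecies Number of species (2..4; single-base alleles can be
#'   pairwise distinct for at most four species).
#' @param nDiagnostic Number of loci planted with a diagnostic site.
#' @param divergence Background per-site substitution rate per species
#'   lineage (fraction in [0, 1)).
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @param species Optional character vector of species labels.
#' @return A \code{\link{RadSimTruth}}.
#' @examples
#' tr <- simulateLocusSet(10, nDiagnostic = 2, divergence = 0, seed = 7)
#' diagnosticLoci(tr)
#' @export
simulateLocusSet <- function(nLoci, locusLength = 100L, nSpecies = 3L,
                             nDiagnostic, divergence = 0.005, seed,
                             species = NULL) {
  stopifnot(nLoci >= 1L, locusLength >= 20L, nSpecies >= 2L)
  if (nSpecies > 4L)
    stop("at most 4 species: diagnostic alleles are single bases")
  if (nDiagnostic > nLoci)
    stop("'nDiagnostic' must not exceed 'nLoci'")
  if (divergence < 0 || divergence >= 1)
    stop("'divergence' must lie in [0, 1)")
  if (is.null(species))
    species <- paste0("species", seq_len(nSpecies))
  stopifnot(length(species) == nSpecies)

  withSeed(seed, {
    anc <- vapply(seq_len(nLoci),
                  function(i) paste0("TCGA", randomDna(locusLength - 4L)),
                  character(1))
    names(anc) <- sprintf("L%04d", seq_len(nLoci))

    diagLoci <- sort(sample.int(nLoci, nDiagnostic))
    diagPos <- integer(nDiagnostic)
    diagAll <- matrix("", nDiagnostic, nSpecies,
                      dimnames = list(names(anc)[diagLoci], species))

    perSpecies <- lapply(species, function(s) anc)
    names(perSpecies) <- species

    ## background divergence on non-diagnostic loci, anchor kept intact
    for (li in setdiff(seq_len(nLoci), diagLoci)) {
      chars <- strsplit(anc[[li]], "", fixed = TRUE)[[1]]
      spMat <- matrix(rep(chars, nSpecies), nrow = nSpecies, byrow = TRUE)
      if (divergence > 0) {
        for (sp in seq_len(nSpecies)) {
          tail <- mutateChars(chars[5:locusLength], divergence)
          spMat[sp, 5:locusLength] <- tail
        }
        ## revert chance all-distinct columns (see Details)
        for (j in 5:locusLength) {
          sp <- nSpecies
          while (length(unique(spMat[, j])) == nSpecies && sp >= 1L) {
            spMat[sp, j] <- chars[j]
            sp <- sp - 1L
          }
        }
      }
      for (sp in seq_len(nSpecies))
        perSpecies[[sp]][li] <- paste(spMat[sp, ], collapse = "")
    }

    ## planted diagnostic sites (no background divergence on these loci)
    for (k in seq_len(nDiagnostic)) {
      li <- diagLoci[k]
      pos <- sample(5:locusLength, 1L)
      alleles <- sample(DNA_BASES4, nSpecies)
      diagPos[k] <- pos
      diagAll[k, ] <- alleles
      for (sp in seq_len(nSpecies)) {
        s <- perSpecies[[sp]][li]
        substr(s, pos, pos) <- alleles[sp]
        perSpecies[[sp]][li] <- s
      }
    }

    new("RadSimTruth",
        species = species,
        ancestral = Biostrings::DNAStringSet(anc),
        locusSequences = lapply(perSpecies, Biostrings::DNAStringSet),
        diagnosticLoci = diagLoci,
        diagnosticPositions = diagPos,
        diagnosticAlleles = diagAll,
        divergence = divergence,
        seed = as.integer(seed))
  })
}

#' Simulate RAD reads for each sample
#'
#' Draws, for every sample, a Poisson number of reads per locus copied from
#' the sample's species consensus, with independent per-base substitution
#' errors and Phred qualities from a clipped normal model. Individuals of a
#' species share the species consensus (within-species homozygosity), the
#' structure the downstream diagnostic filter assumes.
#'
#' @param truth A \code{\link{RadSimTruth}}.
#' @param nSamples Integer vector of samples per species (recycled if
#'   length 1).
#' @param depth Expected reads per locus per sample (Poisson mean, >= 1).
#' @param errorRate Per-base substitution error rate in [0, 0.5).
#' @param qualityMean,qualitySd Normal model for per-base Phred scores,
#'   clipped to [2, 41] (the instrument range).
#' @param rcFraction Fraction of reads emitted as reverse complements
#'   (default 0: a single canonical orientation; set > 0 to exercise the
#'   assembler's \code{rcAware} flag).
#' @param seed Integer seed.
#' @return Named list of \code{\link{RadReads}}, one per sample.
#' @export
simulateReads <- function(truth, nSamples, depth = 20, errorRate = 0.001,
                          qualityMean = 38, qualitySd = 3, rcFraction = 0,
                          seed) {
  stopifnot(is(truth, "RadSimTruth"), depth >= 1)
  if (errorRate < 0 || errorRate >= 0.5)
    stop("'errorRate' must lie in [0, 0.5)")
  species <- truth@species
  nSamples <- rep_len(as.integer(nSamples), length(species))

  withSeed(seed, {
    out <- list()
    for (sp in seq_along(species)) {
      consMat <- seqsToMatrix(as.character(truth@locusSequences[[sp]]))
      L <- ncol(consMat)
      nl <- nrow(consMat)
      for (ind in seq_len(nSamples[sp])) {
        sid <- sprintf("%s_s%02d", species[sp], ind)
        counts <- rpois(nl, depth)
        locusOf <- rep.int(seq_len(nl), counts)
        nr <- length(locusOf)
        bases <- consMat[locusOf, , drop = FALSE]
        if (errorRate > 0 && nr > 0L) {
          hits <- which(runif(nr * L) < errorRate)
          for (h in hits)
            bases[h] <- sample(setdiff(DNA_BASES4, bases[h]), 1L)
        }
        quals <- matrix(pmin(pmax(as.integer(round(
          rnorm(nr * L, qualityMean, qualitySd))), 2L), 41L), nr, L)
        if (rcFraction > 0 && nr > 0L) {
          flip <- which(runif(nr) < rcFraction)
          for (f in flip) {
            bases[f, ] <- rev(chartr("ACGT", "TGCA", bases[f, ]))
            quals[f, ] <- rev(quals[f, ])
          }
        }
        out[[sid]] <- new("RadReads",
          sampleId = sid,
          species = species[sp],
          readIds = sprintf("%s_L%04d_r%03d", sid, locusOf,
                            sequence(counts)),
          sequences = matrixToSeqs(bases),
          qualities = quals,
          trueLocus = locusOf)
      }
    }
    out
  })
}

#' Simulate a barcode reference and query set
#'
#' Generates one reference barcode per species from a common ancestor plus
#' per-species query sequences, with within-species divergence much smaller
#' than between-species divergence (the regime in which percent-identity
#' barcoding is reliable). The default length is the conventional ~650 bp
#' COI barcode.
#'
#' @param nSpecies Number of species.
#' @param perSpeciesQueries Integer vector of queries per species.
#' @param barcodeLength Barcode length in bases.
#' @param withinDivergence Query-to-own-reference substitution rate.
#' @param betweenDivergence Approximate pairwise reference divergence;
#'   must exceed \code{withinDivergence}.
#' @param seed Integer seed.
#' @param species Optional species labels.
#' @return List with elements \code{reference} (a
#'   \code{\link{BarcodeReference}}), \code{queries} (a \code{DNAStringSet})
#'   and \code{truth} (named character of true species per query).
#' @export
simulateBarcodeSet <- function(nSpecies = 3L, perSpeciesQueries,
                               barcodeLength = 650L,
                               withinDivergence, betweenDivergence, seed,
                               species = NULL) {
  if (withinDivergence >= betweenDivergence)
    stop("'withinDivergence' must be smaller than 'betweenDivergence'")
  if (is.null(species))
    species <- paste0("species", seq_len(nSpecies))
  perSpeciesQueries <- rep_len(as.integer(perSpeciesQueries), nSpecies)

  withSeed(seed, {
    ancestor <- strsplit(randomDna(barcodeLength), "", fixed = TRUE)[[1]]
    refs <- character(nSpecies)
    for (sp in seq_len(nSpecies))
      refs[sp] <- paste(mutateChars(ancestor, betweenDivergence / 2), collapse = "")
    names(refs) <- sprintf("REF%03d", seq_len(nSpecies))

    queries <- character(0)
    truthLab <- character(0)
    for (sp in seq_len(nSpecies)) {
      refChars <- strsplit(refs[sp], "", fixed = TRUE)[[1]]
      for (qi in seq_len(perSpeciesQueries[sp])) {
        q <- paste(mutateChars(refChars, withinDivergence), collapse = "")
        qname <- sprintf("q_%s_%02d", species[sp], qi)
        queries[qname] <- q
        truthLab[qname] <- species[sp]
      }
    }
    list(
      reference = new("BarcodeReference",
                      sequences = Biostrings::DNAStringSet(refs),
                      species = species),
      queries = Biostrings::DNAStringSet(queries),
      truth = truthLab
    )
  })
}

## File IO --------------------------------------------------------------------

#' Write simulated reads as per-sample FASTQ (Phred+33)
#'
#' @param reads Named list of \code{\link{RadReads}} (from
#'   \code{\link{simulateReads}}).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeRadFastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rr in reads) {
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(rr@sequences, rr@readIds)),
      Biostrings::PhredQuality(vapply(seq_along(rr@sequences), function(i)
        phredToString(rr@qualities[i, ]), character(1))))
    p <- file.path(dir, paste0(rr@sampleId, ".fastq"))
    Biostrings::writeQualityScaledXStringSet(qs, p)
    paths[rr@sampleId] <- p
  }
  invisible(paths)
}

#' Read per-sample FASTQ files back into RadReads
#'
#' The sample identifier is taken from the file name; the true locus of
#' origin is not recovered (the pipeline never uses it).
#'
#' @param files Character vector of FASTQ paths, or a directory containing
#'   \code{*.fastq}.
#' @param species Named character vector mapping sample id to species label
#'   (optional; defaults to \code{NA}).
#' @return Named list of \code{\link{RadReads}}.
#' @export
readRadFastq <- function(files, species = NULL) {
  if (length(files) == 1L && dir.exists(files))
    files <- sort(list.files(files, pattern = "\\.fastq$", full.names = TRUE))
  out <- list()
  for (f in files) {
    sid <- sub("\\.fastq$", "", basename(f))
    ## suppressed: Biostrings warns about dropping (empty) mcols on read
    qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(f))
    qmat <- if (length(qs)) {
      do.call(rbind, lapply(as.character(Biostrings::quality(qs)), stringToPhred))
    } else matrix(integer(0), 0, 0)
    out[[sid]] <- new("RadReads",
      sampleId = sid,
      species = if (!is.null(species) && sid %in% names(species))
        unname(species[sid]) else NA_character_,
      readIds = names(qs),
      sequences = unname(as.character(qs)),
      qualities = qmat,
      trueLocus = rep(NA_integer_, length(qs)))
  }
  out
}

#' Write simulation truth to plain-text files
#'
#' Writes the per-species locus consensuses as FASTA and the planted
#' diagnostic sites as a TSV truth table (locus_id, position, species,
#' allele).
#'
#' @param truth A \code{\link{RadSimTruth}}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
writeSimTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(unlist(lapply(
    truth@species, function(sp) {
      x <- as.character(truth@locusSequences[[sp]])
      setNames(x, paste0(sp, "|", names(x)))
    })))
  fa <- file.path(dir, "true_loci.fasta")
  Biostrings::writeXStringSet(seqs, fa)

  lid <- names(truth@ancestral)[truth@diagnosticLoci]
  tab <- do.call(rbind, lapply(seq_along(truth@diagnosticLoci), function(k)
    data.frame(locus_id = lid[k],
               position = truth@diagnosticPositions[k],
               species = truth@species,
               allele = truth@diagnosticAlleles[k, ])))
  tsv <- file.path(dir, "truth_diagnostic.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, tsv = tsv))
}
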