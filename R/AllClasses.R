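#' Ground truth for a simulated RAD locus set
#'
#' Container for the simulated "truth" behind a RAD experiment: per-species
#' locus consensus sequences, which loci carry a planted species-diagnostic
#' site, where that site sits within the locus, and which allele each species
#' is fixed for. Produced by \code{\link{simulateLocusSet}} and consumed by
#' \code{\link{simulateReads}} and by tests that score recovery.
#'
#' @slot species Character vector of species labels.
#' @slot ancestral \code{DNAStringSet} of ancestral locus sequences.
#' @slot locusSequences Named list (one element per species) of
#'   \code{DNAStringSet}s holding each species' locus consensuses.
#' @slot diagnosticLoci Integer indices of loci carrying a planted
#'   diagnostic site.
#' @slot diagnosticPositions Integer 1-based positions of the planted site
#'   within each diagnostic locus (parallel to \code{diagnosticLoci}).
#' @slot diagnosticAlleles Character matrix (diagnostic loci x species) of
#'   the fixed allele each species carries at the planted site.
#' @slot divergence Per-site background substitution rate used.
#' @slot seed Integer seed the simulation was generated with.
#' @export
setClass("RadSimTruth",
  slots = c(
    species = "character",
    ancestral = "DNAStringSet",
    locusSequences = "list",
    diagnosticLoci = "integer",
    diagnosticPositions = "integer",
    diagnosticAlleles = "matrix",
    divergence = "numeric",
    seed = "integer"
  )
)

setValidity("RadSimTruth", function(object) {
  msg <- character()
  nl <- length(object@ancestral)
  if (!all(names(object@locusSequences) == object@species))
    msg <- c(msg, "locusSequences must be named by species")
  if (any(object@diagnosticLoci > nl) || any(object@diagnosticLoci < 1L))
    msg <- c(msg, "diagnostic locus indices must lie in 1..n_loci")
  if (length(object@diagnosticPositions) != length(object@diagnosticLoci))
    msg <- c(msg, "diagnosticPositions must parallel diagnosticLoci")
  if (nrow(object@diagnosticAlleles) != length(object@diagnosticLoci) ||
      ncol(object@diagnosticAlleles) != length(object@species))
    msg <- c(msg, "diagnosticAlleles must be diagnostic-loci x species")
  for (i in seq_len(nrow(object@diagnosticAlleles))) {
    a <- object@diagnosticAlleles[i, ]
    if (anyDuplicated(a))
      msg <- c(msg, sprintf("alleles at diagnostic locus %d are not pairwise distinct",
                            object@diagnosticLoci[i]))
  }
  if (length(msg)) msg else TRUE
})

#' Simulated RAD reads for one sample
#'
#' Equal-length single-end reads with per-base Phred (Sanger-scale)
#' qualities. \code{trueLocus} records each read's locus of origin for test
#' introspection only; no pipeline stage reads it.
#'
#' @slot sampleId Sample identifier.
#' @slot species Species label of the sample.
#' @slot readIds Character read identifiers.
#' @slot sequences Character vector of read sequences over A,C,G,T,N.
#' @slot qualities Integer matrix (reads x positions) of Phred scores.
#' @slot trueLocus Integer locus-of-origin per read (introspection only).
#' @export
setClass("RadReads",
  slots = c(
    sampleId = "character",
    species = "character",
    readIds = "character",
    sequences = "character",
    qualities = "matrix",
    trueLocus = "integer"
  )
)

setValidity("RadReads", function(object) {
  n <- length(object@sequences)
  if (length(object@readIds) != n)
    return("readIds and sequences lengths differ")
  if (n > 0L && nrow(object@qualities) != n)
    return("qualities must have one row per read")
  if (n > 0L && any(nchar(object@sequences) != ncol(object@qualities)))
    return("sequence length must equal the number of quality columns")
  TRUE
})

#' Cross-sample catalog of assembled RAD loci
#'
#' The result of merging per-sample loci across samples: one consensus per
#' catalog locus, per-sample read pileups aligned to catalog coordinates, a
#' match table, and stage counts for the run log.
#'
#' @slot consensus \code{DNAStringSet} of catalog consensuses (named).
#' @slot pileups List indexed \code{[[locus]][[sample]]}, each element a list
#'   with character matrix \code{bases} and integer matrix \code{quals}
#'   (assigned reads x positions).
#' @slot matches \code{data.frame} with columns \code{sample},
#'   \code{catalog_locus}, \code{distance}, \code{depth}.
#' @slot unmatched \code{data.frame} of sample loci left unmatched.
#' @slot params \code{list} of assembly parameters used.
#' @slot log Named numeric vector of stage counts.
#' @export
setClass("RadCatalog",
  slots = c(
    consensus = "DNAStringSet",
    pileups = "list",
    matches = "data.frame",
    unmatched = "data.frame",
    params = "list",
    log = "numeric"
  )
)

#' Reference barcode set
#'
#' A local reference set for percent-identity species assignment: one entry
#' per reference sequence with a unique accession label and a species label.
#'
#' @slot sequences \code{DNAStringSet}, names are accession labels.
#' @slot species Character species label per entry.
#' @export
setClass("BarcodeReference",
  slots = c(sequences = "DNAStringSet", species = "character")
)

setValidity("BarcodeReference", function(object) {
  msg <- character()
  if (length(object@sequences) == 0L)
    msg <- c(msg, "reference set must be non-empty")
  if (length(object@species) != length(object@sequences))
    msg <- c(msg, "species labels must parallel sequences")
  if (anyDuplicated(names(object@sequences)))
    msg <- c(msg, "accession labels must be unique")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "reference sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Species-diagnostic marker panel
#'
#' An ordered set of SNP positions on named amplicon regions with the allele
#' each species is expected to carry, plus the PCR primer pair and expected
#' product size per region. The built-in panel is returned by
#' \code{\link{codPanel}}.
#'
#' @slot primers \code{data.frame} with columns \code{region},
#'   \code{forward}, \code{reverse}, \code{annealing_temp},
#'   \code{product_size}.
#' @slot alleles \code{data.frame} with columns \code{region},
#'   \code{position} (1-based within the amplicon), \code{species},
#'   \code{allele}.
#' @export
setClass("DiagnosticPanel",
  slots = c(primers = "data.frame", alleles = "data.frame")
)

setValidity("DiagnosticPanel", function(object) {
  msg <- character()
  pr <- object@primers
  al <- object@alleles
  need_pr <- c("region", "forward", "reverse", "annealing_temp", "product_size")
  need_al <- c("region", "position", "species", "allele")
  if (!all(need_pr %in% names(pr)))
    msg <- c(msg, "primers table is missing required columns")
  if (!all(need_al %in% names(al)))
    msg <- c(msg, "alleles table is missing required columns")
  if (length(msg)) return(msg)
  if (!all(grepl("^[ACGT]+$", pr$forward)) || !all(grepl("^[ACGT]+$", pr$reverse)))
    msg <- c(msg, "primers must be non-empty ACGT strings")
  if (!all(al$region %in% pr$region))
    msg <- c(msg, "every allele row must reference a primer region")
  sp <- sort(unique(al$species))
  for (key in unique(paste(al$region, al$position))) {
    rows <- al[paste(al$region, al$position) == key, ]
    if (!identical(sort(rows$species), sp))
      msg <- c(msg, sprintf("allele table incomplete at %s", key))
    if (anyDuplicated(rows$allele))
      msg <- c(msg, sprintf("alleles not pairwise distinct across species at %s", key))
  }
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "RadSimTruth", function(object) {
  cat(sprintf("RadSimTruth: %d loci x %d species (%s)\n",
              length(object@ancestral), length(object@species),
              paste(object@species, collapse = ", ")))
  cat(sprintf("  %d diagnostic loci planted at loci: %s\n",
              length(object@diagnosticLoci),
              paste(object@diagnosticLoci, collapse = ", ")))
  cat(sprintf("  background divergence %.4g subs/site, seed %d\n",
              object@divergence, object@seed))
})

setMethod("show", "RadReads", function(object) {
  cat(sprintf("RadReads: sample %s (%s), %d reads of length %d\n",
              object@sampleId, object@species, length(object@sequences),
              if (length(object@sequences)) nchar(object@sequences[[1]]) else 0L))
})

setMethod("show", "RadCatalog", function(object) {
  cat(sprintf("RadCatalog: %d loci, %d sample-locus matches (%d unmatched)\n",
              length(object@consensus), nrow(object@matches),
              nrow(object@unmatched)))
  cat(sprintf("  params: m=%d M=%d n=%d\n", object@params$m,
              object@params$M, object@params$n))
})

setMethod("show", "BarcodeReference", function(object) {
  cat(sprintf("BarcodeReference: %d entries, %d species\n",
              length(object@sequences), length(unique(object@species))))
})

setMethod("show", "DiagnosticPanel", function(object) {
  cat(sprintf("DiagnosticPanel: %d regions, %d SNP positions, %d species\n",
              nrow(object@primers),
              nrow(unique(object@alleles[, c("region", "position")])),
              length(unique(object@alleles$species))))
  for (r in object@primers$region) {
    pos <- sort(unique(object@alleles$position[object@alleles$region == r]))
    cat(sprintf("  region %s: positions %s (%d bp product)\n", r,
                paste(pos, collapse = "/"),
                object@primers$product_size[object@primers$region == r]))
  }
})
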