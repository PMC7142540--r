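#' Number of simulated loci
#'
#' @param x A \code{\link{RadSimTruth}}.
#' @return Integer count of loci in the simulation.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @export
setMethod("nLoci", "RadSimTruth", function(x) length(x@ancestral))

#' Accessors for simulation truth
#'
#' @param x A \code{\link{RadSimTruth}}.
#' @return \code{diagnosticLoci} returns the planted locus indices;
#'   \code{diagnosticPositions} the 1-based site offsets;
#'   \code{diagnosticAlleles} the loci x species allele matrix;
#'   \code{locusSequences} the per-species \code{DNAStringSet} list;
#'   \code{speciesLabels} the species names.
#' @export
setGeneric("diagnosticLoci", function(x) standardGeneric("diagnosticLoci"))

#' @export
setMethod("diagnosticLoci", "RadSimTruth", function(x) x@diagnosticLoci)

#' @rdname diagnosticLoci
#' @export
setGeneric("diagnosticPositions", function(x) standardGeneric("diagnosticPositions"))

#' @export
setMethod("diagnosticPositions", "RadSimTruth", function(x) x@diagnosticPositions)

#' @rdname diagnosticLoci
#' @export
setGeneric("diagnosticAlleles", function(x) standardGeneric("diagnosticAlleles"))

#' @export
setMethod("diagnosticAlleles", "RadSimTruth", function(x) x@diagnosticAlleles)

#' @rdname diagnosticLoci
#' @export
setGeneric("locusSequences", function(x) standardGeneric("locusSequences"))

#' @export
setMethod("locusSequences", "RadSimTruth", function(x) x@locusSequences)

#' @rdname diagnosticLoci
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @export
setMethod("speciesLabels", "RadSimTruth", function(x) x@species)

#' @export
setMethod("speciesLabels", "BarcodeReference", function(x) x@species)

#' Catalog accessors
#'
#' @param x A \code{\link{RadCatalog}}.
#' @return \code{consensusSequences} returns the catalog consensuses as a
#'   \code{DNAStringSet}; \code{catalogMatches} the sample-to-catalog match
#'   table; \code{catalogPileups} the per-locus per-sample pileups;
#'   \code{stageCounts} the run-log counters.
#' @export
setGeneric("consensusSequences", function(x) standardGeneric("consensusSequences"))

#' @export
setMethod("consensusSequences", "RadCatalog", function(x) x@consensus)

#' @rdname consensusSequences
#' @export
setGeneric("catalogMatches", function(x) standardGeneric("catalogMatches"))

#' @export
setMethod("catalogMatches", "RadCatalog", function(x) x@matches)

#' @rdname consensusSequences
#' @export
setGeneric("catalogPileups", function(x) standardGeneric("catalogPileups"))

#' @export
setMethod("catalogPileups", "RadCatalog", function(x) x@pileups)

#' @rdname consensusSequences
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @export
setMethod("stageCounts", "RadCatalog", function(x) x@log)

#' Panel accessors
#'
#' @param x A \code{\link{DiagnosticPanel}}.
#' @return \code{panelPrimers} returns the primer table; \code{panelAlleles}
#'   the species x (region, position) allele table; \code{panelRegions} the
#'   region identifiers.
#' @export
setGeneric("panelPrimers", function(x) standardGeneric("panelPrimers"))

#' @export
setMethod("panelPrimers", "DiagnosticPanel", function(x) x@primers)

#' @rdname panelPrimers
#' @export
setGeneric("panelAlleles", function(x) standardGeneric("panelAlleles"))

#' @export
setMethod("panelAlleles", "DiagnosticPanel", function(x) x@alleles)

#' @rdname panelPrimers
#' @export
setGeneric("panelRegions", function(x) standardGeneric("panelRegions"))

#' @export
setMethod("panelRegions", "DiagnosticPanel", function(x) x@primers$region)
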