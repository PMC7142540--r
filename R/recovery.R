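#' Map catalog loci back to simulated true loci
#'
#' For every catalog locus, finds the nearest simulated locus (minimum
#' Hamming distance to any species' consensus). Used to score how well the
#' pipeline recovered the planted truth; not part of the discovery pipeline
#' itself.
#'
#' @param catalog A \code{\link{RadCatalog}}.
#' @param truth A \code{\link{RadSimTruth}} with loci of the same length.
#' @return A \code{data.frame}: \code{catalog_locus}, \code{true_locus}
#'   (index), \code{distance}.
#' @export
mapCatalogToTruth <- function(catalog, truth) {
  trueSeqs <- lapply(truth@locusSequences, as.character)
  nl <- nLoci(truth)
  rows <- lapply(names(catalog@consensus), function(cl) {
    cs <- as.character(catalog@consensus[[cl]])
    d <- vapply(seq_len(nl), function(li)
      min(vapply(trueSeqs, function(ts) hammingDistance(cs, ts[li]),
                 numeric(1))), numeric(1))
    data.frame(catalog_locus = cl, true_locus = which.min(d),
               distance = min(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score diagnostic-site recovery against the simulation truth
#'
#' Maps each reported diagnostic site to the simulated locus behind its
#' catalog locus and scores it as a true positive iff that locus was
#' planted diagnostic and the reported position equals the planted
#' position. Precision and recall are then computed against the planted
#' set.
#'
#' @param diagnostics The \code{data.frame} from
#'   \code{\link{diagnosticFilter}}.
#' @param catalog The \code{\link{RadCatalog}} the sites were called on.
#' @param truth The \code{\link{RadSimTruth}}.
#' @return A list: \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, and \code{found} (logical per planted locus).
#' @export
scoreRecovery <- function(diagnostics, catalog, truth) {
  plantedKey <- paste(truth@diagnosticLoci, truth@diagnosticPositions)
  found <- setNames(logical(length(plantedKey)), plantedKey)
  tp <- 0L; fp <- 0L
  if (nrow(diagnostics) > 0L) {
    m <- mapCatalogToTruth(catalog, truth)
    trueOf <- setNames(m$true_locus, m$catalog_locus)
    for (i in seq_len(nrow(diagnostics))) {
      key <- paste(trueOf[[diagnostics$locus[i]]], diagnostics$position[i])
      if (key %in% plantedKey) {
        tp <- tp + 1L
        found[key] <- TRUE
      } else {
        fp <- fp + 1L
      }
    }
  }
  fn <- sum(!found)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn),
       found = found)
}
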