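#' Call the genotype of one sample at one pileup column
#'
#' Bases with Phred quality below \code{minBaseQuality} are masked; if the
#' remaining depth is below \code{minDepth} the call is missing. Otherwise
#' the call is homozygous when the top allele's fraction reaches
#' \code{homozygoteFraction}, heterozygous when exactly two alleles each
#' reach \code{1 - homozygoteFraction}, and missing otherwise.
#'
#' @param bases Character vector of pileup bases at one position for one
#'   sample.
#' @param quals Integer Phred quality per base.
#' @param minBaseQuality Minimum base quality (default 25).
#' @param minDepth Minimum post-masking depth (default 5).
#' @param homozygoteFraction Major-allele fraction required for a
#'   homozygous call (default 0.9).
#' @return A genotype string \code{"A/A"} (homozygous), \code{"A/G"}
#'   (heterozygous, alleles sorted), or \code{NA} (missing).
#' @examples
#' callGenotype(rep("A", 10), rep(40L, 10))               # "A/A"
#' callGenotype(rep("A", 4), rep(40L, 4))                 # NA: depth < 5
#' callGenotype(rep(c("A", "G"), 6), rep(40L, 12))        # "A/G"
#' @export
callGenotype <- function(bases, quals, minBaseQuality = 25L, minDepth = 5L,
                         homozygoteFraction = 0.9) {
  keep <- quals >= minBaseQuality & bases %in% DNA_BASES4
  bases <- bases[keep]
  if (length(bases) < minDepth) return(NA_character_)
  tab <- sort(table(bases), decreasing = TRUE)
  frac <- as.numeric(tab) / length(bases)
  if (frac[1] >= homozygoteFraction) {
    top <- names(tab)[frac == frac[1]]
    b <- sort(top)[1]  # alphabetical tie-break, deterministic
    return(paste(b, b, sep = "/"))
  }
  qualifying <- names(tab)[frac >= (1 - homozygoteFraction)]
  if (length(qualifying) == 2L) {
    ab <- sort(qualifying)
    return(paste(ab[1], ab[2], sep = "/"))
  }
  NA_character_
}

#' Call SNPs on a catalog and return a genotype matrix
#'
#' Genotypes every sample at every catalog position and retains the rows
#' (catalog locus, 1-based position) at which at least two distinct alleles
#' occur among the non-missing genotypes — the segregating sites.
#'
#' @param catalog A \code{\link{RadCatalog}}.
#' @param species Optional named character vector (sample id -> species
#'   label); defaults to the labels recorded at assembly time.
#' @inheritParams callGenotype
#' @return A \code{SummarizedExperiment}: assay \code{"genotype"} (rows =
#'   segregating sites, columns = samples), \code{rowData} columns
#'   \code{locus}, \code{position}, \code{ref} (catalog consensus base),
#'   \code{colData} column \code{species}.
#' @export
callSnps <- function(catalog, species = NULL, minBaseQuality = 25L,
                     minDepth = 5L, homozygoteFraction = 0.9) {
  stopifnot(is(catalog, "RadCatalog"))
  samples <- catalog@params$samples
  if (is.null(species)) species <- catalog@params$species
  species <- setNames(unname(species[samples]), samples)

  rows <- list()
  gts <- list()
  for (cl in names(catalog@consensus)) {
    consChars <- strsplit(as.character(catalog@consensus[[cl]]), "")[[1]]
    L <- length(consChars)
    G <- matrix(NA_character_, L, length(samples),
                dimnames = list(NULL, samples))
    for (sid in intersect(samples, names(catalog@pileups[[cl]]))) {
      pu <- catalog@pileups[[cl]][[sid]]
      for (j in seq_len(L)) {
        G[j, sid] <- callGenotype(pu$bases[, j], pu$quals[, j],
                                  minBaseQuality, minDepth,
                                  homozygoteFraction)
      }
    }
    nAlleles <- apply(G, 1L, function(g) {
      length(unique(unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))))
    })
    poly <- which(nAlleles >= 2L)
    for (j in poly) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus = cl, position = j, ref = consChars[j],
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- G[j, ]
    }
  }
  rd <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), position = integer(0),
               ref = character(0))
  gmat <- if (length(gts)) do.call(rbind, gts) else
    matrix(NA_character_, 0, length(samples), dimnames = list(NULL, samples))
  rownames(gmat) <- if (nrow(rd)) paste0(rd$locus, ":", rd$position) else
    character(0)
  SummarizedExperiment(
    assays = list(genotype = gmat),
    rowData = DataFrame(rd, row.names = rownames(gmat)),
    colData = DataFrame(species = unname(species), row.names = samples))
}

#' Two-clause diagnostic SNP filter
#'
#' Applies the species-diagnostic criteria to a genotype matrix. A site
#' passes iff, within every species, (1) every non-missing genotype is
#' homozygous and the modal genotype's share among that species' samples
#' strictly exceeds \code{concordance}, and (2) the species' modal
#' (consensus) alleles are pairwise distinct across all species. Per-clause
#' exclusion counts are attached as attribute \code{"funnel"}.
#'
#' @param genotypes A \code{SummarizedExperiment} from
#'   \code{\link{callSnps}} (colData must carry a \code{species} column with
#'   no species empty).
#' @param concordance Strict lower bound on the modal-genotype share
#'   (default 0.8, i.e. "more than 80\%").
#' @param countMissing Count missing-genotype samples in the concordance
#'   denominator (default TRUE; conservative — a site genotyped in few
#'   samples of a species cannot pass on a thin majority).
#' @return A \code{data.frame} with one row per diagnostic site: columns
#'   \code{locus}, \code{position}, then one allele and one concordance
#'   column per species. Attribute \code{"funnel"}: rows in, clause-1
#'   survivors, clause-2 survivors.
#' @export
diagnosticFilter <- function(genotypes, concordance = 0.8,
                             countMissing = TRUE) {
  if (concordance <= 0 || concordance > 1)
    stop("'concordance' must lie in (0, 1]")
  sp <- colData(genotypes)$species
  if (length(unique(sp)) < 2L)
    stop("need at least two species")
  if (any(is.na(sp)) || any(table(sp) < 1L))
    stop("every sample must carry a species label")
  speciesLevels <- unique(sp)
  G <- assay(genotypes, "genotype")
  rd <- as.data.frame(rowData(genotypes))

  out <- list()
  clause1 <- 0L; clause2 <- 0L
  for (i in seq_len(nrow(G))) {
    allele <- setNames(rep(NA_character_, length(speciesLevels)), speciesLevels)
    conc <- setNames(rep(NA_real_, length(speciesLevels)), speciesLevels)
    ok1 <- TRUE
    for (s in speciesLevels) {
      g <- G[i, sp == s]
      gn <- g[!is.na(g)]
      hom <- grepl("^([ACGT])/\\1$", gn)
      if (length(gn) == 0L || !all(hom)) { ok1 <- FALSE; break }
      tab <- sort(table(gn), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) { ok1 <- FALSE; break }
      denom <- if (countMissing) length(g) else length(gn)
      share <- as.numeric(tab[1]) / denom
      if (share <= concordance) { ok1 <- FALSE; break }
      allele[s] <- substr(names(tab)[1], 1L, 1L)
      conc[s] <- share
    }
    if (!ok1) next
    clause1 <- clause1 + 1L
    if (anyDuplicated(allele)) next
    clause2 <- clause2 + 1L
    row <- data.frame(locus = rd$locus[i], position = rd$position[i],
                      stringsAsFactors = FALSE)
    for (s in speciesLevels) {
      row[[paste0("allele_", s)]] <- allele[[s]]
      row[[paste0("concordance_", s)]] <- conc[[s]]
    }
    out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else {
    proto <- data.frame(locus = character(0), position = integer(0))
    for (s in speciesLevels) {
      proto[[paste0("allele_", s)]] <- character(0)
      proto[[paste0("concordance_", s)]] <- numeric(0)
    }
    proto
  }
  attr(res, "funnel") <- c(rows_in = nrow(G), clause1_pass = clause1,
                           clause2_pass = clause2)
  res
}

## VCF 4.2 export / import ----------------------------------------------------

#' Export a genotype matrix as VCF 4.2
#'
#' Writes one record per segregating site with the catalog locus as CHROM,
#' the 1-based position within the locus as POS, the catalog consensus base
#' as REF, the other observed alleles (sorted) as ALT, per-sample GT fields,
#' and the flag \code{DIAG} in INFO on species-diagnostic rows. The output
#' is deterministic (no timestamps), so write-read-write round trips are
#' byte-identical.
#'
#' @param genotypes A \code{SummarizedExperiment} from
#'   \code{\link{callSnps}} (or \code{\link{readGenotypeVcf}}).
#' @param file Output path.
#' @param diagnostics Optional \code{data.frame} from
#'   \code{\link{diagnosticFilter}} whose (locus, position) rows get the
#'   DIAG flag; if absent, a logical \code{diag} column in \code{rowData}
#'   is used when present.
#' @return Invisibly, \code{file}.
#' @export
exportVcf <- function(genotypes, file, diagnostics = NULL) {
  G <- assay(genotypes, "genotype")
  if (nrow(G) == 0L) stop("genotype matrix is empty")
  rd <- as.data.frame(rowData(genotypes))
  diag <- if (!is.null(diagnostics)) {
    paste0(rd$locus, ":", rd$position) %in%
      paste0(diagnostics$locus, ":", diagnostics$position)
  } else if (!is.null(rd$diag)) rd$diag else rep(FALSE, nrow(rd))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coddiag",
    "##INFO=<ID=DIAG,Number=0,Type=Flag,Description=\"Species-diagnostic site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(G)), collapse = "\t"))
  body <- vapply(seq_len(nrow(G)), function(i) {
    g <- G[i, ]
    obs <- unique(unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE)))
    ref <- rd$ref[i]
    alt <- sort(setdiff(obs, ref))
    alleles <- c(ref, alt)
    gt <- vapply(g, function(cell) {
      if (is.na(cell)) return("./.")
      ab <- match(strsplit(cell, "/", fixed = TRUE)[[1]], alleles) - 1L
      paste(ab, collapse = "/")
    }, character(1))
    paste(c(rd$locus[i], rd$position[i], ".", ref,
            if (length(alt)) paste(alt, collapse = ",") else ".",
            ".", ".", if (diag[i]) "DIAG" else ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a coddiag VCF back into a genotype matrix
#'
#' Parses a VCF written by \code{\link{exportVcf}} and reconstructs the
#' genotype \code{SummarizedExperiment}, including the DIAG flag (as a
#' logical \code{diag} column in \code{rowData}). Species labels are not
#' stored in VCF and come back as \code{NA}.
#'
#' @param file Path to a VCF file.
#' @return A \code{SummarizedExperiment}.
#' @export
readGenotypeVcf <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  rd <- list(); gts <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    alleles <- c(f[4], if (f[5] != ".") strsplit(f[5], ",", fixed = TRUE)[[1]])
    gt <- vapply(f[-(1:9)], function(cell) {
      if (cell == "./.") return(NA_character_)
      idx <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]]) + 1L
      paste(alleles[idx], collapse = "/")
    }, character(1))
    rd[[length(rd) + 1L]] <- data.frame(
      locus = f[1], position = as.integer(f[2]), ref = f[4],
      diag = grepl("(^|;)DIAG(;|$)", f[8]), stringsAsFactors = FALSE)
    gts[[length(gts) + 1L]] <- gt
  }
  rdf <- do.call(rbind, rd)
  gmat <- do.call(rbind, gts)
  dimnames(gmat) <- list(paste0(rdf$locus, ":", rdf$position), samples)
  SummarizedExperiment(
    assays = list(genotype = gmat),
    rowData = DataFrame(rdf, row.names = rownames(gmat)),
    colData = DataFrame(species = rep(NA_character_, length(samples)),
                        row.names = samples))
}

#' Write the diagnostic-site table as TSV
#'
#' @param diagnostics Result of \code{\link{diagnosticFilter}}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
writeDiagnostics <- function(diagnostics, file) {
  write.table(diagnostics, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
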