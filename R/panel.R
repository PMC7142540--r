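#' The built-in cod species-identification panel
#'
#' Returns the published five-SNP / two-amplicon marker panel that
#' distinguishes \emph{Gadus morhua}, \emph{Reinhardtius hippoglossoides}
#' and \emph{Dissostichus eleginoides}. Region 12014 (291-bp amplicon,
#' annealing 64 degC) carries SNPs at amplicon positions 82, 112 and 220;
#' region 42229 (193 bp, 63 degC) at positions 127 and 163. At every
#' position the three species carry pairwise-distinct alleles, so any
#' single genotyped position already separates all three.
#'
#' @return A validated \code{\link{DiagnosticPanel}}.
#' @examples
#' codPanel()
#' @export
codPanel <- function() {
  primers <- data.frame(
    region = c("12014", "42229"),
    forward = c("CAGATACCCTCGAATA", "ATTCGGGCAGAACTAAGCCAACCTG"),
    reverse = c("CAAACAAATAGAGGGGTTTGGTA", "CTCATGTTATTTATTCGAGGGAAAGC"),
    annealing_temp = c(64, 63),
    product_size = c(291L, 193L),
    stringsAsFactors = FALSE)
  sp <- c("G. morhua", "R. hippoglossoides", "D. eleginoides")
  alleles <- rbind(
    data.frame(region = "12014", position = 82L, species = sp,
               allele = c("G", "T", "A")),
    data.frame(region = "12014", position = 112L, species = sp,
               allele = c("T", "A", "G")),
    data.frame(region = "12014", position = 220L, species = sp,
               allele = c("A", "G", "T")),
    data.frame(region = "42229", position = 127L, species = sp,
               allele = c("G", "A", "T")),
    data.frame(region = "42229", position = 163L, species = sp,
               allele = c("A", "C", "G")))
  new("DiagnosticPanel", primers = primers, alleles = alleles)
}

#' Read a panel from a TSV file
#'
#' Expects columns \code{region}, \code{primer_f}, \code{primer_r},
#' \code{annealing_temp}, \code{product_size}, \code{position},
#' \code{species}, \code{allele} (primer metadata repeated per allele row).
#'
#' @param file Path to a TSV file.
#' @return A validated \code{\link{DiagnosticPanel}}.
#' @export
readPanel <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  primers <- unique(tab[, c("region", "primer_f", "primer_r",
                            "annealing_temp", "product_size")])
  names(primers) <- c("region", "forward", "reverse", "annealing_temp",
                      "product_size")
  primers$annealing_temp <- as.numeric(primers$annealing_temp)
  primers$product_size <- as.integer(primers$product_size)
  alleles <- tab[, c("region", "position", "species", "allele")]
  alleles$position <- as.integer(alleles$position)
  new("DiagnosticPanel", primers = primers, alleles = alleles)
}

#' Write a panel to TSV
#'
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
writePanel <- function(panel, file) {
  tab <- merge(panel@alleles, panel@primers, by = "region")
  tab <- tab[order(tab$region, tab$position, tab$species),
             c("region", "forward", "reverse", "annealing_temp",
               "product_size", "position", "species", "allele")]
  names(tab)[2:3] <- c("primer_f", "primer_r")
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Extract the flanking window around a SNP position
#'
#' Returns up to \code{flank} bases on each side of the focal position,
#' truncated at the sequence ends, together with the focal position's
#' 1-based offset within the window.
#'
#' @param reference A DNA string.
#' @param position 1-based focal position within \code{reference}.
#' @param flank Number of bases requested on each side (>= 1).
#' @return A list: \code{sequence}, \code{focalOffset}, \code{start},
#'   \code{end} (window coordinates on the reference).
#' @export
extractFlanks <- function(reference, position, flank) {
  reference <- as.character(reference)
  position <- as.integer(position)
  L <- nchar(reference)
  if (position < 1L || position > L)
    stop(sprintf("position %d out of range 1..%d", position, L))
  stopifnot(flank >= 1L)
  start <- max(1L, position - as.integer(flank))
  end <- min(L, position + as.integer(flank))
  list(sequence = substr(reference, start, end),
       focalOffset = position - start + 1L,
       start = start, end = end)
}

#' In-silico PCR
#'
#' Finds the forward primer on the forward strand and the reverse primer's
#' reverse complement downstream of it, each with at most
#' \code{maxMismatch} mismatches, and returns every valid product. The
#' amplicon spans the forward-primer start through the end of the
#' reverse-primer site, inclusive (both primer sequences are part of the
#' product, as in real PCR). No product is a result, not an error.
#'
#' @param template A DNA string.
#' @param forward,reverse Primer sequences (5'->3', ACGT).
#' @param maxMismatch Mismatches tolerated per primer site (default 0).
#' @return A \code{data.frame} with columns \code{start}, \code{end},
#'   \code{length}, \code{sequence}; zero rows if no product.
#' @export
inSilicoPcr <- function(template, forward, reverse, maxMismatch = 0L) {
  template <- as.character(template)
  if (nchar(template) == 0L) stop("'template' must be non-empty")
  subj <- Biostrings::DNAString(template)
  fHits <- Biostrings::matchPattern(forward, subj, max.mismatch = maxMismatch)
  rcHits <- Biostrings::matchPattern(reverseComplement1(reverse), subj,
                                     max.mismatch = maxMismatch)
  out <- list()
  for (fs in Biostrings::start(fHits)) {
    fe <- fs + nchar(forward) - 1L
    for (k in seq_along(rcHits)) {
      rs <- Biostrings::start(rcHits)[k]
      re <- Biostrings::end(rcHits)[k]
      if (rs > fe) {
        out[[length(out) + 1L]] <- data.frame(
          start = fs, end = re, length = re - fs + 1L,
          sequence = substr(template, fs, re), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Run in-silico PCR with a panel region's primer pair
#'
#' @param template A DNA string.
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @param region Region identifier in the panel.
#' @inheritParams inSilicoPcr
#' @return As \code{\link{inSilicoPcr}}.
#' @export
amplifyRegion <- function(template, panel, region, maxMismatch = 0L) {
  pr <- panel@primers[panel@primers$region == region, ]
  if (nrow(pr) != 1L) stop(sprintf("unknown region '%s'", region))
  inSilicoPcr(template, pr$forward, pr$reverse, maxMismatch)
}

#' Read panel alleles off an amplicon
#'
#' Reads the base at each of the region's 1-based panel positions. An N, or
#' a position beyond the amplicon's end, yields a missing observation.
#'
#' @param amplicon The amplicon sequence (character or \code{DNAString}).
#' @param region Region identifier.
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @return Named character vector of observed alleles (names are
#'   positions); \code{NA} where unreadable.
#' @export
genotypeAmplicon <- function(amplicon, region, panel) {
  if (!region %in% panel@primers$region)
    stop(sprintf("unknown region '%s'", region))
  amplicon <- as.character(amplicon)
  positions <- sort(unique(panel@alleles$position[panel@alleles$region == region]))
  obs <- vapply(positions, function(p) {
    if (p > nchar(amplicon) || p < 1L) return(NA_character_)
    b <- substr(amplicon, p, p)
    if (b %in% DNA_BASES4) b else NA_character_
  }, character(1))
  setNames(obs, positions)
}

#' Assign a species from observed panel alleles
#'
#' A species matches iff every non-missing observed allele equals its panel
#' entry. Exactly one matching species yields a call; zero or several yield
#' a no-call, with per-species counts of agreeing positions reported either
#' way.
#'
#' @param observed A \code{data.frame} with columns \code{region},
#'   \code{position}, \code{allele} (\code{NA} allele = missing).
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @return A list: \code{species} (label or \code{NA}), \code{status}
#'   (\code{"call"} or \code{"no_call"}), \code{nMatching} (named integer
#'   per species), \code{nScored} (non-missing positions used).
#' @export
assignSpeciesFromPanel <- function(observed, panel) {
  obs <- observed[!is.na(observed$allele), , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("need at least one non-missing observed allele")
  al <- panel@alleles
  speciesLevels <- unique(al$species)
  nMatch <- setNames(integer(length(speciesLevels)), speciesLevels)
  full <- setNames(logical(length(speciesLevels)), speciesLevels)
  for (s in speciesLevels) {
    exp_s <- al[al$species == s, ]
    key <- paste(exp_s$region, exp_s$position)
    expAllele <- setNames(exp_s$allele, key)
    got <- expAllele[paste(obs$region, obs$position)]
    nMatch[s] <- sum(got == obs$allele, na.rm = TRUE)
    full[s] <- all(!is.na(got)) && all(got == obs$allele)
  }
  if (sum(full) == 1L) {
    list(species = names(full)[full], status = "call",
         nMatching = nMatch, nScored = nrow(obs))
  } else {
    list(species = NA_character_, status = "no_call",
         nMatching = nMatch, nScored = nrow(obs))
  }
}

#' Genotype and assign a set of template sequences
#'
#' For each template, amplifies every panel region in silico, reads the
#' panel positions off the (first) product, and assigns a species from the
#' pooled observations. Templates amplifying no region are reported as
#' no-calls with zero scored positions.
#'
#' @param templates Named \code{DNAStringSet} or character vector.
#' @param panel A \code{\link{DiagnosticPanel}} (default
#'   \code{\link{codPanel}()}).
#' @param maxMismatch Primer-site mismatches tolerated.
#' @return A \code{data.frame}: \code{sample_id}, \code{region} summary
#'   columns (observed alleles per region, \code{-} where absent),
#'   \code{n_scored}, \code{species}, \code{status}.
#' @export
panelCall <- function(templates, panel = codPanel(), maxMismatch = 0L) {
  templates <- asNamedCharacter(templates)
  if (is.null(names(templates)))
    names(templates) <- sprintf("template%02d", seq_along(templates))
  rows <- lapply(names(templates), function(sid) {
    obs <- data.frame(region = character(0), position = integer(0),
                      allele = character(0))
    regionStr <- setNames(rep("-", nrow(panel@primers)), panel@primers$region)
    for (r in panel@primers$region) {
      prod <- amplifyRegion(templates[[sid]], panel, r, maxMismatch)
      if (nrow(prod) == 0L) next
      alleles <- genotypeAmplicon(prod$sequence[1], r, panel)
      obs <- rbind(obs, data.frame(region = r,
                                   position = as.integer(names(alleles)),
                                   allele = unname(alleles)))
      regionStr[r] <- paste(ifelse(is.na(alleles), ".", alleles),
                            collapse = "")
    }
    if (nrow(obs[!is.na(obs$allele), ]) == 0L) {
      call <- list(species = NA_character_, status = "no_call", nScored = 0L)
    } else {
      call <- assignSpeciesFromPanel(obs, panel)
    }
    df <- data.frame(sample_id = sid, stringsAsFactors = FALSE)
    for (r in names(regionStr)) df[[paste0("alleles_", r)]] <- regionStr[[r]]
    df$n_scored <- call$nScored
    df$species <- call$species
    df$status <- call$status
    df
  })
  do.call(rbind, rows)
}

#' Synthetic demonstration amplicons for the built-in panel
#'
#' The study's true genomic amplicon sequences are not published; these
#' synthetic stand-ins embed each region's primer pair at the amplicon ends
#' and each species' panel alleles at the panel positions, over a shared
#' random filler, at the published product sizes. Comparing the three
#' species' amplicons column-wise therefore segregates exactly at the panel
#' positions.
#'
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @param seed Integer seed for the shared filler.
#' @return Named list (by region) of \code{DNAStringSet}s, one sequence per
#'   species.
#' @export
syntheticAmplicons <- function(panel = codPanel(), seed = 101L) {
  withSeed(seed, {
    speciesLevels <- unique(panel@alleles$species)
    out <- list()
    for (ri in seq_len(nrow(panel@primers))) {
      pr <- panel@primers[ri, ]
      size <- pr$product_size
      rcR <- reverseComplement1(pr$reverse)
      fillerLen <- size - nchar(pr$forward) - nchar(rcR)
      stopifnot(fillerLen >= 0L)
      base <- paste0(pr$forward, randomDna(fillerLen), rcR)
      al <- panel@alleles[panel@alleles$region == pr$region, ]
      seqs <- vapply(speciesLevels, function(s) {
        x <- base
        for (k in which(al$species == s)) {
          p <- al$position[k]
          substr(x, p, p) <- al$allele[k]
        }
        x
      }, character(1))
      out[[pr$region]] <- Biostrings::DNAStringSet(setNames(seqs, speciesLevels))
    }
    out
  })
}

#' Synthetic demonstration templates
#'
#' Builds eight synthetic template sequences: two per species embedding both
#' regions' synthetic amplicons in random genomic flanks, plus two
#' non-target templates carrying no primer sites (stand-ins for the
#' negative-control species \emph{E. coioides} and
#' \emph{B. pectinirostris}, whose sequences are not published).
#'
#' @param panel A \code{\link{DiagnosticPanel}}.
#' @param seed Integer seed.
#' @return A named \code{DNAStringSet} of 8 templates.
#' @export
demoTemplates <- function(panel = codPanel(), seed = 101L) {
  amps <- syntheticAmplicons(panel, seed)
  withSeed(seed + 1L, {
    speciesLevels <- unique(panel@alleles$species)
    out <- character(0)
    for (s in speciesLevels) {
      for (rep_i in 1:2) {
        tpl <- paste0(randomDna(40 + 7 * rep_i),
                      as.character(amps[[1]][[s]]),
                      randomDna(30),
                      as.character(amps[[2]][[s]]),
                      randomDna(40))
        out[sprintf("%s_%d", gsub("[. ]+", "_", s), rep_i)] <- tpl
      }
    }
    for (neg in c("E_coioides_neg", "B_pectinirostris_neg")) {
      repeat {  # reject fillers that contain a primer site by chance
        tpl <- randomDna(600)
        hit <- any(vapply(seq_len(nrow(panel@primers)), function(ri)
          nrow(amplifyRegion(tpl, panel, panel@primers$region[ri])) > 0,
          logical(1)))
        if (!hit) break
      }
      out[neg] <- tpl
    }
    Biostrings::DNAStringSet(out)
  })
}

#' Count segregating columns among equal-length sequences
#'
#' @param seqs Character vector or \code{DNAStringSet} of equal-length
#'   sequences.
#' @return Number of columns at which more than one base occurs.
#' @export
countSegregatingSites <- function(seqs) {
  m <- seqsToMatrix(as.character(seqs))
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}
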