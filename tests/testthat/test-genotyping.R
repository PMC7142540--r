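test_that("single-column genotype calls respect quality, depth and allele-fraction rules", {
  expect_identical(callGenotype(rep("A", 10), rep(40L, 10)), "A/A")
  ## depth boundary: 4 < 5 is missing
  expect_identical(callGenotype(rep("A", 4), rep(40L, 4)), NA_character_)
  ## balanced alleles: heterozygous, sorted
  expect_identical(callGenotype(rep(c("G", "A"), 6), rep(40L, 12)), "A/G")
  ## quality masking can push a column below the depth threshold
  expect_identical(callGenotype(rep("A", 10), rep(20L, 10)), NA_character_)
  expect_identical(callGenotype(c(rep("A", 6), rep("C", 6)),
                                c(rep(40L, 6), rep(10L, 6))), "A/A")
  ## three mid-frequency alleles: no confident call
  expect_identical(callGenotype(rep(c("A", "C", "G"), 4), rep(40L, 12)),
                   NA_character_)
  ## Ns never contribute
  expect_identical(callGenotype(c(rep("A", 5), rep("N", 5)),
                                rep(40L, 10)), "A/A")
})

simSmall <- function() {
  truth <- simulateLocusSet(12, nDiagnostic = 3, divergence = 0, seed = 41)
  reads <- simulateReads(truth, nSamples = c(2, 2, 2), depth = 15,
                         errorRate = 0, seed = 42)
  list(truth = truth, catalog = assembleSamples(reads))
}

test_that("SNP calling emits exactly the planted segregating sites on noiseless data", {
  ss <- simSmall()
  gt <- callSnps(ss$catalog)
  expect_identical(nrow(gt), 3L)
  sc <- scoreRecovery(diagnosticFilter(gt), ss$catalog, ss$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)

  ## per-row allele sets equal a direct pileup tally oracle
  pu <- catalogPileups(ss$catalog)
  rd <- as.data.frame(SummarizedExperiment::rowData(gt))
  for (i in seq_len(nrow(gt))) {
    tallied <- sort(unique(unlist(lapply(pu[[rd$locus[i]]], function(p) {
      keep <- p$quals[, rd$position[i]] >= 25
      unique(p$bases[keep, rd$position[i]])
    }))))
    called <- sort(unique(unlist(strsplit(
      stats::na.omit(SummarizedExperiment::assay(gt)[i, ]), "/"))))
    expect_identical(called, tallied)
  }
})

test_that("monomorphic input yields an empty genotype matrix", {
  truth <- simulateLocusSet(6, nDiagnostic = 0, divergence = 0, seed = 43)
  reads <- simulateReads(truth, nSamples = c(1, 1, 1), depth = 15,
                         errorRate = 0, seed = 44)
  gt <- callSnps(assembleSamples(reads))
  expect_identical(nrow(gt), 0L)
})

test_that("the diagnostic filter enforces both clauses with a strict concordance bound", {
  mkSe <- function(cells, species) {
    G <- do.call(rbind, cells)
    colnames(G) <- sprintf("s%02d", seq_len(ncol(G)))
    rownames(G) <- sprintf("CL%04d:%d", seq_len(nrow(G)), seq_len(nrow(G)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(genotype = G),
      rowData = S4Vectors::DataFrame(
        locus = sprintf("CL%04d", seq_len(nrow(G))),
        position = seq_len(nrow(G)),
        ref = rep("A", nrow(G)), row.names = rownames(G)),
      colData = S4Vectors::DataFrame(species = species,
                                     row.names = colnames(G)))
  }
  sp <- rep(c("m", "h", "e"), each = 5)
  fixedRow <- c(rep("G/G", 5), rep("T/T", 5), rep("A/A", 5))

  ## fixed distinct alleles pass with the expected consensus
  d1 <- diagnosticFilter(mkSe(list(fixedRow), sp))
  expect_identical(nrow(d1), 1L)
  expect_identical(c(d1$allele_m, d1$allele_h, d1$allele_e),
                   c("G", "T", "A"))
  expect_identical(unname(attr(d1, "funnel")),
                   c(1L, 1L, 1L))

  ## 4/5 = 80% concordance fails the strict "more than 80%" clause
  row80 <- fixedRow; row80[5] <- NA
  d2 <- diagnosticFilter(mkSe(list(row80), sp))
  expect_identical(nrow(d2), 0L)
  expect_identical(unname(attr(d2, "funnel")[["clause1_pass"]]), 0L)
  ## but it passes when missing samples leave the denominator
  d2b <- diagnosticFilter(mkSe(list(row80), sp), countMissing = FALSE)
  expect_identical(nrow(d2b), 1L)

  ## a heterozygous sample fails clause 1
  rowHet <- fixedRow; rowHet[1] <- "A/G"
  expect_identical(nrow(diagnosticFilter(mkSe(list(rowHet), sp))), 0L)

  ## shared consensus allele between two species fails clause 2
  rowShared <- c(rep("G/G", 5), rep("G/G", 5), rep("A/A", 5))
  d3 <- diagnosticFilter(mkSe(list(rowShared), sp))
  expect_identical(nrow(d3), 0L)
  expect_identical(unname(attr(d3, "funnel")),
                   c(1L, 1L, 0L))

  ## fewer than two species is an error
  expect_error(diagnosticFilter(mkSe(list(fixedRow), rep("m", 15))),
               "two species")
})

test_that("VCF export writes one record per site and round-trips byte-identically", {
  ss <- simSmall()
  gt <- callSnps(ss$catalog)
  dg <- diagnosticFilter(gt)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  exportVcf(gt, f1, diagnostics = dg)
  lines <- readLines(f1)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nrow(gt))

  back <- readGenotypeVcf(f1)
  exportVcf(back, f2)
  expect_identical(readLines(f2), lines)

  ## GT entries equal the matrix cells under the documented encoding
  expect_identical(unname(SummarizedExperiment::assay(back)),
                   unname(SummarizedExperiment::assay(gt)))
  expect_identical(SummarizedExperiment::rowData(back)$diag,
                   rep(TRUE, nrow(gt)))  # all segregating rows are planted here

  ## an established VCF reader parses the same genotypes
  vcf <- VariantAnnotation::readVcf(f1)
  gtv <- VariantAnnotation::geno(vcf)$GT
  alleleList <- lapply(seq_len(nrow(gtv)), function(i)
    c(as.character(VariantAnnotation::ref(vcf))[i],
      as.character(VariantAnnotation::alt(vcf)[[i]])))
  decode <- function(code, i) {
    if (code %in% c("./.", ".")) return(NA_character_)
    idx <- as.integer(strsplit(code, "/")[[1]]) + 1L
    paste(alleleList[[i]][idx], collapse = "/")
  }
  for (i in seq_len(nrow(gtv)))
    for (j in seq_len(ncol(gtv)))
      expect_identical(decode(gtv[i, j], i),
                       unname(SummarizedExperiment::assay(gt)[i, j]))
})

test_that("raising thresholds never increases call or diagnostic counts", {
  truth <- simulateLocusSet(15, nDiagnostic = 3, divergence = 0.005, seed = 45)
  reads <- simulateReads(truth, nSamples = c(2, 2, 2), depth = 10,
                         errorRate = 0.005, qualityMean = 35, qualitySd = 4,
                         seed = 46)
  catalog <- assembleSamples(reads)

  nCalls <- function(minBQ, minDepth) {
    sum(vapply(catalogPileups(catalog), function(bySample)
      sum(vapply(bySample, function(p)
        sum(vapply(seq_len(ncol(p$bases)), function(j)
          !is.na(callGenotype(p$bases[, j], p$quals[, j],
                              minBaseQuality = minBQ, minDepth = minDepth)),
          logical(1))), numeric(1))), numeric(1)))
  }
  expect_true(nCalls(25, 5) >= nCalls(30, 5))
  expect_true(nCalls(25, 5) >= nCalls(25, 8))
  expect_true(nCalls(30, 8) <= nCalls(25, 5))

  gt <- callSnps(catalog)
  ## depth-floor increases can only silence calls, never add alleles
  gtStrict <- callSnps(catalog, minDepth = 8L)
  expect_true(nrow(gtStrict) <= nrow(gt))
  nd <- function(se, conc) nrow(diagnosticFilter(se, concordance = conc))
  expect_true(nd(gt, 0.9) <= nd(gt, 0.8))
  expect_true(nd(gt, 0.99) <= nd(gt, 0.9))
})

test_that("diagnostic output is invariant to sample permutation", {
  truth <- simulateLocusSet(10, nDiagnostic = 2, divergence = 0.005, seed = 47)
  reads <- simulateReads(truth, nSamples = c(2, 2, 2), depth = 15,
                         errorRate = 0.001, seed = 48)
  d1 <- diagnosticFilter(callSnps(assembleSamples(reads)))
  set.seed(49)
  perm <- sample(length(reads))
  d2 <- diagnosticFilter(callSnps(assembleSamples(reads[perm])))
  key <- function(d) {
    cols <- sort(grep("^allele_", names(d), value = TRUE))
    do.call(paste, c(d[order(d$locus, d$position),
                       c("locus", "position", cols)], sep = ":"))
  }
  expect_identical(key(d1), key(d2))
})
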