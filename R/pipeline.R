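#' Default run configuration
#'
#' All thresholds default to the published study's stated values: stack
#' depth m = 2, within-sample mismatch M = 2, catalog mismatch n = 3, base
#' quality >= 25, depth >= 5, species concordance > 0.8, barcode identity
#' >= 98. The simulation block defaults to the study's sample design
#' (6/12/10 samples for the three species, 100-bp tags).
#'
#' @return A nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = NULL,  # mandatory, must be supplied
    out_dir = NULL,
    simulate = list(
      n_loci = 50L,
      locus_length = 100L,
      n_diagnostic = 5L,
      divergence = 0.005,
      n_samples = c(6L, 12L, 10L),
      species = c("G_morhua", "R_hippoglossoides", "D_eleginoides"),
      depth = 20,
      error_rate = 0.001,
      quality_mean = 38,
      quality_sd = 3
    ),
    fastq_dir = NULL,
    labels = NULL,
    assembly = list(m = 2L, M = 2L, n = 3L, rc_aware = FALSE),
    snp = list(min_base_quality = 25L, min_depth = 5L,
               homozygote_fraction = 0.9, concordance = 0.8,
               count_missing = TRUE),
    barcode = list(min_identity = 98)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unspecified keys take the defaults of \code{\link{defaultRunConfig}};
#' the seed is mandatory (reproducibility is not optional).
#'
#' @param file Path to a YAML file, or a configuration list.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  merged <- modifyList(defaultRunConfig(), cfg)
  validateRunConfig(merged)
  merged
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed))
    stop("config must specify an integer 'seed'")
  a <- cfg$assembly; s <- cfg$snp
  if (a$m < 1L) stop("assembly$m must be >= 1")
  if (a$M < 0L || a$n < 0L) stop("assembly$M and assembly$n must be >= 0")
  if (s$min_depth < 1L) stop("snp$min_depth must be >= 1")
  if (s$min_base_quality < 0L) stop("snp$min_base_quality must be >= 0")
  if (s$concordance <= 0 || s$concordance > 1)
    stop("snp$concordance must lie in (0, 1]")
  if (s$homozygote_fraction <= 0 || s$homozygote_fraction > 1)
    stop("snp$homozygote_fraction must lie in (0, 1]")
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (sim$n_diagnostic > sim$n_loci)
      stop("simulate$n_diagnostic must not exceed simulate$n_loci")
    if (sim$error_rate < 0 || sim$error_rate >= 0.5)
      stop("simulate$error_rate must lie in [0, 0.5)")
  }
  invisible(TRUE)
}

#' Run the discovery pipeline end to end
#'
#' Simulate (or load) per-sample RAD reads, quality-filter, assemble into a
#' cross-sample catalog, call SNPs, apply the diagnostic filter, and write
#' all stage outputs plus a funnel log of stage counts. Re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param config A configuration list or YAML path (see
#'   \code{\link{readRunConfig}}).
#' @param outDir Output directory; overrides \code{config$out_dir}. If
#'   neither is given, nothing is written and results are only returned.
#' @return Invisibly, a list: \code{truth} (a \code{\link{RadSimTruth}} or
#'   \code{NULL} for real reads), \code{catalog}, \code{genotypes},
#'   \code{diagnostics}, \code{funnel} (named counts), \code{dir}.
#' @export
runDiscovery <- function(config, outDir = NULL) {
  cfg <- readRunConfig(config)
  if (is.null(outDir)) outDir <- cfg$out_dir

  truth <- NULL
  if (!is.null(cfg$fastq_dir)) {
    if (!dir.exists(cfg$fastq_dir))
      stop(sprintf("fastq_dir '%s' does not exist", cfg$fastq_dir))
    if (is.null(cfg$labels) || !file.exists(cfg$labels))
      stop("a sample->species labels TSV is required with fastq_dir")
    lab <- read.table(cfg$labels, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    speciesOf <- setNames(lab$species, lab$sample)
    readsList <- readRadFastq(cfg$fastq_dir, species = speciesOf)
    for (sid in names(readsList))
      readsList[[sid]]@species <- unname(speciesOf[sid])
  } else {
    sim <- cfg$simulate
    truth <- simulateLocusSet(
      nLoci = sim$n_loci, locusLength = sim$locus_length,
      nSpecies = length(sim$species), nDiagnostic = sim$n_diagnostic,
      divergence = sim$divergence, seed = cfg$seed, species = sim$species)
    readsList <- simulateReads(
      truth, nSamples = sim$n_samples, depth = sim$depth,
      errorRate = sim$error_rate, qualityMean = sim$quality_mean,
      qualitySd = sim$quality_sd, seed = cfg$seed + 1L)
  }

  catalog <- assembleSamples(readsList,
                             m = cfg$assembly$m, M = cfg$assembly$M,
                             n = cfg$assembly$n,
                             rcAware = isTRUE(cfg$assembly$rc_aware))
  genotypes <- callSnps(catalog,
                        minBaseQuality = cfg$snp$min_base_quality,
                        minDepth = cfg$snp$min_depth,
                        homozygoteFraction = cfg$snp$homozygote_fraction)
  diagnostics <- diagnosticFilter(genotypes,
                                  concordance = cfg$snp$concordance,
                                  countMissing = isTRUE(cfg$snp$count_missing))
  dfunnel <- attr(diagnostics, "funnel")
  funnel <- c(stageCounts(catalog),
              snp_rows = unname(dfunnel["rows_in"]),
              clause1_pass = unname(dfunnel["clause1_pass"]),
              diagnostic_sites = unname(dfunnel["clause2_pass"]))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCatalog(catalog, outDir)
    if (nrow(genotypes) > 0L)
      exportVcf(genotypes, file.path(outDir, "genotypes.vcf"),
                diagnostics = diagnostics)
    writeDiagnostics(diagnostics, file.path(outDir, "diagnostics.tsv"))
    write.table(data.frame(stage = names(funnel), count = unname(funnel)),
                file.path(outDir, "funnel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
    if (!is.null(truth)) writeSimTruth(truth, outDir)
  }
  invisible(list(truth = truth, catalog = catalog, genotypes = genotypes,
                 diagnostics = diagnostics, funnel = funnel, dir = outDir))
}

#' Run the packaged panel demonstration
#'
#' Genotypes the packaged synthetic demonstration templates (two per
#' species plus two non-target negative controls) against the built-in
#' panel: six correct species calls and two no-calls are expected.
#'
#' @param outDir Optional directory for a \code{demo_calls.tsv}.
#' @param seed Seed for the synthetic templates (default 101).
#' @return The \code{\link{panelCall}} \code{data.frame} (8 rows).
#' @export
runDemo <- function(outDir = NULL, seed = 101L) {
  calls <- panelCall(demoTemplates(seed = seed))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(calls, file.path(outDir, "demo_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  calls
}
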