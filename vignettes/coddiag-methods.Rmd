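---
title: "Methods: diagnostic SNP discovery and species assignment for cod products"
author: "coddiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic SNP discovery and species assignment for cod products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coddiag)
```

# The problem

High-value "cod" products (sold in China under the umbrella name *Xue Yu*)
mix at least three biologically distant species: Atlantic cod (*Gadus
morhua*), Greenland turbot (*Reinhardtius hippoglossoides*) and Patagonian
toothfish (*Dissostichus eleginoides*). Morphology is useless on fillets and
steaks, and protein markers do not survive cooking, so authentication rests
on DNA. `coddiag` implements the two genetic routes that together support
such authentication:

1. **COI barcoding** — assign a query sequence to a species by best-hit
   percent identity against a reference barcode set, accepting the
   assignment at ≥ 98% identity, and confirm that the sequences group by
   species on a distance tree.
2. **RAD-seq diagnostic SNPs** — without any reference genome, assemble
   restriction-site-anchored reads into per-sample loci and a cross-sample
   catalog, call genotypes, and retain the sites at which every species is
   *fixed* for a *different* allele. Such sites identify a species from a
   single genotype, and a small panel of them (here: five SNPs on two PCR
   amplicons) makes a practical assay.

A seeded simulator generates ground-truthed inputs for every stage, so the
entire pipeline is testable offline, with recovery scored against a known
planted truth.

# The discovery model

## Locus assembly

RAD reads are fixed-length tags anchored at TaqI (`TCGA`) restriction
sites, so homologous tags align without gaps and Hamming distance is the
natural metric (gapped alignment is deliberately out of scope). Assembly
proceeds in the classic stack/catalog stages:

* **Stacking** (`buildStacks`): reads of one sample are grouped by exact
  sequence identity; groups with depth ≥ `m` (default 2) become primary
  stacks, the rest form a secondary pool.
* **Merging** (`mergeStacks`): primary stacks within Hamming distance `M`
  (default 2) are merged by single-linkage into loci. Each secondary read
  is then placed on the *unique* nearest locus within `M`; ties or no
  locus in range discard the read — we prefer losing a read to assigning
  it arbitrarily. The locus consensus is the per-position modal base over
  all assigned reads.
* **Catalog** (`buildCatalog`): sample-locus consensuses from all samples
  are single-linkage merged at Hamming distance `n` (default 3). This is
  the step that brings homologous loci of *different species* into one
  catalog entry; `n` therefore bounds the interspecific divergence a
  usable marker locus may show. The catalog consensus is the
  depth-weighted modal base per position — note it is a majority
  consensus across species and may match no single species exactly at
  polymorphic columns.
* **Matching** (`matchSamples`): every sample locus is placed on the
  nearest unique catalog locus within `n`, carrying its read pileup into
  catalog coordinates.

Single linkage is a deliberate, simple interpretation of the merge
parameters: it is deterministic, has an obvious brute-force oracle
(connected components of the thresholded distance graph, verified in the
tests with an independent igraph implementation), and matches the
fixed-length, anchored-tag setting. It is not a re-implementation of any
particular assembler's likelihood model.

Determinism is enforced everywhere by explicit tie-breaking: stacks and
loci are ordered by (depth descending, sequence lexicographic), modal-base
ties resolve alphabetically, and equidistant assignments are refused
rather than broken arbitrarily. Re-running a configuration reproduces
byte-identical outputs.

## Genotype calling

At each catalog position, each sample's pileup column is reduced to a
genotype (`callGenotype`):

* bases with Phred quality < 25 are masked;
* columns with post-masking depth < 5 are missing;
* the call is homozygous if the top allele's fraction is ≥ 0.9,
  heterozygous if exactly two alleles each reach 0.1, missing otherwise.

The quality and depth floors (25 and 5) are the published retention
thresholds of the assay this package re-implements; the allele-fraction
rule fills a gap (no heterozygote model was published) with the simplest
depth-robust choice, and 0.9 is exposed as `homozygoteFraction`. A site
enters the genotype matrix (a `SummarizedExperiment`) only if at least two
distinct alleles are observed across samples.

One subtlety worth documenting: with a fraction-based rule, the number of
*called genotypes* is monotone non-increasing in the depth floor (masking
can only silence calls), but raising the *base-quality* floor can
re-weight allele fractions and, in contrived pileups, surface a minor
allele that a lower threshold absorbed. The monotonicity property we test
is therefore the one that is actually guaranteed: calls versus depth floor
and diagnostic sites versus concordance; quality-floor monotonicity is
verified empirically under the simulator's quality model.

## The diagnostic filter

A segregating site is species-diagnostic (`diagnosticFilter`) iff:

1. **within every species**: all non-missing genotypes are homozygous and
   the modal genotype's share *strictly exceeds* 80% of the species'
   samples ("more than 80%" is read literally: 4/5 = 80% fails);
2. **across species**: the species' modal alleles are pairwise distinct.

Missing genotypes count in the concordance denominator by default
(`countMissing = TRUE`): a locus genotyped in only a thin majority of a
species' samples should not pass on that majority alone. Whether the
original assay counted missing samples is not stated anywhere we could
check, so the complementary behaviour is available behind the flag. A tie
for the modal genotype fails clause 1 (no genotype is "more than" anything).

Per-clause exclusion counts are logged, so a run reports its funnel:
reads in → retained → loci → segregating sites → clause-1 survivors →
diagnostic sites.

# The barcode module

Queries are assigned by best-hit percent identity over a global pairwise
alignment (match +1, mismatch −1, gap open 2, gap extend 0.5; Biostrings
`pairwiseAlignment`). Identity is matching columns over aligned columns
with terminal-gap columns excluded, so fragment queries are not penalised
for length. `N` counts as a mismatch — conservative and deterministic.
Because co-optimal alignments can differ in column count, the pair is
aligned in a canonical (lexicographic) order, which makes the reported
identity exactly symmetric. A local reference FASTA replaces any live
database query: results then never depend on network access or database
versions, while the ≥ 98% decision rule is preserved.

The grouping check builds a neighbor-joining tree on Kimura two-parameter
distances and asks, per species, whether its tips form a clade on the
unrooted tree. NJ/K2P stands in for Bayesian tree inference deliberately:
the property being checked is *species-group concordance*, which any
consistent distance method recovers at these divergences, not topology
identity. Saturated pairs (non-positive logarithm argument) are flagged as
undefined distances rather than clamped.

# The marker panel

`codPanel()` ships the published five-SNP/two-amplicon panel: region 12014
(291-bp product, primers at 64 °C) with SNPs at amplicon positions
82/112/220, and region 42229 (193 bp, 63 °C) with SNPs at 127/163, and the
species × position allele table. Positions are interpreted as 1-based
within the sequenced amplicon — the only reading under which position 220
fits the 291-bp product while the 42229 positions fit its 193-bp product.
At load the panel is validated: complete allele table, pairwise-distinct
alleles at every position. An exhaustive check (31 non-empty position
subsets × 3 species) confirms every subset of positions still identifies
all three species, i.e. the assay tolerates any single- or multi-position
dropout.

`inSilicoPcr` finds the forward primer and the reverse primer's reverse
complement downstream (exact match by default; `maxMismatch` available)
and returns every valid product — absence of a product is a result, not an
error, exactly as a negative control lane is a result. The true genomic
amplicon sequences were never published, so the packaged demonstration
templates are synthetic: they embed the real primers and the real panel
alleles at the real offsets over a shared random filler, and are labelled
synthetic everywhere. They demonstrate and test the calling logic; they do
not reproduce the original amplicons. Negative-control templates contain
no primer sites and yield no-calls, mirroring the assay's non-target
species controls.

# The simulator: what it emulates, and what it does not

`simulateLocusSet` + `simulateReads` generate the structure the discovery
method assumes:

* loci anchored at a TaqI remnant, 100 bp (the tag length of the emulated
  design), single-end — downstream tag analysis only uses the
  restriction-anchored read, so paired-end realism adds nothing here;
* three species at a background divergence of 0.005 substitutions/site
  from a common ancestor (see below), every individual homozygous for its
  species consensus;
* planted diagnostic loci carrying one site with pairwise-distinct fixed
  alleles across species, recorded as ground truth;
* per-sample, per-locus read depth ~ Poisson(20) — the standard shotgun
  depth model; the real study never published its depth distribution, so
  this is a stand-in, not a claim about the study;
* per-base substitution errors at 0.001 with Phred qualities from a
  clipped normal (mean 38, sd 3, clipped to [2, 41]), written as
  Phred+33 FASTQ.

Two generator choices deserve justification:

* **Background divergence 0.005/site.** The three real species are in
  different families and diverge far beyond what a Hamming-3 catalog merge
  tolerates across a 100-bp tag. The loci that such a pipeline can use are
  by construction the conserved tail of the genome — the catalog step
  *selects* for loci that still merge across species. The simulator
  therefore models that conserved subset directly: 0.5% background
  divergence keeps cross-species tag distances near the merge bound
  without guaranteeing every locus merges (at typical seeds a locus or two
  may split, which the pipeline tolerates gracefully).
* **No chance diagnostic columns.** Background substitutions occasionally
  produce, by chance, a column where all three species differ pairwise —
  a bona-fide diagnostic site that was not planted. The generator reverts
  such columns (outside planted loci) so that the planted set is *exactly*
  the set of diagnostic sites and recovery can be scored as precision and
  recall against a clean truth. Without the guard, roughly one run in five
  at these settings would contain an unplanted true positive and the
  recovery score would measure the seed, not the method.

The simulator does **not** model: within-species polymorphism, indels,
coalescent/demographic structure, PCR duplicates, adapter read-through,
quality-correlated errors, or reverse-complement read mixing (available as
an option, off by default, to exercise the assembler's orientation flag).
Passing the recovery tests therefore shows the pipeline is correct under
its own assumptions — fixed, homozygous, species-diagnostic differences on
alignable tags — not that it is robust to every artifact of real
libraries.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 2 | minimum reads for a primary stack (within sample) |
| `M` | 2 | max Hamming distance merged within a sample |
| `n` | 3 | max Hamming distance merged/matched across samples |
| `minBaseQuality` | 25 | Phred floor per pileup base |
| `minDepth` | 5 | post-masking depth floor per genotype |
| `homozygoteFraction` | 0.9 | top-allele fraction for a homozygous call |
| `concordance` | 0.8 | strict lower bound on modal-genotype share per species |
| barcode threshold | 98% | identity needed to accept a barcode assignment |
| depth / error / divergence | 20 / 0.001 / 0.005 | simulator defaults |

`m`, `M`, `n`, the quality/depth floors, the 80% concordance and the 98%
identity rule are the published values of the assay; the rest are the
package's own documented choices.

# Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline at the
study's sample design — 3 species with 6/12/10 samples, 50 loci of which 5
planted diagnostic, depth 20, error 0.001 (≈ 28,000 reads) — plus smaller
seeded instances for unit and property tests, and brute-force oracle
comparisons on ≤ 200 reads where all-pairs clustering is exhaustively
checkable. On these inputs the pipeline recovers exactly the planted loci
(precision = recall = 1) and barcode assignment is 100% accurate with all
species monophyletic; every such number quoted anywhere in the
documentation is computed by the tests or by `scripts/acceptance.R`, not
asserted.

# Known limitations

* Hamming-based single-linkage is not any published assembler's exact
  algorithm; agreement is proven against an in-package-independent oracle,
  not against external software output.
* The diagnostic filter handles biallelic-per-species, fixed-difference
  markers only; it reports (and discards) everything else rather than
  modelling it.
* The funnel's absolute counts from the original deposited reads (tens of
  gigabases, thousands of SNPs) are not reproducible at desk scale; the
  package reproduces the funnel's *shape* and the decision rules, at
  simulation scale.
* Percent identity depends mildly on the alignment scoring chosen; the
  scoring is documented, configurable, and fixed by default, but identity
  values near a threshold should be interpreted with that in mind.
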