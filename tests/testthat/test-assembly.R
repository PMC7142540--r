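test_that("quality filter applies the per-read rule exactly", {
  seqs <- rep(paste(rep("A", 50), collapse = ""), 3)
  good <- mk_reads(seqs, q = 40L)
  expect_identical(length(qualityFilter(good)@sequences), 3L)

  bad <- mk_reads(seqs[1], q = 2L)
  expect_identical(length(qualityFilter(bad)@sequences), 0L)

  ## mixed seeded batch against a read-by-read oracle
  set.seed(31)
  n <- 40; L <- 60
  reads <- mk_reads(vapply(1:n, function(i) oracle_random_dna(L), ""))
  reads@qualities <- matrix(sample(c(2L, 15L, 30L, 40L), n * L, TRUE,
                                   prob = c(.05, .1, .2, .65)), n, L)
  ## plant some Ns
  ch <- strsplit(reads@sequences[5], "")[[1]]; ch[1:6] <- "N"
  reads@sequences[5] <- paste(ch, collapse = "")
  kept <- qualityFilter(reads)
  oracle_keep <- vapply(1:n, function(i) {
    lowq <- mean(reads@qualities[i, ] < 20)
    nn <- mean(strsplit(reads@sequences[i], "")[[1]] == "N")
    lowq <= 0.10 && nn <= 0.05
  }, logical(1))
  expect_identical(kept@readIds, reads@readIds[oracle_keep])
})

test_that("stacking groups exact duplicates and respects the depth threshold", {
  set.seed(32)
  s1 <- oracle_random_dna(40); s2 <- mutate_k(s1, 3)
  st <- buildStacks(mk_reads(c(rep(s1, 5), s2)), m = 2)
  expect_length(st$primary, 1L)
  expect_identical(st$primary[[1]]$sequence, s1)
  expect_length(st$primary[[1]]$idx, 5L)
  expect_identical(st$secondary, 6L)

  ## all unique reads: nothing reaches depth 2
  uniq <- mk_reads(vapply(1:6, function(i) oracle_random_dna(40), ""))
  st2 <- buildStacks(uniq, m = 2)
  expect_length(st2$primary, 0L)
  expect_identical(st2$secondary, 1:6)

  ## seeded batch equals an independent hash-grouping oracle, and the
  ## primary/secondary split partitions the reads
  pool <- vapply(1:5, function(i) oracle_random_dna(30), "")
  seqs <- sample(pool, 60, replace = TRUE, prob = c(.4, .3, .15, .1, .05))
  st3 <- buildStacks(mk_reads(seqs), m = 3)
  oracle <- split(seq_along(seqs), seqs)
  oracle_primary <- oracle[lengths(oracle) >= 3]
  got <- setNames(lapply(st3$primary, `[[`, "idx"),
                  vapply(st3$primary, `[[`, "", "sequence"))
  expect_identical(got[sort(names(got))],
                   lapply(oracle_primary[sort(names(oracle_primary))], as.integer))
  all_idx <- sort(c(unlist(got, use.names = FALSE), st3$secondary))
  expect_identical(all_idx, seq_along(seqs))
  ## deterministic ordering: depth descending, then sequence
  depths <- lengths(lapply(st3$primary, `[[`, "idx"))
  expect_true(all(diff(depths) <= 0))

  ## unequal read lengths are rejected already at container construction
  expect_error(mk_reads(c("ACGT", "ACGTA")), "quality columns")
})

test_that("rc-aware stacking canonicalises read orientation", {
  set.seed(33)
  s <- oracle_random_dna(40)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  st <- buildStacks(mk_reads(c(s, rc, s, rc)), m = 2, rcAware = TRUE)
  expect_length(st$primary, 1L)
  expect_length(st$primary[[1]]$idx, 4L)
  expect_identical(st$primary[[1]]$sequence, min(s, rc))
})

test_that("stack merging follows single-linkage with modal consensus and unique secondary placement", {
  set.seed(34)
  s1 <- oracle_random_dna(40)
  s2 <- s1; substr(s2, 10, 10) <- if (substr(s1, 10, 10) == "A") "C" else "A"
  ## two stacks 1 apart, M=2: one locus, consensus takes the deeper base
  ml <- mergeStacks(buildStacks(mk_reads(c(rep(s1, 5), rep(s2, 3)))), M = 2)
  expect_length(ml$loci, 1L)
  expect_identical(ml$loci[[1]]$consensus, s1)
  expect_identical(ml$loci[[1]]$depth, 8L)

  ## three mismatches apart, M=2: two loci
  s3 <- mutate_k(s1, 3)
  while (oracle_hamming(s1, s3) != 3) s3 <- mutate_k(s1, 3)
  ml2 <- mergeStacks(buildStacks(mk_reads(c(rep(s1, 4), rep(s3, 2)))), M = 2)
  expect_length(ml2$loci, 2L)

  ## a secondary read equidistant from two loci is discarded
  p1 <- 5L; p2 <- 25L
  flip <- function(x, p) { substr(x, p, p) <-
    setdiff(c("A", "C"), substr(x, p, p))[1]; x }
  t1 <- s1; t2 <- flip(flip(s1, p1), p2)   # distance 2 from t1
  sec <- flip(s1, p1)                       # distance 1 from both
  ml3 <- mergeStacks(buildStacks(mk_reads(c(rep(t1, 3), rep(t2, 3), sec)),
                                 m = 2), M = 1)
  expect_length(ml3$loci, 2L)
  expect_identical(ml3$discarded, 7L)
  ## conservation: assigned + discarded = reads in
  expect_identical(sum(vapply(ml3$loci, `[[`, integer(1), "depth")) +
                     length(ml3$discarded), 7L)
})

test_that("merge partition equals brute-force single-linkage on a seeded batch", {
  set.seed(35)
  truth <- simulateLocusSet(6, locusLength = 60, nSpecies = 2,
                            nDiagnostic = 1, divergence = 0.01, seed = 5)
  reads <- simulateReads(truth, nSamples = c(1, 1), depth = 15,
                         errorRate = 0.01, seed = 6)
  for (rr in reads) {
    st <- buildStacks(rr, m = 2)
    ml <- mergeStacks(st, M = 2)
    ## partition of primary stacks implied by final locus membership
    stackSeqs <- vapply(st$primary, `[[`, "", "sequence")
    lociOf <- vapply(seq_along(st$primary), function(si) {
      r1 <- st$primary[[si]]$idx[1]
      which(vapply(ml$loci, function(l) r1 %in% l$idx, logical(1)))
    }, integer(1))
    expect_true(same_partition(lociOf, oracle_single_linkage(stackSeqs, 2)))
    ## conservation at the sample level
    assigned <- sum(vapply(ml$loci, `[[`, integer(1), "depth"))
    expect_identical(assigned + length(ml$discarded), length(rr@sequences))
  }
})

test_that("catalog construction merges homologous loci across samples", {
  set.seed(36)
  s <- oracle_random_dna(50)
  mk_sample <- function(seqs, sample)
    mergeStacks(buildStacks(mk_reads(seqs, sample = sample), m = 2), M = 2)
  ## identical locus in three samples: one catalog locus, three provenance rows
  samples <- list(a = mk_sample(rep(s, 4), "a"),
                  b = mk_sample(rep(s, 5), "b"),
                  c = mk_sample(rep(s, 3), "c"))
  cat1 <- buildCatalog(samples, n = 3)
  expect_length(cat1$consensus, 1L)
  expect_identical(nrow(cat1$members), 3L)
  expect_identical(unname(cat1$consensus[1]), s)

  ## three species variants within n of each other collapse to one locus
  v2 <- mutate_k(s, 2); v3 <- mutate_k(s, 2)
  cat2 <- buildCatalog(list(a = mk_sample(rep(s, 4), "a"),
                            b = mk_sample(rep(v2, 4), "b"),
                            c = mk_sample(rep(v3, 4), "c")), n = 3)
  expect_length(cat2$consensus, 1L)

  ## seeded multi-sample set equals the brute-force oracle
  truth <- simulateLocusSet(8, locusLength = 60, nDiagnostic = 2,
                            divergence = 0.005, seed = 8)
  reads <- simulateReads(truth, nSamples = c(2, 1, 1), depth = 12,
                         errorRate = 0.001, seed = 9)
  merged <- lapply(reads, function(r)
    mergeStacks(buildStacks(r, m = 2), M = 2))
  cat3 <- buildCatalog(merged, n = 3)
  allCons <- unlist(lapply(merged, function(ms)
    vapply(ms$loci, `[[`, "", "consensus")), use.names = FALSE)
  expect_true(same_partition(cat3$members$catalog_locus,
                             oracle_single_linkage(allCons, 3)))

  expect_error(buildCatalog(list(a = mk_sample(rep(s, 4), "a"),
                                 b = mk_sample(rep(substr(s, 1, 40), 4), "b"))),
               "mixed")
})

test_that("sample loci match the catalog at the nearest unique locus", {
  set.seed(37)
  s1 <- oracle_random_dna(50)
  s2 <- mutate_k(s1, 10)
  mk_sample <- function(seqs, sample)
    mergeStacks(buildStacks(mk_reads(seqs, sample = sample), m = 2), M = 2)
  samples <- list(a = mk_sample(c(rep(s1, 4), rep(s2, 4)), "a"))
  cat1 <- buildCatalog(samples, n = 3)
  mm <- matchSamples(cat1, samples, n = 3)
  expect_identical(nrow(mm$matches), 2L)
  expect_true(all(mm$matches$distance == 0))

  ## a locus farther than n from everything stays unmatched
  far <- mk_sample(rep(mutate_k(s1, 6), 4), "b")
  mm2 <- matchSamples(list(consensus = c(CL0001 = s1)), list(b = far), n = 3)
  expect_identical(nrow(mm2$matches), 0L)
  expect_identical(nrow(mm2$unmatched), 1L)

  ## equidistant catalog loci leave the locus unmatched (tie)
  flip <- function(x, p, to) { substr(x, p, p) <- to; x }
  base <- paste(rep("A", 30), collapse = "")
  cA <- flip(base, 5, "C"); cB <- flip(base, 25, "G")
  mid <- mk_sample(rep(base, 4), "c")  # distance 1 from both
  mm3 <- matchSamples(list(consensus = c(CL0001 = cA, CL0002 = cB)),
                      list(c = mid), n = 3)
  expect_identical(nrow(mm3$matches), 0L)
  expect_identical(nrow(mm3$unmatched), 1L)
})

test_that("a full simulated run recovers every true locus exactly once", {
  truth <- simulateLocusSet(20, nDiagnostic = 3, divergence = 0.005, seed = 13)
  reads <- simulateReads(truth, nSamples = c(2, 2, 2), depth = 20,
                         errorRate = 0.001, seed = 14)
  cat0 <- assembleSamples(reads)
  expect_identical(length(consensusSequences(cat0)), 20L)
  m <- mapCatalogToTruth(cat0, truth)
  expect_identical(sort(m$true_locus), 1:20)
  ## the catalog consensus is a depth-weighted majority across species, so
  ## it may sit a base or two off any single species at diverged columns
  expect_true(all(m$distance <= 3))
  ## every sample matched at every catalog locus
  tab <- table(catalogMatches(cat0)$sample)
  expect_true(all(tab == 20))
  ## stage counts are conserved and non-increasing
  lg <- stageCounts(cat0)
  expect_true(lg["reads_in"] >= lg["reads_retained"])
  expect_identical(unname(lg["reads_retained"]),
                   unname(lg["reads_assigned"] + lg["reads_discarded"]))
})

test_that("assembly output is deterministic and invariant to sample order", {
  truth <- simulateLocusSet(10, nDiagnostic = 2, divergence = 0.005, seed = 21)
  reads <- simulateReads(truth, nSamples = c(2, 1, 1), depth = 12,
                         errorRate = 0.001, seed = 22)
  c1 <- assembleSamples(reads)
  c2 <- assembleSamples(reads)
  expect_identical(as.character(consensusSequences(c1)),
                   as.character(consensusSequences(c2)))
  c3 <- assembleSamples(rev(reads))
  expect_identical(sort(as.character(consensusSequences(c1))),
                   sort(as.character(consensusSequences(c3))))
  expect_identical(as.character(consensusSequences(c1)),
                   as.character(consensusSequences(c3)))
})
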