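## Independent oracles used by the tests. These deliberately re-derive
## results with different machinery than the package (regex scans, igraph
## components, a from-scratch affine-gap DP) so that agreement is evidence,
## not tautology.

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## single-linkage clusters at a distance threshold, via igraph components
oracle_single_linkage <- function(seqs, threshold) {
  n <- length(seqs)
  edges <- c()
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (oracle_hamming(seqs[i], seqs[j]) <= threshold)
          edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

## two partitions (integer/character membership vectors) describe the same
## grouping iff the co-membership relations agree
same_partition <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  m1 <- outer(p1, p1, "==")
  m2 <- outer(p2, p2, "==")
  all(m1 == m2)
}

## Needleman-Wunsch/Gotoh global alignment with affine gaps, cost of a
## length-k gap = open + k * ext (the Biostrings convention). Returns the
## optimal score and one optimal alignment (traceback prefers diagonal).
oracle_gotoh <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  ## traceback, preferring M then X then Y
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      pa <- c(A[i - 1], pa); pb <- c(B[j - 1], pb)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      pa <- c(A[i - 1], pa); pb <- c("-", pb)
      prev <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                Y[i - 1, j] - open - ext)
      state <- which.max(prev)
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j - 1], pb)
      prev <- c(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                Y[i, j - 1] - ext)
      state <- which.max(prev)
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- 3
    if (j == 1 && i > 1) state <- 2
  }
  list(score = score, pattern = paste(pa, collapse = ""),
       subject = paste(pb, collapse = ""))
}

## percent identity from an oracle alignment, end-gap columns excluded
oracle_identity <- function(aln) {
  pc <- strsplit(aln$pattern, "")[[1]]
  sc <- strsplit(aln$subject, "")[[1]]
  endgap <- function(ch) {
    e <- logical(length(ch))
    r <- rle(ch == "-")
    if (r$values[1]) e[seq_len(r$lengths[1])] <- TRUE
    if (r$values[length(r$values)])
      e[(length(ch) - r$lengths[length(r$lengths)] + 1):length(ch)] <- TRUE
    e
  }
  keep <- !(endgap(pc) | endgap(sc))
  100 * sum(pc[keep] == sc[keep] & pc[keep] != "-") / sum(keep)
}

## construct a RadReads object directly (uniform quality)
mk_reads <- function(seqs, sample = "s1", species = "sp1", q = 40L) {
  L <- nchar(seqs[1])
  methods::new("RadReads",
               sampleId = sample, species = species,
               readIds = sprintf("%s_r%03d", sample, seq_along(seqs)),
               sequences = unname(seqs),
               qualities = matrix(as.integer(q), length(seqs), L),
               trueLocus = rep(NA_integer_, length(seqs)))
}

## substitute exactly k positions of a sequence (at distinct sites)
mutate_k <- function(seq, k, from_pos = 1L) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(from_pos:length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
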