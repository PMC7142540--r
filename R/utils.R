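DNA_BASES4 <- c("A", "C", "G", "T")

## Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
## stream; all exported generators route randomness through this so they are
## pure functions of their arguments.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

randomDna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

## Substitute each base independently with probability `rate`, always to a
## different base (Jukes-Cantor-like, no transition bias, no indels).
mutateChars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES4, chars[i]), 1L)
  }
  chars
}

## Equal-length sequence vector -> character matrix (one row per sequence).
seqsToMatrix <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("sequences must all have the same length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = n, byrow = TRUE)
}

matrixToSeqs <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

## All-pairs Hamming distances between equal-length sequences, computed as
## L minus the match-count Gram matrix of per-base indicator matrices; keeps
## the catalog step O(n^2 L / word) instead of a character loop.
hammingMatrix <- function(seqs) {
  m <- seqsToMatrix(seqs)
  L <- ncol(m)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c(DNA_BASES4, "N")) {
    ind <- (m == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- L - matches
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("Hamming distance requires equal-length sequences")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## Connected components of the graph linking pairs with distance <= threshold
## (single-linkage clusters at that threshold). Returns an integer membership
## vector; component ids follow first appearance order.
singleLinkageComponents <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## Depth-weighted modal base per column of a character matrix; ties broken
## alphabetically for determinism. `weights` is one weight per row.
weightedConsensus <- function(m, weights = rep(1, nrow(m))) {
  apply_col <- function(col) {
    tab <- tapply(weights, factor(col, levels = DNA_BASES4), sum)
    tab[is.na(tab)] <- 0
    DNA_BASES4[which.max(tab)]  # which.max takes first => alphabetical tie-break
  }
  paste(vapply(seq_len(ncol(m)), function(j) apply_col(m[, j]), character(1)),
        collapse = "")
}

## Phred+33 helpers -----------------------------------------------------------

phredToString <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L, multiple = FALSE)
}

stringToPhred <- function(s) {
  utf8ToInt(s) - 33L
}

## as.character() that keeps names (base drops them on character input)
asNamedCharacter <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)  # DNAStringSet etc. keep names
}

reverseComplement1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
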