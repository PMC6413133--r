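# Fixture builders used across test files. All synthetic, all built in code.

# a SiteWindowSet from literal 400-nt sequences
makeWindows <- function(seqs) SiteWindowSet(seqs)

# a 400-nt window with given segments written at site-relative positions
windowWith <- function(..., fill = "C") {
  w <- strrep(fill, 400)
  pieces <- list(...)
  for (p in pieces) {
    i <- posToIndex(p$at)
    substr(w, i, i + nchar(p$seq) - 1L) <- p$seq
  }
  w
}

# n windows of i.i.d. bases with the given probabilities (DNA letters)
randWindows <- function(n, seed, probs = c(A = .25, C = .25,
                                           G = .25, T = .25)) {
  set.seed(seed)
  mat <- matrix(sample(names(probs), n * 400, replace = TRUE, prob = probs),
                nrow = n)
  makeWindows(apply(mat, 1L, paste, collapse = ""))
}

# all sequences of length L over the given alphabet
enumSeqs <- function(L, alphabet = c("A", "T")) {
  if (L == 0L) return(character(0))
  do.call(paste0, expand.grid(rep(list(alphabet), L),
                              stringsAsFactors = FALSE))
}

# independent greedy non-overlapping counter: scan left to right, on a
# match jump a full motif length
greedyOracle <- function(seq, motif) {
  n <- nchar(seq)
  k <- nchar(motif)
  cnt <- 0L
  i <- 1L
  while (i + k - 1L <= n) {
    if (substr(seq, i, i + k - 1L) == motif) {
      cnt <- cnt + 1L
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  cnt
}

# a profile matrix built from explicit per-position A/C/G/U frequencies
profileMatrix <- function(fA, fC, fG, fU, nWindows = 1000L) {
  m <- rbind(A = fA, C = fC, G = fG, U = fU)
  colnames(m) <- as.character(indexToPos(seq_len(ncol(m))))
  attr(m, "nWindows") <- nWindows
  m
}
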