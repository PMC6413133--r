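## Single-nucleotide variant groups of canonical poly(A) signals, their
## position frequency matrices, and PSSM log-odds scoring.

RNA_BASES <- c("A", "C", "G", "U")

hammingDist <- function(a, b) {
  a <- strsplit(normalizeMotif(a), "")[[1]]
  b <- strsplit(normalizeMotif(b), "")[[1]]
  if (length(a) != length(b)) return(NA_integer_)
  sum(a != b)
}

#' Enumerate single-nucleotide variants of a signal
#'
#' All 3k motifs at Hamming distance exactly 1 from the canonical signal,
#' in lexicographic (RNA alphabet) order.
#'
#' @param canonical the canonical motif (DNA or RNA alphabet).
#' @return Character vector of variants in the RNA alphabet.
#' @examples
#' length(enumerateSNV("UGUAA"))  # 15
#' @export
enumerateSNV <- function(canonical) {
  w <- dnaToRna(normalizeMotif(canonical))
  ch <- strsplit(w, "")[[1]]
  out <- character(0)
  for (j in seq_along(ch)) {
    for (b in setdiff(RNA_BASES, ch[j])) {
      v <- ch
      v[j] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  sort(unique(out))
}

#' Compile a canonical signal's variant group from a motif table
#'
#' Members are the canonical signal plus every single-nucleotide variant
#' found within the table's top \code{topN} ranks (for the canonical's
#' length), each carrying its per-transcript frequency. The combined
#' frequency is the plain sum of member frequencies; a transcript carrying
#' two members contributes to both, as in the usual "overall frequency"
#' tabulations of signal groups.
#'
#' @param table a motif table from \code{\link{scanRegion}}.
#' @param canonical the canonical signal.
#' @param topN rank cutoff for variant membership (default 100).
#' @return A \code{\link{VariantGroup-class}}. If the canonical signal is
#'   absent from the table it is included with frequency 0 and a warning.
#' @export
compileVariantGroup <- function(table, canonical, topN = 100L) {
  can <- dnaToRna(normalizeMotif(canonical))
  k <- nchar(can)
  sub <- table[table$k == k, , drop = FALSE]
  if (!nrow(sub)) stop("motif table has no motifs of length ", k)
  top <- topMotifs(sub, topN, k)
  canFreq <- sub$frequency_pct[match(can, sub$motif)]
  if (is.na(canFreq)) {
    warning("canonical signal ", can, " absent from the motif table")
    canFreq <- 0
  }
  vars <- enumerateSNV(can)
  hit <- top[top$motif %in% vars, , drop = FALSE]
  members <- data.frame(motif = c(can, hit$motif),
                        frequency_pct = c(canFreq, hit$frequency_pct),
                        stringsAsFactors = FALSE)
  new("VariantGroup", canonical = can, members = members,
      combinedFrequency = sum(members$frequency_pct),
      sourceTopN = as.integer(topN))
}

#' Position frequency matrix of a variant group
#'
#' Column j is the frequency-weighted distribution of bases at motif
#' position j over the group members (weights are the members'
#' per-transcript frequencies, matching logo construction "based on their
#' frequencies"); columns sum to 1.
#'
#' @param group a \code{\link{VariantGroup-class}} with positive total
#'   frequency.
#' @return A 4 x k matrix, rows A, C, G, U.
#' @export
buildPFM <- function(group) {
  m <- group@members
  wts <- m$frequency_pct
  if (sum(wts) <= 0) stop("variant group has no frequency mass")
  k <- nchar(group@canonical)
  pfm <- matrix(0, nrow = 4L, ncol = k, dimnames = list(RNA_BASES, NULL))
  for (i in seq_len(nrow(m))) {
    ch <- strsplit(m$motif[i], "")[[1]]
    for (j in seq_len(k)) pfm[ch[j], j] <- pfm[ch[j], j] + wts[i]
  }
  pfm / sum(wts)
}

#' Build a PSSM and score k-mers against it
#'
#' The PSSM entry for base b at position j is
#' log2((pfm[b,j] + pseudocount, column-renormalized) / background[b]);
#' the score of a k-mer is the sum of its positional entries, so scores are
#' additive over positions and the expected score under the background is
#' non-positive.
#'
#' @param pfm a position frequency matrix from \code{\link{buildPFM}}.
#' @param background base distribution (A, C, G, U); uniform by default.
#' @param pseudocount added to every PFM cell before renormalization.
#' @return \code{buildPSSM()}: a 4 x k log-odds matrix;
#'   \code{pssmScore()}: a numeric score.
#' @examples
#' g <- new("VariantGroup", canonical = "UGUAA",
#'          members = data.frame(motif = "UGUAA", frequency_pct = 100),
#'          combinedFrequency = 100, sourceTopN = 1L)
#' pssmScore(buildPSSM(buildPFM(g)), "UGUAA")  # about 2 bits per position
#' @export
buildPSSM <- function(pfm, background = c(A = 0.25, C = 0.25,
                                          G = 0.25, U = 0.25),
                      pseudocount = 0.01) {
  if (!all(rownames(pfm) == RNA_BASES)) stop("pfm rows must be A,C,G,U")
  bg <- background[RNA_BASES]
  if (any(is.na(bg)) || any(bg <= 0)) stop("background must be positive over A,C,G,U")
  padj <- sweep(pfm + pseudocount, 2L, colSums(pfm + pseudocount), "/")
  log2(sweep(padj, 1L, bg, "/"))
}

#' @rdname buildPSSM
#' @param pssm a PSSM from \code{buildPSSM()}.
#' @param kmer a k-mer of the PSSM's width (DNA or RNA alphabet).
#' @export
pssmScore <- function(pssm, kmer) {
  w <- dnaToRna(normalizeMotif(kmer))
  if (nchar(w) != ncol(pssm))
    stop("k-mer length ", nchar(w), " != PSSM width ", ncol(pssm))
  ch <- strsplit(w, "")[[1]]
  sum(pssm[cbind(match(ch, RNA_BASES), seq_along(ch))])
}

#' Canonical signal frequencies in their reference intervals
#'
#' Per-transcript gap-mode frequencies of UGUAA over \code{-80..-15} and of
#' AAUAAA over \code{-50..-15}, the coordinates conventionally used to
#' compare species on a UGUAA/AAUAAA plane.
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @return A data.frame with columns \code{motif}, \code{region} and
#'   \code{frequency_pct}.
#' @export
canonicalSignalFrequencies <- function(x) {
  freqOf <- function(motif, region) {
    k <- nchar(motif)
    tab <- scanRegion(x, region, kMin = k, kMax = k, mode = "gap")
    f <- tab$frequency_pct[match(dnaToRna(normalizeMotif(motif)), tab$motif)]
    if (is.na(f)) 0 else f
  }
  data.frame(
    motif = c("UGUAA", "AAUAAA"),
    region = c("-80..-15", "-50..-15"),
    frequency_pct = c(freqOf("UGUAA", Region(-80L, -15L, "UGUAA_ref")),
                      freqOf("AAUAAA", Region(-50L, -15L, "AAUAAA_ref"))),
    stringsAsFactors = FALSE)
}
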