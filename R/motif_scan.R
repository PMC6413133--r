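## Exhaustive k-mer scanning in site-relative regions, under three counting
## modes:
##   overlap - every match start counts;
##   gap     - greedy left-to-right, a new match is only accepted >= gap+1
##             bases after the previous accepted start (gap = k-1 gives the
##             standard non-overlapping count);
##   once    - at most one occurrence per sequence, the one closest to the
##             poly(A) site.
## Motifs are accepted in the DNA or RNA alphabet and normalized to DNA
## internally; all reported motifs use the RNA alphabet.

normalizeMotif <- function(motif) {
  m <- chartr("Uu", "Tt", toupper(as.character(motif)))
  m <- toupper(m)
  if (any(!grepl("^[ACGT]+$", m)))
    stop("motif must be over A,C,G,T/U: ", paste(motif, collapse = ", "))
  m
}

dnaToRna <- function(x) chartr("T", "U", x)

## 1-based match starts of `motif` in `seqChar` (exact, overlapping)
matchStarts <- function(seqChar, motif) {
  n <- nchar(seqChar)
  k <- nchar(motif)
  if (k > n) return(integer(0))
  sv <- utf8ToInt(seqChar)
  mv <- utf8ToInt(motif)
  S <- n - k + 1L
  ok <- sv[seq_len(S)] == mv[1L]
  if (k > 1L) for (j in 2:k) ok <- ok & sv[seq.int(j, n - k + j)] == mv[j]
  which(ok)
}

## greedy left-to-right selection forbidding a new start within `gap` bases
greedySelect <- function(starts, gap) {
  sel <- integer(0)
  nextOk <- 1L
  for (s in starts) {
    if (s >= nextOk) {
      sel <- c(sel, s)
      nextOk <- s + gap + 1L
    }
  }
  sel
}

#' Count motif occurrences in a sequence
#'
#' @param seq a single sequence (DNA or RNA alphabet; N never matches).
#' @param motif the motif to count (3-8 nt typical, any length allowed).
#' @param mode \code{"gap"}, \code{"overlap"} or \code{"once"}. In gap mode,
#'   after a match is accepted at position p the next acceptable start is
#'   p + gap + 1; \code{gap = nchar(motif) - 1} (the default) yields the
#'   greedy non-overlapping count. Once mode keeps only the rightmost match
#'   (the one closest to the poly(A) site when \code{seq} is an upstream
#'   region read 5'->3'); see \code{\link{scanRegion}} for the site-aware
#'   selection in downstream or straddling regions.
#' @param gap non-negative integer; only used by gap mode.
#' @return A list with \code{count} and the accepted \code{starts}
#'   (1-based). A motif longer than the sequence gives count 0.
#' @examples
#' countOccurrences("ATATATAT", "ATATAT", mode = "gap", gap = 5)$count  # 1
#' countOccurrences("ATATATAT", "ATATAT", mode = "overlap")$count      # 2
#' @export
countOccurrences <- function(seq, motif, mode = c("gap", "overlap", "once"),
                             gap = NULL) {
  mode <- mode[1L]
  if (!mode %in% c("gap", "overlap", "once"))
    stop("mode must be one of gap, overlap, once")
  seq <- chartr("Uu", "Tt", toupper(as.character(seq)))
  if (length(seq) != 1L) stop("`seq` must be a single sequence")
  motif <- normalizeMotif(motif)
  st <- matchStarts(seq, motif)
  st <- switch(mode,
    overlap = st,
    gap = {
      if (is.null(gap)) gap <- nchar(motif) - 1L
      if (gap < 0L) stop("gap must be >= 0")
      greedySelect(st, as.integer(gap))
    },
    once = if (length(st)) st[length(st)] else st)
  list(count = length(st), starts = st)
}

## once-mode selection among in-region starts, in the site frame:
## upstream region -> closest to -1 (rightmost); downstream -> closest to +1
## (leftmost); straddling -> smallest |position|, upstream wins exact ties.
selectOnce <- function(starts, positions, region) {
  if (!length(starts)) return(starts)
  if (region@end < 0L) return(starts[length(starts)])
  if (region@start > 0L) return(starts[1L])
  a <- abs(positions)
  best <- which(a == min(a))
  if (length(best) > 1L) best <- best[positions[best] < 0L]
  starts[best[1L]]
}

## extract the region substring of every window as character
regionChars <- function(x, region) {
  idx <- regionIndices(region, upstreamLength(x), downstreamLength(x))
  substr(windowChars(x), idx[1L], idx[length(idx)])
}

#' Exhaustively scan a region for 3-8 nt motifs
#'
#' Enumerates every k-mer (kMin..kMax) actually observed inside the region
#' across all windows and tabulates, per motif: the number of windows with
#' at least one in-region occurrence, the per-transcript frequency (percent
#' of windows), and the total occurrence count under the chosen mode. A
#' match is in-region only when the full motif lies inside
#' \code{[start, end]}; k-mers containing N are skipped.
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @param region a \code{\link{Region}}.
#' @param kMin,kMax motif length range (defaults 3 and 8).
#' @param mode counting mode, see \code{\link{countOccurrences}}.
#' @param gap gap-mode distance; \code{NULL} means k-1 per motif length.
#' @return A data.frame (motif table) with columns \code{motif} (RNA),
#'   \code{k}, \code{n_seqs_with_hit}, \code{frequency_pct},
#'   \code{total_occurrences}, \code{rank} (within each k: frequency desc,
#'   occurrences desc, then lexicographic), sorted by k then rank.
#' @examples
#' w <- SiteWindowSet(strrep("TGTAA", 80))
#' scanRegion(w, Region(-35, -10), kMin = 5, kMax = 5)[1, ]
#' @export
scanRegion <- function(x, region, kMin = 3L, kMax = 8L,
                       mode = c("gap", "overlap", "once"), gap = NULL) {
  mode <- match.arg(mode)
  if (length(x) == 0L) stop("empty window set")
  if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
  regChars <- regionChars(x, region)
  n <- length(regChars)
  L <- regionLength(region)
  out <- list()
  for (k in seq.int(kMin, kMax)) {
    S <- L - k + 1L
    if (S < 1L) next
    kmat <- vapply(seq_len(S),
                   function(i) substr(regChars, i, i + k - 1L),
                   character(n))
    kmat <- matrix(kmat, nrow = n)
    valid <- matrix(!grepl("N", kmat, fixed = TRUE), nrow = n)
    perWindow <- lapply(seq_len(n), function(w) {
      km <- kmat[w, valid[w, ]]
      if (!length(km)) return(NULL)
      st <- which(valid[w, ])
      cnt <- table(km)
      occ <- switch(mode,
        overlap = as.integer(cnt),
        once = rep(1L, length(cnt)),
        gap = {
          g <- if (is.null(gap)) k - 1L else as.integer(gap)
          o <- rep(1L, length(cnt))
          multi <- names(cnt)[cnt > 1L]
          for (m in multi)
            o[match(m, names(cnt))] <-
              length(greedySelect(st[km == m], g))
          o
        })
      setNames(occ, names(cnt))
    })
    flat <- unlist(perWindow)
    if (is.null(flat)) next
    occTab <- tapply(flat, names(flat), sum)
    hitTab <- table(names(flat))
    motifs <- sort(names(occTab))
    df <- data.frame(motif = dnaToRna(motifs), k = k,
                     n_seqs_with_hit = as.integer(hitTab[motifs]),
                     frequency_pct = 100 * as.integer(hitTab[motifs]) / n,
                     total_occurrences = as.integer(occTab[motifs]),
                     stringsAsFactors = FALSE)
    ord <- order(-df$frequency_pct, -df$total_occurrences, df$motif)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    out[[as.character(k)]] <- df
  }
  if (!length(out)) stop("region shorter than every requested motif length")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-ranked motifs of a given length
#'
#' @param table a motif table from \code{\link{scanRegion}}.
#' @param n number of motifs to return (the whole table if fewer exist).
#' @param k motif length to select.
#' @return The top \code{n} rows for length \code{k}, re-ranked 1..n;
#'   ties broken by total occurrences, then lexicographically.
#' @export
topMotifs <- function(table, n, k) {
  if (n < 1L) stop("n must be >= 1")
  sub <- table[table$k == k, , drop = FALSE]
  ord <- order(-sub$frequency_pct, -sub$total_occurrences, sub$motif)
  sub <- head(sub[ord, , drop = FALSE], n)
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}

#' Positional distribution of a motif
#'
#' Counts motif occurrences by site-relative start position (the position of
#' the motif's 5' base) across all windows, under the chosen counting mode.
#' When a region is given, counting is restricted to matches that lie fully
#' inside it, so the column sum equals the motif's total occurrence count
#' from \code{\link{scanRegion}} on the same region and mode.
#'
#' @inheritParams scanRegion
#' @param motif the motif (DNA or RNA alphabet).
#' @param region optional \code{\link{Region}}; default is the full window.
#' @return A data.frame with \code{position} (every possible start position
#'   in the region) and \code{count}.
#' @export
positionalDistribution <- function(x, motif,
                                   region = NULL,
                                   mode = c("gap", "overlap", "once"),
                                   gap = NULL) {
  mode <- match.arg(mode)
  up <- upstreamLength(x); dn <- downstreamLength(x)
  if (is.null(region)) region <- Region(-up, dn, "window")
  motif <- normalizeMotif(motif)
  k <- nchar(motif)
  if (is.null(gap)) gap <- k - 1L
  regChars <- regionChars(x, region)
  L <- regionLength(region)
  S <- L - k + 1L
  idx0 <- posToIndex(region@start, up, dn)
  allPos <- if (S >= 1L) indexToPos(idx0 + seq_len(S) - 1L, up, dn)
            else integer(0)
  counts <- setNames(rep(0L, length(allPos)), allPos)
  if (S >= 1L) {
    for (s in regChars) {
      st <- matchStarts(s, motif)
      st <- switch(mode,
        overlap = st,
        gap = greedySelect(st, as.integer(gap)),
        once = selectOnce(st, indexToPos(idx0 + st - 1L, up, dn), region))
      if (length(st)) {
        ## starts are distinct within a window, so +1 per key is exact
        key <- as.character(indexToPos(idx0 + st - 1L, up, dn))
        counts[key] <- counts[key] + 1L
      }
    }
  }
  data.frame(position = allPos, count = as.integer(counts))
}
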