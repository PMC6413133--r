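## Single-nucleotide positional profiles, data-driven FUE/NUE/CE inference
## and cleavage-site dinucleotide statistics.

#' Single-nucleotide positional profile
#'
#' Per-position base frequencies across all windows, reported in the RNA
#' alphabet (rows A, C, G, U; columns are site-relative positions). N bases
#' are excluded from the denominator of their column.
#'
#' @param x a \code{\link{SiteWindowSet}} with at least one window.
#' @return A 4 x (upstream+downstream) numeric matrix with an
#'   \code{nWindows} attribute; column names are site-relative positions.
#' @examples
#' p <- nucleotideProfile(SiteWindowSet(strrep("A", 400)))
#' p["A", "-1"]  # 1
#' @export
nucleotideProfile <- function(x) {
  if (length(x) == 0L) stop("empty window set")
  cm <- consensusMatrix(windowSeqs(x))
  acgt <- matrix(0, nrow = 4L, ncol = ncol(cm),
                 dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) if (b %in% rownames(cm)) acgt[b, ] <- cm[b, ]
  denom <- colSums(acgt)
  freq <- sweep(acgt, 2L, pmax(denom, 1L), "/")
  freq[, denom == 0L] <- NA_real_
  rownames(freq) <- c("A", "C", "G", "U")
  colnames(freq) <- as.character(
    indexToPos(seq_len(ncol(freq)), upstreamLength(x), downstreamLength(x)))
  attr(freq, "nWindows") <- length(x)
  freq
}

## centered moving average over columns, partial means at the edges
smoothRows <- function(mat, width) {
  if (width <= 1L) return(mat)
  half <- (width - 1L) %/% 2L
  nc <- ncol(mat)
  out <- mat
  for (j in seq_len(nc)) {
    cols <- max(1L, j - half):min(nc, j + half)
    out[, j] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Find A/U crossings in a profile
#'
#' Scans 5'->3' for positions where the sign of freq(A) - freq(U) changes
#' between consecutive positions. A crossing is reported at the position on
#' the A-dominant side of the pair (the position entering A dominance for
#' an upward crossing, the last A-dominant position for a downward one);
#' exact equality at a position is reported at that position. An optional
#' moving-average smoother tames the noisiness of empirical profiles.
#'
#' @param profile a profile matrix from \code{\link{nucleotideProfile}} (or
#'   any 4 x N matrix with rows A,C,G,U and position column names).
#' @param from,to site-relative search range (inclusive).
#' @param smoothWidth moving-average window (1 = no smoothing).
#' @return Integer vector of crossing positions, in 5'->3' order (empty if
#'   none).
#' @export
findAUCrossings <- function(profile, from, to, smoothWidth = 1L) {
  prof <- smoothRows(profile, smoothWidth)
  pos <- as.integer(colnames(prof))
  j1 <- match(as.integer(from), pos)
  j2 <- match(as.integer(to), pos)
  if (is.na(j1) || is.na(j2) || j1 > j2)
    stop("search range outside the profile")
  d <- prof["A", ] - prof["U", ]
  nc <- length(d)
  crossings <- integer(0)
  for (j in seq.int(j1, j2)) {
    if (is.na(d[j])) next
    if (d[j] == 0) {
      ## exact equality is a crossing only when the profile passes through
      ## it (adjacent differences of opposite sign); a flat stretch is not
      if (j > 1L && j < nc && !is.na(d[j - 1L]) && !is.na(d[j + 1L]) &&
          d[j - 1L] * d[j + 1L] < 0)
        crossings <- c(crossings, pos[j])
    } else if (j < j2 && !is.na(d[j + 1L]) && d[j + 1L] != 0 &&
               sign(d[j]) != sign(d[j + 1L])) {
      crossings <- c(crossings, if (d[j + 1L] > 0) pos[j + 1L] else pos[j])
    }
  }
  unique(crossings)
}

#' Infer FUE/NUE/CE regions from a nucleotide profile
#'
#' The NUE starts at the first A/U crossing found in \code{-45..-20}
#' (fallback \code{-30}) and ends at the last A/U crossing in \code{-20..-5}
#' (fallback \code{-10}). If a positional distribution of a candidate signal
#' is supplied, the NUE bounds are widened (toward the side holding more of
#' the remaining mass) until they cover at least 90\% of that motif's
#' occurrences. The FUE runs from the 5'-most position where G or U is
#' dominant -- its frequency exceeding every other base by at least
#' \code{dominanceMargin} over at least \code{dominanceRun} consecutive
#' positions -- down to one base before the NUE start; without such
#' dominance the FUE start falls back to \code{-200}. The CE is fixed at
#' \code{-10..+10}.
#'
#' @param profile profile matrix from \code{\link{nucleotideProfile}}.
#' @param motifDistribution optional data.frame from
#'   \code{\link{positionalDistribution}} for the candidate NUE signal.
#' @param minWindows minimum number of windows the profile must summarize;
#'   fewer is an error advising manual regions (noisy profiles make
#'   crossing detection meaningless).
#' @param dominanceMargin,dominanceRun the definition of sustained G/U
#'   dominance for the FUE start.
#' @param smoothWidth moving-average width for crossing detection.
#' @return A \code{\link{RegionSet-class}} with provenance \code{"auto"}.
#' @export
inferRegions <- function(profile, motifDistribution = NULL,
                         minWindows = 50L, dominanceMargin = 0.05,
                         dominanceRun = 20L, smoothWidth = 5L) {
  nW <- attr(profile, "nWindows")
  if (is.null(nW) || nW < minWindows)
    stop("profile built from fewer than ", minWindows,
         " windows; supply regions manually via RegionSet()")
  cr1 <- findAUCrossings(profile, -45L, -20L, smoothWidth)
  cr2 <- findAUCrossings(profile, -20L, -5L, smoothWidth)
  nueStart <- if (length(cr1)) cr1[1L] else -30L
  nueEnd <- if (length(cr2)) cr2[length(cr2)] else -10L
  if (posToIndex(nueStart) > posToIndex(nueEnd)) {
    nueStart <- -30L; nueEnd <- -10L
  }
  if (!is.null(motifDistribution)) {
    bounds <- widenToCover(motifDistribution, nueStart, nueEnd, 0.9)
    nueStart <- bounds[1L]; nueEnd <- bounds[2L]
  }
  pos <- as.integer(colnames(profile))
  upTo <- posToIndex(nueStart) - 1L
  fueStart <- NA_integer_
  if (upTo >= dominanceRun) {
    sub <- profile[, seq_len(upTo), drop = FALSE]
    others <- function(b) setdiff(c("A", "C", "G", "U"), b)
    dom <- (sub["G", ] >= apply(sub[others("G"), , drop = FALSE], 2L, max) +
              dominanceMargin) |
           (sub["U", ] >= apply(sub[others("U"), , drop = FALSE], 2L, max) +
              dominanceMargin)
    dom[is.na(dom)] <- FALSE
    r <- rle(dom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values & r$lengths >= dominanceRun)
    if (length(good)) fueStart <- pos[starts[good[1L]]]
  }
  if (is.na(fueStart)) fueStart <- -200L
  if (posToIndex(fueStart) >= posToIndex(nueStart)) fueStart <- -200L
  fueEnd <- posShift(nueStart, -1L)
  RegionSet(fue = Region(fueStart, fueEnd, "FUE"),
            nue = Region(nueStart, nueEnd, "NUE"),
            provenance = "auto")
}

## widen [start,end] until it covers >= frac of the distribution's mass
widenToCover <- function(dist, start, end, frac) {
  total <- sum(dist$count)
  if (total == 0L) return(c(start, end))
  inside <- function(s, e) {
    sel <- posToIndex(dist$position) >= posToIndex(s) &
      posToIndex(dist$position) <= posToIndex(e)
    sum(dist$count[sel])
  }
  s <- start; e <- end
  lo <- min(dist$position[dist$count > 0L])
  hi <- max(dist$position[dist$count > 0L])
  while (inside(s, e) / total < frac) {
    canLeft <- posToIndex(s) > posToIndex(lo)
    canRight <- posToIndex(e) < posToIndex(hi)
    if (!canLeft && !canRight) break
    gainLeft <- if (canLeft) inside(posShift(s, -1L), e) else -1L
    gainRight <- if (canRight) inside(s, posShift(e, 1L)) else -1L
    if (gainLeft >= gainRight) s <- posShift(s, -1L) else e <- posShift(e, 1L)
  }
  c(s, e)
}

#' Cleavage-site dinucleotide table
#'
#' Tallies the dinucleotide at site-relative positions (-2, -1) across
#' windows and reports the 16 frequencies plus the YA (UA+CA) and BA
#' (UA+CA+GA) aggregates. Windows with N at -2/-1 are excluded from the
#' denominator and counted in \code{nExcluded}.
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @return A list with \code{table} (data.frame: dinucleotide, count,
#'   frequency), \code{YA}, \code{BA} and \code{nExcluded}.
#' @examples
#' cleavageDinucleotide(SiteWindowSet(strrep("CA", 200)))$BA  # 1
#' @export
cleavageDinucleotide <- function(x) {
  if (length(x) == 0L) stop("empty window set")
  up <- upstreamLength(x); dn <- downstreamLength(x)
  d <- substr(windowChars(x), posToIndex(-2L, up, dn),
              posToIndex(-1L, up, dn))
  keep <- !grepl("N", d, fixed = TRUE)
  lv <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  cnt <- table(factor(d[keep], levels = sort(lv)))
  freq <- as.numeric(cnt) / max(sum(keep), 1L)
  tab <- data.frame(dinucleotide = dnaToRna(names(cnt)),
                    count = as.integer(cnt), frequency = freq,
                    stringsAsFactors = FALSE)
  fOf <- function(dd) tab$frequency[match(dd, tab$dinucleotide)]
  ya <- sum(fOf(c("UA", "CA")))
  list(table = tab, YA = ya, BA = ya + fOf("GA"),
       nExcluded = sum(!keep))
}
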