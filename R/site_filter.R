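## Internal-priming artifact removal and site deduplication.
##
## An oligo(dT)-primed cDNA can anneal to a genomic A-run instead of a real
## poly(A) tail, so a putative site whose surrounding genomic sequence is
## A-rich is suspect. A window is flagged when the genomic bases at
## site-relative positions -10..+10 (20 bases, no position 0) contain a run
## of >= 6 consecutive A, or when any 10-nt window fully inside -10..+10
## contains >= 7 A. N and any non-A character count as non-A, so masked
## sequence never causes a flag (conservative retention).

## the -10..+10 subsequence of each window, as characters
primingContext <- function(x) {
  i1 <- posToIndex(-10L, upstreamLength(x), downstreamLength(x))
  i2 <- posToIndex(10L, upstreamLength(x), downstreamLength(x))
  substr(windowChars(x), i1, i2)
}

#' Internal-priming test for one window
#'
#' @param window a single 400-nt window sequence, or directly the 20-base
#'   \code{-10..+10} context.
#' @param upstream,downstream geometry used to locate \code{-10..+10} when a
#'   full window is given.
#' @return A list with \code{flag} (logical) and \code{rule}
#'   (\code{"run6"}, \code{"win7of10"} or \code{NA}); \code{"run6"} takes
#'   precedence when both rules fire.
#' @examples
#' isInternalPriming("CCCAAAAAACCCCCCCCCCC")$flag   # 6 consecutive A
#' isInternalPriming(strrep("C", 20))$flag          # clean
#' @export
isInternalPriming <- function(window, upstream = 300L, downstream = 100L) {
  window <- toupper(as.character(window))
  if (length(window) != 1L) stop("one window at a time; see internalPriming()")
  n <- nchar(window)
  ctx <- if (n == 20L) window
         else substr(window, posToIndex(-10L, upstream, downstream),
                     posToIndex(10L, upstream, downstream))
  if (nchar(ctx) != 20L) stop("window too short to cover -10..+10")
  res <- primingRules(ctx)
  list(flag = res != "", rule = if (res == "") NA_character_ else res)
}

## vectorised rule evaluation over 20-base contexts; returns "", "run6", or
## "win7of10" per element
primingRules <- function(ctx) {
  run6 <- grepl("AAAAAA", ctx, fixed = TRUE)
  isA <- matrix(0L, length(ctx), 20L)
  for (j in 1:20) isA[, j] <- as.integer(substr(ctx, j, j) == "A")
  cum <- cbind(0L, t(apply(isA, 1L, cumsum)))
  win7 <- rep(FALSE, length(ctx))
  for (s in 1:11) win7 <- win7 | (cum[, s + 10L] - cum[, s]) >= 7L
  ifelse(run6, "run6", ifelse(win7, "win7of10", ""))
}

#' Internal-priming flags for a window set
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @return A data.frame with one row per window: \code{flag} and
#'   \code{rule} as in \code{\link{isInternalPriming}}.
#' @export
internalPriming <- function(x) {
  rule <- primingRules(primingContext(x))
  data.frame(flag = rule != "",
             rule = ifelse(rule == "", NA_character_, rule),
             stringsAsFactors = FALSE)
}

#' Collapse redundant poly(A) sites
#'
#' Multiple ESTs frequently support the same cleavage site; sites identical
#' in (contig, coordinate, strand) are merged into one record whose support
#' is the sum. Output is sorted by contig, coordinate, strand for
#' deterministic downstream behaviour.
#'
#' @param sites a \code{GRanges} of cleavage sites.
#' @return A deduplicated \code{GRanges}.
#' @examples
#' gr <- GenomicRanges::GRanges(c("c1", "c1"), IRanges::IRanges(5, width = 1),
#'                              strand = "+")
#' S4Vectors::mcols(gr)$support <- c(1L, 3L)
#' dedupeSites(gr)
#' @export
dedupeSites <- function(sites) {
  if (length(sites) == 0L) return(sites)
  key <- paste(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites),
               as.character(GenomicRanges::strand(sites)), sep = "\r")
  support <- tapply(siteSupport(sites), key, sum)
  first <- !duplicated(key)
  out <- sites[first]
  mcols(out)$support <- as.integer(support[key[first]])
  ord <- order(as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out),
               as.character(GenomicRanges::strand(out)))
  out[ord]
}

#' Remove internal-priming windows
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @return A list with \code{windows} (the retained
#'   \code{SiteWindowSet}, input order preserved), \code{report} (a
#'   \code{\link{FilterReport}}) and \code{flagged} (the per-window logical
#'   vector).
#' @export
filterWindows <- function(x) {
  fl <- internalPriming(x)
  keep <- !fl$flag
  report <- FilterReport(nInput = length(x),
                         nInternalPriming = sum(fl$flag),
                         nRetained = sum(keep))
  list(windows = x[keep], report = report, flagged = fl$flag)
}
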