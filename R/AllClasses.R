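#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement consensusMatrix subseq
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats rbinom rpois setNames
#' @importFrom utils head read.table write.table
NULL

## ---------------------------------------------------------------------------
## Region
## ---------------------------------------------------------------------------

#' Region: a labelled site-relative interval
#'
#' A \code{Region} is a closed interval of site-relative positions over which
#' motif scanning or background fitting is restricted. Positions follow the
#' no-zero convention of \code{\link{posToIndex}}: the cleavage base is
#' \code{-1} and \code{+1} is the first downstream base. Canonical labels are
#' \code{"FUE"} (far upstream element), \code{"NUE"} (near upstream element)
#' and \code{"CE"} (cleavage element, conventionally \code{-10..+10}).
#'
#' @param start,end site-relative positions, \code{start <= end} in 5'->3'
#'   order, neither equal to 0.
#' @param label region label.
#' @return A \code{Region} object.
#' @examples
#' Region(-35, -10, "NUE")
#' regionLength(Region(-10, 10, "CE"))
#' @aliases Region-class
#' @export
setClass("Region",
         representation(label = "character",
                        start = "integer",
                        end = "integer"))

setValidity("Region", function(object) {
  s <- object@start; e <- object@end
  if (length(s) != 1L || length(e) != 1L) return("start/end must be scalars")
  if (s == 0L || e == 0L) return("positions cannot be 0 (no position 0)")
  if (s < -300L || e > 100L) return("region outside [-300,-1] U [+1,+100]")
  if (posToIndex(s) > posToIndex(e)) return("start must not be 3' of end")
  TRUE
})

#' @rdname Region-class
#' @export
Region <- function(start, end, label = "custom") {
  new("Region", label = as.character(label),
      start = as.integer(start), end = as.integer(end))
}

#' @rdname Region-class
#' @param x,object a \code{Region}.
#' @export
regionStart <- function(x) x@start

#' @rdname Region-class
#' @export
regionEnd <- function(x) x@end

#' @rdname Region-class
#' @export
regionLabel <- function(x) x@label

#' @rdname Region-class
#' @export
regionLength <- function(x) {
  posToIndex(x@end) - posToIndex(x@start) + 1L
}

## 1-based window indices covered by a region
regionIndices <- function(x, upstream = 300L, downstream = 100L) {
  seq(posToIndex(x@start, upstream, downstream),
      posToIndex(x@end, upstream, downstream))
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region <%s> %+d..%+d (%d nt)\n", object@label,
              object@start, object@end, regionLength(object)))
})

## ---------------------------------------------------------------------------
## SiteWindowSet
## ---------------------------------------------------------------------------

#' SiteWindowSet: strand-corrected windows around poly(A) sites
#'
#' Holds one fixed-length window per poly(A) site, each read 5'->3' of the
#' transcript with the cleavage base at site-relative position \code{-1}
#' (window index \code{upstream}). Sequences are stored as DNA; motif tables
#' and profiles are reported in the RNA alphabet.
#'
#' @param windows a \code{DNAStringSet} (or character vector) of equal-length
#'   window sequences.
#' @param sites a \code{GRanges} of the corresponding cleavage coordinates
#'   (width-1 ranges, strand \code{+}/\code{-}, optional \code{support}
#'   metadata column). If omitted, placeholder sites are created, which is
#'   convenient for pre-extracted window FASTA.
#' @param upstream,downstream window geometry; widths must equal
#'   \code{upstream + downstream}.
#' @param dropped data.frame log of sites that could not be extracted
#'   (columns contig, coord, strand, reason).
#' @return A \code{SiteWindowSet}.
#' @examples
#' w <- SiteWindowSet(paste(rep("ACGT", 100), collapse = ""))
#' length(w)
#' @aliases SiteWindowSet-class
#' @export
setClass("SiteWindowSet",
         representation(windows = "DNAStringSet",
                        sites = "GRanges",
                        upstream = "integer",
                        downstream = "integer",
                        dropped = "data.frame"))

setValidity("SiteWindowSet", function(object) {
  w <- object@windows
  len <- object@upstream + object@downstream
  if (length(w) != length(object@sites))
    return("windows and sites must be parallel")
  if (length(w) && !all(Biostrings::width(w) == len))
    return(sprintf("all windows must be exactly %d nt", len))
  TRUE
})

#' @rdname SiteWindowSet-class
#' @export
SiteWindowSet <- function(windows, sites = NULL, upstream = 300L,
                          downstream = 100L, dropped = emptyDropLog()) {
  if (is.character(windows)) windows <- DNAStringSet(windows)
  if (is.null(sites)) {
    n <- length(windows)
    sites <- GRanges(rep("synthetic", n),
                     IRanges(start = rep(as.integer(upstream), n), width = 1L),
                     strand = rep("+", n))
    mcols(sites)$support <- rep(1L, n)
  }
  new("SiteWindowSet", windows = windows, sites = sites,
      upstream = as.integer(upstream), downstream = as.integer(downstream),
      dropped = dropped)
}

emptyDropLog <- function() {
  data.frame(contig = character(), coord = integer(),
             strand = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' @rdname SiteWindowSet-class
#' @param x,object a \code{SiteWindowSet}.
#' @export
windowSeqs <- function(x) x@windows

#' @rdname SiteWindowSet-class
#' @export
windowSites <- function(x) x@sites

#' @rdname SiteWindowSet-class
#' @export
droppedSites <- function(x) x@dropped

#' @rdname SiteWindowSet-class
#' @export
upstreamLength <- function(x) x@upstream

#' @rdname SiteWindowSet-class
#' @export
downstreamLength <- function(x) x@downstream

#' @rdname SiteWindowSet-class
#' @export
setMethod("length", "SiteWindowSet", function(x) length(x@windows))

#' @rdname SiteWindowSet-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SiteWindowSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, windows = x@windows[i], sites = x@sites[i])
})

setMethod("show", "SiteWindowSet", function(object) {
  cat(sprintf("SiteWindowSet with %d windows (-%d..-1 / +1..+%d)\n",
              length(object), object@upstream, object@downstream))
  if (nrow(object@dropped))
    cat(sprintf("  %d site(s) dropped during extraction\n",
                nrow(object@dropped)))
})

## character vector of window sequences (internal workhorse)
windowChars <- function(x) as.character(x@windows)

## ---------------------------------------------------------------------------
## FilterReport
## ---------------------------------------------------------------------------

#' FilterReport: bookkeeping for site filtering
#'
#' Records the fate of every input site: retained, removed as an
#' internal-priming artifact, collapsed as a duplicate, or dropped because
#' its window would run past a contig end. The fates partition the input, so
#' \code{nRetained + nInternalPriming + nDuplicatesCollapsed + nOutOfBounds
#' == nInput}.
#'
#' @param nInput,nInternalPriming,nDuplicatesCollapsed,nOutOfBounds,nRetained
#'   integer counts.
#' @return A \code{FilterReport}.
#' @aliases FilterReport-class
#' @export
setClass("FilterReport",
         representation(nInput = "integer",
                        nInternalPriming = "integer",
                        nDuplicatesCollapsed = "integer",
                        nOutOfBounds = "integer",
                        nRetained = "integer"))

setValidity("FilterReport", function(object) {
  with_slots <- c(object@nInternalPriming, object@nDuplicatesCollapsed,
                  object@nOutOfBounds, object@nRetained)
  if (any(with_slots < 0L)) return("counts must be non-negative")
  if (sum(with_slots) != object@nInput)
    return("fates must partition the input (counts do not conserve)")
  TRUE
})

#' @rdname FilterReport-class
#' @export
FilterReport <- function(nInput, nInternalPriming = 0L,
                         nDuplicatesCollapsed = 0L, nOutOfBounds = 0L,
                         nRetained = nInput - nInternalPriming -
                           nDuplicatesCollapsed - nOutOfBounds) {
  new("FilterReport", nInput = as.integer(nInput),
      nInternalPriming = as.integer(nInternalPriming),
      nDuplicatesCollapsed = as.integer(nDuplicatesCollapsed),
      nOutOfBounds = as.integer(nOutOfBounds),
      nRetained = as.integer(nRetained))
}

#' @rdname FilterReport-class
#' @param x a \code{FilterReport}.
#' @export
reportCounts <- function(x) {
  c(n_input = x@nInput, n_internal_priming = x@nInternalPriming,
    n_duplicates_collapsed = x@nDuplicatesCollapsed,
    n_out_of_bounds = x@nOutOfBounds, n_retained = x@nRetained)
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  print(reportCounts(object))
})

## ---------------------------------------------------------------------------
## MarkovBackground
## ---------------------------------------------------------------------------

#' MarkovBackground: order-m background model for motif statistics
#'
#' Transition and initial probabilities of an order-\code{m} Markov chain
#' over \{A,C,G,T\}, fitted to the scanned sequences with an add-0.25
#' pseudocount per cell (see \code{\link{fitMarkov}}).
#'
#' @aliases MarkovBackground-class
#' @export
setClass("MarkovBackground",
         representation(order = "integer",
                        initial = "numeric",
                        transitions = "matrix",
                        trainedOn = "character",
                        nTrain = "integer"))

setValidity("MarkovBackground", function(object) {
  tr <- object@transitions
  if (any(tr < 0) || any(object@initial < 0))
    return("probabilities must be non-negative")
  if (any(abs(rowSums(tr) - 1) > 1e-9))
    return("transition rows must sum to 1")
  if (abs(sum(object@initial) - 1) > 1e-9)
    return("initial distribution must sum to 1")
  TRUE
})

#' @rdname MarkovBackground-class
#' @param x a \code{MarkovBackground}.
#' @export
markovOrder <- function(x) x@order

setMethod("show", "MarkovBackground", function(object) {
  cat(sprintf("MarkovBackground order %d, trained on %s (%d k-mers)\n",
              object@order, object@trainedOn, object@nTrain))
})

## ---------------------------------------------------------------------------
## RegionSet
## ---------------------------------------------------------------------------

#' RegionSet: the FUE/NUE/CE cis-element layout
#'
#' Bundles the three signal regions. The cleavage element is fixed at
#' \code{-10..+10}; the NUE must lie upstream of it and the FUE must end
#' immediately 5' of the NUE start.
#'
#' @param fue,nue \code{Region} objects.
#' @param provenance \code{"auto"} (inferred from a profile) or
#'   \code{"manual"}.
#' @return A \code{RegionSet}.
#' @aliases RegionSet-class
#' @export
setClass("RegionSet",
         representation(fue = "Region", nue = "Region", ce = "Region",
                        provenance = "character"))

setValidity("RegionSet", function(object) {
  if (object@ce@start != -10L || object@ce@end != 10L)
    return("CE is fixed at -10..+10")
  if (posToIndex(object@nue@start) >= posToIndex(object@ce@start))
    return("NUE must start upstream of the CE")
  if (posToIndex(object@fue@end) + 1L != posToIndex(object@nue@start))
    return("FUE must end immediately upstream of the NUE start")
  if (!object@provenance %in% c("auto", "manual"))
    return("provenance must be 'auto' or 'manual'")
  TRUE
})

#' @rdname RegionSet-class
#' @export
RegionSet <- function(fue, nue, provenance = "manual") {
  new("RegionSet", fue = fue, nue = nue,
      ce = Region(-10L, 10L, "CE"), provenance = provenance)
}

#' @rdname RegionSet-class
#' @param x a \code{RegionSet}.
#' @export
fueRegion <- function(x) x@fue

#' @rdname RegionSet-class
#' @export
nueRegion <- function(x) x@nue

#' @rdname RegionSet-class
#' @export
ceRegion <- function(x) x@ce

#' @rdname RegionSet-class
#' @export
regionProvenance <- function(x) x@provenance

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet (%s)\n", object@provenance))
  show(object@fue); show(object@nue); show(object@ce)
})

## ---------------------------------------------------------------------------
## VariantGroup
## ---------------------------------------------------------------------------

#' VariantGroup: a canonical signal and its single-nucleotide variants
#'
#' Compiled from a ranked motif table: the canonical signal plus every
#' Hamming-distance-1 variant found within the table's top ranks, each with
#' its per-transcript frequency. The combined frequency is the plain sum of
#' member frequencies (a transcript carrying two members is counted twice,
#' matching the usual tabulation of "overall" signal-group frequencies).
#'
#' @aliases VariantGroup-class
#' @export
setClass("VariantGroup",
         representation(canonical = "character",
                        members = "data.frame",
                        combinedFrequency = "numeric",
                        sourceTopN = "integer"))

setValidity("VariantGroup", function(object) {
  m <- object@members
  if (!all(c("motif", "frequency_pct") %in% names(m)))
    return("members needs columns motif, frequency_pct")
  if (!object@canonical %in% m$motif)
    return("canonical must be a member")
  hd <- vapply(m$motif, function(v) hammingDist(v, object@canonical),
               integer(1))
  if (any(hd > 1L)) return("members must be within Hamming distance 1")
  if (abs(object@combinedFrequency - sum(m$frequency_pct)) > 1e-9)
    return("combinedFrequency must equal the sum of member frequencies")
  TRUE
})

#' @rdname VariantGroup-class
#' @param x a \code{VariantGroup}.
#' @export
canonicalSignal <- function(x) x@canonical

#' @rdname VariantGroup-class
#' @export
variantMembers <- function(x) x@members

#' @rdname VariantGroup-class
#' @export
combinedFrequency <- function(x) x@combinedFrequency

setMethod("show", "VariantGroup", function(object) {
  cat(sprintf("VariantGroup %s: %d member(s), combined %.2f%% (top %d)\n",
              object@canonical, nrow(object@members),
              object@combinedFrequency, object@sourceTopN))
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' SimConfig: parameters of the synthetic window generator
#'
#' Describes the statistical architecture the analysis assumes: per-region
#' i.i.d. base compositions (upstream background, U-rich FUE, A-peaked NUE,
#' A-poor CE, downstream background), a signal motif planted at a uniform
#' random start within an interval with probability \code{plantProb}, a
#' cleavage dinucleotide written at \code{-2/-1} with probability
#' \code{ceDinucleotideProb}, internal-priming decoys (a 6-nt A-run inside
#' \code{-10..+10}) with probability \code{primingDecoyProb}, and duplicate
#' site rows at \code{duplicateSiteRate} for deduplication testing. Output
#' is bit-reproducible for a fixed (config, seed).
#'
#' @param nSites number of poly(A) sites to emit.
#' @param seed integer RNG seed.
#' @param compositions named list of blocks, each
#'   \code{list(region = Region(...), probs = c(A=,C=,G=,U=))}; the blocks
#'   must tile \code{-300..+100}.
#' @param plantedMotif signal motif (RNA or DNA alphabet).
#' @param plantProb planting probability per window.
#' @param plantInterval \code{Region} of allowed motif start positions.
#' @param ceDinucleotide 2-mer written at \code{-2/-1}.
#' @param ceDinucleotideProb its probability.
#' @param primingDecoyProb probability of an internal-priming decoy.
#' @param duplicateSiteRate probability a site is emitted twice.
#' @param upstream,downstream window geometry.
#' @return A \code{SimConfig}.
#' @aliases SimConfig-class
#' @export
setClass("SimConfig",
         representation(nSites = "integer", seed = "integer",
                        compositions = "list",
                        plantedMotif = "character", plantProb = "numeric",
                        plantInterval = "Region",
                        ceDinucleotide = "character",
                        ceDinucleotideProb = "numeric",
                        primingDecoyProb = "numeric",
                        duplicateSiteRate = "numeric",
                        upstream = "integer", downstream = "integer"))

setValidity("SimConfig", function(object) {
  probs <- c(object@plantProb, object@ceDinucleotideProb,
             object@primingDecoyProb, object@duplicateSiteRate)
  if (any(probs < 0) || any(probs > 1))
    return("probabilities must be in [0,1]")
  if (object@nSites < 1L) return("nSites must be >= 1")
  len <- object@upstream + object@downstream
  covered <- unlist(lapply(object@compositions, function(b)
    regionIndices(b$region, object@upstream, object@downstream)))
  if (length(covered) != len || anyDuplicated(covered) ||
      !setequal(covered, seq_len(len)))
    return("composition blocks must tile the window exactly once")
  for (b in object@compositions) {
    p <- b$probs
    if (!setequal(names(p), c("A", "C", "G", "U")) || abs(sum(p) - 1) > 1e-9)
      return("each composition needs probs A,C,G,U summing to 1")
  }
  k <- nchar(object@plantedMotif)
  iv <- object@plantInterval
  if (posToIndex(iv@start, object@upstream, object@downstream) + k - 1L > len)
    return("planted motif cannot fit inside the window from plantInterval")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d sites, seed %d, motif %s (pi=%.2f in %+d..%+d), q=%.2f\n",
    object@nSites, object@seed, object@plantedMotif, object@plantProb,
    object@plantInterval@start, object@plantInterval@end,
    object@primingDecoyProb))
})
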