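## Order-m Markov background models and binomial Z-scores for motif
## over-representation, in the style of oligo-analysis: the expected count
## of a word w over T possible start positions is E = T * P(w), with
## variance approximated as binomial, var = T * P(w) * (1 - P(w)). The
## word-autocorrelation correction is deliberately omitted (documented
## limitation); observed counts must therefore be overlap-mode counts so
## that observation and expectation refer to the same start-position space.

DNA_BASES <- c("A", "C", "G", "T")

## all 4^m DNA contexts of length m ("" for m = 0)
allContexts <- function(m) {
  if (m == 0L) return("")
  do.call(paste0, expand.grid(rep(list(DNA_BASES), m),
                              stringsAsFactors = FALSE)[, m:1, drop = FALSE])
}

#' Fit an order-m Markov background to a scanned region
#'
#' Transition probabilities are maximum-likelihood frequencies over all
#' in-region (m+1)-mers pooled across windows, with an add-one-quarter
#' pseudocount per cell: P(b | c) = (n(cb) + 0.25) / (n(c.) + 1). The
#' initial distribution over m-mers is fitted the same way from all
#' in-region m-mers. k-mers containing N are skipped.
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @param region the \code{\link{Region}} the statistics refer to.
#' @param order Markov order m >= 0; the region must be at least m+1 long.
#' @return A \code{\link{MarkovBackground-class}} object.
#' @examples
#' w <- SiteWindowSet(strrep("A", 400))
#' bg <- fitMarkov(w, Region(-35, -10), order = 1)
#' wordProbability(bg, "AAAAA")  # close to 1
#' @export
fitMarkov <- function(x, region, order = 1L) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  L <- regionLength(region)
  if (L < order + 1L)
    stop("region (", L, " nt) shorter than order+1 = ", order + 1L)
  regChars <- regionChars(x, region)
  kmerCounts <- function(k) {
    if (k == 0L) return(setNames(0, ""))
    S <- L - k + 1L
    km <- unlist(lapply(seq_len(S),
                        function(i) substr(regChars, i, i + k - 1L)))
    km <- km[!grepl("N", km, fixed = TRUE)]
    table(km)
  }
  cnt1 <- kmerCounts(order + 1L)
  ctx <- allContexts(order)
  trans <- matrix(0, nrow = length(ctx), ncol = 4L,
                  dimnames = list(ctx, DNA_BASES))
  for (b in DNA_BASES) {
    key <- paste0(ctx, b)
    v <- as.integer(cnt1[key])
    v[is.na(v)] <- 0L
    trans[, b] <- v
  }
  transP <- (trans + 0.25) / (rowSums(trans) + 1)
  if (order == 0L) {
    initial <- setNames(1, "")
  } else {
    cntM <- kmerCounts(order)
    v <- as.integer(cntM[ctx])
    v[is.na(v)] <- 0L
    initial <- setNames((v + 0.25) / (sum(v) + 0.25 * length(ctx)), ctx)
  }
  new("MarkovBackground", order = order, initial = initial,
      transitions = transP,
      trainedOn = sprintf("%s %+d..%+d (%d windows)", region@label,
                          region@start, region@end, length(x)),
      nTrain = as.integer(sum(cnt1)))
}

#' Probability of a word under a Markov background
#'
#' P(w) = P_init(w[1..m]) * prod_j P(w[j] | w[j-m..j-1]); over all 4^k
#' words of length k these probabilities sum to 1.
#'
#' @param bg a \code{\link{MarkovBackground-class}}.
#' @param motif a word of length >= order+1 (DNA or RNA alphabet).
#' @return The probability as a single numeric.
#' @export
wordProbability <- function(bg, motif) {
  w <- normalizeMotif(motif)
  k <- nchar(w)
  m <- bg@order
  if (k < m + 1L) stop("motif shorter than order+1")
  p <- if (m == 0L) 1 else unname(bg@initial[substr(w, 1L, m)])
  for (j in seq.int(m + 1L, k)) {
    ## row 1 for the order-0 model ("" is not addressable by name)
    ri <- if (m == 0L) 1L else match(substr(w, j - m, j - 1L),
                                     rownames(bg@transitions))
    p <- p * bg@transitions[ri, substr(w, j, j)]
  }
  p
}

#' Markov order and Z-score cutoff by motif length
#'
#' Short words (triplets and tetramers) are scored against an order-1
#' background with a Z-score cutoff of 5; pentamers through octamers use an
#' order-3 background with a cutoff of 3.
#'
#' @param k motif length, 3..8.
#' @return A list with \code{order} and \code{cutoff}.
#' @examples
#' significancePolicy(3)  # order 1, cutoff 5
#' significancePolicy(6)  # order 3, cutoff 3
#' @export
significancePolicy <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L || k > 8L)
    stop("policy is defined for motif lengths 3..8")
  if (k <= 4L) list(order = 1L, cutoff = 5.0) else list(order = 3L, cutoff = 3.0)
}

## overlap-mode total occurrences of one motif in a region
observedOverlapCount <- function(x, region, motif) {
  motif <- normalizeMotif(motif)
  sum(vapply(regionChars(x, region),
             function(s) length(matchStarts(s, motif)), integer(1),
             USE.NAMES = FALSE))
}

#' Z-score of a motif against a Markov background
#'
#' With T the number of possible start positions (windows x (L - k + 1)),
#' p the Markov word probability, E = T p and sd = sqrt(T p (1 - p)), the
#' Z-score is (O - E) / sd. O must be (and by default is) the overlap-mode
#' occurrence count over the same region, so that observed and expected
#' counts range over the same start positions. The background order and the
#' significance cutoff default to \code{\link{significancePolicy}} for the
#' motif's length.
#'
#' @param x a \code{\link{SiteWindowSet}}.
#' @param region scanned \code{\link{Region}}.
#' @param motif motif to score (one or more).
#' @param background optional pre-fitted \code{MarkovBackground}; when
#'   several motifs of different policy orders are scored, backgrounds are
#'   fitted per order as needed.
#' @param observed optional observed overlap counts (recomputed if NULL).
#' @param order,cutoff optional overrides of the length policy.
#' @return A data.frame with one row per motif: \code{motif},
#'   \code{k}, \code{observed}, \code{expected}, \code{sd}, \code{z},
#'   \code{order_used}, \code{cutoff}, \code{significant} (z >= cutoff).
#' @export
motifZScore <- function(x, region, motif, background = NULL,
                        observed = NULL, order = NULL, cutoff = NULL) {
  motifs <- normalizeMotif(motif)
  n <- length(x)
  L <- regionLength(region)
  rows <- vector("list", length(motifs))
  bgCache <- list()
  if (!is.null(background))
    bgCache[[as.character(background@order)]] <- background
  for (i in seq_along(motifs)) {
    w <- motifs[i]
    k <- nchar(w)
    pol <- if (is.null(order) || is.null(cutoff)) significancePolicy(k)
           else list(order = as.integer(order), cutoff = cutoff)
    if (!is.null(order)) pol$order <- as.integer(order)
    if (!is.null(cutoff)) pol$cutoff <- cutoff
    key <- as.character(pol$order)
    if (is.null(bgCache[[key]]))
      bgCache[[key]] <- fitMarkov(x, region, pol$order)
    bg <- bgCache[[key]]
    O <- if (is.null(observed)) observedOverlapCount(x, region, w)
         else observed[i]
    nPos <- n * (L - k + 1L)
    p <- wordProbability(bg, w)
    E <- nPos * p
    sd <- sqrt(nPos * p * (1 - p))
    if (sd == 0) stop("degenerate background for motif ", w)
    z <- (O - E) / sd
    rows[[i]] <- data.frame(motif = dnaToRna(w), k = k, observed = O,
                            expected = E, sd = sd, z = z,
                            order_used = bg@order, cutoff = pol$cutoff,
                            significant = z >= pol$cutoff,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
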