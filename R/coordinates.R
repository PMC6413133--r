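#' Site-relative coordinate convention
#'
#' Windows around a poly(A) site use the site-relative frame
#' \code{-upstream .. -1, +1 .. +downstream}: the cleavage base is position
#' \code{-1} and there is no position 0. \code{posToIndex()} maps a
#' site-relative position to the 1-based index into the window sequence;
#' \code{indexToPos()} is its inverse. With the defaults (300 nt upstream,
#' 100 nt downstream) position \code{-300} is index 1, \code{-1} is index
#' 300, \code{+1} is index 301 and \code{+100} is index 400.
#'
#' @param pos integer vector of site-relative positions (no zeros).
#' @param index integer vector of 1-based window indices.
#' @param upstream,downstream window geometry in nucleotides.
#' @return \code{posToIndex()}: integer indices; \code{indexToPos()}:
#'   integer site-relative positions.
#' @examples
#' posToIndex(c(-300, -1, 1, 100))
#' indexToPos(posToIndex(-25))
#' @export
posToIndex <- function(pos, upstream = 300L, downstream = 100L) {
  pos <- as.integer(pos)
  bad <- is.na(pos) | pos == 0L | pos < -upstream | pos > downstream
  if (any(bad)) {
    stop("position(s) ", paste(pos[bad], collapse = ", "),
         " outside [-", upstream, ",-1] U [+1,+", downstream,
         "] (there is no position 0)")
  }
  ifelse(pos < 0L, pos + upstream + 1L, pos + upstream)
}

#' @rdname posToIndex
#' @export
indexToPos <- function(index, upstream = 300L, downstream = 100L) {
  index <- as.integer(index)
  bad <- is.na(index) | index < 1L | index > upstream + downstream
  if (any(bad)) {
    stop("index(es) out of 1..", upstream + downstream)
  }
  ifelse(index <= upstream, index - upstream - 1L, index - upstream)
}

## All valid positions from start to end (inclusive), skipping 0.
posSeq <- function(start, end, upstream = 300L, downstream = 100L) {
  indexToPos(seq(posToIndex(start, upstream, downstream),
                 posToIndex(end, upstream, downstream)),
             upstream, downstream)
}

## Position `by` steps 3'-ward of `pos` in the no-zero frame.
posShift <- function(pos, by, upstream = 300L, downstream = 100L) {
  indexToPos(posToIndex(pos, upstream, downstream) + as.integer(by),
             upstream, downstream)
}
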