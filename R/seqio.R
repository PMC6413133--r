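#' Read a genome FASTA
#'
#' Reads contig sequences, uppercases them, and maps IUPAC ambiguity codes
#' other than A/C/G/T to N (with a warning stating how many positions were
#' masked). Contig IDs are the first whitespace-delimited token of each
#' header; duplicate IDs are an error.
#'
#' @param path path to a FASTA file.
#' @return A named \code{DNAStringSet}, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "ACGTacgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate contig ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  chars <- toupper(as.character(seqs))
  masked <- gsub("[^ACGTN]", "N", chars)
  nMasked <- sum(vapply(gregexpr("[^ACGTN]", chars),
                        function(m) sum(m > 0L), integer(1)))
  if (nMasked > 0L)
    warning(nMasked, " non-ACGTN position(s) masked to N")
  out <- DNAStringSet(masked)
  names(out) <- ids
  out
}

#' Read a poly(A)-site table
#'
#' Reads cleavage-site coordinates as a \code{GRanges} of width-1 ranges.
#' Two dialects are supported: \code{"tsv"} (columns contig, 1-based
#' position of the cleavage base, strand, optional EST support count;
#' a header line is detected automatically) and \code{"bed"} (BED6;
#' 0-based half-open, so a row \code{chr1 499 500} is cleavage coordinate
#' 500; the score column is used as support when it is a positive integer).
#'
#' @param path path to the site table.
#' @param dialect \code{"tsv"} or \code{"bed"}.
#' @return A \code{GRanges} with a \code{support} metadata column.
#' @export
readSites <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("site table not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- dialect == "tsv" &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t| +")[[1]][2])))
  tab <- read.table(path, header = hasHeader, sep = "",
                    stringsAsFactors = FALSE)
  if (dialect == "tsv") {
    if (ncol(tab) < 3L) stop("TSV site table needs >= 3 columns")
    contig <- as.character(tab[[1]])
    coordRaw <- tab[[2]]
    strand <- as.character(tab[[3]])
    support <- if (ncol(tab) >= 4L) tab[[4]] else rep(1L, nrow(tab))
  } else {
    if (ncol(tab) < 6L) stop("BED site table needs >= 6 columns")
    contig <- as.character(tab[[1]])
    coordRaw <- tab[[3]]  # 0-based half-open end == 1-based position
    strand <- as.character(tab[[6]])
    score <- suppressWarnings(as.integer(tab[[5]]))
    support <- ifelse(!is.na(score) & score >= 1L, score, 1L)
  }
  coord <- suppressWarnings(as.integer(coordRaw))
  if (any(is.na(coord)) || any(coord != as.numeric(coordRaw)))
    stop("non-integer coordinate(s) in ", path)
  if (any(coord < 1L)) stop("coordinates must be >= 1")
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  support <- suppressWarnings(as.integer(support))
  if (any(is.na(support)) || any(support < 1L))
    stop("support counts must be integers >= 1")
  gr <- GRanges(contig, IRanges(coord, width = 1L), strand = strand)
  mcols(gr)$support <- support
  gr
}

#' Write a poly(A)-site table (TSV dialect)
#'
#' @param sites a \code{GRanges} as returned by \code{\link{readSites}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSites <- function(sites, path) {
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(sites)),
                   pos_1based = GenomicRanges::start(sites),
                   strand = as.character(GenomicRanges::strand(sites)),
                   support = siteSupport(sites))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

siteSupport <- function(sites) {
  s <- mcols(sites)$support
  if (is.null(s)) rep(1L, length(sites)) else as.integer(s)
}

#' Extract windows around poly(A) sites
#'
#' For a plus-strand site at coordinate \code{c}, the window is the genomic
#' interval \code{[c-upstream+1, c+downstream]} so that the cleavage base
#' \code{c} sits at site-relative position \code{-1}. For a minus-strand
#' site it is the reverse complement of \code{[c-downstream, c+upstream-1]},
#' again placing the (complemented) base at \code{c} at position \code{-1},
#' with the returned sequence reading 5'->3' of the transcript. Sites whose
#' window would run past a contig end, or whose contig is absent from the
#' genome, are dropped (never padded) and recorded in the drop log so that
#' downstream frequency denominators always refer to full-length windows.
#'
#' @param genome a named \code{DNAStringSet} (see \code{\link{readGenome}}).
#' @param sites a \code{GRanges} of cleavage sites.
#' @param upstream,downstream window geometry (defaults 300/100).
#' @return A \code{\link{SiteWindowSet}}; \code{droppedSites()} lists every
#'   site that was not extracted, with its reason
#'   (\code{"unknown_contig"} or \code{"out_of_bounds"}).
#' @export
extractWindows <- function(genome, sites, upstream = 300L,
                           downstream = 100L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  contig <- as.character(GenomicRanges::seqnames(sites))
  coord <- GenomicRanges::start(sites)
  std <- as.character(GenomicRanges::strand(sites))
  if (!all(std %in% c("+", "-")))
    stop("sites must have strand + or -")
  known <- contig %in% names(genome)
  clen <- rep(NA_integer_, length(sites))
  clen[known] <- Biostrings::width(genome)[match(contig[known],
                                                 names(genome))]
  from <- ifelse(std == "+", coord - upstream + 1L, coord - downstream)
  to <- ifelse(std == "+", coord + downstream, coord + upstream - 1L)
  ok <- known & from >= 1L & to <= clen
  reason <- ifelse(!known, "unknown_contig",
                   ifelse(!ok, "out_of_bounds", NA_character_))
  dropped <- data.frame(contig = contig[!ok], coord = coord[!ok],
                        strand = std[!ok], reason = reason[!ok],
                        stringsAsFactors = FALSE)
  seqs <- character(sum(ok))
  idx <- which(ok)
  if (length(idx)) {
    gchar <- NULL; lastContig <- ""
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (contig[i] != lastContig) {
        gchar <- as.character(genome[[contig[i]]])
        lastContig <- contig[i]
      }
      seqs[j] <- substr(gchar, from[i], to[i])
    }
  }
  win <- DNAStringSet(seqs)
  minus <- std[ok] == "-"
  if (any(minus)) win[minus] <- reverseComplement(win[minus])
  SiteWindowSet(win, sites[ok], upstream, downstream, dropped)
}

#' Read / write window FASTA
#'
#' Window sets are serialized as FASTA with headers
#' \code{contig:coord:strand[:support]} so that site identity survives a
#' round trip. \code{readWindows()} also accepts arbitrary headers
#' (pre-extracted windows from elsewhere), in which case placeholder site
#' records are created.
#'
#' @param x a \code{SiteWindowSet}.
#' @param path FASTA path.
#' @param upstream,downstream window geometry of the file being read.
#' @return \code{readWindows()}: a \code{SiteWindowSet};
#'   \code{writeWindows()}: invisibly, \code{path}.
#' @export
writeWindows <- function(x, path) {
  s <- windowSites(x)
  hdr <- sprintf("%s:%d:%s:%d", as.character(GenomicRanges::seqnames(s)),
                 GenomicRanges::start(s),
                 as.character(GenomicRanges::strand(s)), siteSupport(s))
  out <- windowSeqs(x)
  names(out) <- hdr
  writeXStringSet(out, path)
  invisible(path)
}

#' @rdname writeWindows
#' @export
readWindows <- function(path, upstream = 300L, downstream = 100L) {
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty window FASTA: ", path)
  parts <- strsplit(names(seqs), ":")
  parsable <- all(vapply(parts, length, integer(1)) >= 3L) &&
    !anyNA(suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))) &&
    all(vapply(parts, `[`, "", 3L) %in% c("+", "-"))
  if (parsable) {
    contig <- vapply(parts, `[`, "", 1L)
    coord <- as.integer(vapply(parts, `[`, "", 2L))
    std <- vapply(parts, `[`, "", 3L)
    support <- suppressWarnings(
      as.integer(vapply(parts, function(p) p[4], "")))
    support[is.na(support)] <- 1L
    gr <- GRanges(contig, IRanges(coord, width = 1L), strand = std)
    mcols(gr)$support <- support
    names(seqs) <- NULL
    SiteWindowSet(seqs, gr, upstream, downstream)
  } else {
    x <- SiteWindowSet(seqs, NULL, upstream, downstream)
    x
  }
}
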