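## Seeded generator of genomes, poly(A) sites and windows with the
## statistical architecture the analysis assumes: per-region i.i.d. base
## compositions, a planted NUE signal, a cleavage dinucleotide at -2/-1,
## internal-priming decoys, and optional duplicate site rows. Ground truth
## for every emitted window is returned alongside.

defaultCompositions <- function() {
  list(
    upstream = list(region = Region(-300L, -181L, "upstream_bg"),
                    probs = c(A = 0.30, C = 0.20, G = 0.20, U = 0.30)),
    fue = list(region = Region(-180L, -33L, "FUE"),
               probs = c(A = 0.15, C = 0.15, G = 0.25, U = 0.45)),
    nue = list(region = Region(-32L, -12L, "NUE"),
               probs = c(A = 0.50, C = 0.15, G = 0.15, U = 0.20)),
    ce = list(region = Region(-11L, 10L, "CE_bg"),
              probs = c(A = 0.05, C = 0.30, G = 0.20, U = 0.45)),
    downstream = list(region = Region(11L, 100L, "downstream_bg"),
                      probs = c(A = 0.30, C = 0.20, G = 0.20, U = 0.30)))
}

#' @rdname SimConfig-class
#' @export
simConfig <- function(nSites = 2000L, seed = 1L,
                      compositions = defaultCompositions(),
                      plantedMotif = "UGUAA", plantProb = 0.5,
                      plantInterval = Region(-30L, -15L, "plant"),
                      ceDinucleotide = "CA", ceDinucleotideProb = 0.55,
                      primingDecoyProb = 0, duplicateSiteRate = 0,
                      upstream = 300L, downstream = 100L) {
  new("SimConfig", nSites = as.integer(nSites), seed = as.integer(seed),
      compositions = compositions,
      plantedMotif = dnaToRna(normalizeMotif(plantedMotif)),
      plantProb = plantProb, plantInterval = plantInterval,
      ceDinucleotide = dnaToRna(normalizeMotif(ceDinucleotide)),
      ceDinucleotideProb = ceDinucleotideProb,
      primingDecoyProb = primingDecoyProb,
      duplicateSiteRate = duplicateSiteRate,
      upstream = as.integer(upstream), downstream = as.integer(downstream))
}

#' Simulate a genome, poly(A) sites and ground truth
#'
#' Each site gets its own contig holding one full window plus nothing else:
#' plus-strand sites sit at coordinate \code{upstream} of a
#' \code{upstream+downstream}-nt contig, minus-strand sites at
#' \code{downstream+1} of the reverse-complemented contig, so
#' \code{\link{extractWindows}} recovers every window without truncation.
#' Bases are drawn block-by-block from the configured compositions; the
#' planted motif overwrites background bases at a uniform random start in
#' the plant interval with probability \code{plantProb}; the cleavage
#' dinucleotide is written at \code{-2/-1} with probability
#' \code{ceDinucleotideProb}; an internal-priming decoy (6-nt A-run fully
#' inside \code{-10..+10}) is written with probability
#' \code{primingDecoyProb}; and each site is emitted a second time with
#' probability \code{duplicateSiteRate}. Output is bit-identical for a
#' fixed config (the global RNG state is restored on exit).
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with \code{genome} (named \code{DNAStringSet}),
#'   \code{sites} (\code{GRanges} with support, duplicates included),
#'   \code{truth} (data.frame: site, contig, coord, strand, planted,
#'   plant_pos, decoy, decoy_pos, ce_dinuc_set, duplicate_of) and
#'   \code{config}.
#' @examples
#' sim <- simulateWindows(simConfig(nSites = 5, seed = 42))
#' length(sim$genome)
#' @export
simulateWindows <- function(config) {
  validObject(config)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(config@seed)
  n <- config@nSites
  up <- config@upstream; dn <- config@downstream
  len <- up + dn
  dnaOf <- c(A = "A", C = "C", G = "G", U = "T")

  ## background, block by block
  mat <- matrix("", nrow = n, ncol = len)
  for (b in config@compositions) {
    idx <- regionIndices(b$region, up, dn)
    mat[, idx] <- sample(dnaOf[names(b$probs)], n * length(idx),
                         replace = TRUE, prob = b$probs)
  }

  ## planted signal
  motif <- strsplit(chartr("U", "T", config@plantedMotif), "")[[1]]
  k <- length(motif)
  ivIdx <- regionIndices(config@plantInterval, up, dn)
  ivIdx <- ivIdx[ivIdx + k - 1L <= len]
  planted <- rbinom(n, 1L, config@plantProb) == 1L
  plantIdx <- rep(NA_integer_, n)
  plantIdx[planted] <- sample(ivIdx, sum(planted), replace = TRUE)
  for (i in which(planted))
    mat[i, plantIdx[i]:(plantIdx[i] + k - 1L)] <- motif

  ## cleavage dinucleotide at -2/-1
  ceSet <- rbinom(n, 1L, config@ceDinucleotideProb) == 1L
  dinuc <- strsplit(chartr("U", "T", config@ceDinucleotide), "")[[1]]
  ceIdx <- c(posToIndex(-2L, up, dn), posToIndex(-1L, up, dn))
  for (i in which(ceSet)) mat[i, ceIdx] <- dinuc

  ## internal-priming decoys: 6 A's fully inside -10..+10
  decoy <- rbinom(n, 1L, config@primingDecoyProb) == 1L
  decoyStarts <- seq(posToIndex(-10L, up, dn), posToIndex(10L, up, dn) - 5L)
  decoyIdx <- rep(NA_integer_, n)
  decoyIdx[decoy] <- sample(decoyStarts, sum(decoy), replace = TRUE)
  for (i in which(decoy)) mat[i, decoyIdx[i]:(decoyIdx[i] + 5L)] <- "A"

  windows <- do.call(paste0, lapply(seq_len(len), function(j) mat[, j]))
  std <- sample(c("+", "-"), n, replace = TRUE)
  contig <- sprintf("ctg%05d", seq_len(n))
  coord <- ifelse(std == "+", up, dn + 1L)
  genome <- DNAStringSet(windows)
  minus <- std == "-"
  if (any(minus)) genome[minus] <- reverseComplement(genome[minus])
  names(genome) <- contig
  support <- rpois(n, 1L) + 1L

  dup <- rbinom(n, 1L, config@duplicateSiteRate) == 1L
  allContig <- c(contig, contig[dup])
  allCoord <- c(coord, coord[dup])
  allStd <- c(std, std[dup])
  allSupport <- c(support, rep(1L, sum(dup)))
  sites <- GRanges(allContig, IRanges(allCoord, width = 1L),
                   strand = allStd)
  mcols(sites)$support <- allSupport

  idxToPosSafe <- function(i) ifelse(is.na(i), NA_integer_,
                                     indexToPos(ifelse(is.na(i), 1L, i),
                                                up, dn))
  truth <- data.frame(
    site = c(seq_len(n), which(dup)),
    contig = allContig, coord = allCoord, strand = allStd,
    planted = c(planted, planted[dup]),
    plant_pos = idxToPosSafe(c(plantIdx, plantIdx[dup])),
    decoy = c(decoy, decoy[dup]),
    decoy_pos = idxToPosSafe(c(decoyIdx, decoyIdx[dup])),
    ce_dinuc_set = c(ceSet, ceSet[dup]),
    duplicate_of = c(rep(NA_integer_, n), which(dup)),
    stringsAsFactors = FALSE)
  truth$duplicate_of[seq_len(n)] <- NA_integer_

  list(genome = genome, sites = sites, truth = truth, config = config)
}

#' Write a simulation to disk
#'
#' Emits \code{<prefix>.genome.fa}, \code{<prefix>.sites.tsv} and
#' \code{<prefix>.truth.tsv}.
#'
#' @param sim result of \code{\link{simulateWindows}}.
#' @param prefix output path prefix.
#' @return Invisibly, the three paths.
#' @export
writeSimulation <- function(sim, prefix) {
  paths <- paste0(prefix, c(".genome.fa", ".sites.tsv", ".truth.tsv"))
  writeXStringSet(sim$genome, paths[1L])
  writeSites(sim$sites, paths[2L])
  write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Analytic per-transcript detection frequency for the planted motif
#'
#' Estimates the probability that a window has at least one in-region
#' occurrence of the planted motif as
#' \code{1 - (1 - pi * c) * prod_s (1 - p(s))}, where \code{c} is the
#' fraction of plant start positions whose motif lies fully inside the scan
#' region and \code{p(s)} is the background (composition) probability of
#' the motif starting at region position \code{s}. Start positions are
#' treated as independent, so this is an estimate suitable for test
#' tolerances, not an exact value.
#'
#' @param config a \code{\link{simConfig}}.
#' @param region scan region; defaults to the configured NUE block.
#' @return Expected per-transcript frequency, in percent.
#' @export
expectedFrequency <- function(config, region = NULL) {
  up <- config@upstream; dn <- config@downstream
  if (is.null(region)) {
    nue <- Filter(function(b) b$region@label == "NUE", config@compositions)
    region <- if (length(nue)) nue[[1L]]$region else config@plantInterval
  }
  motif <- strsplit(config@plantedMotif, "")[[1]]  # RNA letters
  k <- length(motif)
  len <- up + dn
  ## per-window-index composition probability of each base
  probAt <- matrix(NA_real_, nrow = 4L, ncol = len,
                   dimnames = list(c("A", "C", "G", "U"), NULL))
  for (b in config@compositions)
    probAt[names(b$probs), regionIndices(b$region, up, dn)] <- b$probs
  regIdx <- regionIndices(region, up, dn)
  startIdx <- regIdx[regIdx + k - 1L <= regIdx[length(regIdx)]]
  motifRow <- match(motif, rownames(probAt))
  pAt <- vapply(startIdx, function(s)
    prod(probAt[cbind(motifRow, s + seq_len(k) - 1L)]), numeric(1))
  ivIdx <- regionIndices(config@plantInterval, up, dn)
  ivIdx <- ivIdx[ivIdx + k - 1L <= len]
  cov <- mean(ivIdx %in% startIdx)
  100 * (1 - (1 - config@plantProb * cov) * prod(1 - pAt))
}
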