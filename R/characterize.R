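#' End-to-end poly(A) signal characterization
#'
#' Runs the per-species workflow: deduplicate sites, extract windows,
#' remove internal-priming artifacts, build the single-nucleotide profile,
#' infer (or accept) the FUE/NUE/CE layout, scan each region for 3-8 nt
#' motifs, Z-score the top NUE motifs against Markov backgrounds, tabulate
#' the cleavage dinucleotide, compile the UGUAA and AAUAAA variant groups
#' with their PFMs, and compute the canonical-signal comparison
#' frequencies. Every stage's result is returned; with \code{outDir} set,
#' one TSV per stage plus a run manifest are written (deterministic
#' content, so identical inputs give byte-identical outputs).
#'
#' @param genome genome as a \code{DNAStringSet} or FASTA path; not needed
#'   when \code{windows} is given.
#' @param sites sites as a \code{GRanges} or table path; not needed when
#'   \code{windows} is given.
#' @param windows optional pre-extracted \code{\link{SiteWindowSet}} or
#'   window FASTA path.
#' @param regions optional \code{\link{RegionSet-class}} overriding
#'   automatic inference.
#' @param kMin,kMax,mode,gap scanning parameters (see
#'   \code{\link{scanRegion}}).
#' @param topN motifs per length carried into ranking/Z-scoring.
#' @param variantTopN rank cutoff for variant-group compilation.
#' @param minWindows minimum windows for automatic region inference.
#' @param dialect site-table dialect when \code{sites} is a path.
#' @param outDir optional output directory.
#' @return A list of class \code{"polyACharacterization"}: \code{windows},
#'   \code{report}, \code{profile}, \code{regions}, \code{scans} (list
#'   fue/nue/ce), \code{zscores}, \code{dinucleotide},
#'   \code{variantGroups}, \code{pfms}, \code{canonical}, \code{manifest}.
#' @export
characterize <- function(genome = NULL, sites = NULL, windows = NULL,
                         regions = NULL, kMin = 3L, kMax = 8L,
                         mode = "gap", gap = NULL, topN = 50L,
                         variantTopN = 100L, minWindows = 50L,
                         dialect = "tsv", outDir = NULL) {
  nDupCollapsed <- 0L
  nOOB <- 0L
  if (is.null(windows)) {
    if (is.null(genome) || is.null(sites))
      stop("provide either windows, or genome plus sites")
    if (is.character(genome)) genome <- readGenome(genome)
    if (is.character(sites)) sites <- readSites(sites, dialect)
    nInput <- length(sites)
    uniq <- dedupeSites(sites)
    nDupCollapsed <- nInput - length(uniq)
    ws <- extractWindows(genome, uniq)
    nOOB <- nrow(droppedSites(ws))
  } else {
    if (is.character(windows)) windows <- readWindows(windows)
    ws <- windows
    nInput <- length(ws)
  }
  fw <- filterWindows(ws)
  report <- FilterReport(nInput = nInput,
                         nInternalPriming = sum(fw$flagged),
                         nDuplicatesCollapsed = nDupCollapsed,
                         nOutOfBounds = nOOB)
  x <- fw$windows
  if (length(x) == 0L) stop("no windows retained after filtering")
  prof <- nucleotideProfile(x)
  regs <- if (is.null(regions)) {
    inferRegions(prof, minWindows = minWindows)
  } else regions
  scans <- list(fue = scanRegion(x, fueRegion(regs), kMin, kMax, mode, gap),
                nue = scanRegion(x, nueRegion(regs), kMin, kMax, mode, gap),
                ce = scanRegion(x, ceRegion(regs), kMin, kMax, mode, gap))
  ## Z-scores for the top NUE motifs of every length, observed counts from
  ## a single overlap-mode scan so that expectation and observation agree
  nueOv <- scanRegion(x, nueRegion(regs), kMin, kMax, "overlap")
  zrows <- list()
  for (k in seq.int(max(kMin, 3L), min(kMax, 8L))) {
    tk <- topMotifs(scans$nue, min(topN, 10L), k)
    if (!nrow(tk)) next
    obs <- nueOv$total_occurrences[match(tk$motif, nueOv$motif)]
    obs[is.na(obs)] <- 0L
    zrows[[as.character(k)]] <-
      motifZScore(x, nueRegion(regs), tk$motif, observed = obs)
  }
  zscores <- do.call(rbind, zrows)
  rownames(zscores) <- NULL
  dinuc <- cleavageDinucleotide(x)
  groups <- list(UGUAA = compileVariantGroup(scans$nue, "UGUAA", variantTopN),
                 AAUAAA = compileVariantGroup(scans$nue, "AAUAAA",
                                              variantTopN))
  pfms <- lapply(groups, function(g)
    if (sum(variantMembers(g)$frequency_pct) > 0) buildPFM(g) else NULL)
  canon <- canonicalSignalFrequencies(x)
  manifest <- c(reportCounts(report),
                n_windows_analyzed = length(x),
                k_min = as.integer(kMin), k_max = as.integer(kMax),
                nue_start = regionStart(nueRegion(regs)),
                nue_end = regionEnd(nueRegion(regs)),
                fue_start = regionStart(fueRegion(regs)),
                fue_end = regionEnd(fueRegion(regs)))
  res <- list(windows = x, report = report, profile = prof, regions = regs,
              scans = scans, zscores = zscores, dinucleotide = dinuc,
              variantGroups = groups, pfms = pfms, canonical = canon,
              manifest = manifest,
              parameters = list(mode = mode, gap = gap, topN = topN,
                                variantTopN = variantTopN))
  class(res) <- "polyACharacterization"
  if (!is.null(outDir)) writeCharacterization(res, outDir)
  res
}

#' @export
print.polyACharacterization <- function(x, ...) {
  cat("poly(A) signal characterization\n")
  print(reportCounts(x$report))
  show(x$regions)
  top <- topMotifs(x$scans$nue, 3L, 5L)
  cat("Top NUE pentamers:",
      paste(sprintf("%s (%.1f%%)", top$motif, top$frequency_pct),
            collapse = ", "), "\n")
  invisible(x)
}

## write one TSV per stage plus a key=value manifest
writeCharacterization <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeWindows(res$windows, file.path(outDir, "windows.fa"))
  tsv(data.frame(metric = names(reportCounts(res$report)),
                 value = as.integer(reportCounts(res$report))),
      "filter_report.tsv")
  prof <- res$profile
  tsv(data.frame(position = as.integer(colnames(prof)),
                 fA = prof["A", ], fC = prof["C", ],
                 fG = prof["G", ], fU = prof["U", ]),
      "profile.tsv")
  regs <- res$regions
  tsv(data.frame(
    label = c("FUE", "NUE", "CE"),
    start = c(regionStart(fueRegion(regs)), regionStart(nueRegion(regs)),
              regionStart(ceRegion(regs))),
    end = c(regionEnd(fueRegion(regs)), regionEnd(nueRegion(regs)),
            regionEnd(ceRegion(regs))),
    provenance = regionProvenance(regs)),
    "regions.tsv")
  for (nm in names(res$scans))
    tsv(res$scans[[nm]], paste0("scan_", nm, ".tsv"))
  if (!is.null(res$zscores)) tsv(res$zscores, "zscores.tsv")
  tsv(res$dinucleotide$table, "dinucleotide.tsv")
  for (nm in names(res$variantGroups)) {
    g <- res$variantGroups[[nm]]
    tsv(variantMembers(g), paste0("variants_", nm, ".tsv"))
    if (!is.null(res$pfms[[nm]])) {
      pfm <- as.data.frame(res$pfms[[nm]])
      names(pfm) <- paste0("pos", seq_len(ncol(pfm)))
      tsv(cbind(base = rownames(res$pfms[[nm]]), pfm),
          paste0("pfm_", nm, ".tsv"))
    }
  }
  tsv(res$canonical, "canonical_signals.tsv")
  writeLines(sprintf("%s=%s", names(res$manifest),
                     as.character(res$manifest)),
             file.path(outDir, "manifest.txt"))
  invisible(outDir)
}
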