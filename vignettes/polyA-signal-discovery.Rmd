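---
title: "Characterizing polyadenylation signals with polyAsig"
author: "polyAsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing polyadenylation signals with polyAsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAsig)
```

# The model

mRNA 3'-end formation is directed by *cis*-elements around the cleavage
(poly(A)) site. polyAsig analyses them in a fixed site-relative frame: the
cleavage base is position **−1**, the first downstream base is **+1**, and
there is no position 0. Windows default to 300 nt upstream and 100 nt
downstream (400 nt total); windows that would run past a contig end are
dropped rather than padded, so every per-transcript frequency has the same
full-length denominator. Minus-strand windows are reverse-complemented so
that every window reads 5'→3' of the transcript. Sequences are handled as
DNA internally; every reported motif, profile row and matrix uses the RNA
alphabet, matching how poly(A) signals are written in the literature.

Three element regions structure the analysis: the far upstream element
(FUE, diffuse, U- or G-rich), the near upstream element (NUE, the
AAUAAA/UGUAA-class signal region roughly 10–35 nt upstream) and the
cleavage element (CE), fixed by convention at −10..+10.

# Internal-priming filtering

An oligo(dT)-primed cDNA can anneal to a genomic A-run and mimic a real
poly(A) tail. A window is treated as an internal-priming candidate when
the genomic bases at −10..+10 (20 bases) contain **(a)** a run of at least
6 consecutive A, or **(b)** at least 7 A within any 10-nt window fully
inside −10..+10 (11 windows, step 1). We read the "−10/+10 region" as
these 20 bases — positions −10..−1 and +1..+10 — and allow an A-run to
straddle the cleavage site, since the artifact does not respect the
cleavage position. N and any non-A character count as non-A, so masked
sequence never causes a flag (conservative retention). Both rules are
monotone in A-content and the filter is idempotent.

# Motif scanning

`scanRegion()` enumerates every k-mer (default 3–8 nt) observed inside a
region and reports, per motif, the number of windows with at least one
in-region occurrence, the per-transcript frequency (percent of windows),
and total occurrences under one of three counting modes:

* **overlap** — every match start counts;
* **gap** — greedy left-to-right: after a match at p, the next acceptable
  start is p + gap + 1. With gap = k − 1 (the default) this is the
  standard greedy non-overlapping count, which prevents a self-overlapping
  word such as AUAUAU from being counted twice in ...AUAUAUAU...;
* **once** — at most one occurrence per window, the one closest to the
  poly(A) site.

Reported frequencies use gap mode with gap = k − 1: per-transcript
detection is the quantity of interest and overlap counting would inflate
self-overlapping words. A match is in-region only when the *full* motif
lies inside the region — no straddling — which keeps region counts
additive and unambiguous. Only observed k-mers are enumerated (hash
counting); the result is identical to enumerating all 4^k words, at
linear memory.

Tie-breaks are fully specified: ranking orders by frequency, then total
occurrences, then lexicographically. In once mode, "closest to the site"
means the rightmost start in an upstream region and the leftmost in a
downstream one; in a region straddling the site (the CE), the smallest
|position| wins and an exact tie (e.g. −2 vs +2) resolves upstream. Ties
are impossible in purely upstream or downstream regions because starts are
distinct.

# Background models and Z-scores

Over-representation is scored against an order-m Markov chain fitted to
the scanned region itself, as in oligo-analysis practice: expectation
comes from the input sequences. Transition probabilities are ML
frequencies over all in-region (m+1)-mers with an **add-0.25 pseudocount
per cell** — P(b|c) = (n(cb) + 0.25)/(n(c·) + 1) — so unseen contexts fall
back to uniform rather than zero; the initial m-mer distribution is
fitted the same way. Word probabilities therefore sum exactly to 1 over
all 4^k words, a property the tests verify exhaustively for k ≤ 6.

For a motif of length k observed O times (overlap mode) over T = windows
× (L − k + 1) start positions, with p its word probability:

E = Tp, sd = √(Tp(1 − p)), Z = (O − E)/sd.

Three choices deserve note:

* **Binomial variance.** The variance ignores word self-overlap
  autocorrelation (the Guibas–Odlyzko correction). The binomial form is
  the documented default of the standard regulatory-sequence tools, is
  testable in closed form, and errs conservatively for the A/U-rich words
  at issue. Exact overlap-aware distributions are a known limitation.
* **Overlap-mode observed counts.** The binomial expectation ranges over
  all start positions, so mixing a non-overlap count with it would bias Z
  downward. Reported *frequencies* use gap mode; Z-scores use overlap.
* **Length policy.** Triplets and tetramers are scored against an order-1
  model with cutoff Z ≥ 5 (short words are well described by low-order
  dependence, and the higher cutoff guards their larger expected counts);
  pentamers–octamers use an order-3 model with cutoff Z ≥ 3.

Because the background is trained on the same region being scanned, a
strongly planted motif inflates its own expectation somewhat; Z-scores are
therefore conservative, which is visible in the parameter-recovery tests
(the planted pentamer's Z grows like √n and clears the cutoff from about a
thousand windows at π = 0.5). A degenerate background (p ∈ {0, 1}) is an
error, not a silent division by zero.

# Profiles and region inference

`nucleotideProfile()` gives per-position base frequencies (N excluded from
the column denominator). `inferRegions()` reconstructs the element layout
from it:

* **NUE** starts at the first A/U crossing found in −45..−20 and ends at
  the last crossing in −20..−5, with fallbacks −30 and −10 — the
  conventional approximate bounds — when no crossing exists. The search
  windows bracket "around −30" and "around −10" generously.
* A crossing is a sign change of freq(A) − freq(U) between adjacent
  positions, reported on the **A-dominant side** of the pair (the
  position entering A dominance for an upward crossing, the last
  A-dominant position for a downward one); exact equality through which
  the profile passes is reported at that position, while a flat stretch
  of equality is not a crossing. This convention makes the inferred NUE
  exactly the A-dominant segment of the profile.
* Crossing detection uses a centered moving average (default width 5)
  because empirical profiles are noisy; the FUE dominance test below uses
  the raw profile, since it already requires sustained dominance.
* **FUE** runs from the 5'-most position where G or U is *dominant* —
  exceeding every other base by ≥ 0.05 for ≥ 20 consecutive positions —
  down to one base before the NUE start, falling back to −200 when no
  sustained dominance exists. "Dominant" is not quantitatively defined in
  the field; we operationalize it as a sustained margin because
  profile dominance in real data is a plateau, not a spike, and both the
  margin and the run length are exposed as parameters.
* If a positional distribution of a candidate signal is supplied, the NUE
  is widened stepwise (toward the side with more remaining mass) until it
  covers ≥ 90% of that motif's occurrences.
* **CE** is fixed at −10..+10. Region inference requires ≥ 50 windows by
  default; below that the profile is too noisy for crossing detection and
  the function insists on manual regions.

`cleavageDinucleotide()` tallies the −2/−1 dinucleotide and its YA
(UA+CA) and BA (UA+CA+GA) aggregates; BA − YA = f(GA) holds by
construction.

# Variant groups, PFMs and PSSMs

`enumerateSNV()` lists all 3k Hamming-distance-1 variants of a canonical
signal. `compileVariantGroup()` collects the canonical plus those variants
present in the top 100 ranks of a motif table (variants are rare enough
that a top-50 cut would miss them); the combined frequency is the plain
sum of member frequencies, reproducing the usual "overall frequency"
tabulation even though a transcript can carry two members — no de-overlap
correction is applied. The PFM weights member base-vectors by their
per-transcript frequencies (logo construction "by frequency", not by raw
occurrence counts). The PSSM applies a 0.01 pseudocount per PFM cell,
renormalizes columns, and takes log2 odds against a base background;
scores are additive over positions and the expected score under the
background is non-positive.

`canonicalSignalFrequencies()` reports UGUAA over −80..−15 and AAUAAA
over −50..−15, the fixed intervals used to place species on a
UGUAA/AAUAAA comparison plane.

# The synthetic generator

`simulateWindows()` emulates the statistical architecture the analysis
assumes, with defaults chosen once as the package's study conditions:

| block | positions | A / C / G / U |
|---|---|---|
| upstream background | −300..−181 | .30 / .20 / .20 / .30 |
| FUE (U-dominant) | −180..−33 | .15 / .15 / .25 / .45 |
| NUE (A-peaked) | −32..−12 | .50 / .15 / .15 / .20 |
| CE background | −11..+10 | .05 / .30 / .20 / .45 |
| downstream background | +11..+100 | .30 / .20 / .20 / .30 |

UGUAA is planted at π = 0.5, start uniform in −30..−15; CA is written at
−2/−1 with probability 0.55; internal-priming decoys (a 6-nt A-run fully
inside −10..+10) default to probability 0 and are switched on where a test
exercises the filter. The FUE margin (U ahead by 0.20) and the NUE/CE
composition flips at −33|−32 and −12|−11 are large relative to sampling
noise at the problem sizes used, so region inference is a sharp test, and
the A-poor CE background makes spontaneous internal-priming false
positives negligible (probability < 10⁻⁵ per window), so the filter can be
tested for *exact* agreement with the decoy truth table. Planting
overwrites background bases (no insertion), keeping windows at 400 nt.
Each site occupies its own contig with the window flush to the contig
ends, so extraction never truncates; strands are assigned 50/50 and EST
support is 1 + Poisson(1). Everything is drawn from a single seed; the
generator snapshots and restores the caller's RNG state.

`expectedFrequency()` provides the analytic per-transcript detection
probability 1 − (1 − πc)·∏(1 − p(s)), where c is the fraction of plant
starts fully inside the scan region and p(s) the composition probability
of the motif at region start s. Start positions are treated as
independent, so this is an estimate good to well under one standard error
at the tested sizes, not an exact value.

What the generator does **not** emulate: positional dependence within
blocks (real profiles ramp smoothly rather than switching at block
boundaries), correlated occurrences of distinct signals, alternative
polyadenylation site clusters, EST mapping noise, and species-specific
profile shapes. Tests passing on generator output therefore validate the
algorithms under their stated assumptions; they do not certify behavior on
any particular genome.

# Numerical choices and problem sizes

Pseudocounts: 0.25 per Markov cell, 0.01 per PFM cell. Transition-row and
PFM-column sums are validated to 1e−9. The exact BA − YA = f(GA) identity
is asserted at 1e−12 (floating-point addition ordering). Test problem
sizes were chosen for statistical adequacy: the exhaustive counting-mode
oracle covers all ~10⁶ (sequence, motif) pairs up to length 12 over a
two-letter alphabet; stochastic checks use 600–2,000 simulated sites,
where 3-standard-error bands make planted rates and compositions sharp;
the end-to-end recovery runs at 2,000 sites, where the planted pentamer's
Z-score comfortably clears its cutoff. The acceptance script re-runs the
full pipeline at 2,000 sites with 30% decoys and 5% duplicate rows.

# Known limitations

* Z-scores ignore word-overlap autocorrelation and multiple testing
  across the 4^k family; reported counts are descriptive.
* The per-region background is also the scanned region, so a dominant
  planted signal raises its own expectation (conservative Z).
* Degenerate-alphabet (IUPAC) motif patterns and EM/Gibbs motif discovery
  are out of scope, as are EST trace processing and EST-to-genome
  alignment.
* Logo and profile rendering are left to dedicated tools; the package
  emits the matrices they consume.
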