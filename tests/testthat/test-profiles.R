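test_that("nucleotide profiles are per-position base frequencies", {
  pA <- nucleotideProfile(makeWindows(strrep("A", 400)))
  expect_true(all(pA["A", ] == 1))
  expect_identical(rownames(pA), c("A", "C", "G", "U"))
  # half A, half T at every position
  p2 <- nucleotideProfile(makeWindows(c(strrep("A", 400), strrep("T", 400))))
  expect_true(all(p2["A", ] == 0.5))
  expect_true(all(p2["U", ] == 0.5))
  # columns are probability vectors
  x <- randWindows(25, seed = 2)
  p <- nucleotideProfile(x)
  expect_true(all(abs(colSums(p) - 1) < 1e-9))
  # N is excluded from the denominator
  wN <- makeWindows(paste0("N", strrep("A", 399)))
  pN <- nucleotideProfile(wN)
  expect_true(is.na(pN["A", "-300"]))
  expect_error(nucleotideProfile(x[0]), "empty")
})

test_that("concatenating window sets mixes their profiles by weight", {
  a <- randWindows(10, seed = 4)
  b <- randWindows(30, seed = 8, probs = c(A = .7, C = .1, G = .1, T = .1))
  ab <- makeWindows(c(as.character(windowSeqs(a)),
                      as.character(windowSeqs(b))))
  pa <- nucleotideProfile(a); pb <- nucleotideProfile(b)
  pab <- nucleotideProfile(ab)
  expect_equal(pab, (10 * pa + 30 * pb) / 40, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("A/U crossings are located analytically", {
  # A ramps 0.1 -> 0.9 while U ramps 0.9 -> 0.1 linearly over -40..-5;
  # the single crossing sits at the midpoint, entering A dominance at -22
  fA <- rep(0.1, 400); fU <- rep(0.9, 400)
  ramp <- seq(0.1, 0.9, length.out = 36)
  idx <- posToIndex(-40):posToIndex(-5)
  fA[idx] <- ramp
  fU[idx] <- 1 - ramp
  prof <- profileMatrix(fA, rep(0, 400), rep(0, 400), fU)
  cr <- findAUCrossings(prof, -40, -5)
  expect_identical(cr, -22L)
  # constant A > U everywhere: no crossing
  flatA <- profileMatrix(rep(.4, 400), rep(.2, 400), rep(.2, 400),
                         rep(.2, 400))
  expect_length(findAUCrossings(flatA, -45, -5), 0)
  # a crossing passing exactly through equality at p is reported at p
  fA2 <- rep(0.2, 400); fU2 <- rep(0.4, 400)
  after <- posToIndex(-19):400
  fA2[after] <- 0.4; fU2[after] <- 0.2
  fA2[posToIndex(-20)] <- 0.3; fU2[posToIndex(-20)] <- 0.3
  profEq <- profileMatrix(fA2, rep(.2, 400), 1 - fA2 - fU2 - 0.2, fU2)
  expect_identical(findAUCrossings(profEq, -25, -15), -20L)
})

test_that("regions are inferred from the generator architecture", {
  sim <- simulateWindows(simConfig(nSites = 1500, seed = 17))
  ws <- extractWindows(sim$genome, sim$sites)
  regs <- inferRegions(nucleotideProfile(ws))
  expect_equal(regionStart(nueRegion(regs)), -32L)
  expect_equal(regionEnd(nueRegion(regs)), -12L)
  expect_equal(regionStart(fueRegion(regs)), -180L)
  expect_equal(regionEnd(fueRegion(regs)), -33L)
  expect_equal(regionStart(ceRegion(regs)), -10L)
  expect_equal(regionEnd(ceRegion(regs)), 10L)
  expect_identical(regionProvenance(regs), "auto")
  # the inferred NUE covers the planting interval used by the generator
  expect_lte(posToIndex(-32L), posToIndex(-30L))
})

test_that("flat profiles trigger the documented fallbacks", {
  flat <- profileMatrix(rep(.25, 400), rep(.25, 400), rep(.25, 400),
                        rep(.25, 400))
  regs <- inferRegions(flat)
  expect_equal(regionStart(nueRegion(regs)), -30L)
  expect_equal(regionEnd(nueRegion(regs)), -10L)
  expect_equal(regionStart(fueRegion(regs)), -200L)
  expect_equal(regionEnd(fueRegion(regs)), -31L)
})

test_that("too few windows is an error and manual regions pass through", {
  p <- nucleotideProfile(randWindows(10, seed = 1))
  expect_error(inferRegions(p), "manually")
  manual <- RegionSet(fue = Region(-150, -36, "FUE"),
                      nue = Region(-35, -10, "NUE"))
  expect_identical(regionProvenance(manual), "manual")
  expect_equal(regionStart(nueRegion(manual)), -35L)
})

test_that("NUE bounds widen to cover a supplied motif distribution", {
  flat <- profileMatrix(rep(.25, 400), rep(.25, 400), rep(.25, 400),
                        rep(.25, 400))
  # put 95% of the mass at -40, outside the fallback NUE of -30..-10
  dist <- data.frame(position = c(-40L, -20L), count = c(95L, 5L))
  regs <- inferRegions(flat, motifDistribution = dist)
  expect_lte(posToIndex(regionStart(nueRegion(regs))), posToIndex(-40L))
})

test_that("cleavage dinucleotide aggregates obey their identities", {
  # every window ends its upstream segment in CA
  allCA <- makeWindows(replicate(5, windowWith(list(at = -2, seq = "CA"))))
  d <- cleavageDinucleotide(allCA)
  expect_equal(d$table$frequency[d$table$dinucleotide == "CA"], 1)
  expect_equal(d$YA, 1)
  expect_equal(d$BA, 1)
  # 50% GA / 50% AA: BA = 0.5, YA = 0
  half <- makeWindows(c(windowWith(list(at = -2, seq = "GA")),
                        windowWith(list(at = -2, seq = "AA"))))
  dh <- cleavageDinucleotide(half)
  expect_equal(dh$BA, 0.5)
  expect_equal(dh$YA, 0)
  # BA - YA = f(GA) on arbitrary windows, and frequencies sum to 1
  x <- randWindows(60, seed = 9)
  dx <- cleavageDinucleotide(x)
  fGA <- dx$table$frequency[dx$table$dinucleotide == "GA"]
  expect_equal(dx$BA - dx$YA, fGA)
  expect_equal(sum(dx$table$frequency), 1)
  # N at -2/-1 is excluded and counted
  wN <- makeWindows(c(windowWith(list(at = -2, seq = "NA")),
                      windowWith(list(at = -2, seq = "CA"))))
  dn <- cleavageDinucleotide(wN)
  expect_equal(dn$nExcluded, 1L)
  expect_equal(dn$table$frequency[dn$table$dinucleotide == "CA"], 1)
})
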