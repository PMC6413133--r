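test_that("counting modes agree with the worked examples", {
  # non-overlapping (gap = k-1) counting collapses an overlapping pair
  expect_equal(countOccurrences("ATATATAT", "ATATAT", "gap", gap = 5)$count, 1)
  ov <- countOccurrences("ATATATAT", "ATATAT", "overlap")
  expect_equal(ov$count, 2)
  expect_identical(ov$starts, c(1L, 3L))
  # greedy left-to-right: the start-5 match is blocked by the start-1 match
  expect_equal(countOccurrences("AATAAATAAA", "AAUAAA", "gap", gap = 5)$count,
               1)
  expect_equal(countOccurrences("AATAAATAAA", "AAUAAA", "overlap")$count, 2)
  # once keeps the rightmost (poly(A)-proximal) match
  on <- countOccurrences("ATATATAT", "ATATAT", "once")
  expect_equal(on$count, 1)
  expect_identical(on$starts, 3L)
  # RNA/DNA input equivalence
  expect_equal(countOccurrences("AUAUAUAU", "ATATAT", "gap")$count, 1)
  # motif longer than sequence is simply absent
  expect_equal(countOccurrences("ACG", "ACGT", "overlap")$count, 0)
  expect_error(countOccurrences("ACGT", "AXG"), "A,C,G,T")
})

test_that("mode inequalities and gap=0 equivalence hold on random sequences", {
  set.seed(7)
  for (i in 1:60) {
    s <- paste(sample(c("A", "T", "G"), sample(8:30, 1), TRUE), collapse = "")
    m <- paste(sample(c("A", "T"), sample(2:4, 1), TRUE), collapse = "")
    on <- countOccurrences(s, m, "once")$count
    g <- countOccurrences(s, m, "gap")$count
    o <- countOccurrences(s, m, "overlap")$count
    expect_lte(on, g)
    expect_lte(g, o)
    expect_equal(countOccurrences(s, m, "gap", gap = 0)$count, o)
    expect_equal(g, greedyOracle(s, m))
  }
})

test_that("scanRegion tabulates per-transcript frequencies and occurrences", {
  # a region that is exactly TGTAA gives a one-row pentamer table
  w1 <- makeWindows(windowWith(list(at = -35, seq = "TGTAA")))
  tab <- scanRegion(w1, Region(-35, -31), kMin = 5, kMax = 5)
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$motif, "UGUAA")
  expect_equal(tab$frequency_pct, 100)
  expect_equal(tab$total_occurrences, 1L)

  # all four windows carry UAA in the region -> 100%
  w4 <- makeWindows(replicate(4, windowWith(list(at = -25, seq = "TAA"))))
  t4 <- scanRegion(w4, Region(-35, -10), kMin = 3, kMax = 3)
  expect_equal(t4$frequency_pct[t4$motif == "UAA"], 100)

  # one window with two non-overlapping copies: 1 hit window, 2 occurrences
  w2 <- makeWindows(c(
    windowWith(list(at = -30, seq = "TGTAA"), list(at = -20, seq = "TGTAA")),
    windowWith()))
  t2 <- scanRegion(w2, Region(-35, -10), kMin = 5, kMax = 5, mode = "gap")
  row <- t2[t2$motif == "UGUAA", ]
  expect_equal(row$n_seqs_with_hit, 1L)
  expect_equal(row$total_occurrences, 2L)
  expect_equal(row$frequency_pct, 50)

  expect_error(scanRegion(w1[0], Region(-35, -10)), "empty")
  # in-region membership needs the full motif inside the region
  wEdge <- makeWindows(windowWith(list(at = -12, seq = "TGTAA")))
  tEdge <- scanRegion(wEdge, Region(-35, -10), kMin = 5, kMax = 5)
  expect_false("UGUAA" %in% tEdge$motif)
})

test_that("frequencies are order-invariant and counts additive", {
  x <- randWindows(40, seed = 11)
  reg <- Region(-35, -10)
  tab <- scanRegion(x, reg, kMin = 3, kMax = 3)
  perm <- x[sample(40)]
  tabP <- scanRegion(perm, reg, kMin = 3, kMax = 3)
  tabP <- tabP[match(tab$motif, tabP$motif), ]
  expect_equal(tab$frequency_pct, tabP$frequency_pct)
  expect_equal(tab$total_occurrences, tabP$total_occurrences)
  # additivity over disjoint subsets
  t1 <- scanRegion(x[1:15], reg, kMin = 3, kMax = 3)
  t2 <- scanRegion(x[16:40], reg, kMin = 3, kMax = 3)
  joint <- merge(t1[, c("motif", "total_occurrences")],
                 t2[, c("motif", "total_occurrences")],
                 by = "motif", all = TRUE)
  joint[is.na(joint)] <- 0L
  both <- joint$total_occurrences.x + joint$total_occurrences.y
  expect_equal(both[match(tab$motif, joint$motif)], tab$total_occurrences)
})

test_that("topMotifs ranks by frequency with documented tie-breaks", {
  tab <- data.frame(
    motif = c("AAA", "CCC", "GGG", "UUU"), k = 3L,
    n_seqs_with_hit = c(4L, 3L, 3L, 3L),
    frequency_pct = c(40, 30, 30, 30),
    total_occurrences = c(5L, 9L, 3L, 3L), rank = NA_integer_)
  top <- topMotifs(tab, 3, 3)
  expect_identical(top$motif, c("AAA", "CCC", "GGG"))
  expect_identical(top$rank, 1:3)
  # n larger than the table returns everything
  expect_equal(nrow(topMotifs(tab, 99, 3)), 4L)
  expect_error(topMotifs(tab, 0, 3), ">= 1")
})

test_that("positional distributions sit in the site frame and sum to scan totals", {
  n <- 50
  x <- makeWindows(replicate(n, windowWith(list(at = -25, seq = "TGTAA"))))
  pd <- positionalDistribution(x, "UGUAA", mode = "gap")
  expect_equal(pd$count[pd$position == -25], n)
  expect_equal(sum(pd$count), n)
  # absent motif gives an all-zero vector
  pd0 <- positionalDistribution(x, "AAAAAA", mode = "gap")
  expect_true(all(pd0$count == 0))
  # region-restricted sum equals the scan table total, same mode
  y <- randWindows(30, seed = 3, probs = c(A = .4, C = .1, G = .1, T = .4))
  reg <- Region(-35, -10)
  for (mode in c("gap", "overlap", "once")) {
    tab <- scanRegion(y, reg, kMin = 3, kMax = 3, mode = mode)
    pdm <- positionalDistribution(y, "AUA", region = reg, mode = mode)
    expect_equal(sum(pdm$count),
                 tab$total_occurrences[tab$motif == "AUA"])
  }
})

test_that("once mode picks the poly(A)-proximal occurrence per region side", {
  w <- makeWindows(windowWith(list(at = -30, seq = "TGTAA"),
                              list(at = -20, seq = "TGTAA")))
  pd <- positionalDistribution(w, "UGUAA", region = Region(-35, -10),
                               mode = "once")
  expect_equal(pd$count[pd$position == -20], 1L)
  expect_equal(sum(pd$count), 1L)
  # downstream region: closest to the site means leftmost
  wd <- makeWindows(windowWith(list(at = 5, seq = "TGTAA"),
                               list(at = 50, seq = "TGTAA")))
  pdd <- positionalDistribution(wd, "UGUAA", region = Region(1, 100),
                                mode = "once")
  expect_equal(pdd$count[pdd$position == 5], 1L)
  expect_equal(sum(pdd$count), 1L)
})
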