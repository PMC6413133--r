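test_that("the order/cutoff policy follows motif length", {
  expect_equal(significancePolicy(3), list(order = 1L, cutoff = 5.0))
  expect_equal(significancePolicy(4), list(order = 1L, cutoff = 5.0))
  expect_equal(significancePolicy(5), list(order = 3L, cutoff = 3.0))
  expect_equal(significancePolicy(8), list(order = 3L, cutoff = 3.0))
  expect_error(significancePolicy(2), "3..8")
  expect_error(significancePolicy(9), "3..8")
})

test_that("fitMarkov learns transition structure", {
  # an all-A region is (up to pseudocount) a deterministic chain A->A
  wA <- makeWindows(rep(strrep("A", 400), 3))
  bg <- fitMarkov(wA, Region(-35, -10), order = 1)
  expect_gt(bg@transitions["A", "A"], 0.98)
  expect_lt(bg@transitions["A", "C"], 0.01)
  expect_gt(wordProbability(bg, "AAA"), 0.95)
  expect_lt(wordProbability(bg, "AAC"), 0.02)
  # unseen contexts fall back to the uniform pseudocount
  expect_equal(unname(bg@transitions["C", ]), rep(0.25, 4))
  # region shorter than order+1 is an error
  expect_error(fitMarkov(wA, Region(-3, -1), order = 3), "shorter")
})

test_that("fitted transitions approach the truth on i.i.d. uniform data", {
  x <- randWindows(400, seed = 21)
  bg <- fitMarkov(x, Region(-300, 100, "window"), order = 1)
  expect_true(all(abs(bg@transitions - 0.25) < 0.01))
})

test_that("word probabilities are a distribution over k-mers", {
  uniformBg <- function(order) {
    ctx <- polyAsig:::allContexts(order)
    new("MarkovBackground", order = as.integer(order),
        initial = stats::setNames(rep(1 / length(ctx), length(ctx)), ctx),
        transitions = matrix(0.25, length(ctx), 4,
                             dimnames = list(ctx, c("A", "C", "G", "T"))),
        trainedOn = "uniform", nTrain = 0L)
  }
  bg1 <- uniformBg(1)
  expect_equal(wordProbability(bg1, "UGUAA"), 0.25^5)
  expect_equal(wordProbability(bg1, "AAUAAA"), 0.25^6)
  expect_error(wordProbability(uniformBg(3), "AC"), "shorter")
  # for a *fitted* model, probabilities over all 4^k words sum to 1
  x <- randWindows(30, seed = 5, probs = c(A = .4, C = .3, G = .2, T = .1))
  for (ord in c(0, 1, 2)) {
    bg <- fitMarkov(x, Region(-40, -10), order = ord)
    for (k in (ord + 1):4) {
      words <- enumSeqs(k, c("A", "C", "G", "T"))
      expect_equal(sum(vapply(words, function(w) wordProbability(bg, w),
                              numeric(1))), 1, tolerance = 1e-9)
    }
  }
})

test_that("the Z-score matches its closed form and is antisymmetric", {
  # frozen arithmetic: T = 1000 starts, p = 0.25^3, O = 100
  ctx <- polyAsig:::allContexts(1)
  bgU <- new("MarkovBackground", order = 1L,
             initial = stats::setNames(rep(0.25, 4), ctx),
             transitions = matrix(0.25, 4, 4,
                                  dimnames = list(ctx, c("A", "C", "G", "T"))),
             trainedOn = "uniform", nTrain = 0L)
  # 250 windows x (6 - 3 + 1) starts = 1000 positions
  x <- makeWindows(rep(strrep("G", 400), 250))
  reg <- Region(-8, -3)
  z <- motifZScore(x, reg, "AAA", background = bgU, observed = 100L,
                   order = 1L, cutoff = 5)
  expect_equal(z$expected, 15.625)
  expect_equal(z$sd, sqrt(1000 * 0.25^3 * (1 - 0.25^3)))
  expect_equal(z$z, (100 - 15.625) / sqrt(1000 * 0.25^3 * (1 - 0.25^3)),
               tolerance = 1e-9)
  expect_true(z$significant)
  # z = 0 exactly when O = E
  z0 <- motifZScore(x, reg, "AAA", background = bgU, observed = 15.625,
                    order = 1L, cutoff = 5)
  expect_equal(z0$z, 0)
  # antisymmetry: O <-> 2E - O negates z
  zm <- motifZScore(x, reg, "AAA", background = bgU,
                    observed = 2 * 15.625 - 100, order = 1L, cutoff = 5)
  expect_equal(zm$z, -z$z)
})

test_that("a degenerate background is rejected", {
  wA <- makeWindows(rep(strrep("A", 400), 5))
  bg <- fitMarkov(wA, Region(-35, -10), order = 0)
  # force p = 1 via a handcrafted deterministic model
  det <- new("MarkovBackground", order = 0L,
             initial = stats::setNames(1, ""),
             transitions = matrix(c(1, 0, 0, 0), 1, 4,
                                  dimnames = list("", c("A", "C", "G", "T"))),
             trainedOn = "det", nTrain = 0L)
  expect_error(motifZScore(wA, Region(-35, -10), "AAA", background = det,
                           observed = 10L, order = 0L, cutoff = 5),
               "degenerate")
})

test_that("no motif is spuriously over-represented in null data", {
  x <- randWindows(400, seed = 31)
  reg <- Region(-32, -12, "NUE")
  tab <- scanRegion(x, reg, kMin = 5, kMax = 5, mode = "overlap")
  z <- motifZScore(x, reg, tab$motif,
                   observed = tab$total_occurrences)
  expect_lt(mean(z$significant), 0.05)
})

test_that("a planted signal clears the significance cutoff", {
  sim <- simulateWindows(simConfig(nSites = 700, seed = 13, plantProb = 0.5))
  ws <- extractWindows(sim$genome, sim$sites)
  z <- motifZScore(ws, Region(-32, -12, "NUE"), "UGUAA")
  expect_true(z$significant)
  expect_equal(z$order_used, 3L)
  expect_equal(z$cutoff, 3.0)
})
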