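quietParams <- function(...) {
  # all event probabilities default to zero; override what the case needs
  args <- list(...)
  defaults <- list(pDiv = 0, p0Self = 0.7, pSDeath = 0, pDDeath = 0,
                   pMig = 0, c = 0, b = 0, g = 0, h = 0, n = 9L,
                   horizon = 10, seed = 1L)
  defaults[names(args)] <- args
  do.call(FeedbackParams, defaults)
}

test_that("self-renewal probabilities follow the printed feedback forms", {
  expect_equal(selfRenewalProb(0, 1.6, 0.7), 0.7)
  expect_equal(selfRenewalProb(1, 1.6, 0.7), 0.7 / 2.6)
  expect_equal(selfRenewalProb(1e6, 1.6, 0.7), 0.7 / (1 + 1.6e6))
  z <- seq(0, 10, 0.5)
  expect_true(all(diff(selfRenewalProb(z, 0.5, 0.7)) < 0))
  expect_error(selfRenewalProb(-1, 1, 0.5))

  expect_equal(taSelfRenewalProb(0, 2), 0)
  expect_equal(taSelfRenewalProb(1, 2), 2 / 3)
  expect_gt(taSelfRenewalProb(1e9, 2), 1 - 1e-8)
  w <- seq(0, 10, 0.5)
  expect_true(all(diff(taSelfRenewalProb(w, 2)) > 0))
  expect_error(taSelfRenewalProb(-1, 1))
})

test_that("a lone stem cell with certain division and self-renewal doubles", {
  p <- quietParams(pDiv = 1, p0Self = 1)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 1L), p)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(cellCounts(out@lattice), c(stem = 2L, ta = 0L, diff = 0L))
})

test_that("divisions into occupied spots abort", {
  coords <- as.matrix(expand.grid(4:6, 4:6))
  codes <- ifelse(coords[, 1] == 5 & coords[, 2] == 5, 1L, 3L)
  p <- quietParams(pDiv = 1, p0Self = 1)
  st <- makeState(latticeWith(9, coords, codes), p)
  set.seed(42)
  out <- abmStep(st, p, steps = 5)
  expect_equal(cellCounts(out@lattice), c(stem = 1L, ta = 0L, diff = 8L))
})

test_that("a lone differentiated cell with certain death clears the grid", {
  p <- quietParams(pDDeath = 1)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 3L), p)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(sum(cellCounts(out@lattice)), 0L)
})

test_that("a differentiating stem division converts the mother", {
  # certain division, certain differentiation: one stem becomes two diff
  p <- quietParams(pDiv = 1, p0Self = 0)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 1L), p)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(cellCounts(out@lattice), c(stem = 0L, ta = 0L, diff = 2L))
})

ffQuiet <- function(...) {
  args <- list(...)
  defaults <- list(pDiv = 0, p0Self = 0.8, qDiv = 0, pSDeath = 0,
                   qTDeath = 0, pDDeath = 0, pMig = 0,
                   c = 0, b = 0, g = 0, h = 0,
                   c2 = 0, b2 = 0, g2 = 0, h2 = 2, useFeedback = FALSE,
                   n = 9L, horizon = 10, seed = 1L)
  defaults[names(args)] <- args
  do.call(FeedforwardParams, defaults)
}

test_that("stem differentiation generates two transit-amplifying cells", {
  p <- ffQuiet(pDiv = 1, p0Self = 0)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 1L), p)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(cellCounts(out@lattice), c(stem = 0L, ta = 2L, diff = 0L))
})

test_that("TA fate follows the local feedforward level", {
  # no feedforward factor: terminal differentiation is certain
  p <- ffQuiet(qDiv = 1)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 2L), p)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(cellCounts(out@lattice), c(stem = 0L, ta = 0L, diff = 2L))

  # saturating feedforward factor: self-renewal nearly certain
  w <- matrix(1e9, 9, 9)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 2L), p, wConc = w)
  set.seed(1)
  out <- abmStep(st, p)
  expect_equal(cellCounts(out@lattice), c(stem = 0L, ta = 2L, diff = 0L))
})

test_that("migration moves cells only into empty spots", {
  p <- quietParams(pMig = 1)
  st <- makeState(latticeWith(9, rbind(c(5, 5)), 3L), p)
  set.seed(3)
  out <- abmStep(st, p)
  occ <- occupiedSpots(out@lattice)
  expect_equal(nrow(occ), 1L)
  expect_equal(max(abs(occ - c(5L, 5L))), 1L)  # moved by one spot

  # a full grid leaves nowhere to go
  st <- makeState(matrix(3L, 9, 9), p)
  set.seed(3)
  out <- abmStep(st, p, steps = 3)
  expect_identical(cellStates(out@lattice), matrix(3L, 9, 9))
})

test_that("runs are bit-reproducible given the seed and chunk-invariant", {
  p <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                      pDDeath = 4.17e-3, pMig = 0, c = 8.33, b = 8.3e-3,
                      g = 0.83, h = 4e-3, n = 30L, horizon = 200, seed = 77L)
  r1 <- runFeedbackABM(p)
  r2 <- runFeedbackABM(p)
  expect_identical(timeSeries(r1), timeSeries(r2))
  expect_identical(cellStates(finalState(r1)@lattice),
                   cellStates(finalState(r2)@lattice))
  expect_identical(concentration(finalState(r1)@fieldZ),
                   concentration(finalState(r2)@fieldZ))
  p2 <- p; p2@seed <- 78L
  expect_false(identical(timeSeries(runFeedbackABM(p2)), timeSeries(r1)))

  # chunked stepping reproduces a single long run exactly
  set.seed(77)
  st <- initialState(p)
  a <- runEngineChunks <- abmStep(abmStep(st, p, 120), p, 80)
  expect_identical(cellStates(a@lattice), cellStates(finalState(r1)@lattice))
})

test_that("population changes are bounded by the sampling count", {
  p <- FeedbackParams(pDiv = 0.5, p0Self = 0.7, pSDeath = 0.01,
                      pDDeath = 0.05, pMig = 0.1, c = 1, b = 0.5, g = 0.2,
                      h = 0.5, n = 20L, horizon = 150, seed = 5L)
  s <- timeSeries(runFeedbackABM(p))
  expect_true(all(abs(diff(s$total)) <= pmax(head(s$total, -1), 0)))
  expect_true(all(s[, c("stem", "ta", "diff")] >= 0))
})

test_that("final lattice counts agree with the recorded series", {
  p <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                      pDDeath = 4.17e-3, pMig = 0.2, c = 8.33, b = 8.3e-3,
                      g = 0.83, h = 4e-3, n = 25L, horizon = 300, seed = 9L)
  r <- runFeedbackABM(p)
  last <- tail(timeSeries(r), 1)
  cc <- cellCounts(r)
  expect_equal(unname(cc), c(last$stem, last$ta, last$diff))
})

test_that("subcritical self-renewal leads to extinction", {
  extinct <- vapply(1:10, function(s) {
    p <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.4, pSDeath = 8.3e-5,
                        pDDeath = 4.17e-3, pMig = 0, c = 0, b = 0, g = 0,
                        h = 0, n = 21L, horizon = 5000, seed = 1000L + s)
    sum(cellCounts(runFeedbackABM(p))) == 0L
  }, TRUE)
  expect_gte(sum(extinct), 9L)
})

test_that("without feedback a supercritical population fills the grid", {
  p <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                      pDDeath = 4.17e-3, pMig = 0.3, c = 0, b = 0, g = 0,
                      h = 0, n = 50L, horizon = 4000, seed = 13L)
  r <- runFeedbackABM(p)
  expect_gte(tail(timeSeries(r)$total, 1), 0.8 * 50^2)
})
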