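test_that("presets carry the documented caption parameters", {
  expect_equal(scenarioPreset("fig2a")@h, 4e-3)
  expect_equal(scenarioPreset("fig2b")@h, 1e-3)
  expect_equal(scenarioPreset("fig4b_small")@n, 100L)
  expect_equal(scenarioPreset("fig4b_large")@n, 150L)
  p <- scenarioPreset("fig1a_small")
  expect_equal(c(p@pDiv, p@p0Self, p@pDDeath, p@pMig), c(4.17e-2, 0.7, 8.3e-3, 0.67))
  expect_equal(c(p@c, p@b, p@g, p@h), c(8.33, 4.17, 83.3, 1.6))
  p4 <- scenarioPreset("fig4ai")
  expect_false(p4@useFeedback)
  expect_equal(c(p4@qDiv, p4@c2, p4@b2, p4@g2, p4@h2),
               c(5.83e-2, 0.833, 8.3e-3, 0.417, 2))
  expect_true(scenarioPreset("fig4b_small")@useFeedback)
  expect_error(scenarioPreset("nope"), "available")
})

test_that("the scale option shrinks the grid and horizon but not rates", {
  p0 <- scenarioPreset("fig2a")
  p <- scenarioPreset("fig2a", scale = 0.5)
  expect_equal(p@n, 100L)
  expect_equal(p@horizon, ceiling(p0@horizon * 0.5))
  expect_equal(p@pDiv, p0@pDiv)
  expect_equal(p@g, p0@g)
  # scale never drops below the seed-block requirement
  expect_gte(scenarioPreset("fig2a", scale = 0.01)@n, 9L)
})

test_that("parameter files round-trip", {
  p <- scenarioPreset("fig4b_small")
  path <- tempfile(fileext = ".txt")
  writeParamsFile(p, path)
  vals <- readParamsFile(path)
  expect_equal(vals$p_div, 4.17e-2)
  expect_equal(vals$h2, 2.5)
  p2 <- paramsFromList(vals, model = "feedforward")
  for (s in slotNames(class(p))) expect_equal(slot(p2, s), slot(p, s))
  unlink(path)
})

test_that("replicates are independent but aggregated", {
  p <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                      pDDeath = 4.17e-3, pMig = 0.2, c = 0, b = 0, g = 0,
                      h = 0, n = 20L, horizon = 200, seed = 50L)
  reps <- runReplicates(p, R = 2, baseSeed = 50L)
  expect_length(reps$runs, 2L)
  expect_false(identical(timeSeries(reps$runs[[1]]), timeSeries(reps$runs[[2]])))
  expect_equal(nrow(reps$summary), 201L)
  expect_equal(reps$runs[[1]]@params@seed, 51L)
  expect_equal(reps$runs[[2]]@params@seed, 52L)
  # aggregation equals a direct mean of the two series
  expect_equal(reps$summary$total_mean,
               (timeSeries(reps$runs[[1]])$total +
                timeSeries(reps$runs[[2]])$total) / 2)
})

test_that("a quiescent run satisfies the steady-state criterion immediately", {
  p <- FeedbackParams(pDiv = 0, p0Self = 0.7, n = 12L, horizon = 500,
                      seed = 1L)
  res <- runToSteadyState(p, maxHours = 500, window = 100L, postHours = 50L,
                          chunk = 100L)
  expect_equal(res$steadyAt, 200L)
  expect_equal(tail(timeSeries(res$run)$stem, 1), 49L)
})

test_that("sweeps are deterministic, prefix-stable and well-formed", {
  base <- FeedbackParams(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                         pDDeath = 4.17e-3, pMig = 0, c = 8.33, b = 8.3e-3,
                         g = 0.83, h = 4e-3, n = 20L, horizon = 2000,
                         seed = 1L)
  opts <- list(maxHours = 400, window = 100L, postHours = 50L)
  sw0 <- do.call(sweep2D, c(list(base, "h", c(1e-4, 1e-2), "g", c(0.1, 10),
                                 draws = 0L, baseSeed = 7L), opts))
  expect_equal(nrow(sw0), 0L)
  sw2 <- do.call(sweep2D, c(list(base, "h", c(1e-4, 1e-2), "g", c(0.1, 10),
                                 draws = 2L, baseSeed = 7L), opts))
  sw3 <- do.call(sweep2D, c(list(base, "h", c(1e-4, 1e-2), "g", c(0.1, 10),
                                 draws = 3L, baseSeed = 7L), opts))
  expect_equal(sw3[1:2, ], sw2)
  expect_true(all(sw2$x_value >= 1e-4 & sw2$x_value <= 1e-2))
  expect_true(all(sw2$outcome %in% c("EXTINCT", "UNIFORM", "CLUMPED")))
  expect_true(all(is.na(sw2$i_disp) == (sw2$outcome == "EXTINCT")))

  # collapsed ranges pin the parameters; outcomes vary only through seeds
  swp <- do.call(sweep2D, c(list(base, "h", c(4e-3, 4e-3), "g", c(0.83, 0.83),
                                 draws = 2L, baseSeed = 7L), opts))
  expect_equal(unique(swp$x_value), 4e-3)
  expect_equal(unique(swp$y_value), 0.83)
  expect_equal(swp$seed, c(8, 9))
})

test_that("spec-style parameter keys resolve to slots", {
  base <- scenarioPreset("fig1c_small")
  expect_equal(lineagegrid:::setParam(base, "p_mig", 0.5)@pMig, 0.5)
  expect_equal(lineagegrid:::setParam(base, "b", 0.1)@b, 0.1)
  expect_error(lineagegrid:::setParam(base, "q_div", 0.1), "unknown")
})

test_that("feedback strength orders outcomes uniform -> clumped -> extinct", {
  outcomes <- sapply(c(1e-4, 4e-3, 1), function(h) {
    vapply(1:3, function(s) {
      p <- scenarioPreset("fig3_baseline", seed = 1500L + s)
      p@n <- 50L
      p@h <- h
      res <- runToSteadyState(p, maxHours = 9000, postHours = 300L)
      classifyOutcome(finalState(res$run)@lattice)
    }, "")
  })
  majority <- apply(outcomes, 2L, function(x) names(which.max(table(x))))
  # weak feedback cannot hold the density down: cells fill the grid uniformly;
  # intermediate feedback carves persistent islands; very strong feedback
  # suppresses self-renewal below criticality and the population dies out
  expect_equal(majority, c("UNIFORM", "CLUMPED", "EXTINCT"))
})
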