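presetTable <- function() {
  fb <- function(...) c(list(model = "feedback"), list(...))
  ff <- function(...) c(list(model = "feedforward"), list(...))
  list(
    # fast cell migration and mediator diffusion: well-mixed regime
    fig1a_small = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 0,
                     pDDeath = 8.3e-3, pMig = 0.67, h = 1.6, c = 8.33,
                     b = 4.17, g = 83.3, n = 100L, horizon = 5000),
    fig1a_large = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 0,
                     pDDeath = 8.3e-3, pMig = 0.67, h = 1.6, c = 8.33,
                     b = 4.17, g = 83.3, n = 200L, horizon = 5000),
    # no cell migration, slow mediator diffusion: spatially restricted
    fig1c_small = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                     pDDeath = 4.17e-3, pMig = 0, h = 4.0e-3, c = 8.33,
                     b = 8.3e-3, g = 0.83, n = 100L, horizon = 25000),
    fig1c_large = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
                     pDDeath = 4.17e-3, pMig = 0, h = 4.0e-3, c = 8.33,
                     b = 8.3e-3, g = 0.83, n = 200L, horizon = 25000),
    # strong vs weak feedback under spatial restriction (clumped vs uniform)
    fig2a = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
               pDDeath = 4.17e-3, pMig = 0, h = 4e-3, c = 8.33,
               b = 8.3e-3, g = 0.83, n = 200L, horizon = 25000),
    fig2b = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-5,
               pDDeath = 4.17e-3, pMig = 0, h = 1e-3, c = 8.33,
               b = 8.3e-3, g = 0.83, n = 200L, horizon = 25000),
    # baseline for the two-parameter outcome sweeps (h is varied)
    fig3_baseline = fb(pDiv = 4.17e-2, p0Self = 0.7, pSDeath = 8.3e-4,
                       pDDeath = 4.17e-3, pMig = 0, h = 4e-3, c = 8.33,
                       b = 8.3e-3, g = 0.833, n = 200L, horizon = 25000),
    # feedforward loop only, no stem/TA death: self-limiting structure
    fig4ai = ff(pDiv = 4.17e-2, p0Self = 0.8, qDiv = 5.83e-2, pSDeath = 0,
                qTDeath = 0, pDDeath = 4.17e-3, pMig = 0, c2 = 0.833,
                b2 = 8.3e-3, g2 = 0.417, h2 = 2, useFeedback = FALSE,
                n = 200L, horizon = 50000),
    # feedforward loop only, with stem/TA death: unbounded expansion
    fig4aii = ff(pDiv = 4.17e-2, p0Self = 0.8, qDiv = 5.83e-2,
                 pSDeath = 8.3e-5, qTDeath = 1e-4, pDDeath = 4.17e-3,
                 pMig = 0, c2 = 0.833, b2 = 8.3e-3, g2 = 0.417, h2 = 2,
                 useFeedback = FALSE, n = 200L, horizon = 50000),
    # combined feedback + feedforward: carrying-capacity-independent homeostasis
    fig4b_small = ff(pDiv = 4.17e-2, p0Self = 0.8, qDiv = 5.83e-2,
                     pSDeath = 8.3e-5, qTDeath = 1e-4, pDDeath = 4.17e-3,
                     pMig = 0, c = 8.33, b = 8.33e-2, g = 0, h = 6.0e-2,
                     c2 = 8.33, b2 = 8.33e-2, g2 = 3.33, h2 = 2.5,
                     useFeedback = TRUE, n = 100L, horizon = 876000),
    fig4b_large = ff(pDiv = 4.17e-2, p0Self = 0.8, qDiv = 5.83e-2,
                     pSDeath = 8.3e-5, qTDeath = 1e-4, pDDeath = 4.17e-3,
                     pMig = 0, c = 8.33, b = 8.33e-2, g = 0, h = 6.0e-2,
                     c2 = 8.33, b2 = 8.33e-2, g2 = 3.33, h2 = 2.5,
                     useFeedback = TRUE, n = 150L, horizon = 876000)
  )
}

#' Scenario presets
#'
#' Named parameter sets for the standard simulation scenarios: the well-mixed
#' regime (`fig1a_*`), spatial restriction with density regulation
#' (`fig1c_*`), clumped vs uniform patterning (`fig2a`, `fig2b`), the
#' outcome-sweep baseline (`fig3_baseline`), the feedforward-only structures
#' (`fig4ai`, `fig4aii`) and the combined feedback + feedforward homeostasis
#' scenario (`fig4b_small`, `fig4b_large`). Rate units are per hour.
#'
#' @param name preset name; see Details. Unknown names raise an error listing
#'   the available presets.
#' @param scale optional shrink factor applied proportionally to the grid
#'   side and the horizon (never to rates or probabilities), for desk-scale
#'   runs.
#' @param seed RNG seed stored in the returned object.
#' @return A [FeedbackParams-class] or [FeedforwardParams-class].
#' @examples
#' scenarioPreset("fig2a")@h   # 4e-3
#' @export
scenarioPreset <- function(name, scale = 1, seed = 1L) {
  tab <- presetTable()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  spec <- tab[[name]]
  model <- spec$model
  spec$model <- NULL
  spec$n <- max(9L, as.integer(round(spec$n * scale)))
  spec$horizon <- max(1, ceiling(spec$horizon * scale))
  spec$seed <- as.integer(seed)
  do.call(if (model == "feedback") FeedbackParams else FeedforwardParams, spec)
}

runOne <- function(params, recordEvery = 0L, horizon = params@horizon) {
  if (is(params, "FeedforwardParams"))
    runFeedforwardABM(params, recordEvery = recordEvery, horizon = horizon)
  else runFeedbackABM(params, recordEvery = recordEvery, horizon = horizon)
}

#' Run a simulation until the steady-state criterion is met
#'
#' Simulates in chunks until the trailing running mean of the stem-cell count
#' changes by at most `relChange` for `window` consecutive steps (see
#' [detectSteadyState()]), then continues for `postHours` more to be well
#' inside the steady phase. Stops at `maxHours` regardless.
#'
#' @param params parameter object (its `seed` slot seeds the RNG).
#' @param maxHours hard cap on the simulated time.
#' @param window,relChange steady-state criterion (see [detectSteadyState()]).
#' @param postHours additional hours simulated after detection.
#' @param chunk chunk size in hours between criterion checks.
#' @return list with elements `run` (a [LineageRun-class]) and `steadyAt`
#'   (detection time in hours, or `NA` if `maxHours` was reached first).
#' @export
runToSteadyState <- function(params, maxHours = params@horizon,
                             window = 1000L, relChange = 0.001,
                             postHours = 500L, chunk = 1000L) {
  set.seed(params@seed)
  state <- initialState(params)
  series <- NULL
  steadyAt <- NA_integer_
  elapsed <- 0L
  while (elapsed < maxHours) {
    todo <- min(chunk, maxHours - elapsed)
    out <- runEngine(state, params, todo)
    state <- out$state
    series <- if (is.null(series)) out$series else
      rbind(series, out$series[-1L, ])
    elapsed <- elapsed + todo
    if (nrow(series) > window + 1L) {
      hit <- detectSteadyState(series$stem, relChange, window)
      if (!is.na(hit)) { steadyAt <- hit; break }
    }
  }
  if (!is.na(steadyAt) && postHours > 0) {
    out <- runEngine(state, params, postHours)
    state <- out$state
    series <- rbind(series, out$series[-1L, ])
  }
  rownames(series) <- NULL
  run <- new("LineageRun", series = series, state = state, params = params,
             snapshots = list(), snapshotTimes = numeric())
  list(run = run, steadyAt = steadyAt)
}

#' Replicate runs with aggregation
#'
#' Runs `R` independent simulations; replicate `r` uses seed
#' `baseSeed + r`. Counts are aggregated pointwise into means and standard
#' errors; each finished lattice is classified with [classifyOutcome()].
#'
#' @param params parameter object.
#' @param R number of replicates (default 46, the standard replication of
#'   the reference scenarios).
#' @param baseSeed base RNG seed (default: the seed in `params`).
#' @param horizon hours per run.
#' @return list with `summary` (see [replicateMeanSE()]), `outcomes`
#'   (character vector), and `runs` (list of [LineageRun-class]).
#' @export
runReplicates <- function(params, R = 46L, baseSeed = params@seed,
                          horizon = params@horizon) {
  stopifnot(R >= 1L)
  runs <- vector("list", R)
  for (r in seq_len(R)) {
    params@seed <- as.integer(baseSeed + r)
    runs[[r]] <- runOne(params, horizon = horizon)
  }
  outcomes <- vapply(runs, classifyOutcome, "")
  summary <- if (R >= 2L) replicateMeanSE(runs) else runs[[1L]]@series
  list(summary = summary, outcomes = outcomes, runs = runs)
}

paramNameMap <- c(
  p_div = "pDiv", p0_self = "p0Self", p_sdeath = "pSDeath",
  p_ddeath = "pDDeath", p_mig = "pMig", c = "c", b = "b", g = "g", h = "h",
  q_div = "qDiv", q_tdeath = "qTDeath", c2 = "c2", b2 = "b2", g2 = "g2",
  h2 = "h2", n = "n", horizon = "horizon", seed = "seed",
  use_feedback = "useFeedback")

resolveSlotName <- function(params, name) {
  slotName <- if (name %in% names(paramNameMap)) paramNameMap[[name]]
              else name
  if (!slotName %in% slotNames(class(params)))
    stop("unknown parameter '", name, "'")
  slotName
}

setParam <- function(params, name, value) {
  s <- resolveSlotName(params, name)
  value <- if (s == "n") as.integer(round(value)) else
           if (s == "seed") as.integer(value) else
           if (s == "useFeedback") as.logical(value) else as.numeric(value)
  slot(params, s) <- value
  validObject(params)
  params
}

#' Two-parameter log-uniform outcome sweep
#'
#' For each draw, both parameters are sampled log-uniformly from their
#' ranges, one simulation is run to the steady-state criterion (plus a fixed
#' post-steady horizon) and its final lattice is classified as `EXTINCT`,
#' `UNIFORM` or `CLUMPED`. Draw `i` derives all of its randomness from
#' `baseSeed + i` (parameter sampling and simulation use separate seedings),
#' so adding draws never perturbs earlier rows.
#'
#' @param baseline parameter object providing all non-swept values.
#' @param paramX,paramY swept parameter names (spec-style keys such as
#'   `"h"`, `"g"`, `"b"`, `"p_mig"` are accepted).
#' @param rangeX,rangeY positive length-2 ranges sampled log-uniformly.
#' @param draws number of simulations.
#' @param baseSeed base seed.
#' @param maxHours,window,relChange,postHours steady-state control, see
#'   [runToSteadyState()].
#' @return data.frame with one row per simulation: `x_name`, `x_value`,
#'   `y_name`, `y_value`, `i_disp` (`NA` for extinct runs), `outcome`,
#'   `seed`.
#' @export
sweep2D <- function(baseline, paramX = "h", rangeX, paramY, rangeY,
                    draws, baseSeed = 1L, maxHours = baseline@horizon,
                    window = 1000L, relChange = 0.001, postHours = 500L) {
  if (any(c(rangeX, rangeY) <= 0)) stop("sweep ranges must be positive")
  rows <- vector("list", draws)
  for (i in seq_len(draws)) {
    set.seed(baseSeed + i)
    x <- 10 ^ stats::runif(1, log10(rangeX[1L]), log10(rangeX[2L]))
    y <- 10 ^ stats::runif(1, log10(rangeY[1L]), log10(rangeY[2L]))
    p <- setParam(setParam(baseline, paramX, x), paramY, y)
    p@seed <- as.integer(baseSeed + i)
    res <- runToSteadyState(p, maxHours = maxHours, window = window,
                            relChange = relChange, postHours = postHours)
    lat <- res$run@state@lattice
    outcome <- classifyOutcome(lat)
    rows[[i]] <- data.frame(
      x_name = paramX, x_value = x, y_name = paramY, y_value = y,
      i_disp = if (outcome == "EXTINCT") NA_real_ else indexOfDispersion(lat),
      outcome = outcome, seed = baseSeed + i)
  }
  if (draws == 0L) {
    return(data.frame(x_name = character(), x_value = numeric(),
                      y_name = character(), y_value = numeric(),
                      i_disp = numeric(), outcome = character(),
                      seed = integer()))
  }
  do.call(rbind, rows)
}

#' Read / write flat `key = value` parameter files
#'
#' Keys are the spec-style parameter names (`p_div`, `p0_self`, `p_sdeath`,
#' `p_ddeath`, `p_mig`, `c`, `b`, `g`, `h`, `q_div`, `q_tdeath`, `c2`, `b2`,
#' `g2`, `h2`, `n`, `horizon`, `seed`, `use_feedback`). Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return `readParamsFile` returns a named list of values.
#' @export
readParamsFile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else as.logical(val)
  }
  out
}

#' @rdname readParamsFile
#' @param values named list, e.g. from `readParamsFile`, possibly overridden.
#' @param model `"feedback"` or `"feedforward"`.
#' @return `paramsFromList` returns a parameter object.
#' @export
paramsFromList <- function(values, model = c("feedback", "feedforward")) {
  model <- match.arg(model)
  params <- if (model == "feedback")
    FeedbackParams(pDiv = 0, p0Self = 0) else
    FeedforwardParams(pDiv = 0, p0Self = 0, qDiv = 0)
  for (key in names(values)) params <- setParam(params, key, values[[key]])
  params
}

#' @rdname readParamsFile
#' @param params parameter object to echo.
#' @export
writeParamsFile <- function(params, path) {
  keys <- names(paramNameMap)
  if (!is(params, "FeedforwardParams"))
    keys <- setdiff(keys, c("q_div", "q_tdeath", "c2", "b2", "g2", "h2",
                            "use_feedback"))
  lines <- vapply(keys, function(k) {
    paste(k, "=", format(slot(params, paramNameMap[[k]])))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
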