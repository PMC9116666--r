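#' Parameters for the two-compartment feedback lattice model
#'
#' Defaults are deliberately not supplied for the event probabilities: every
#' scenario should state them (or use [scenarioPreset()]).
#'
#' @param pDiv stem division probability per sampling.
#' @param p0Self basal self-renewal probability.
#' @param pSDeath stem death probability per sampling.
#' @param pDDeath differentiated-cell death probability per sampling.
#' @param pMig migration probability per sampling.
#' @param c,b,g,h feedback-mediator production, decay, hop rate and strength.
#' @param n grid side length (>= 9).
#' @param horizon default run length in hours.
#' @param seed RNG seed.
#' @return A [FeedbackParams-class].
#' @export
FeedbackParams <- function(pDiv, p0Self, pSDeath = 0, pDDeath = 0, pMig = 0,
                           c = 0, b = 0, g = 0, h = 0,
                           n = 100L, horizon = 1000, seed = 1L) {
  new("FeedbackParams", pDiv = pDiv, p0Self = p0Self, pSDeath = pSDeath,
      pDDeath = pDDeath, pMig = pMig, c = c, b = b, g = g, h = h,
      n = as.integer(n), horizon = as.numeric(horizon), seed = as.integer(seed))
}

#' Parameters for the three-compartment feedforward lattice model
#'
#' @inheritParams FeedbackParams
#' @param qDiv transit-amplifying division probability per sampling.
#' @param qTDeath transit-amplifying death probability per sampling.
#' @param c2,b2,g2,h2 feedforward-mediator production, decay, hop rate and
#'   strength.
#' @param useFeedback include the negative-feedback field z (producers:
#'   differentiated cells) in addition to the feedforward field w.
#' @return A [FeedforwardParams-class].
#' @export
FeedforwardParams <- function(pDiv, p0Self, qDiv, pSDeath = 0, qTDeath = 0,
                              pDDeath = 0, pMig = 0,
                              c = 0, b = 0, g = 0, h = 0,
                              c2 = 0, b2 = 0, g2 = 0, h2 = 0,
                              useFeedback = FALSE,
                              n = 100L, horizon = 1000, seed = 1L) {
  new("FeedforwardParams", pDiv = pDiv, p0Self = p0Self, pSDeath = pSDeath,
      pDDeath = pDDeath, pMig = pMig, c = c, b = b, g = g, h = h,
      qDiv = qDiv, qTDeath = qTDeath, c2 = c2, b2 = b2, g2 = g2, h2 = h2,
      useFeedback = useFeedback,
      n = as.integer(n), horizon = as.numeric(horizon), seed = as.integer(seed))
}

#' Local stem-cell self-renewal probability under negative feedback
#'
#' `p_self = p0 / (1 + h z)`: the more feedback factor present in the patch
#' under the dividing stem cell, the lower the probability that the division
#' self-renews. Strictly decreasing in `z` for `h > 0`, with `p_self = p0`
#' at `z = 0` and `p_self -> 0` as `z -> Inf`.
#'
#' @param z local feedback-factor concentration (non-negative).
#' @param h feedback strength (non-negative).
#' @param p0 basal self-renewal probability.
#' @return Probability (vectorised over `z`).
#' @export
selfRenewalProb <- function(z, h, p0) {
  if (any(z < 0) || h < 0 || p0 < 0 || p0 > 1)
    stop("require z >= 0, h >= 0 and p0 in [0, 1]")
  p0 / (1 + h * z)
}

#' Local transit-amplifying self-renewal probability under feedforward control
#'
#' `q_self = 1 - 1/(1 + h2 w)`: without feedforward factor TA divisions
#' terminally differentiate with certainty (`q_self(0) = 0`); for large `w`
#' the probability of TA self-renewal approaches one.
#'
#' @param w local feedforward-factor concentration (non-negative).
#' @param h2 feedforward strength (non-negative).
#' @return Probability (vectorised over `w`).
#' @export
taSelfRenewalProb <- function(w, h2) {
  if (any(w < 0) || h2 < 0) stop("require w >= 0 and h2 >= 0")
  1 - 1 / (1 + h2 * w)
}

#' Initial simulation state: centred 7 x 7 stem block, zero fields
#'
#' @param params a [FeedbackParams-class] or [FeedforwardParams-class].
#' @return A [LineageState-class].
#' @export
initialState <- function(params) {
  lat <- initCenterBlock(params@n, 7L)
  ff <- is(params, "FeedforwardParams")
  useZ <- !ff || params@useFeedback
  fz <- if (useZ) MediatorField(params@n, params@c, params@b, params@g, params@h)
        else NULL
  fw <- if (ff) MediatorField(params@n, params@c2, params@b2, params@g2, params@h2)
        else NULL
  new("LineageState", lattice = lat, fieldZ = fz, fieldW = fw, time = 0)
}

# Shared driver around the compiled engine. `steps` whole hours are simulated;
# the RNG state of the session is consumed (callers seed it).
runEngine <- function(state, params, steps, snapshotEvery = 0L,
                      earlyStopExtinct = TRUE) {
  ff <- is(params, "FeedforwardParams")
  # a field that can never become nonzero is skipped entirely
  useZ <- !is.null(state@fieldZ) &&
    (params@c > 0 || max(state@fieldZ@conc) > 0)
  useW <- !is.null(state@fieldW) &&
    (params@c2 > 0 || max(state@fieldW@conc) > 0)
  n <- params@n
  zero <- matrix(0, n, n)
  res <- cpp_run_lineage(
    state@lattice@states,
    if (useZ) state@fieldZ@conc else zero,
    if (useW) state@fieldW@conc else zero,
    params@pDiv, params@p0Self, params@pSDeath, params@pDDeath, params@pMig,
    if (ff) params@qDiv else 0, if (ff) params@qTDeath else 0,
    params@c, params@b, params@g, params@h, useZ,
    if (ff) params@c2 else 0, if (ff) params@b2 else 0,
    if (ff) params@g2 else 0, if (ff) params@h2 else 0, useW,
    ff, as.integer(steps), as.integer(snapshotEvery), earlyStopExtinct)
  lat <- CellLattice(n, res$lattice)
  fz <- state@fieldZ
  if (useZ) fz@conc <- res$z
  fw <- state@fieldW
  if (useW) fw@conc <- res$w
  newState <- new("LineageState", lattice = lat, fieldZ = fz, fieldW = fw,
                  time = state@time + steps)
  counts <- res$counts
  series <- data.frame(t = state@time + 0:steps,
                       stem = counts[, 1L], ta = counts[, 2L],
                       diff = counts[, 3L])
  series$total <- series$stem + series$ta + series$diff
  list(series = series, state = newState,
       snapshots = res$snapshots,
       snapshotTimes = state@time + as.numeric(res$snapshot_times))
}

#' Advance a hybrid simulation by whole time steps
#'
#' One time step is one hour: the occupied-spot list is sampled `N` times
#' (`N` = cell count at the start of the step) applying division,
#' differentiation, death and migration events, then each active mediator
#' field is advanced one time unit with the producer mask taken from the
#' post-update occupancy. Uses (and advances) the session RNG stream; seed it
#' with [set.seed()] for reproducibility.
#'
#' @param state a [LineageState-class].
#' @param params matching parameter object.
#' @param steps number of one-hour steps (default 1).
#' @return The advanced [LineageState-class].
#' @export
abmStep <- function(state, params, steps = 1L) {
  runEngine(state, params, steps)$state
}

makeRun <- function(out, params) {
  new("LineageRun", series = out$series, state = out$state, params = params,
      snapshots = out$snapshots, snapshotTimes = out$snapshotTimes)
}

#' Run the two-compartment feedback model
#'
#' Seeds a centred 7 x 7 block of stem cells on an empty grid with zero
#' mediator everywhere, seeds the RNG from `params@seed`, and iterates the
#' hybrid step for `horizon` hours. Counts are recorded every step; lattice
#' snapshots every `recordEvery` steps (0 = none).
#'
#' @param params a [FeedbackParams-class].
#' @param recordEvery snapshot interval in steps.
#' @param horizon override of `params@horizon` (hours).
#' @return A [LineageRun-class].
#' @export
runFeedbackABM <- function(params, recordEvery = 0L, horizon = params@horizon) {
  stopifnot(is(params, "FeedbackParams"), !is(params, "FeedforwardParams"))
  set.seed(params@seed)
  out <- runEngine(initialState(params), params, as.integer(horizon),
                   snapshotEvery = recordEvery)
  makeRun(out, params)
}

#' Run the three-compartment feedforward model
#'
#' As [runFeedbackABM()], with transit-amplifying cells maintained by the
#' stem-cell-secreted feedforward field and, optionally, negative feedback on
#' stem-cell self-renewal from the differentiated-cell-secreted field.
#'
#' @param params a [FeedforwardParams-class].
#' @param useFeedback include the negative-feedback field (defaults to the
#'   value stored in `params`).
#' @param recordEvery snapshot interval in steps.
#' @param horizon override of `params@horizon` (hours).
#' @return A [LineageRun-class].
#' @export
runFeedforwardABM <- function(params, useFeedback = params@useFeedback,
                              recordEvery = 0L, horizon = params@horizon) {
  stopifnot(is(params, "FeedforwardParams"))
  params@useFeedback <- useFeedback
  set.seed(params@seed)
  out <- runEngine(initialState(params), params, as.integer(horizon),
                   snapshotEvery = recordEvery)
  makeRun(out, params)
}

#' @rdname timeSeries
#' @export
setGeneric("timeSeries", function(x) standardGeneric("timeSeries"))

#' Per-step cell counts of a finished run
#' @param x a [LineageRun-class].
#' @return data.frame with columns `t`, `stem`, `ta`, `diff`, `total`.
#' @rdname timeSeries
#' @export
setMethod("timeSeries", "LineageRun", function(x) x@series)

#' @rdname finalState
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' Final state of a finished run
#' @param x a [LineageRun-class].
#' @rdname finalState
#' @export
setMethod("finalState", "LineageRun", function(x) x@state)

setMethod("show", "LineageRun", function(object) {
  s <- object@series
  last <- s[nrow(s), ]
  cat(sprintf("LineageRun: n=%d, %d hours simulated\n",
              object@params@n, nrow(s) - 1L))
  cat(sprintf("  final counts: %d stem, %d TA, %d differentiated (total %d)\n",
              last$stem, last$ta, last$diff, last$total))
  if (length(object@snapshots))
    cat(sprintf("  %d lattice snapshots recorded\n", length(object@snapshots)))
})

setMethod("show", "LineageState", function(object) {
  cc <- cellCounts(object@lattice)
  cat(sprintf("LineageState at t=%g h: %d stem, %d TA, %d diff; fields: %s\n",
              object@time, cc[["stem"]], cc[["ta"]], cc[["diff"]],
              paste(c(if (!is.null(object@fieldZ)) "z",
                      if (!is.null(object@fieldW)) "w"), collapse = ", ")))
})

setMethod("show", "FeedbackParams", function(object) {
  cat(sprintf("FeedbackParams: pDiv=%g p0Self=%g pSDeath=%g pDDeath=%g pMig=%g\n",
              object@pDiv, object@p0Self, object@pSDeath, object@pDDeath,
              object@pMig))
  cat(sprintf("  field z: c=%g b=%g g=%g h=%g; n=%d horizon=%g seed=%d\n",
              object@c, object@b, object@g, object@h, object@n,
              object@horizon, object@seed))
})

setMethod("show", "FeedforwardParams", function(object) {
  callNextMethod()
  cat(sprintf("  TA: qDiv=%g qTDeath=%g; field w: c2=%g b2=%g g2=%g h2=%g; feedback %s\n",
              object@qDiv, object@qTDeath, object@c2, object@b2, object@g2,
              object@h2, if (object@useFeedback) "on" else "off"))
})
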