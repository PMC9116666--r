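#' @import methods
NULL

CELL_CODES <- c(EMPTY = 0L, STEM = 1L, TA = 2L, DIFF = 3L)

#' CellLattice: an n x n grid of cell states
#'
#' Each spot of the grid holds at most one cell, coded as an integer:
#' 0 = empty, 1 = stem cell, 2 = transit-amplifying cell, 3 = differentiated
#' cell. Coordinates throughout the package are 1-based `(row, col)` pairs and
#' canonical orderings are row-major (by row, then column).
#'
#' @slot n side length of the grid (number of spots per side).
#' @slot states integer matrix of dimension `n x n` with values in `0:3`.
#' @export
setClass("CellLattice", representation(n = "integer", states = "matrix"))

setValidity("CellLattice", function(object) {
  msg <- character()
  if (length(object@n) != 1L || object@n < 1L)
    msg <- c(msg, "n must be a single positive integer")
  if (!is.integer(object@states))
    msg <- c(msg, "states must be an integer matrix")
  if (!identical(dim(object@states), c(object@n, object@n)))
    msg <- c(msg, "states must be an n x n matrix")
  else if (!all(object@states %in% 0:3))
    msg <- c(msg, "states must take values in 0:3 (empty/stem/TA/diff)")
  if (length(msg)) msg else TRUE
})

#' MediatorField: deterministic per-patch concentration of one diffusing factor
#'
#' Every spot of the cell grid is associated with a patch carrying a
#' non-negative concentration of a signalling mediator. The field obeys, per
#' patch i, `dz_i/dt = c * 1[producer] - b z_i - m_i g z_i + g Z_i`, where
#' `Z_i` is the summed concentration over the up-to-8 Moore-adjacent patches
#' and `m_i` is the actual (boundary-truncated) neighbour count. Instantiated
#' once for the negative-feedback factor (secreted by differentiated cells)
#' and once for the feedforward factor (secreted by stem cells).
#'
#' @slot n side length (matches the cell grid).
#' @slot conc `n x n` non-negative concentration matrix.
#' @slot prodRate production rate `c` on producer patches (per hour).
#' @slot decayRate first-order decay rate `b` (per hour).
#' @slot hopRate nearest-neighbour hop rate `g` (per hour).
#' @slot inhibStrength feedback strength `h` entering the self-renewal
#'   probability (dimensionless per concentration unit).
#' @export
setClass("MediatorField", representation(
  n = "integer", conc = "matrix",
  prodRate = "numeric", decayRate = "numeric", hopRate = "numeric",
  inhibStrength = "numeric"
))

setValidity("MediatorField", function(object) {
  msg <- character()
  if (!identical(dim(object@conc), c(object@n, object@n)))
    msg <- c(msg, "conc must be an n x n matrix")
  else if (any(object@conc < 0))
    msg <- c(msg, "concentrations must be non-negative")
  for (s in c("prodRate", "decayRate", "hopRate", "inhibStrength")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste(s, "must be a single non-negative number"))
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the two-compartment feedback lattice model
#'
#' Per-sampling event probabilities for the stochastic cell layer plus the
#' parameters of the negative-feedback mediator field. Time unit is one hour;
#' one lattice time step corresponds to one hour.
#'
#' @slot pDiv stem-cell division probability per sampling.
#' @slot p0Self basal self-renewal probability (no feedback).
#' @slot pSDeath stem-cell death probability per sampling.
#' @slot pDDeath differentiated-cell death probability per sampling.
#' @slot pMig migration probability per sampling.
#' @slot c,b,g,h production, decay, hop rate and feedback strength of the
#'   feedback mediator.
#' @slot n grid side length (must be at least 9 to hold the 7 x 7 seed block).
#' @slot horizon default simulation horizon in hours.
#' @slot seed RNG seed.
#' @export
setClass("FeedbackParams", representation(
  pDiv = "numeric", p0Self = "numeric", pSDeath = "numeric",
  pDDeath = "numeric", pMig = "numeric",
  c = "numeric", b = "numeric", g = "numeric", h = "numeric",
  n = "integer", horizon = "numeric", seed = "integer"
))

validProbabilities <- function(object, slots) {
  msg <- character()
  for (s in slots) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste(s, "must be a probability in [0, 1]"))
  }
  msg
}

setValidity("FeedbackParams", function(object) {
  msg <- validProbabilities(object, c("pDiv", "p0Self", "pSDeath", "pDDeath", "pMig"))
  for (s in c("c", "b", "g", "h")) {
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (object@n < 9L)
    msg <- c(msg, "n must be at least 9 (the initial block is 7 x 7)")
  if (object@horizon < 1) msg <- c(msg, "horizon must be at least one hour")
  if (length(msg)) msg else TRUE
})

#' Parameters of the three-compartment feedforward lattice model
#'
#' Extends [FeedbackParams-class] with transit-amplifying (TA) cell event
#' probabilities and the parameters of the stem-cell-secreted feedforward
#' field `w`. The negative-feedback field can be switched off entirely
#' (`useFeedback = FALSE`) to study the feedforward loop in isolation.
#'
#' @slot qDiv TA division probability per sampling.
#' @slot qTDeath TA death probability per sampling.
#' @slot c2,b2,g2,h2 production, decay, hop rate and strength of the
#'   feedforward mediator.
#' @slot useFeedback logical; include the negative-feedback field z.
#' @export
setClass("FeedforwardParams", contains = "FeedbackParams", representation(
  qDiv = "numeric", qTDeath = "numeric",
  c2 = "numeric", b2 = "numeric", g2 = "numeric", h2 = "numeric",
  useFeedback = "logical"
))

setValidity("FeedforwardParams", function(object) {
  msg <- validProbabilities(object, c("qDiv", "qTDeath"))
  for (s in c("c2", "b2", "g2", "h2")) {
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("MediatorFieldOrNULL", c("MediatorField", "NULL"))

#' LineageState: instantaneous state of a hybrid simulation
#'
#' @slot lattice the cell grid.
#' @slot fieldZ negative-feedback mediator field (producers: differentiated
#'   cells), or NULL when the feedback layer is disabled.
#' @slot fieldW feedforward mediator field (producers: stem cells), or NULL
#'   for the two-compartment model.
#' @slot time hours elapsed.
#' @export
setClass("LineageState", representation(
  lattice = "CellLattice",
  fieldZ = "MediatorFieldOrNULL",
  fieldW = "MediatorFieldOrNULL",
  time = "numeric"
))

#' LineageRun: a finished simulation
#'
#' Holds the per-step counts of each cell type, the final lattice and mediator
#' fields, any intermediate lattice snapshots, and the parameters used.
#'
#' @slot series data.frame with columns `t`, `stem`, `ta`, `diff`, `total`
#'   (one row per hour, including t = 0).
#' @slot state final [LineageState-class].
#' @slot params the parameter object the run was started from.
#' @slot snapshots list of lattice snapshot matrices.
#' @slot snapshotTimes times (hours) of the snapshots.
#' @export
setClass("LineageRun", representation(
  series = "data.frame",
  state = "LineageState",
  params = "FeedbackParams",
  snapshots = "list",
  snapshotTimes = "numeric"
))

#' Mean-field model parameters (two-compartment, no carrying capacity)
#'
#' The non-spatial model `dS/dt = r S (2p - 1)`,
#' `dD/dt = 2 r S (1 - p) - alpha D` with Hill-type feedback
#' `p(D) = p' / (1 + f1 D^kappa1)` and `r(D) = r' / (1 + f2 D^kappa2)`.
#'
#' @slot rBasal basal division rate `r'` (per hour).
#' @slot pBasal basal self-renewal probability `p'`.
#' @slot f1,kappa1 strength and exponent of the feedback on p.
#' @slot f2,kappa2 strength and exponent of the feedback on r.
#' @slot alpha differentiated-cell death rate (per hour).
#' @export
setClass("Model1Params", representation(
  rBasal = "numeric", pBasal = "numeric",
  f1 = "numeric", kappa1 = "numeric", f2 = "numeric", kappa2 = "numeric",
  alpha = "numeric"
))

setValidity("Model1Params", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (object@pBasal > 1) msg <- c(msg, "pBasal must be at most 1")
  if (length(msg)) msg else TRUE
})

#' Mean-field model parameters with carrying capacity and explicit mediator
#'
#' The well-mixed counterpart of the lattice model:
#' `dS/dt = r S (2p - 1)(1 - (S+D)/K) - eta S`,
#' `dD/dt = 2 r S (1 - p)(1 - (S+D)/K) - alpha D`, `dZ/dt = xi D - beta Z`,
#' with `p = p' / (1 + f Z / K)`. The mediator abundance is divided by the
#' carrying capacity because, on the lattice, a larger system dilutes the
#' secreted factor.
#'
#' @slot r division rate (per hour).
#' @slot pBasal basal self-renewal probability `p'`.
#' @slot f feedback strength.
#' @slot K carrying capacity (cells; the lattice analogue is n^2).
#' @slot eta stem-cell death rate (per hour).
#' @slot alpha differentiated-cell death rate (per hour).
#' @slot xi mediator production rate (per hour).
#' @slot beta mediator decay rate (per hour).
#' @export
setClass("Model2Params", representation(
  r = "numeric", pBasal = "numeric", f = "numeric", K = "numeric",
  eta = "numeric", alpha = "numeric", xi = "numeric", beta = "numeric"
))

setValidity("Model2Params", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (object@pBasal > 1) msg <- c(msg, "pBasal must be at most 1")
  if (object@K <= 0) msg <- c(msg, "K must be positive")
  if (length(msg)) msg else TRUE
})
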