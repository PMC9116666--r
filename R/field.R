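#' Construct a mediator field
#'
#' @param n grid side length (one patch per lattice spot).
#' @param prodRate production rate `c` on producer-occupied patches (per hour).
#' @param decayRate decay rate `b` (per hour).
#' @param hopRate nearest-neighbour hop rate `g` (per hour).
#' @param inhibStrength feedback strength `h`.
#' @param conc optional initial `n x n` concentration matrix (default zero).
#' @return A [MediatorField-class].
#' @export
MediatorField <- function(n, prodRate, decayRate, hopRate, inhibStrength = 0,
                          conc = NULL) {
  n <- as.integer(n)
  if (is.null(conc)) conc <- matrix(0, n, n)
  new("MediatorField", n = n, conc = conc,
      prodRate = as.numeric(prodRate), decayRate = as.numeric(decayRate),
      hopRate = as.numeric(hopRate), inhibStrength = as.numeric(inhibStrength))
}

#' @rdname concentration
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))

#' Concentration matrix of a mediator field
#' @param x a [MediatorField-class].
#' @rdname concentration
#' @export
setMethod("concentration", "MediatorField", function(x) x@conc)

#' Total mediator over all patches
#'
#' @param x a [MediatorField-class].
#' @return Scalar sum of the concentration over the grid.
#' @export
setGeneric("totalMediator", function(x) standardGeneric("totalMediator"))

#' @rdname totalMediator
#' @export
setMethod("totalMediator", "MediatorField", function(x) sum(x@conc))

setMethod("show", "MediatorField", function(object) {
  cat(sprintf(
    "MediatorField %d x %d (c=%g, b=%g, g=%g, h=%g): total %.6g, max %.6g\n",
    object@n, object@n, object@prodRate, object@decayRate, object@hopRate,
    object@inhibStrength, sum(object@conc), max(object@conc)))
})

#' Instantaneous rate of change of the field
#'
#' Evaluates `dz_i/dt = c * 1[producer_i] - b z_i - m_i g z_i + g Z_i` on
#' every patch, where `Z_i` is the sum over the Moore-adjacent patches and
#' `m_i` the boundary-truncated neighbour count. Boundary patches exchange
#' only with their existing neighbours (no-flux wall).
#'
#' @param field a [MediatorField-class].
#' @param producers `n x n` logical matrix marking producer-occupied patches.
#' @return `n x n` matrix of rates (per hour).
#' @export
fieldRHS <- function(field, producers) {
  stopifnot(is(field, "MediatorField"))
  if (!identical(dim(producers), dim(field@conc)))
    stop("producer mask dimensions must match the field")
  z <- field@conc
  n <- field@n
  pad <- matrix(0, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- z
  nbrSum <- matrix(0, n, n)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbrSum <- nbrSum + pad[(2:(n + 1L)) + dr, (2:(n + 1L)) + dc]
  }
  m <- matrix(8, n, n)
  m[1L, ] <- m[n, ] <- m[, 1L] <- m[, n] <- 5
  m[1L, 1L] <- m[1L, n] <- m[n, 1L] <- m[n, n] <- 3
  field@prodRate * (producers * 1) - field@decayRate * z -
    m * field@hopRate * z + field@hopRate * nbrSum
}

#' Advance a mediator field with a frozen producer mask
#'
#' Integrates the linear patch dynamics for `duration` hours. By default a
#' classical 4th-order Runge-Kutta scheme is used with substep
#' `dt * (b + 16 g) <= 1.2`; for stiff parameter sets (`b + 16 g > 480`,
#' e.g. very fast mediator diffusion) an implicit-Euler scheme with a banded
#' Cholesky factorisation is used instead, which is unconditionally stable and
#' positivity-preserving. Passing `substeps` explicitly forces the
#' Runge-Kutta scheme with that many substeps; as `substeps` grows the result
#' converges to the exact solution of the linear system.
#'
#' @param field a [MediatorField-class].
#' @param producers logical `n x n` producer mask, frozen for the whole call.
#' @param duration hours to advance (default 1, one lattice time step).
#' @param substeps optional explicit substep count (forces RK4).
#' @return The advanced [MediatorField-class].
#' @export
advanceField <- function(field, producers, duration = 1, substeps = NULL) {
  stopifnot(is(field, "MediatorField"))
  if (!identical(dim(producers), dim(field@conc)))
    stop("producer mask dimensions must match the field")
  if (duration <= 0) stop("duration must be positive")
  mode(producers) <- "logical"
  conc <- cpp_advance_field(field@conc, producers, field@prodRate,
                            field@decayRate, field@hopRate, duration,
                            if (is.null(substeps)) -1L else as.integer(substeps))
  field@conc <- conc
  field
}

#' Read / write plain-text field snapshots
#'
#' `n` lines of `n` whitespace-separated concentrations in scientific
#' notation.
#'
#' @param x a [MediatorField-class] or numeric matrix.
#' @param path file path.
#' @export
writeFieldSnapshot <- function(x, path) {
  m <- if (is(x, "MediatorField")) x@conc else x
  lines <- apply(m, 1L, function(r) paste(sprintf("%.10e", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFieldSnapshot
#' @return `readFieldSnapshot` returns the concentration matrix.
#' @export
readFieldSnapshot <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
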