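#' Construct an empty cell lattice
#'
#' @param n side length of the grid.
#' @param states optional `n x n` integer matrix of cell codes (0 = empty,
#'   1 = stem, 2 = transit-amplifying, 3 = differentiated); defaults to all
#'   empty.
#' @return A [CellLattice-class] object.
#' @export
CellLattice <- function(n, states = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.null(states)) states <- matrix(0L, n, n)
  storage.mode(states) <- "integer"
  new("CellLattice", n = n, states = states)
}

#' Moore neighbourhood of a grid spot
#'
#' Returns the coordinates of all in-grid spots at Chebyshev distance one from
#' `(row, col)` on an `n x n` grid with hard-wall boundaries (no periodic
#' wrap). Interior spots have 8 neighbours, edges 5, corners 3. The result is
#' sorted in row-major canonical order; coordinates are 1-based.
#'
#' @param n grid side length.
#' @param row,col 1-based coordinates of the focal spot.
#' @return Integer matrix with columns `row` and `col`, one neighbour per row.
#' @examples
#' nrow(mooreNeighbors(100, 50, 50))  # 8
#' nrow(mooreNeighbors(100, 1, 1))    # 3
#' @export
mooreNeighbors <- function(n, row, col) {
  n <- as.integer(n); row <- as.integer(row); col <- as.integer(col)
  if (row < 1L || row > n || col < 1L || col > n)
    stop("coordinates out of range: must have 1 <= row, col <= n")
  rr <- rep(row + (-1:1), each = 3L)
  cc <- rep(col + (-1:1), times = 3L)
  keep <- !(rr == row & cc == col) & rr >= 1L & rr <= n & cc >= 1L & cc <= n
  out <- cbind(row = rr[keep], col = cc[keep])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Initial condition: a centred block of stem cells
#'
#' Fills a `side x side` square of stem cells in the centre of an otherwise
#' empty grid. When `n - side` is odd the block origin is at offset
#' `floor((n - side)/2)`, i.e. the block sits one spot off true centre.
#'
#' @param n grid side length.
#' @param side side of the stem-cell block (default 7, the standard seeding).
#' @return A [CellLattice-class].
#' @export
initCenterBlock <- function(n, side = 7L) {
  n <- as.integer(n); side <- as.integer(side)
  if (side > n) stop("side must not exceed n")
  if (side < 1L) stop("side must be positive")
  off <- (n - side) %/% 2L
  states <- matrix(0L, n, n)
  idx <- (off + 1L):(off + side)
  states[idx, idx] <- CELL_CODES[["STEM"]]
  CellLattice(n, states)
}

#' @rdname cellCounts
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' Count cells of each kind
#'
#' @param x a [CellLattice-class] or [LineageRun-class] (final lattice).
#' @return Named integer vector with elements `stem`, `ta`, `diff`.
#' @export
#' @rdname cellCounts
setMethod("cellCounts", "CellLattice", function(x) {
  s <- x@states
  c(stem = sum(s == 1L), ta = sum(s == 2L), diff = sum(s == 3L))
})

#' @rdname cellCounts
#' @export
setMethod("cellCounts", "LineageRun", function(x) cellCounts(x@state@lattice))

#' Coordinates of all occupied spots
#'
#' @param x a [CellLattice-class].
#' @return Integer matrix with columns `row`, `col` in row-major canonical
#'   order (0 rows if the lattice is empty).
#' @export
setGeneric("occupiedSpots", function(x) standardGeneric("occupiedSpots"))

#' @rdname occupiedSpots
#' @export
setMethod("occupiedSpots", "CellLattice", function(x) {
  w <- which(x@states != 0L, arr.ind = TRUE)
  out <- cbind(row = as.integer(w[, 1L]), col = as.integer(w[, 2L]))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
})

#' @rdname latticeSide
#' @export
setGeneric("latticeSide", function(x) standardGeneric("latticeSide"))

#' Grid side length
#' @param x a [CellLattice-class] or [MediatorField-class].
#' @rdname latticeSide
#' @export
setMethod("latticeSide", "CellLattice", function(x) x@n)

#' @rdname latticeSide
#' @export
setMethod("latticeSide", "MediatorField", function(x) x@n)

#' @rdname cellStates
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' Integer matrix of cell state codes
#' @param x a [CellLattice-class].
#' @rdname cellStates
#' @export
setMethod("cellStates", "CellLattice", function(x) x@states)

setMethod("show", "CellLattice", function(object) {
  cc <- cellCounts(object)
  cat(sprintf("CellLattice %d x %d: %d stem, %d TA, %d differentiated (%d occupied of %d spots)\n",
              object@n, object@n, cc[["stem"]], cc[["ta"]], cc[["diff"]],
              sum(cc), object@n^2))
})

#' Read / write plain-text lattice snapshots
#'
#' The snapshot format is `n` lines of `n` whitespace-separated integer codes
#' (0 = empty, 1 = stem, 2 = TA, 3 = differentiated), row by row.
#'
#' @param x a [CellLattice-class].
#' @param path file path.
#' @export
writeLatticeSnapshot <- function(x, path) {
  stopifnot(is(x, "CellLattice"))
  write.table(x@states, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeLatticeSnapshot
#' @return `readLatticeSnapshot` returns a [CellLattice-class].
#' @export
readLatticeSnapshot <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (nrow(m) != ncol(m)) stop("snapshot is not square")
  CellLattice(nrow(m), m)
}
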