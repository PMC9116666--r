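#' Quadrat-based index of dispersion
#'
#' Partitions the grid into non-overlapping `squareSide x squareSide` blocks,
#' counts all cells (any kind) per block, and returns the ratio of the sample
#' variance (denominator: number of blocks minus one) to the mean of the
#' block counts. Values near 1 indicate random placement, values well above 1
#' a clumped pattern, values below 1 an even spacing.
#'
#' @param x a [CellLattice-class], [LineageRun-class] (final lattice), or an
#'   integer state matrix.
#' @param squareSide quadrat side (default 10); must divide the grid side.
#' @return Non-negative scalar.
#' @export
indexOfDispersion <- function(x, squareSide = 10L) {
  counts <- quadratCounts(x, squareSide)
  mean(counts) ^ (-1) * stats::var(as.vector(counts))
}

quadratCounts <- function(x, squareSide = 10L) {
  s <- stateMatrixOf(x)
  n <- nrow(s)
  squareSide <- as.integer(squareSide)
  if (n %% squareSide != 0L)
    stop("grid side must be divisible by the quadrat side")
  occ <- (s != 0L) * 1L
  if (sum(occ) == 0L)
    stop("index of dispersion is undefined on an empty lattice")
  nb <- n %/% squareSide
  apply(array(occ, c(squareSide, nb, squareSide, nb)), c(2L, 4L), sum)
}

stateMatrixOf <- function(x) {
  if (is(x, "LineageRun")) x <- x@state@lattice
  if (is(x, "CellLattice")) x <- x@states
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("need a square state matrix")
  x
}

#' Classify the long-term outcome of a run
#'
#' `EXTINCT` when no cells remain; otherwise `CLUMPED` when the index of
#' dispersion exceeds `threshold` and `UNIFORM` otherwise (ties count as
#' `UNIFORM`).
#'
#' @inheritParams indexOfDispersion
#' @param threshold classification threshold on the index of dispersion
#'   (default 1.5).
#' @return One of `"EXTINCT"`, `"UNIFORM"`, `"CLUMPED"`.
#' @export
classifyOutcome <- function(x, threshold = 1.5, squareSide = 10L) {
  s <- stateMatrixOf(x)
  if (all(s == 0L)) return("EXTINCT")
  if (indexOfDispersion(s, squareSide) > threshold) "CLUMPED" else "UNIFORM"
}

#' Detect a steady state in a stem-cell count series
#'
#' A run is considered at steady state once the trailing running mean of the
#' stem-cell counts (window length `window`) differs by at most `relChange`
#' (relative, guarded against a zero mean) from its value `window` steps
#' earlier, i.e. the temporal average has not moved by more than 0.1 percent
#' over 1000 consecutive steps at the defaults. Returns the 1-based index of
#' the first step satisfying the condition (a constant series gives
#' `2 * window`), or `NA` when it is never met. A series growing linearly at
#' unit slope is never steady under this rule, while bounded fluctuations
#' around a constant level are averaged out.
#'
#' @param series a [LineageRun-class], a data.frame with a `stem` column, or
#'   a numeric vector of stem counts.
#' @param relChange relative tolerance (default 0.001, i.e. 0.1 percent).
#' @param window window length in steps (default 1000).
#' @return Integer index, or `NA_integer_` if not reached.
#' @export
detectSteadyState <- function(series, relChange = 0.001, window = 1000L) {
  x <- stemSeriesOf(series)
  window <- as.integer(window)
  if (length(x) <= window) stop("series must be longer than the window")
  if (length(x) < 2L * window) return(NA_integer_)
  cs <- cumsum(c(0, x))
  rm <- (cs[(window + 1L):(length(x) + 1L)] - cs[1:(length(x) - window + 1L)]) /
    window                                   # rm[i] = mean over t in (i-1, i-1+window]
  lag <- window
  cur <- rm[(lag + 1L):length(rm)]           # mean ending at t = 2*window ... T
  prev <- rm[1:(length(rm) - lag)]           # mean ending window steps earlier
  ok <- abs(cur - prev) / pmax(abs(prev), 1e-12) <= relChange
  hit <- which(ok)
  if (!length(hit)) NA_integer_ else 2L * window + hit[1L] - 1L
}

stemSeriesOf <- function(series) {
  if (is(series, "LineageRun")) series <- series@series
  if (is.data.frame(series)) series$stem else as.numeric(series)
}

#' Pointwise mean and standard error over replicate runs
#'
#' @param runs list (length >= 2) of [LineageRun-class] objects or count
#'   data.frames of equal length.
#' @return data.frame with columns `t` and, for each of `stem`, `ta`, `diff`,
#'   `total`, a `_mean` and `_se` column (`se = sd / sqrt(R)`).
#' @export
replicateMeanSE <- function(runs) {
  dfs <- lapply(runs, function(r) if (is(r, "LineageRun")) r@series else r)
  if (length(dfs) < 2L) stop("need at least two replicate runs")
  len <- vapply(dfs, nrow, 1L)
  if (length(unique(len)) != 1L) stop("replicate series must have equal length")
  R <- length(dfs)
  out <- data.frame(t = dfs[[1L]]$t)
  for (v in c("stem", "ta", "diff", "total")) {
    m <- vapply(dfs, function(d) as.numeric(d[[v]]), numeric(len[1L]))
    out[[paste0(v, "_mean")]] <- rowMeans(m)
    out[[paste0(v, "_se")]] <- apply(m, 1L, stats::sd) / sqrt(R)
  }
  out
}
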