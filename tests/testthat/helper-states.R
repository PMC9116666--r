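# Construct a LineageState from an explicit state matrix, for single-event
# enumeration tests. Fields start at zero unless overridden.
makeState <- function(states, params, zConc = NULL, wConc = NULL) {
  n <- nrow(states)
  storage.mode(states) <- "integer"
  lat <- CellLattice(n, states)
  ff <- is(params, "FeedforwardParams")
  useZ <- !ff || params@useFeedback
  fz <- if (useZ) MediatorField(n, params@c, params@b, params@g, params@h,
                                conc = zConc) else NULL
  fw <- if (ff) MediatorField(n, params@c2, params@b2, params@g2, params@h2,
                              conc = wConc) else NULL
  new("LineageState", lattice = lat, fieldZ = fz, fieldW = fw, time = 0)
}

# Place cells (codes) at given 1-based coordinates on an empty n x n grid.
latticeWith <- function(n, coords, codes) {
  s <- matrix(0L, n, n)
  for (i in seq_len(nrow(coords))) s[coords[i, 1L], coords[i, 2L]] <- codes[i]
  s
}
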