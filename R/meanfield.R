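#' @describeIn Model1Params-class Constructor.
#' @param rBasal,pBasal,f1,kappa1,f2,kappa2,alpha see slot documentation.
#' @export
Model1Params <- function(rBasal, pBasal, f1 = 0, kappa1 = 1, f2 = 0,
                         kappa2 = 1, alpha = 0) {
  new("Model1Params", rBasal = rBasal, pBasal = pBasal, f1 = f1,
      kappa1 = kappa1, f2 = f2, kappa2 = kappa2, alpha = alpha)
}

#' @describeIn Model2Params-class Constructor.
#' @param r,pBasal,f,K,eta,alpha,xi,beta see slot documentation.
#' @export
Model2Params <- function(r, pBasal, f, K, eta = 0, alpha = 0, xi = 0,
                         beta = 1) {
  new("Model2Params", r = r, pBasal = pBasal, f = f, K = K, eta = eta,
      alpha = alpha, xi = xi, beta = beta)
}

#' Right-hand side of the basic two-compartment mean-field model
#'
#' `dS/dt = r S (2p - 1)`, `dD/dt = 2 r S (1 - p) - alpha D`, with
#' `p = p'/(1 + f1 D^kappa1)` and `r(D) = r'/(1 + f2 D^kappa2)`. With constant
#' `p = 1/2` the stem-cell equation vanishes for every `S` (a neutrally
#' stable continuum of equilibria); feedback on the division rate `r` alone
#' never creates an equilibrium.
#'
#' @param state named numeric vector with elements `S` and `D`.
#' @param params a [Model1Params-class].
#' @return Named vector `c(S = dS/dt, D = dD/dt)`.
#' @export
model1RHS <- function(state, params) {
  S <- state[["S"]]; D <- state[["D"]]
  p <- params@pBasal / (1 + params@f1 * D^params@kappa1)
  r <- params@rBasal / (1 + params@f2 * D^params@kappa2)
  c(S = r * S * (2 * p - 1),
    D = 2 * r * S * (1 - p) - params@alpha * D)
}

#' Closed-form equilibrium of the basic feedback model
#'
#' For `p' > 0.5` and `f1 > 0` the feedback-regulated model has the stable
#' positive equilibrium
#' `D* = ((2 p' - 1)/f1)^(1/kappa1)` and
#' `S* = (alpha / r') D* (1 + f2 D*^kappa2)`.
#' For `p' <= 0.5` no positive equilibrium exists (the population goes
#' extinct); for `f1 = 0` the model grows without bound when `p' > 0.5`.
#'
#' @param params a [Model1Params-class].
#' @return `list(S = S*, D = D*)`, or `NULL` when no finite positive
#'   equilibrium exists.
#' @export
model1Equilibrium <- function(params) {
  if (params@pBasal <= 0.5 || params@f1 <= 0) return(NULL)
  Dstar <- ((2 * params@pBasal - 1) / params@f1)^(1 / params@kappa1)
  Sstar <- (params@alpha / params@rBasal) * Dstar *
    (1 + params@f2 * Dstar^params@kappa2)
  list(S = Sstar, D = Dstar)
}

#' Numerically integrate the basic mean-field model
#'
#' @param params a [Model1Params-class].
#' @param init named vector `c(S = , D = )`.
#' @param horizon hours.
#' @param times optional output time grid (defaults to 200 points).
#' @param rtol,atol solver tolerances passed to [deSolve::lsoda()].
#' @return Matrix with columns `time`, `S`, `D`.
#' @export
integrateModel1 <- function(params, init, horizon, times = NULL,
                            rtol = 1e-10, atol = 1e-10) {
  if (any(init < 0)) stop("initial state must be non-negative")
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  f <- function(t, y, p) list(model1RHS(y, params))
  unclass(deSolve::lsoda(c(S = init[["S"]], D = init[["D"]]), times, f,
                         rtol = rtol, atol = atol))
}

#' Right-hand side of the mean-field model with carrying capacity
#'
#' The well-mixed counterpart of the lattice simulation:
#' `dS/dt = r S (2p - 1)(1 - (S+D)/K) - eta S`,
#' `dD/dt = 2 r S (1 - p)(1 - (S+D)/K) - alpha D`,
#' `dZ/dt = xi D - beta Z`, with `p = p'/(1 + f Z/K)`.
#'
#' @param state named vector with elements `S`, `D`, `Z`.
#' @param params a [Model2Params-class].
#' @return Named derivative vector.
#' @export
model2RHS <- function(state, params) {
  S <- state[["S"]]; D <- state[["D"]]; Z <- state[["Z"]]
  p <- params@pBasal / (1 + params@f * Z / params@K)
  brake <- 1 - (S + D) / params@K
  c(S = params@r * S * (2 * p - 1) * brake - params@eta * S,
    D = 2 * params@r * S * (1 - p) * brake - params@alpha * D,
    Z = params@xi * D - params@beta * Z)
}

#' Numerically integrate the carrying-capacity mean-field model
#'
#' @param params a [Model2Params-class].
#' @param init named vector `c(S = , D = , Z = )`.
#' @param horizon hours.
#' @param times optional output time grid.
#' @param rtol,atol solver tolerances ([deSolve::lsoda()], stiff-capable).
#' @return Matrix with columns `time`, `S`, `D`, `Z`.
#' @export
integrateModel2 <- function(params, init, horizon, times = NULL,
                            rtol = 1e-10, atol = 1e-10) {
  if (any(init < 0)) stop("initial state must be non-negative")
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  f <- function(t, y, p) list(model2RHS(y, params))
  out <- deSolve::lsoda(c(S = init[["S"]], D = init[["D"]], Z = init[["Z"]]),
                        times, f, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0) stop("ODE integration failed")
  unclass(out)
}

#' Attracting equilibrium of the carrying-capacity model
#'
#' When the low-density growth condition `r(2p' - 1) > eta` holds (for
#' `eta = 0` this is exactly `p' > 0.5`), the system has a stable positive
#' equilibrium, located numerically: a long integration (`10^5` hours) is
#' polished by Newton iteration until `||rhs||_inf <= 1e-10 K`. Otherwise the
#' population dies out and the trivial equilibrium `(0, 0, 0)` is returned.
#' Because the system is invariant under `(S, D, Z, K) -> lambda (S, D, Z, K)`,
#' the equilibrium is exactly proportional to `K`.
#'
#' @param params a [Model2Params-class].
#' @param init starting state for the locating integration.
#' @return Named vector `c(S, D, Z)`.
#' @export
model2Equilibrium <- function(params, init = c(S = 49, D = 0, Z = 0)) {
  if (params@r * (2 * params@pBasal - 1) <= params@eta)
    return(c(S = 0, D = 0, Z = 0))
  traj <- integrateModel2(params, init, 1e5, times = c(0, 1e5))
  x <- traj[nrow(traj), c("S", "D", "Z")]
  rhs <- function(y) {
    y <- unname(y)
    model2RHS(c(S = y[1L], D = y[2L], Z = y[3L]), params)
  }
  for (iter in 1:100) {
    fx <- rhs(x)
    if (max(abs(fx)) <= 1e-12 * params@K) break
    J <- pracma::jacobian(function(y) rhs(y), x)
    x <- x - solve(J, fx)
  }
  if (max(abs(rhs(x))) > 1e-10 * params@K)
    stop("equilibrium root-finding did not converge")
  c(S = x[[1L]], D = x[[2L]], Z = x[[3L]])
}
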