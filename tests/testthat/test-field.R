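noProd <- function(n) matrix(FALSE, n, n)

test_that("field rates match the patch equation on hand-checked cases", {
  # a uniform field is invariant under pure diffusion, boundaries included
  f <- MediatorField(10, 0, 0, 0.83, conc = matrix(2.5, 10, 10))
  expect_equal(fieldRHS(f, noProd(10)), matrix(0, 10, 10))

  # a unit spike in the interior: -8g at the spike, +g on its 8 neighbours
  z <- matrix(0, 9, 9); z[5, 5] <- 1
  f <- MediatorField(9, 0, 0, 0.83, conc = z)
  r <- fieldRHS(f, noProd(9))
  expect_equal(r[5, 5], -8 * 0.83)
  expect_equal(r[4:6, 4:6][-5], rep(0.83, 8))
  expect_equal(sum(abs(r)), 2 * 8 * 0.83)

  # producer patch at its local steady state z = c/b (g = 0)
  zss <- 8.33 / 4.17
  f <- MediatorField(5, 8.33, 4.17, 0, conc = matrix(zss, 5, 5))
  expect_equal(fieldRHS(f, matrix(TRUE, 5, 5)), matrix(0, 5, 5),
               tolerance = 1e-12)

  expect_error(fieldRHS(f, matrix(TRUE, 4, 4)), "dimensions")
})

test_that("pure diffusion conserves mass to 1e-9 in both solver branches", {
  set.seed(42)
  z0 <- matrix(runif(400), 20, 20)
  for (g in c(0.83, 83.3)) {  # explicit RK4 branch, then implicit branch
    f <- MediatorField(20, 0, 0, g, conc = z0)
    f1 <- advanceField(f, noProd(20), 1)
    expect_lt(abs(totalMediator(f1) - sum(z0)) / sum(z0), 1e-9)
    expect_true(all(concentration(f1) >= 0))
  }
})

test_that("scalar closed forms are recovered", {
  # exponential decay: c = 0, g = 0, b = 4.17
  f <- MediatorField(6, 0, 4.17, 0, conc = matrix(1, 6, 6))
  out <- advanceField(f, noProd(6), 1, substeps = 2000)
  expect_equal(concentration(out)[3, 3], exp(-4.17), tolerance = 1e-9)

  # saturating production on every patch: z(t) = (c/b)(1 - e^{-bt}),
  # independent of g because the field stays uniform
  f <- MediatorField(8, 8.33, 4.17, 0.83)
  out <- advanceField(f, matrix(TRUE, 8, 8), 1)
  expect_equal(max(abs(concentration(out) - 8.33 / 4.17 * (1 - exp(-4.17)))),
               0, tolerance = 1e-4)
  # approach to the uniform steady state c/b (residual e^{-bt} ~ 5e-5 at
  # t = 10/b)
  out <- advanceField(f, matrix(TRUE, 8, 8), 10 / 4.17)
  expect_equal(concentration(out)[4, 4], 8.33 / 4.17, tolerance = 1e-3)
})

test_that("the advance map is linear in the initial field for a fixed mask", {
  set.seed(7)
  n <- 7
  z1 <- matrix(runif(n^2), n, n); z2 <- matrix(runif(n^2), n, n)
  adv <- function(z) concentration(advanceField(
    MediatorField(n, 0, 0.9, 0.4, conc = z), noProd(n), 1))
  expect_equal(adv(2 * z1 + 3 * z2), 2 * adv(z1) + 3 * adv(z2),
               tolerance = 1e-8)
})

test_that("the field advance agrees with a dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (n in c(4, 6, 8)) {
    set.seed(n)
    z0 <- matrix(runif(n^2), n, n)
    mask <- matrix(runif(n^2) < 0.4, n, n)
    cc <- 2.3; b <- 1.1; g <- 0.7
    # dense generator built independently from mooreNeighbors
    N <- n^2
    A <- matrix(0, N, N)
    id <- function(r, c) r + (c - 1) * n
    for (r in 1:n) for (c in 1:n) {
      nb <- mooreNeighbors(n, r, c)
      A[id(r, c), id(r, c)] <- -b - nrow(nb) * g
      for (k in seq_len(nrow(nb)))
        A[id(r, c), id(nb[k, 1], nb[k, 2])] <- g
    }
    E <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
    exact <- E %*% as.vector(z0) +
      solve(A, (E - diag(N)) %*% (cc * as.vector(mask)))
    f <- MediatorField(n, cc, b, g, conc = z0)
    got <- concentration(advanceField(f, mask, 1, substeps = 20000))
    expect_lt(max(abs(as.vector(got) - exact)), 1e-6)
  }
})

test_that("the stiff implicit branch approximates a converged explicit solve", {
  n <- 6
  set.seed(3)
  z0 <- matrix(runif(n^2), n, n)
  mask <- matrix(runif(n^2) < 0.4, n, n)
  f <- MediatorField(n, 8.33, 4.17, 83.3, conc = z0)  # b + 16 g > 480
  imp <- concentration(advanceField(f, mask, 1))
  ref <- concentration(advanceField(f, mask, 1, substeps = 2e5))
  expect_lt(max(abs(imp - ref) / pmax(ref, 1e-9)), 0.05)
  expect_true(all(imp >= 0))
})

test_that("totals and snapshots behave", {
  expect_equal(totalMediator(MediatorField(10, 0, 0, 0)), 0)
  f <- MediatorField(10, 0, 0, 0, conc = matrix(0.37, 10, 10))
  expect_equal(totalMediator(f), 37)
  set.seed(9)
  z <- matrix(rexp(25), 5, 5)
  f <- MediatorField(5, 1, 1, 1, conc = z)
  # brute-force loop oracle
  tot <- 0
  for (i in 1:5) for (j in 1:5) tot <- tot + z[i, j]
  expect_equal(totalMediator(f), tot)

  path <- tempfile(fileext = ".txt")
  writeFieldSnapshot(f, path)
  expect_equal(readFieldSnapshot(path), z, tolerance = 1e-9)
  unlink(path)
})

test_that("invalid field inputs are rejected", {
  f <- MediatorField(5, 1, 1, 1)
  expect_error(advanceField(f, matrix(FALSE, 4, 4)), "dimensions")
  expect_error(advanceField(f, matrix(FALSE, 5, 5), duration = 0), "positive")
  expect_error(MediatorField(5, -1, 1, 1))
  expect_error(MediatorField(5, 1, 1, 1, conc = matrix(-1, 5, 5)))
})
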