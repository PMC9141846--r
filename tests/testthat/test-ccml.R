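test_that("1D checkerboard matches the hand-worked sign pattern", {
  M <- checkerboard_1d(4)$M
  ## 0-based rule M[i, i+-1] = (-1)^i, periodic
  expect_equal(M[1, 2], 1);  expect_equal(M[1, 4], 1)
  expect_equal(M[2, 1], -1); expect_equal(M[2, 3], -1)
  expect_equal(M[3, 2], 1);  expect_equal(M[3, 4], 1)
  expect_equal(M[4, 3], -1); expect_equal(M[4, 1], -1)
  expect_equal(sum(M != 0), 8L)
})

test_that("checkerboard constructions are exactly antisymmetric with imaginary spectra", {
  for (cm in list(checkerboard_1d(4), checkerboard_1d(64),
                  checkerboard_2d(4, 4), checkerboard_2d(8, 6),
                  bipartite_gaussian_2d(6, 6),
                  bipartite_gaussian_2d(5, 7, sigma = 1.5))) {
    expect_identical(max(abs(cm$M + t(cm$M))), 0)
    ev <- eigen(cm$M, only.values = TRUE)$values
    expect_lt(max(abs(Re(ev))), 1e-10 * max(1, max(abs(ev))))
  }
  expect_error(checkerboard_1d(7), "even")
  expect_error(checkerboard_2d(4, 5), "even")
})

test_that("2D checkerboard rows have four unit couplings", {
  M <- checkerboard_2d(4, 4)$M
  expect_true(all(rowSums(M != 0) == 4))
  expect_true(all(abs(M[M != 0]) == 1))
})

test_that("bipartite Gaussian kernel has the printed values and translation invariance", {
  cm <- bipartite_gaussian_2d(8, 8, sigma = 1)
  n <- 64
  K <- cm$M[1:n, (n + 1):(2 * n)]
  ## site 1 is (0,0); site 2 is (1,0) in the flattened layout
  expect_equal(K[1, 1], 1)
  expect_equal(K[1, 2], exp(-1 / 2))
  ## circulant structure: K depends only on the periodic displacement
  shift <- function(p, di, dj) {
    i <- (p - 1) %% 8; j <- (p - 1) %/% 8
    ((i + di) %% 8) + 8 * ((j + dj) %% 8) + 1
  }
  for (p in c(1, 13, 40)) for (q in c(2, 22, 57)) {
    expect_equal(K[p, q], K[shift(p, 2, 3), shift(q, 2, 3)])
  }
})

test_that("exposure operators are orthogonal with unit determinant", {
  cm1 <- checkerboard_1d(16)
  cm2 <- checkerboard_2d(4, 4)
  cm3 <- bipartite_gaussian_2d(4, 4)
  for (cm in list(cm1, cm2, cm3)) for (lam in c(0, 0.5, 2, 8)) {
    U <- exposure(cm, lam)$U
    n <- nrow(U)
    expect_lt(max(abs(crossprod(U) - diag(n))), 1e-8)
    expect_lt(abs(det(U) - 1), 1e-8)
  }
  expect_identical(exposure(cm1, 0)$U, diag(16))
})

test_that("matrix exponential matches the eigendecomposition closed form at n = 4", {
  cm <- checkerboard_1d(4)
  lam <- 1.3
  ## -i M is Hermitian: orthonormal eigenbasis, real eigenfrequencies w,
  ## U = Re(V exp(i lam w) V*) -- the cosine/sine closed form
  h <- eigen(-1i * cm$M, symmetric = TRUE)
  U_closed <- Re(h$vectors %*% diag(exp(1i * lam * h$values)) %*%
                   Conj(t(h$vectors)))
  expect_lt(max(abs(exposure(cm, lam)$U - U_closed)), 1e-12)
})

test_that("row decomposition splits onto sublattices and broadens with exposure", {
  cm <- checkerboard_1d(64)
  rd <- row_decomposition(exposure(cm, 4))
  even <- rd$offsets %% 2 == 0
  ## cosh part lives on even offsets, sinh part on odd offsets
  expect_lt(max(abs(rd$symmetric[!even])), 1e-12)
  expect_lt(max(abs(rd$antisymmetric[even])), 1e-12)
  expect_gt(max(abs(rd$symmetric[even])), 0.01)
  ## magnitudes are even in the offset
  for (o in 1:31) {
    i_p <- which(rd$offsets == o); i_m <- which(rd$offsets == -o)
    expect_equal(abs(rd$symmetric[i_p]), abs(rd$symmetric[i_m]),
                 tolerance = 1e-10)
    expect_equal(abs(rd$antisymmetric[i_p]), abs(rd$antisymmetric[i_m]),
                 tolerance = 1e-10)
  }
  ## lam = 0: delta at the origin, no antisymmetric part
  rd0 <- row_decomposition(exposure(cm, 0))
  expect_equal(rd0$symmetric[rd0$offsets == 0], 1)
  expect_lt(max(abs(rd0$antisymmetric)), 1e-15)
  ## diffusive broadening
  rd8 <- row_decomposition(exposure(cm, 8))
  expect_gt(rd8$width90_sym, rd$width90_sym)
  ## 2D sources are refused
  expect_error(row_decomposition(exposure(checkerboard_2d(4, 4), 1)), "1D")
})

test_that("the Gaussian map has the printed values and bound", {
  expect_identical(gaussian_map(0, 3), 0)
  expect_equal(gaussian_map(1, 1), exp(-0.5))
  x <- seq(-5, 5, by = 1e-3)
  expect_lte(max(abs(gaussian_map(x, 2))), 2 * exp(-0.5))
  expect_equal(max(abs(gaussian_map(c(-1, 1), 2))), 2 * exp(-0.5))
})

test_that("the stroboscopic step applies map then norm-preserving coupling", {
  cm <- checkerboard_1d(16)
  set.seed(7)
  v <- rnorm(16)
  ## lam = 0 reduces to the bare map, bit for bit
  expect_identical(ccml_step(v, exposure(cm, 0), 1.7),
                   as.numeric(diag(16) %*% gaussian_map(v, 1.7)))
  ## quiescent state is invariant
  expect_identical(ccml_step(numeric(16), exposure(cm, 0.7), 1.7),
                   numeric(16))
  ## orthogonal coupling preserves the norm of the mapped field
  for (i in 1:5) {
    v <- rnorm(16, sd = i)
    out <- ccml_step(v, exposure(cm, 0.7), 2.5)
    expect_equal(sqrt(sum(out^2)), sqrt(sum(gaussian_map(v, 2.5)^2)),
                 tolerance = 1e-10)
  }
})

test_that("subcritical maps decay and trajectories are deterministic", {
  cm <- checkerboard_1d(16)
  op <- exposure(cm, 0.5)
  f0 <- random_field(16, a = 0.5, seed = 3)
  sim <- ccml_simulate(f0, op, c = 0.8, steps = 200, transient = 0)
  expect_lt(sqrt(mean(sim$values[, 200]^2)), 1e-6)
  s1 <- ccml_simulate(f0, op, c = 2, steps = 50, transient = 10)
  s2 <- ccml_simulate(f0, op, c = 2, steps = 50, transient = 10)
  expect_identical(s1$values, s2$values)
  expect_equal(dim(s1$values), c(16L, 40L))
})

test_that("printed 2D bipartite parameter points run without blow-up", {
  bp <- bipartite_gaussian_2d(8, 8)
  for (pp in list(c(0.5, -1.2), c(0.53, -2.3))) {
    sim <- ccml_simulate(random_field(128, seed = 2), exposure(bp, pp[1]),
                         pp[2], steps = 400, transient = 100)
    expect_true(all(is.finite(sim$values)))
    expect_gt(sqrt(mean(sim$values^2)), 0.05)  # sustained activity
  }
})
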