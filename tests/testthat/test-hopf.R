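test_that("steady response follows the closed forms at and below criticality", {
  ## unforced: origin for mu <= 0, limit cycle sqrt(mu) for mu > 0
  expect_equal(hopf_steady_response(hopf_params(mu = 0, F = 0))$amplitude, 0)
  expect_equal(hopf_steady_response(hopf_params(mu = -1, F = 0))$amplitude, 0)
  expect_equal(hopf_steady_response(hopf_params(mu = 0.04, F = 0))$amplitude,
               0.2)
  ## critical resonant response: R^3 = F
  expect_equal(hopf_steady_response(hopf_params(F = 1e-6))$amplitude, 1e-2,
               tolerance = 1e-10)
  for (F in 10^seq(-9, -1)) {
    R <- hopf_steady_response(hopf_params(mu = 0, omega0 = 1, F = F))$amplitude
    expect_lt(abs(R^3 - F) / F, 1e-10)
  }
  ## every returned root solves the response cubic (independent residual check)
  p <- hopf_params(mu = 0.3, omega0 = 2, F = 0.05, omega = 2.1)
  r <- hopf_steady_response(p)
  for (R in r$roots) {
    resid <- R^2 * ((p$mu - R^2)^2 + (p$omega0 - p$omega)^2) - p$F^2
    expect_lt(abs(resid), 1e-12)
  }
})

test_that("bistable regime reports all roots sorted, flagged", {
  ## mu = 1, detuning 0.2 < mu/sqrt(3), F^2 between the fold values
  p <- hopf_params(mu = 1, omega0 = 1, F = sqrt(0.1), omega = 1.2)
  r <- hopf_steady_response(p)
  expect_true(r$multistable)
  expect_length(r$roots, 3L)
  expect_equal(r$roots, sort(r$roots))
  expect_equal(r$amplitude, r$roots[1])
})

test_that("time integration reproduces steady amplitudes and transient decay", {
  ## damped linear regime: |z| decays essentially to zero within 10 units
  tr <- hopf_simulate(hopf_params(mu = -1), duration = 10, z0 = 0.1)
  expect_lt(tr$amplitude[length(tr$amplitude)], 1e-4)
  ## critical forced response R = F^(1/3)
  tr <- hopf_simulate(hopf_params(F = 1e-3), duration = 2000, dt = 0.05)
  expect_equal(tr$amplitude[length(tr$amplitude)], 0.1, tolerance = 0.01)
  ## spontaneous limit cycle grows from small seed to sqrt(mu)
  tr <- hopf_simulate(hopf_params(mu = 0.04, F = 0), duration = 400,
                      z0 = 1e-3)
  expect_equal(tr$amplitude[length(tr$amplitude)], 0.2, tolerance = 0.01)
})

test_that("simulation agrees with the steady-state root on the unique branch", {
  set.seed(42)
  for (i in 1:8) {
    mu <- runif(1, -1, 0)           # subcritical: single branch guaranteed
    F <- 10^runif(1, -4, -1)
    off <- runif(1, -0.3, 0.3)
    p <- hopf_params(mu = mu, omega0 = 1, F = F, omega = 1 + off)
    r <- hopf_steady_response(p)
    expect_false(r$multistable)
    tr <- hopf_simulate(p, duration = 60 / max(abs(mu), 0.1), dt = 0.05)
    expect_equal(tr$amplitude[length(tr$amplitude)], r$amplitude,
                 tolerance = 0.01)
  }
})

test_that("response exponent is 1/3 at criticality and 1 in the linear regime", {
  Fg <- exp(seq(log(1e-8), log(1e-2), length.out = 30))
  e <- hopf_response_exponent(mu = 0, omega_offset = 0, F_grid = Fg)
  expect_gt(e$slope, 0.32); expect_lt(e$slope, 0.34)
  expect_false(e$low_confidence)
  e2 <- hopf_response_exponent(mu = -1, omega_offset = 0,
                               F_grid = exp(seq(log(1e-8), log(1e-4),
                                                length.out = 20)))
  expect_equal(e2$slope, 1, tolerance = 1e-6)
  ## one-decade grid: same law, but flagged low-confidence
  e3 <- hopf_response_exponent(0, 0, exp(seq(log(1e-6), log(1e-5),
                                             length.out = 10)))
  expect_true(e3$low_confidence)
  expect_equal(e3$slope, 1/3, tolerance = 1e-6)
})

test_that("tuning sharpens and gain diverges as forcing weakens at criticality", {
  og <- seq(0.8, 1.2, length.out = 401)
  t1 <- hopf_tuning_curve(mu = 0, F = 1e-4, omega_grid = og)
  t2 <- hopf_tuning_curve(mu = 0, F = 1e-2, omega_grid = og)
  ## resonant gain F^(-2/3)
  expect_equal(attr(t1, "gain"), 1e-4^(-2/3), tolerance = 1e-3)
  ## relative half-width grows with forcing
  expect_lt(attr(t1, "half_width"), attr(t2, "half_width"))
  ## linear-response gain bound away from criticality
  t3 <- hopf_tuning_curve(mu = -1, F = 1e-3, omega_grid = og)
  expect_lte(attr(t3, "gain"), 1 / abs(-1) * (1 + 1e-9))
})
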