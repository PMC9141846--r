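test_that("the synthetic generator is seeded and honours its stability guard", {
  s1 <- synth_series(4, 2, 100, eigs4, seed = 7)
  s2 <- synth_series(4, 2, 100, eigs4, seed = 7)
  expect_identical(s1$data, s2$data)
  expect_error(synth_series(2, 1, 100, list(c(0.5, 3))), "unstable")
  expect_s3_class(synth_series(2, 1, 100, list(c(0.5, 3)), force = TRUE),
                  "mc_series")
  ## channel-count bookkeeping: a conjugate pair consumes two states
  expect_error(synth_series(3, 1, 100, eigs4), "states")
})

test_that("fast-decaying modes give the expected autocorrelation time", {
  ## all modes at Re = -50 1/s: OU-like autocorrelation time 1/50 s
  s <- synth_series(4, 30, 1000, list(c(-50, 0), c(-50, 0), c(-50, 0),
                                      c(-50, 0)), seed = 3)
  a <- acf(s$data[1, ], lag.max = 200, plot = FALSE)$acf[, 1, 1]
  tau <- (which(a < exp(-1))[1] - 1) / 1000
  expect_gt(tau, 0.5 / 50); expect_lt(tau, 2 / 50)
})

test_that("noiseless blocks recover the true propagator exactly", {
  s <- synth_series(4, 0.5, 200, eigs4, noise_level = 0, seed = 5)
  f <- fit_window(s$data[, 1:20])
  expect_lt(max(abs(f$A - s$provenance$A_true)), 1e-8)
  expect_false(f$rank_deficient)
  ## least-squares error shrinks with block length
  sn <- synth_series(4, 40, 200, eigs4, seed = 6)
  e_short <- max(abs(fit_window(sn$data[, 1:200])$A - sn$provenance$A_true))
  e_long <- max(abs(fit_window(sn$data)$A - sn$provenance$A_true))
  expect_lt(e_long, e_short)
  ## constant input takes the flagged pseudo-inverse path
  expect_warning(fc <- fit_window(matrix(1, 3, 50)), "rank-deficient")
  expect_true(fc$rank_deficient)
  ## too-short blocks are refused
  expect_error(fit_window(matrix(rnorm(12), 4, 3)), "samples")
})

test_that("window eigenvalues are consistent between discrete and continuous forms", {
  s <- synth_series(4, 10, 100, eigs4, seed = 11)
  fits <- critical_modes(s, window = 1, hop = 0.5)
  for (w in fits$windows) {
    expect_equal(sort(Re(eigen(w$A, only.values = TRUE)$values)),
                 sort(Re(w$eigs_discrete)), tolerance = 1e-12)
    expect_lt(max(Mod(exp(w$eigs_continuous / fits$fs) - w$eigs_discrete)),
              1e-10)
  }
  ## a window spanning the full series equals a single direct fit
  f_all <- critical_modes(s, window = 10, hop = 10)
  expect_length(f_all$windows, 1L)
  expect_equal(f_all$windows[[1]]$A, fit_window(s$data)$A)
})

test_that("a mid-series stabilization shows up as a shift in window eigenvalues", {
  sA <- synth_series(4, 10, 100, list(c(-2, 8), c(-2, 20)), seed = 21)
  sB <- synth_series(4, 10, 100, list(c(-30, 8), c(-30, 20)), seed = 22)
  s <- mc_series(cbind(sA$data, sB$data), 100)
  fits <- critical_modes(s, window = 1, hop = 1)
  mean_re <- vapply(fits$windows,
                    function(w) mean(Re(w$eigs_continuous)), 0)
  st <- vapply(fits$windows, `[[`, 0, "start_time")
  expect_gt(mean(mean_re[st < 9]), mean(mean_re[st > 11]) + 10)
})

test_that("surrogates preserve what they claim to preserve", {
  s <- synth_series(4, 4, 100, eigs4, seed = 13)
  ## per-channel marginals survive the time shuffle exactly
  sh <- surrogate(s, "channel_time_shuffle", seed = 1)
  for (ch in 1:4)
    expect_identical(sort(sh$data[ch, ]), sort(s$data[ch, ]))
  ## phase randomization keeps per-channel periodograms
  pr <- surrogate(s, "phase_randomize", seed = 2)
  for (ch in 1:4) {
    expect_equal(Mod(fft(pr$data[ch, ])), Mod(fft(s$data[ch, ])),
                 tolerance = 1e-8)
  }
  expect_gt(max(abs(pr$data - s$data)), 0.01)  # but the series differs
  ## window shuffle permutes intact blocks
  ws <- surrogate(s, "window_shuffle", seed = 3, window_len = 50)
  orig_blocks <- apply(matrix(seq_len(400), 50), 2,
                       function(ix) paste(signif(s$data[1, ix], 10),
                                          collapse = ","))
  shuf_blocks <- apply(matrix(seq_len(400), 50), 2,
                       function(ix) paste(signif(ws$data[1, ix], 10),
                                          collapse = ","))
  expect_setequal(shuf_blocks, orig_blocks)
  expect_false(identical(shuf_blocks, orig_blocks))
})

test_that("shuffling drives fitted eigenvalues away from the instability line", {
  for (sd_ in 1:3) {
    s <- synth_series(4, 20, 100, list(c(-1, 5), c(-3, 12)), seed = sd_)
    f0 <- critical_modes(s, window = 1, hop = 1)
    f1 <- critical_modes(surrogate(s, "channel_time_shuffle", seed = sd_),
                         window = 1, hop = 1)
    expect_gt(criticality_index(f1)$mean_abs_re,
              criticality_index(f0)$mean_abs_re)
  }
})

test_that("the criticality index recovers known mode decay rates", {
  ## noiseless transient: pooled |Re| equals the mean of the target |Re|
  s <- synth_series(4, 0.4, 250, eigs4, noise_level = 0, seed = 8)
  fits <- critical_modes(s, window = 0.4, hop = 0.4)
  expect_equal(criticality_index(fits)$mean_abs_re, (3 + 3 + 9 + 5) / 4,
               tolerance = 1e-6)
  ## ordering across generator conditions
  deep <- critical_modes(synth_series(4, 20, 100,
                                      list(c(-50, 5), c(-50, 12)),
                                      seed = 2), window = 1, hop = 1)
  shallow <- critical_modes(synth_series(4, 20, 100,
                                         list(c(-1, 5), c(-1, 12)),
                                         seed = 2), window = 1, hop = 1)
  expect_gt(criticality_index(deep)$mean_abs_re,
            criticality_index(shallow)$mean_abs_re)
})

test_that("eigenvalue histograms pool, fold, and separate conditions", {
  re_e <- seq(-60, 10, by = 2); im_e <- seq(-50, 50, by = 2)
  sA <- synth_series(4, 20, 100, list(c(-2, 5), c(-2, 15)), seed = 31)
  sB <- synth_series(4, 20, 100, list(c(-20, 5), c(-20, 15)), seed = 32)
  fA <- critical_modes(sA, window = 1, hop = 1)
  fB <- critical_modes(sB, window = 1, hop = 1)
  hA <- eigen_histogram(fA, re_e, im_e, "awake-like")
  hB <- eigen_histogram(fB, re_e, im_e, "anesthetized-like")
  ## all eigenvalues accounted for
  nw <- length(fA$windows)
  expect_equal(sum(hA$counts) + hA$overflow, nw * 4)
  ## conjugate symmetry: fold over Im = 0
  expect_equal(hA$counts, hA$counts[, ncol(hA$counts):1])
  ## the stabilized condition sits further left
  expect_lt(critpoise:::hist_re_center(hB),
            critpoise:::hist_re_center(hA) - 10)
})

test_that("the stability-shift permutation test behaves at its edges", {
  s <- synth_series(4, 10, 100, eigs4, seed = 41)
  f <- critical_modes(s, window = 1, hop = 1)
  sh <- stability_shift(f, f, n_perm = 99, seed = 1)
  expect_identical(sh$delta_mean_re, 0)
  expect_gt(sh$permutation_p, 0.5)  # identical inputs cannot look extreme
  ## refuses degenerate inputs
  f1 <- critical_modes(s, window = 10, hop = 10)  # single window
  expect_error(stability_shift(f1, f, n_perm = 9), "2 clean windows")
})
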