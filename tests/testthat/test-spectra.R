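test_that("constant fields concentrate all power at DC", {
  s <- make_series_1d(matrix(2.5, 8, 32))
  sp <- st_spectrum(s, block_len = 32)
  dc <- critpoise:::dc_mask(sp)
  expect_gt(sp$power[dc], 0)
  expect_lt(sum(sp$power[!dc]), 1e-20 * sum(sp$power))
  ## zero non-DC power means entropy is undefined
  expect_error(spectral_entropy(sp), "undefined")
  expect_equal(low_frequency_power(sp), 0)
})

test_that("a bin-aligned travelling wave occupies one conjugate bin pair", {
  s <- plane_wave_series(n = 16, nt = 64, k = 3, f = 5)
  sp <- st_spectrum(s, block_len = 64)
  p <- sort(as.numeric(sp$power), decreasing = TRUE)
  expect_gt(sum(p[1:2]), 0.999 * sum(p))
  expect_equal(p[1], p[2], tolerance = 1e-10)
})

test_that("Parseval holds per block", {
  s <- noise_series_1d(n = 8, nt = 64, seed = 4)
  sp <- st_spectrum(s, block_len = 64)  # single block
  expect_equal(sum(sp$power), sum(s$values^2), tolerance = 1e-8)
})

test_that("white-noise spectra are flat and flatten further with averaging", {
  rel_spread <- function(nt) {
    s <- noise_series_1d(n = 16, nt = nt, seed = 11)
    sp <- st_spectrum(s, block_len = 64)
    sd(sp$power) / mean(sp$power)
  }
  expect_lt(rel_spread(2048), rel_spread(128))
  ## low-frequency power of white noise is about the band's bin fraction
  s <- noise_series_1d(n = 16, nt = 4096, seed = 12)
  sp <- st_spectrum(s, block_len = 64)
  rel <- array(0, dim = dim(sp$power))
  for (d in 1:2)
    rel <- pmax(rel, critpoise:::aperm_axis(abs(sp$axes[[d]]) / 0.5,
                                            dim(sp$power), d))
  dc <- critpoise:::dc_mask(sp)
  frac_bins <- sum(rel <= 0.1 & !dc) / sum(!dc)
  expect_equal(low_frequency_power(sp, 0.1), frac_bins, tolerance = 0.25)
})

test_that("entropy reaches its bounds on degenerate spectra", {
  ## all power in one bin -> 0 bits
  p <- array(0, dim = c(8, 16)); p[3, 5] <- 1
  expect_equal(spectral_entropy(make_spectrum(p)), 0)
  ## uniform power over B bins -> log2(B) bits
  p <- array(1, dim = c(8, 16))
  expect_equal(spectral_entropy(make_spectrum(p), exclude_dc = FALSE),
               log2(8 * 16))
  expect_equal(spectral_entropy(make_spectrum(p)), log2(8 * 16 - 1))
})

test_that("synchronized (spatially uniform, temporally white) trajectories have no spatial spread", {
  set.seed(5)
  row <- rnorm(256)
  s <- make_series_1d(matrix(row, 16, 256, byrow = TRUE))
  sp <- st_spectrum(s, block_len = 128)
  k0 <- which(sp$axes[[1]] == 0)
  expect_gt(sum(sp$power[k0, ]), 0.999 * sum(sp$power))
  ## temporal spread is broad: many temporal bins carry power
  pt <- sp$power[k0, ]
  expect_gt(sum(pt > 0.1 * mean(pt)), 64)
})

test_that("spectra are invariant under lattice translation", {
  s <- noise_series_1d(n = 16, nt = 128, seed = 8)
  s_shift <- make_series_1d(s$values[c(6:16, 1:5), ])
  sp1 <- st_spectrum(s, block_len = 64)
  sp2 <- st_spectrum(s_shift, block_len = 64)
  expect_lt(max(abs(sp1$power - sp2$power)), 1e-10 * max(sp1$power))
})

test_that("slow large-scale patterns put their power in the low-frequency band", {
  s <- plane_wave_series(n = 32, nt = 128, k = 1, f = 2)
  sp <- st_spectrum(s, block_len = 128)
  expect_gt(low_frequency_power(sp, band = 0.1), 0.999)
})

test_that("phase diagram cells are bounded, flagged, and reproducible in isolation", {
  cm <- checkerboard_1d(16)
  pd <- phase_diagram(cm, c_values = c(0.5, 2.5), lam_values = c(0.3, 0.6),
                      steps = 300, transient = 44, block_len = 64, seed = 9)
  expect_equal(dim(pd$entropy), c(2L, 2L))
  ## subcritical c column is quiescent
  expect_true(all(pd$flags[1, ] == "quiescent"))
  expect_true(all(is.na(pd$entropy[1, ])))
  ## active cells respect the entropy bound
  nbins <- 16 * 64 - 1
  expect_true(all(pd$entropy[2, ] >= 0 & pd$entropy[2, ] <= log2(nbins)))
  expect_true(all(pd$low_freq_power[2, ] >= 0 & pd$low_freq_power[2, ] <= 1))
  ## any cell is reproducible from its derived seed alone
  cell_seed <- critpoise:::derive_seed(9, 2, 1)
  sim <- ccml_simulate(random_field(16, a = 1, seed = cell_seed),
                       exposure(cm, 0.3), 2.5, 300, 44)
  expect_equal(spectral_entropy(st_spectrum(sim, 64)), pd$entropy[2, 1])
})
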