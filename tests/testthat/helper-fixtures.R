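## Shared fixtures, all generated in code.

## lattice_series built directly from a values matrix (1D chain)
make_series_1d <- function(values) {
  structure(list(values = values,
                 geometry = lattice_geometry("chain_1d", nrow(values)),
                 params = list(c = NA_real_, lam = NA_real_),
                 transient = 0L),
            class = "lattice_series")
}

## bin-aligned travelling plane wave on an n-site chain over nt steps:
## x_i^t = cos(2*pi*(k*i/n - f*t/nt))
plane_wave_series <- function(n = 16, nt = 64, k = 3, f = 5) {
  i <- 0:(n - 1); t <- 0:(nt - 1)
  make_series_1d(cos(2 * pi * outer(k * i / n, f * t / nt, `-`)))
}

## white-noise series on a chain
noise_series_1d <- function(n = 16, nt = 128, seed = 1) {
  set.seed(seed)
  make_series_1d(matrix(rnorm(n * nt), n, nt))
}

## st_spectrum with a manually prescribed power array (1D chain axes)
make_spectrum <- function(power) {
  axes <- lapply(dim(power), function(m) {
    k <- 0:(m - 1L)
    ifelse(k <= m %/% 2, k, k - m) / m
  })
  structure(list(power = power, axes = axes, n_averages = 1L),
            class = "st_spectrum")
}

## a small stable mode specification consuming exactly 4 channels
eigs4 <- list(c(-3, 7), c(-9, 0), c(-5, 0))
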