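#' Spatiotemporal power spectrum of a lattice trajectory
#'
#' Fourier transforms the field over all spatial dimensions and over
#' time within blocks of `block_len` steps (overlapping by `overlap`),
#' and averages the modulus-squared across blocks. The power array is
#' normalized so that, per block, the sum over all bins equals the sum
#' of squared field values (Parseval). No taper is applied: map
#' trajectories are not continuous signals, and leakage is consistent
#' across parameter cells.
#'
#' @param series A `lattice_series` from [ccml_simulate()].
#' @param block_len Time samples per block (default 128).
#' @param overlap Fractional overlap between consecutive blocks
#'   (default 0.5).
#' @return An `st_spectrum`: `power` array over (spatial bins...,
#'   temporal bins), `axes` (list of normalized frequency vectors in
#'   cycles per sample, one per dimension; time last), `n_averages`.
#' @export
st_spectrum <- function(series, block_len = 128L, overlap = 0.5) {
  stopifnot(inherits(series, "lattice_series"),
            overlap >= 0, overlap < 1)
  arr <- series_array(series)
  nd <- length(dim(arr))
  nt <- dim(arr)[nd]
  block_len <- as.integer(block_len)
  if (block_len > nt)
    stop(sprintf("block_len = %d exceeds series length %d", block_len, nt))
  hop <- max(1L, as.integer(round(block_len * (1 - overlap))))
  starts <- seq.int(1L, nt - block_len + 1L, by = hop)
  spat <- dim(arr)[-nd]
  power <- array(0, dim = c(spat, block_len))
  N <- prod(dim(power))
  idx <- c(lapply(spat, seq_len), list(NULL))  # spatial slices fixed
  for (s0 in starts) {
    idx[[nd]] <- s0:(s0 + block_len - 1L)
    block <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    power <- power + Mod(stats::fft(block))^2 / N
  }
  power <- power / length(starts)
  axes <- lapply(dim(power), function(m) {
    k <- 0:(m - 1L)
    ifelse(k <= m %/% 2, k, k - m) / m
  })
  structure(list(power = power, axes = axes,
                 n_averages = length(starts)),
            class = "st_spectrum")
}

#' @method print st_spectrum
#' @export
print.st_spectrum <- function(x, ...) {
  cat(sprintf("Spatiotemporal spectrum: %s bins, %d block average(s), total power %.6g\n",
              paste(dim(x$power), collapse = " x "), x$n_averages,
              sum(x$power)))
  invisible(x)
}

## logical array marking the DC (all-zero-frequency) bin
dc_mask <- function(spec) {
  m <- array(TRUE, dim = dim(spec$power))
  for (d in seq_along(spec$axes)) {
    zero <- spec$axes[[d]] == 0
    m <- m & aperm_axis(zero, dim(spec$power), d)
  }
  m
}

## broadcast a per-axis logical/numeric vector over the full array shape
aperm_axis <- function(v, dims, d) {
  perm <- seq_along(dims)
  perm[c(1L, d)] <- perm[c(d, 1L)]
  aperm(array(v, dim = dims[perm]), order(perm))
}

#' Spectral entropy of a spatiotemporal spectrum
#'
#' Treats the power spectrum, normalized to sum to 1 over the included
#' bins, as a probability distribution and returns its Shannon entropy
#' in bits. Concentrated spectra (pure regimes: frozen patterns,
#' synchronized states) give low entropy; broadband spectra (chaos)
#' give high entropy; complex spatiotemporal behaviour sits in between.
#' The DC bin is excluded by default since the interesting structure
#' lives at low but non-zero frequencies.
#'
#' @param spec An [st_spectrum()].
#' @param exclude_dc Drop the all-zero-frequency bin (default TRUE).
#' @return Entropy in bits, in `[0, log2(#included bins)]`.
#' @export
spectral_entropy <- function(spec, exclude_dc = TRUE) {
  stopifnot(inherits(spec, "st_spectrum"))
  p <- as.numeric(spec$power)
  if (exclude_dc) p <- p[!dc_mask(spec)]
  tot <- sum(p)
  if (tot <= 0)
    stop("zero total power: entropy undefined")
  p <- p[p > 0] / tot
  -sum(p * log2(p))
}

#' Low-frequency power fraction
#'
#' Fraction of the non-DC power lying in the low-frequency box
#' `0 < max_d |f_d| / Nyquist_d <= band` (infinity-norm ball over all
#' spatial and temporal frequency axes, DC excluded). Complex
#' long-range, long-time behaviour concentrates power at low but
#' non-zero spatiotemporal frequencies and scores near 1; white
#' (chaotic) spectra score near the band's bin-volume fraction.
#'
#' @param spec An [st_spectrum()].
#' @param band Fraction of Nyquist defining "low" (default 0.1).
#' @return Fraction in `[0, 1]`.
#' @export
low_frequency_power <- function(spec, band = 0.1) {
  stopifnot(inherits(spec, "st_spectrum"), band > 0, band < 0.5 + 1e-12)
  rel <- array(0, dim = dim(spec$power))
  for (d in seq_along(spec$axes))
    rel <- pmax(rel, aperm_axis(abs(spec$axes[[d]]) / 0.5,
                                dim(spec$power), d))
  dc <- dc_mask(spec)
  p <- as.numeric(spec$power)
  denom <- sum(p[!dc])
  if (denom <= 0) return(0)
  sum(p[!dc & rel <= band]) / denom
}

#' Spectral-entropy phase diagram over (c, lambda)
#'
#' For each exposure time `lambda` the operator `U = expm(lambda * M)`
#' is built once; for each map prefactor `c` the lattice is simulated
#' from a seeded random field, and the spectral entropy and
#' low-frequency power of the post-transient trajectory are recorded.
#' Each cell's RNG seed is derived from `(seed, c index, lambda index)`
#' so any cell can be reproduced in isolation. Cells whose field decays
#' to numerical zero are flagged `"quiescent"` (entropy `NA`); cells
#' that blow up are flagged `"blowup"` and never abort the sweep.
#'
#' @param coupling A `coupling_matrix`.
#' @param c_values,lam_values Grid vectors.
#' @param steps,transient Simulation length and discarded prefix.
#' @param block_len,overlap Spectrum block parameters
#'   (see [st_spectrum()]).
#' @param band Low-frequency band (see [low_frequency_power()]).
#' @param field_scale Half-width of the uniform initial field.
#' @param seed Global seed.
#' @return A `phase_diagram`: `entropy` and `low_freq_power` matrices
#'   (rows = c, cols = lambda), `flags` matrix, grids, and the run
#'   configuration.
#' @export
phase_diagram <- function(coupling, c_values, lam_values,
                          steps = 768L, transient = 256L,
                          block_len = 128L, overlap = 0.5, band = 0.1,
                          field_scale = 1, seed = 1L) {
  stopifnot(inherits(coupling, "coupling_matrix"),
            length(c_values) >= 1L, length(lam_values) >= 1L)
  nc <- length(c_values); nl <- length(lam_values)
  ent <- lfp <- matrix(NA_real_, nc, nl,
                       dimnames = list(signif(c_values, 6),
                                       signif(lam_values, 6)))
  flags <- matrix("ok", nc, nl)
  n <- coupling$geometry$n_sites
  for (li in seq_len(nl)) {
    op <- exposure(coupling, lam_values[li])
    for (ci in seq_len(nc)) {
      cell_seed <- derive_seed(seed, ci, li)
      res <- tryCatch({
        field0 <- random_field(n, a = field_scale, seed = cell_seed)
        sim <- ccml_simulate(field0, op, c_values[ci], steps, transient)
        rms <- sqrt(mean(sim$values^2))
        if (rms < 1e-8) {
          list(flag = "quiescent", ent = NA_real_, lfp = NA_real_)
        } else {
          sp <- st_spectrum(sim, block_len, overlap)
          list(flag = "ok", ent = spectral_entropy(sp),
               lfp = low_frequency_power(sp, band))
        }
      }, error = function(e) list(flag = "blowup", ent = NA_real_,
                                  lfp = NA_real_))
      flags[ci, li] <- res$flag
      ent[ci, li] <- res$ent
      lfp[ci, li] <- res$lfp
    }
  }
  structure(list(c_values = c_values, lam_values = lam_values,
                 entropy = ent, low_freq_power = lfp, flags = flags,
                 run_config = list(coupling = coupling$descriptor,
                                   steps = steps, transient = transient,
                                   block_len = block_len,
                                   overlap = overlap, band = band,
                                   field_scale = field_scale,
                                   seed = seed)),
            class = "phase_diagram")
}

#' @method print phase_diagram
#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d c-values x %d lambda-values (%s)\n",
              length(x$c_values), length(x$lam_values),
              x$run_config$coupling))
  tab <- table(factor(x$flags, levels = c("ok", "quiescent", "blowup")))
  cat(sprintf("  cells: %d ok, %d quiescent, %d blowup; entropy range [%.3g, %.3g] bits\n",
              tab[["ok"]], tab[["quiescent"]], tab[["blowup"]],
              suppressWarnings(min(x$entropy, na.rm = TRUE)),
              suppressWarnings(max(x$entropy, na.rm = TRUE))))
  invisible(x)
}

#' @method plot phase_diagram
#' @export
plot.phase_diagram <- function(x, what = c("entropy", "low_freq_power"),
                               ...) {
  what <- match.arg(what)
  graphics::image(x$c_values, x$lam_values, x[[what]],
                  xlab = "c", ylab = "lambda", main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Regime classification and contiguity of the complex region
#'
#' Splits the finite-entropy cells of a phase diagram into terciles —
#' low (ordered), intermediate (complex), high (chaotic) — and measures
#' how contiguous the intermediate-tercile region is: the size of its
#' largest 4-connected component on the (c, lambda) grid divided by the
#' number of intermediate cells. A value >= 0.5 indicates the complex
#' behaviour occupies a solid region of parameter space rather than
#' isolated points.
#'
#' @param pd A [phase_diagram()].
#' @return List with `tercile` (matrix: "quiescent"/"low"/"mid"/"high"),
#'   `mid_contiguity` (fraction), `n_mid`.
#' @export
phase_regions <- function(pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  e <- pd$entropy
  fin <- is.finite(e)
  qs <- stats::quantile(e[fin], c(1/3, 2/3), names = FALSE)
  terc <- matrix("quiescent", nrow(e), ncol(e))
  terc[fin & e <= qs[1]] <- "low"
  terc[fin & e > qs[1] & e <= qs[2]] <- "mid"
  terc[fin & e > qs[2]] <- "high"
  mid <- terc == "mid"
  list(tercile = terc,
       mid_contiguity = largest_component_fraction(mid),
       n_mid = sum(mid))
}

## largest 4-connected component of a logical matrix, as a fraction of
## all TRUE cells (flood fill)
largest_component_fraction <- function(mask) {
  n_true <- sum(mask)
  if (n_true == 0L) return(NA_real_)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L; best <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    stack <- list(c(i, j)); size <- 0L
    lab[i, j] <- comp
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        q <- p + d
        if (q[1] >= 1L && q[1] <= nrow(mask) && q[2] >= 1L &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] &&
            lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- comp
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    if (size > best) best <- size
  }
  best / n_true
}
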