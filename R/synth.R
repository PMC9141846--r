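#' Multichannel time series container
#'
#' A channels x samples real matrix with sampling-rate and channel
#' metadata; the container consumed by [critical_modes()]. Emulates
#' multichannel electrophysiology (ECoG-like) recordings.
#'
#' @param data Channels x samples numeric matrix, all finite.
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_names Optional character vector (default `ch1..chn`).
#' @param provenance List recording how the data were produced
#'   (generator parameters and seed, or file origin).
#' @return An object of class `mc_series`.
#' @export
mc_series <- function(data, fs, channel_names = NULL, provenance = list()) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("non-finite samples in series")
  stopifnot(fs > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 provenance = provenance),
            class = "mc_series")
}

#' @method print mc_series
#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("Multichannel series: %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @method plot mc_series
#' @export
plot.mc_series <- function(x, ...) {
  tm <- seq_len(ncol(x$data)) / x$fs
  off <- 3 * stats::sd(x$data)
  graphics::matplot(tm, t(x$data) + off * (seq_len(nrow(x$data)) - 1),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "channel (offset)", ...)
  invisible(x)
}

#' Synthetic multichannel recording with prescribed dynamical modes
#'
#' Generates noise-driven linear dynamics whose continuous-time
#' eigenvalues sit at prescribed distances from the imaginary axis: for
#' each `(re, im)` pair in `eig_spec` (re in 1/s, im in Hz; the complex
#' conjugate is implied automatically for `im != 0`), the discrete-time
#' propagator gets a 2x2 rotation-scaling block with radius
#' `exp(re / fs)` and angle `2 pi im / fs` (or a real 1x1 block for
#' `im = 0`). The blocks are conjugated by a random orthogonal matrix so
#' channels mix all modes, then iterated with i.i.d. Gaussian
#' innovations of standard deviation `noise_level`, after a warm-up long
#' enough to forget the initial state. Deterministic given `seed`.
#'
#' A specification with any `re >= 0` describes unstable dynamics and is
#' refused unless `force = TRUE`.
#'
#' With `noise_level = 0` the output is a pure transient from a random
#' initial state (no warm-up), useful for exact-recovery checks.
#'
#' @param n_channels Number of channels; must equal the number of
#'   states consumed by `eig_spec` (2 per oscillatory pair, 1 per real
#'   mode).
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param eig_spec List of `c(re, im)` pairs (or a 2-column matrix).
#' @param noise_level Innovation standard deviation (default 1).
#' @param seed RNG seed.
#' @param force Allow unstable specifications.
#' @return An `mc_series`; its `provenance` holds the generator
#'   arguments and the true propagator `A_true`.
#' @export
synth_series <- function(n_channels, duration, fs, eig_spec,
                         noise_level = 1, seed = 1L, force = FALSE) {
  if (is.list(eig_spec)) eig_spec <- do.call(rbind, eig_spec)
  eig_spec <- matrix(as.numeric(eig_spec), ncol = 2L)
  if (any(eig_spec[, 1] >= 0) && !force)
    stop("unstable eigenvalue specification (re >= 0); pass force = TRUE ",
         "to generate anyway")
  sizes <- ifelse(eig_spec[, 2] != 0, 2L, 1L)
  if (sum(sizes) != n_channels)
    stop(sprintf("eig_spec consumes %d states but n_channels = %d",
                 sum(sizes), n_channels))
  ## block-diagonal rotation-scaling propagator
  A <- matrix(0, n_channels, n_channels)
  pos <- 1L
  for (k in seq_len(nrow(eig_spec))) {
    r <- exp(eig_spec[k, 1] / fs)
    if (sizes[k] == 2L) {
      th <- 2 * pi * eig_spec[k, 2] / fs
      A[pos:(pos + 1L), pos:(pos + 1L)] <-
        r * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      pos <- pos + 2L
    } else {
      A[pos, pos] <- r
      pos <- pos + 1L
    }
  }
  nt <- as.integer(round(duration * fs))
  stopifnot(nt >= 2L)
  res <- with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_channels^2), n_channels)))
    Af <- Q %*% A %*% t(Q)
    X <- matrix(0, n_channels, nt)
    if (noise_level > 0) {
      warm <- as.integer(min(10 * fs, 2000L))
      x <- stats::rnorm(n_channels)
      for (s in seq_len(warm))
        x <- Af %*% x + noise_level * stats::rnorm(n_channels)
      for (s in seq_len(nt)) {
        x <- Af %*% x + noise_level * stats::rnorm(n_channels)
        X[, s] <- x
      }
    } else {
      x <- stats::rnorm(n_channels)
      for (s in seq_len(nt)) {
        x <- Af %*% x
        X[, s] <- x
      }
    }
    list(A = Af, X = X)
  })
  A <- res$A; X <- res$X
  mc_series(X, fs,
            provenance = list(generator = "synth_series",
                              eig_spec = eig_spec,
                              noise_level = noise_level, seed = seed,
                              A_true = A))
}

#' Surrogate copies of a multichannel series
#'
#' Transformed copies that destroy targeted structure, used as negative
#' controls for critical mode analysis:
#' \describe{
#'   \item{`channel_time_shuffle`}{independently permutes samples within
#'     each channel: destroys all temporal dynamics while preserving
#'     each channel's marginal distribution exactly.}
#'   \item{`phase_randomize`}{replaces each channel's Fourier phases by
#'     i.i.d. uniform phases (conjugate-symmetric, DC and Nyquist bins
#'     kept real): preserves each channel's power spectrum, destroys
#'     cross-channel and nonlinear structure.}
#'   \item{`window_shuffle`}{permutes whole consecutive windows of
#'     `window_len` samples: destroys slow ordering, preserves local
#'     dynamics within windows.}
#' }
#'
#' @param series An `mc_series`.
#' @param method One of the three methods above.
#' @param seed RNG seed.
#' @param window_len Window length in samples for `window_shuffle`
#'   (default 1 s of data).
#' @return A new `mc_series` with the surrogate data.
#' @export
surrogate <- function(series,
                      method = c("channel_time_shuffle",
                                 "phase_randomize", "window_shuffle"),
                      seed = 1L, window_len = NULL) {
  stopifnot(inherits(series, "mc_series"))
  method <- match.arg(method)
  X <- series$data
  nch <- nrow(X); nt <- ncol(X)
  Y <- with_seed(seed, switch(method,
    channel_time_shuffle = {
      t(apply(X, 1, sample))
    },
    phase_randomize = {
      out <- X
      for (ch in seq_len(nch)) {
        F <- stats::fft(X[ch, ])
        half <- if (nt %% 2L == 0L) nt %/% 2L - 1L else (nt - 1L) %/% 2L
        ph <- stats::runif(half, 0, 2 * pi)
        newF <- F
        if (half > 0) {
          newF[2:(half + 1L)] <- Mod(F[2:(half + 1L)]) * exp(1i * ph)
          newF[nt:(nt - half + 1L)] <- Conj(newF[2:(half + 1L)])
        }
        out[ch, ] <- Re(stats::fft(newF, inverse = TRUE)) / nt
      }
      out
    },
    window_shuffle = {
      wl <- if (is.null(window_len)) as.integer(round(series$fs))
            else as.integer(window_len)
      nw <- nt %/% wl
      stopifnot(nw >= 2L)
      perm <- sample(nw)
      cols <- unlist(lapply(perm, function(w) ((w - 1L) * wl + 1L):(w * wl)))
      cbind(X[, cols, drop = FALSE],
            X[, seq_len(nt) > nw * wl, drop = FALSE])
    }))
  mc_series(Y, series$fs, series$channel_names,
            provenance = c(series$provenance,
                           list(surrogate = method, surrogate_seed = seed)))
}
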