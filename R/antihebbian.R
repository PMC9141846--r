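#' Configuration for the anti-Hebbian self-poising network
#'
#' The model couples linear activity dynamics to anti-Hebbian synaptic
#' plasticity:
#' \deqn{\dot x = M x, \qquad \dot M = \alpha (I - x x^\top).}
#' Activity grows along unstable modes of `M`; the plasticity term then
#' subtracts the activity's outer product, pushing those modes back
#' toward stability, while the `alpha I` drift pushes stable modes up.
#' The net effect is that all eigenvalues of `M` collapse onto the
#' imaginary axis and fluctuate around it: the network poises itself at
#' a bank of simultaneous Hopf bifurcations.
#'
#' Timescales: unstable eigenvalues stabilize within a time of order 1;
#' the whole spectrum flattens onto the axis over a time of order
#' `1/alpha`; the stationary fluctuations live on the intermediate
#' (geometric-mean) timescale `1/sqrt(alpha)`.
#'
#' @param n System size (number of units), >= 2.
#' @param alpha Learning rate, > 0.
#' @param dt Integration step; default `0.01 * min(1, 1/alpha)` so both
#'   timescales are resolved.
#' @param T Total integration time; default `10/alpha`.
#' @param seed RNG seed for the initial conditions.
#' @param init_scale_x Standard deviation of initial activity entries.
#' @param init_scale_M Standard deviation of initial synaptic entries;
#'   default `1/sqrt(n)` gives an initial spectrum of O(1) radius
#'   (circular law).
#' @return An object of class `ah_config`.
#' @export
ah_config <- function(n = 32L, alpha = 1e-3, dt = NULL, T = NULL,
                      seed = 1L, init_scale_x = 1,
                      init_scale_M = 1 / sqrt(n)) {
  stopifnot(n >= 2, alpha > 0)
  if (is.null(dt)) dt <- 0.01 * min(1, 1 / alpha)
  if (is.null(T)) T <- 10 / alpha
  stopifnot(dt > 0, T > dt)
  structure(list(n = as.integer(n), alpha = alpha, dt = dt, T = T,
                 seed = as.integer(seed), init_scale_x = init_scale_x,
                 init_scale_M = init_scale_M),
            class = "ah_config")
}

#' Draw the initial state of the anti-Hebbian network
#'
#' Entries of the activity vector `x` and the synaptic matrix `M` are
#' i.i.d. Gaussian with the configured scales, drawn from the seeded
#' RNG; deterministic given the seed.
#'
#' @param config An [ah_config()] object.
#' @return A list of class `ah_state` with `x`, `M` and `t = 0`.
#' @export
ah_init <- function(config) {
  stopifnot(inherits(config, "ah_config"))
  n <- config$n
  draws <- with_seed(config$seed, list(
    x = stats::rnorm(n, sd = config$init_scale_x),
    M = stats::rnorm(n * n, sd = config$init_scale_M)))
  x <- if (config$init_scale_x == 0) numeric(n) else draws$x
  M <- matrix(if (config$init_scale_M == 0) 0 else draws$M, n, n)
  structure(list(x = x, M = M, t = 0), class = "ah_state")
}

#' Integrate the anti-Hebbian system and track the synaptic spectrum
#'
#' Advances activity and synapse jointly with fixed-step RK4 (compiled
#' core), recording the eigenvalues of `M`, the activity, `tr(M)` and
#' `||x||^2` every `record_every` steps. The recorded spectra are
#' assembled into an [eigen_trace] with eigenvalues matched across
#' adjacent frames by greedy nearest-neighbour assignment in the complex
#' plane (matching only affects per-eigenvalue traces, not pooled
#' summaries).
#'
#' @param state An [ah_init()] state.
#' @param config The matching [ah_config()].
#' @param record_every Record every this many integration steps.
#' @return A list of class `ah_sim`: `trace` (an `eigen_trace`), `x`
#'   (n x frames activity), `trM`, `xnorm2`, final `state`, and `config`.
#' @export
ah_integrate <- function(state, config, record_every = NULL) {
  stopifnot(inherits(state, "ah_state"), inherits(config, "ah_config"))
  nsteps <- ceiling(config$T / config$dt)
  if (is.null(record_every)) {
    ## aim for ~2000 frames; enough to resolve the 1/sqrt(alpha) tail
    record_every <- max(1L, floor(nsteps / 2000))
  }
  res <- ah_integrate_cpp(state$x, state$M, config$alpha, config$dt,
                          as.integer(nsteps), as.integer(record_every))
  eigs <- match_eigen_frames(matrix(complex(real = res$eig_re,
                                            imaginary = res$eig_im),
                                    nrow = nrow(res$eig_re)))
  trace <- eigen_trace(res$times, eigs)
  structure(list(trace = trace, x = res$x, trM = as.numeric(res$trM),
                 xnorm2 = as.numeric(res$xnorm2),
                 state = structure(list(x = as.numeric(res$x_final),
                                        M = res$M_final,
                                        t = nsteps * config$dt),
                                   class = "ah_state"),
                 config = config),
            class = "ah_sim")
}

#' @method print ah_sim
#' @export
print.ah_sim <- function(x, ...) {
  tr <- x$trace
  nf <- length(tr$times)
  re_final <- Re(tr$eigs[, nf])
  cat(sprintf("Anti-Hebbian run: n = %d, alpha = %g, T = %g (%d frames)\n",
              x$config$n, x$config$alpha, x$config$T, nf))
  cat(sprintf("  final spectrum: max Re = %.4g, mean |Re| = %.4g\n",
              max(re_final), mean(abs(re_final))))
  invisible(x)
}

#' Time-indexed eigenvalue trace
#'
#' Eigenvalues of an evolving real matrix, one column per recorded time,
#' rows matched across adjacent frames. Spectra of real matrices are
#' closed under complex conjugation.
#'
#' @param times Vector of record times.
#' @param eigs Complex matrix, n eigenvalues x length(times) frames.
#' @return An object of class `eigen_trace`.
#' @export
eigen_trace <- function(times, eigs) {
  stopifnot(length(times) == ncol(eigs))
  structure(list(times = times, eigs = eigs), class = "eigen_trace")
}

#' @method print eigen_trace
#' @export
print.eigen_trace <- function(x, ...) {
  cat(sprintf("Eigenvalue trace: %d eigenvalues over %d frames, t in [%g, %g]\n",
              nrow(x$eigs), ncol(x$eigs), min(x$times), max(x$times)))
  invisible(x)
}

#' @method plot eigen_trace
#' @export
plot.eigen_trace <- function(x, log = "x", ...) {
  t <- x$times
  if (grepl("x", log) && t[1] <= 0) t[1] <- t[2] / 2
  graphics::matplot(t, t(Re(x$eigs)), type = "l", lty = 1, col = 1,
                    log = log, xlab = "time", ylab = "Re / Im eigenvalue", ...)
  graphics::matlines(t, t(Im(x$eigs)), lty = 1, col = 2)
  graphics::abline(h = 0, col = "grey", lty = 2)
  invisible(x)
}

## Greedy nearest-neighbour matching of eigenvalue columns across frames.
## Each frame is permuted so that eigenvalue k stays close to its position
## in the previous frame.
match_eigen_frames <- function(eigs) {
  n <- nrow(eigs); nf <- ncol(eigs)
  if (nf < 2L) return(eigs)
  out <- eigs
  for (f in 2:nf) {
    prev <- out[, f - 1L]; cur <- eigs[, f]
    d <- abs(outer(prev, cur, `-`))
    perm <- integer(n)
    ord <- order(d)
    used_r <- logical(n); used_c <- logical(n)
    for (k in ord) {
      r <- (k - 1L) %% n + 1L; cc <- (k - 1L) %/% n + 1L
      if (!used_r[r] && !used_c[cc]) {
        perm[r] <- cc; used_r[r] <- TRUE; used_c[cc] <- TRUE
        if (all(used_r)) break
      }
    }
    out[, f] <- cur[perm]
  }
  out
}

#' Epoch summary of a self-poising eigenvalue trace
#'
#' Summarizes the three epochs of the anti-Hebbian relaxation:
#' `t_stabilize`, the first recorded time at which every eigenvalue has
#' negative real part (an epoch of order 1); `t_flatten`, the first time
#' the mean `|Re|` falls below `flatten_frac` of its initial value (an
#' epoch of order `1/alpha`); and `fluct_timescale`, the decay time of
#' the autocorrelation of single-eigenvalue real parts over the
#' stationary tail (of order `1/sqrt(alpha)`). The decay time is the
#' first lag at which the autocorrelation drops below `1/e`, reported as
#' the median across eigenvalue traces; a trace with zero variance (or
#' one whose autocorrelation never decays within the tail) yields `Inf`.
#'
#' @param trace An [eigen_trace].
#' @param alpha Learning rate of the run (sets the expected epochs).
#' @param flatten_frac Fraction of the initial mean `|Re|` defining
#'   flattening (default 0.5; the stationary fluctuation band scales as
#'   `sqrt(alpha)`, so fractions below that band are never reached and
#'   yield `NA`).
#' @param tail_start Start of the stationary tail; default `5/alpha`.
#' @return List with `t_stabilize`, `t_flatten`, `fluct_timescale`.
#' @export
ah_epoch_summary <- function(trace, alpha, flatten_frac = 0.5,
                             tail_start = 5 / alpha) {
  stopifnot(inherits(trace, "eigen_trace"))
  t <- trace$times; re <- Re(trace$eigs)
  if (max(t) < 2 / alpha)
    stop(sprintf("trace spans only t = %g; need well beyond 1/alpha = %g",
                 max(t), 1 / alpha))
  max_re <- apply(re, 2, max)
  mean_abs <- colMeans(abs(re))
  i_stab <- which(max_re < 0)
  t_stabilize <- if (length(i_stab)) t[min(i_stab)] else NA_real_
  i_flat <- which(mean_abs < flatten_frac * mean_abs[1L])
  t_flatten <- if (length(i_flat)) t[min(i_flat)] else NA_real_

  tail_idx <- which(t >= tail_start)
  if (length(tail_idx) < 20L)
    stop("stationary tail too short for an autocorrelation timescale")
  dt_rec <- stats::median(diff(t))
  taus <- apply(re[, tail_idx, drop = FALSE], 1, acf_decay_time,
                dt = dt_rec)
  list(t_stabilize = t_stabilize, t_flatten = t_flatten,
       fluct_timescale = stats::median(taus))
}

## First lag (in time units) at which the sample ACF drops below 1/e.
acf_decay_time <- function(y, dt) {
  if (stats::sd(y) == 0) return(Inf)
  lag_max <- length(y) - 2L
  a <- stats::acf(y, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  below <- which(a < exp(-1))
  if (!length(below)) return(Inf)
  (below[1L] - 1L) * dt
}

#' Fluctuation-timescale scaling across learning rates
#'
#' Runs the anti-Hebbian model at each `alpha`, extracts the stationary
#' fluctuation timescale via [ah_epoch_summary()], and regresses
#' `log(timescale)` on `log(1/alpha)`. The self-poised regime fluctuates
#' on the geometric-mean timescale `1/sqrt(alpha)`, i.e. slope 1/2.
#'
#' @param alphas Vector of learning rates.
#' @param n System size.
#' @param seed Base seed (one run per alpha, seeds derived).
#' @param T_factor Run length in units of `1/alpha` (default 10).
#' @return List with `slope`, per-alpha `timescales`, and `alphas`.
#' @export
ah_timescale_scaling <- function(alphas, n = 32L, seed = 1L, T_factor = 10) {
  taus <- vapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    cfg <- ah_config(n = n, alpha = a, T = T_factor / a,
                     seed = seed + 977L * i)
    sim <- ah_integrate(ah_init(cfg), cfg)
    ah_epoch_summary(sim$trace, a, tail_start = T_factor / a / 2)$fluct_timescale
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / alphas)), log(taus))
  list(slope = unname(fit$coefficients[2L]), timescales = taus,
       alphas = alphas)
}
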