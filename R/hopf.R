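#' Parameters of the forced Hopf normal form
#'
#' The supercritical Hopf normal form with unit cubic coefficient and
#' sinusoidal forcing,
#' \deqn{\dot z = (\mu + i\omega_0) z - |z|^2 z + F e^{i\omega t},}
#' the canonical reduction of a nonlinear oscillator near a Hopf
#' bifurcation. `mu` measures the distance to the bifurcation (`mu = 0`
#' is the critical point), `omega0` is the natural angular frequency,
#' `F` the forcing amplitude and `omega` the forcing angular frequency.
#'
#' @param mu Control parameter (dimensionless distance to bifurcation).
#' @param omega0 Natural angular frequency, rad per unit time; must be > 0.
#' @param F Forcing amplitude, >= 0.
#' @param omega Forcing angular frequency, rad per unit time. Defaults to
#'   `omega0` (resonant forcing).
#' @return An object of class `hopf_params`.
#' @examples
#' p <- hopf_params(mu = 0, omega0 = 1, F = 1e-6)
#' hopf_steady_response(p)$amplitude  # F^(1/3) = 0.01
#' @export
hopf_params <- function(mu = 0, omega0 = 1, F = 0, omega = omega0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F < 0)
    stop("forcing amplitude F must be a finite scalar >= 0")
  if (!is.numeric(omega0) || length(omega0) != 1L || omega0 <= 0)
    stop("natural frequency omega0 must be > 0")
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  structure(list(mu = mu, omega0 = omega0, F = F, omega = omega),
            class = "hopf_params")
}

#' @method print hopf_params
#' @export
print.hopf_params <- function(x, ...) {
  cat(sprintf("Forced Hopf normal form: mu = %g, omega0 = %g, F = %g, omega = %g\n",
              x$mu, x$omega0, x$F, x$omega))
  invisible(x)
}

#' Steady-state response amplitude of the forced Hopf normal form
#'
#' In the frame co-rotating with the forcing, a phase-locked solution
#' `z = R exp(i(omega t + phi))` satisfies
#' \deqn{R^2 \left[(\mu - R^2)^2 + (\omega_0 - \omega)^2\right] = F^2,}
#' a cubic in `R^2`. At the critical point (`mu = 0`) under resonant
#' forcing this reduces to `R = F^(1/3)`, the compressive 1/3-power law.
#' For `F = 0` the unforced attractor amplitude is returned: 0 for
#' `mu <= 0` and the limit-cycle radius `sqrt(mu)` for `mu > 0`.
#'
#' In part of the `mu > 0`, mistuned regime the cubic has multiple
#' positive roots (bistability). All roots are then returned, sorted
#' ascending, with `multistable = TRUE`; `amplitude` is the smallest
#' root and callers tracking a branch by continuation should pick from
#' `roots` themselves — no root is silently discarded.
#'
#' @param params A [hopf_params()] object.
#' @return A list with `amplitude` (smallest nonnegative root),
#'   `roots` (all nonnegative steady amplitudes, ascending) and
#'   `multistable` (logical).
#' @export
hopf_steady_response <- function(params) {
  stopifnot(inherits(params, "hopf_params"))
  mu <- params$mu; F <- params$F
  delta <- params$omega0 - params$omega
  if (F == 0) {
    amp <- if (mu > 0) sqrt(mu) else 0
    return(list(amplitude = amp, roots = amp, multistable = FALSE))
  }
  ## cubic in u = R^2:  u^3 - 2 mu u^2 + (mu^2 + delta^2) u - F^2 = 0
  co <- c(-F^2, mu^2 + delta^2, -2 * mu, 1)
  rt <- polyroot(co)
  u <- Re(rt[abs(Im(rt)) < 1e-9 * (1 + Mod(rt))])
  u <- sort(u[u > 0])
  if (length(u) == 0L)  # F > 0 guarantees one positive root; numeric guard
    stop("no positive steady-state root found")
  R <- sqrt(u)
  list(amplitude = R[1L], roots = R, multistable = length(R) > 1L)
}

#' Integrate the forced Hopf normal form
#'
#' Fixed-step 4th-order Runge-Kutta in the frame co-rotating with the
#' forcing (`w = z exp(-i omega t)`), where the forcing is constant and
#' the fast oscillation need not be resolved:
#' `dw/dt = (mu + i(omega0 - omega)) w - |w|^2 w + F`.
#' The modulus `|z| = |w|` is unaffected by the frame change.
#'
#' @param params A [hopf_params()] object.
#' @param duration Total integration time (same units as 1/omega0).
#' @param dt Step size; default 1/100 of the forcing period.
#' @param z0 Initial condition (complex, lab frame at t = 0).
#' @param record_every Record the state every this many steps.
#' @return A list of class `hopf_traj` with `time`, `z` (lab frame),
#'   `amplitude` (`|z|`) and the input `params`.
#' @export
hopf_simulate <- function(params, duration, dt = NULL, z0 = 0+0i,
                          record_every = 1L) {
  stopifnot(inherits(params, "hopf_params"), duration > 0)
  if (is.null(dt)) dt <- 0.01 * 2 * pi / max(abs(params$omega), params$omega0)
  stopifnot(dt > 0)
  nstep <- max(1L, ceiling(duration / dt))
  a <- complex(real = params$mu, imaginary = params$omega0 - params$omega)
  F <- params$F
  deriv <- function(w) a * w - Mod(w)^2 * w + F
  w <- as.complex(z0)
  idx <- seq(0L, nstep, by = as.integer(record_every))
  out <- complex(length(idx)); out[1L] <- w
  j <- 2L
  for (s in seq_len(nstep)) {
    k1 <- deriv(w)
    k2 <- deriv(w + dt / 2 * k1)
    k3 <- deriv(w + dt / 2 * k2)
    k4 <- deriv(w + dt * k3)
    w <- w + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(Re(w)) || !is.finite(Im(w)))
      stop(sprintf("integration blow-up at step %d (t = %g)", s, s * dt))
    if (j <= length(idx) && s == idx[j]) { out[j] <- w; j <- j + 1L }
  }
  tm <- idx * dt
  structure(list(time = tm, z = out * exp(1i * params$omega * tm),
                 amplitude = Mod(out), params = params),
            class = "hopf_traj")
}

#' @method print hopf_traj
#' @export
print.hopf_traj <- function(x, ...) {
  cat(sprintf("Hopf trajectory: %d samples over t = [0, %g]; final |z| = %.6g\n",
              length(x$time), max(x$time), x$amplitude[length(x$amplitude)]))
  invisible(x)
}

#' @method plot hopf_traj
#' @export
plot.hopf_traj <- function(x, ...) {
  graphics::plot(x$time, x$amplitude, type = "l", xlab = "time",
                 ylab = "|z|", ...)
  invisible(x)
}

#' Log-log slope of the steady response versus forcing
#'
#' Sweeps the forcing amplitude over `F_grid`, computes the steady
#' response at each point via [hopf_steady_response()], and returns the
#' least-squares slope of `log(amplitude)` against `log(F)`. At the
#' critical point under resonant forcing the slope is 1/3 (compressive
#' power law); far below the bifurcation it is 1 (linear response).
#'
#' Multistable grid points cannot be assigned a single amplitude and are
#' excluded, with a warning giving their count. Grids spanning fewer
#' than three decades yield a `low_confidence` flag.
#'
#' @param mu Control parameter.
#' @param omega_offset Detuning `omega - omega0` of the forcing.
#' @param F_grid Vector of forcing amplitudes, all > 0.
#' @param omega0 Natural frequency (default 1).
#' @return List with `slope`, `n_multistable`, `low_confidence`, and the
#'   swept `F` and `amplitude` vectors actually used.
#' @export
hopf_response_exponent <- function(mu, omega_offset = 0, F_grid, omega0 = 1) {
  stopifnot(all(F_grid > 0), length(F_grid) >= 3L)
  amps <- numeric(length(F_grid)); multi <- logical(length(F_grid))
  for (i in seq_along(F_grid)) {
    r <- hopf_steady_response(hopf_params(mu = mu, omega0 = omega0,
                                          F = F_grid[i],
                                          omega = omega0 + omega_offset))
    amps[i] <- r$amplitude; multi[i] <- r$multistable
  }
  if (any(multi))
    warning(sprintf("%d multistable grid points excluded from the fit",
                    sum(multi)))
  keep <- !multi
  fit <- stats::lm.fit(cbind(1, log(F_grid[keep])), log(amps[keep]))
  decades <- log10(max(F_grid) / min(F_grid))
  list(slope = unname(fit$coefficients[2L]),
       n_multistable = sum(multi),
       low_confidence = decades < 3,
       F = F_grid[keep], amplitude = amps[keep])
}

#' Frequency tuning curve of the forced Hopf normal form
#'
#' Sweeps the forcing frequency at fixed `mu` and `F` and reports the
#' steady response amplitude, the resonant gain `max(R)/F`, and the
#' relative half-width of the resonance: the width (in units of
#' `omega0`) of the band where the amplitude exceeds `1/sqrt(2)` of the
#' peak. Near criticality the gain diverges as `F^(-2/3)` and the
#' resonance sharpens as the forcing weakens — both signatures vanish
#' for larger forcings.
#'
#' @param mu Control parameter.
#' @param F Forcing amplitude, > 0.
#' @param omega_grid Vector of forcing frequencies to sweep.
#' @param omega0 Natural frequency (default 1).
#' @return A `response_curve` object: data frame with columns `abscissa`
#'   and `amplitude`, `sweep_kind = "frequency"`, and attributes `gain`,
#'   `half_width` (relative), `n_multistable`.
#' @export
hopf_tuning_curve <- function(mu, F, omega_grid, omega0 = 1) {
  stopifnot(F > 0, length(omega_grid) >= 3L)
  amps <- numeric(length(omega_grid)); multi <- logical(length(omega_grid))
  for (i in seq_along(omega_grid)) {
    r <- hopf_steady_response(hopf_params(mu = mu, omega0 = omega0, F = F,
                                          omega = omega_grid[i]))
    amps[i] <- r$amplitude; multi[i] <- r$multistable
  }
  peak <- max(amps)
  above <- which(amps >= peak / sqrt(2))
  hw <- (omega_grid[max(above)] - omega_grid[min(above)]) / omega0
  response_curve(omega_grid, amps, sweep_kind = "frequency",
                 gain = peak / F, half_width = hw,
                 n_multistable = sum(multi))
}

#' Construct a response curve
#'
#' A swept steady-state response: `abscissa` is the swept quantity
#' (forcing amplitude or forcing frequency), `amplitude` the
#' corresponding steady `|z|`.
#'
#' @param abscissa Swept values.
#' @param amplitude Nonnegative response amplitudes, same length.
#' @param sweep_kind `"forcing"` or `"frequency"`.
#' @param ... Further attributes stored on the object (e.g. `gain`).
#' @return A data frame of class `response_curve`.
#' @export
response_curve <- function(abscissa, amplitude,
                           sweep_kind = c("forcing", "frequency"), ...) {
  sweep_kind <- match.arg(sweep_kind)
  stopifnot(length(abscissa) == length(amplitude), all(amplitude >= 0))
  out <- data.frame(abscissa = abscissa, amplitude = amplitude)
  attr(out, "sweep_kind") <- sweep_kind
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("response_curve", "data.frame")
  out
}

#' @method print response_curve
#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve (%s sweep), %d points; peak amplitude %.6g\n",
              attr(x, "sweep_kind"), nrow(x), max(x$amplitude)))
  if (!is.null(attr(x, "gain")))
    cat(sprintf("  resonant gain %.6g, relative half-width %.6g\n",
                attr(x, "gain"), attr(x, "half_width")))
  invisible(x)
}

#' @method plot response_curve
#' @export
plot.response_curve <- function(x, log = "", ...) {
  xl <- if (attr(x, "sweep_kind") == "forcing") "forcing F" else "forcing frequency"
  graphics::plot(x$abscissa, x$amplitude, type = "l", log = log,
                 xlab = xl, ylab = "steady |z|", ...)
  invisible(x)
}
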