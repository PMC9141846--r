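#' The Gaussian map
#'
#' Elementwise `f(x) = c * x * exp(-x^2 / 2)`, the local (per-site)
#' dynamics of the critically coupled map lattice. The map is bounded,
#' `|f(x)| <= |c| exp(-1/2)` with the extremum at `x = +-1`; the origin
#' is a fixed point, stable for `|c| < 1`, and the map undergoes the
#' classic period-doubling route to chaos as `|c|` grows. (The map
#' prefactor is written alpha in some treatments; `c` is used here.)
#'
#' @param x Numeric vector/array.
#' @param c Map prefactor.
#' @return `c * x * exp(-x^2/2)`, same shape as `x`.
#' @export
gaussian_map <- function(x, c) c * x * exp(-x^2 / 2)

#' One stroboscopic step of a critically coupled map lattice
#'
#' Applies the local map to every site, then the exposure operator:
#' `x[t+1] = U %*% f(x[t])` — map first, coupling second, exactly in
#' that order. Because `U` is orthogonal the coupling stage preserves
#' the Euclidean norm of the mapped field; all contraction or expansion
#' of phase space comes from the map.
#'
#' @param field Site vector.
#' @param op An [exposure()] operator (its dimension must match).
#' @param c Map prefactor.
#' @return The next field vector.
#' @export
ccml_step <- function(field, op, c) {
  stopifnot(inherits(op, "exposure_operator"),
            length(field) == nrow(op$U))
  out <- as.numeric(op$U %*% gaussian_map(field, c))
  if (!all(is.finite(out)))
    stop("non-finite field after coupling step")
  out
}

#' Simulate a critically coupled map lattice
#'
#' Iterates [ccml_step()] from `field0`, discards the first `transient`
#' steps, and returns the remaining trajectory as a `lattice_series`
#' (sites x time matrix plus geometry and parameters). Deterministic
#' given `field0`.
#'
#' @param field0 Initial site vector (see [random_field()]).
#' @param op Exposure operator.
#' @param c Map prefactor.
#' @param steps Total number of steps to iterate.
#' @param transient Leading steps to discard (`0 <= transient < steps`).
#' @return A `lattice_series`: list with `values` (sites x kept steps),
#'   `geometry`, `params = list(c, lam)`, `transient`.
#' @export
ccml_simulate <- function(field0, op, c, steps, transient = 0L) {
  stopifnot(steps > transient, transient >= 0L)
  n <- nrow(op$U)
  stopifnot(length(field0) == n)
  keep <- steps - transient
  values <- matrix(0, n, keep)
  x <- as.numeric(field0)
  for (s in seq_len(steps)) {
    x <- tryCatch(ccml_step(x, op, c),
                  error = function(e)
                    stop(sprintf("blow-up at step %d: %s", s,
                                 conditionMessage(e))))
    if (s > transient) values[, s - transient] <- x
  }
  structure(list(values = values, geometry = op$source$geometry,
                 params = list(c = c, lam = op$lam),
                 transient = as.integer(transient)),
            class = "lattice_series")
}

#' Random initial lattice field
#'
#' I.i.d. uniform entries on `[-a, a]`, drawn from the seeded RNG.
#'
#' @param n Number of sites.
#' @param a Half-width of the uniform range (default 1).
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
random_field <- function(n, a = 1, seed = 1L) {
  with_seed(seed, stats::runif(n, -a, a))
}

#' @method print lattice_series
#' @export
print.lattice_series <- function(x, ...) {
  cat(sprintf("Lattice field series: %s, %d sites x %d steps (c = %g, lambda = %g)\n",
              x$geometry$kind, nrow(x$values), ncol(x$values),
              x$params$c, x$params$lam))
  cat(sprintf("  field RMS %.4g, range [%.4g, %.4g]\n",
              sqrt(mean(x$values^2)), min(x$values), max(x$values)))
  invisible(x)
}

#' @method plot lattice_series
#' @export
plot.lattice_series <- function(x, ...) {
  graphics::image(t(x$values), xlab = "time", ylab = "site",
                  col = grDevices::hcl.colors(64, "RdBu"), ...)
  invisible(x)
}

## reshape a lattice_series' values into (spatial dims..., time) array
series_array <- function(series) {
  g <- series$geometry
  dims <- switch(g$kind,
    chain_1d = g$shape,
    grid_2d = g$shape,
    bipartite_grid_2d = c(g$shape, 2L))
  array(series$values, dim = c(dims, ncol(series$values)))
}
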