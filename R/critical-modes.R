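#' Least-squares AR(1) fit on one block
#'
#' Ordinary least squares for the one-step linear propagator:
#' `A = argmin sum_t || x[t+1] - A x[t] ||^2` over the block, solved via
#' the normal equations. Channel means are removed first by default
#' (an affine offset otherwise biases `A`). A rank-deficient regressor
#' (e.g. constant input) is solved with the Moore-Penrose pseudoinverse
#' and flagged.
#'
#' @param X Channels x samples numeric matrix (one block); needs at
#'   least `channels + 1` samples (`channels + 2` with demeaning).
#' @param demean Remove per-channel means before fitting (default TRUE).
#' @return List with `A`, `residual_rms` (per channel), `residual_rms_pooled`,
#'   `rank_deficient` (logical).
#' @export
fit_window <- function(X, demean = TRUE) {
  X <- as.matrix(X)
  nch <- nrow(X); nt <- ncol(X)
  if (nt < nch + 1L)
    stop(sprintf("block has %d samples; need >= channels + 1 = %d",
                 nt, nch + 1L))
  Xp <- X[, -nt, drop = FALSE]   # regressors x_t
  Xn <- X[, -1L, drop = FALSE]   # responses  x_{t+1}
  if (demean) {
    Xp <- Xp - rowMeans(Xp)
    Xn <- Xn - rowMeans(Xn)
  }
  G <- tcrossprod(Xp)            # X X'
  C <- tcrossprod(Xn, Xp)        # Y X'
  qrG <- qr(G)
  deficient <- qrG$rank < nch
  if (deficient) {
    warning("rank-deficient regressor block; using pseudo-inverse")
    A <- C %*% MASS::ginv(G)
  } else {
    A <- t(solve(qrG, t(C)))
  }
  resid <- Xn - A %*% Xp
  list(A = A,
       residual_rms = sqrt(rowMeans(resid^2)),
       residual_rms_pooled = sqrt(mean(resid^2)),
       rank_deficient = deficient)
}

#' Critical mode analysis: sliding-window AR(1) fits
#'
#' Fits the discrete-time linear law of motion `x[t+1] = A x[t] + eta`
#' in short sliding windows over a multichannel recording — brief
#' enough to resolve nonstationarity, long enough to populate the
#' statistics — and maps each window's propagator eigenvalues to the
#' complex growth-rate plane: `eigs_continuous = log(eigs_discrete) * fs`
#' (principal branch), whose real part is a growth/decay rate in 1/s
#' and whose imaginary part is an angular frequency in rad/s
#' (`freq_hz = Im / (2 pi)`). Eigenvalues near the imaginary axis
#' (`Re ~ 0`) indicate dynamics poised at instability; frequencies
#' above Nyquist alias and are unrepresentable.
#'
#' This is the estimator interface of the package: it returns a classed
#' fit object with `print`, `summary`, `coef`, and `plot` methods.
#'
#' @param series An [mc_series()].
#' @param window Window length in seconds (default 2).
#' @param hop Hop between window starts in seconds (default 0.5).
#' @param demean Per-window channel mean removal (default TRUE; no other
#'   pre-processing is applied, deliberately).
#' @return An object of class `critical_modes`: list with `windows`
#'   (per-window list of `A`, `eigs_discrete`, `eigs_continuous`,
#'   `residual_rms`, `start_time`, `flagged`), `window_len`, `hop`
#'   (samples), `fs`, `series_provenance`.
#' @export
critical_modes <- function(series, window = 2, hop = 0.5, demean = TRUE) {
  stopifnot(inherits(series, "mc_series"))
  fs <- series$fs
  wl <- as.integer(round(window * fs))
  hp <- max(1L, as.integer(round(hop * fs)))
  nt <- ncol(series$data)
  if (wl > nt)
    stop(sprintf("window of %d samples exceeds series length %d", wl, nt))
  starts <- seq.int(1L, nt - wl + 1L, by = hp)
  wins <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + wl - 1L)
    flagged <- FALSE
    fit <- withCallingHandlers(
      fit_window(series$data[, idx, drop = FALSE], demean = demean),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    ed <- eigen(fit$A, only.values = TRUE)$values
    wins[[k]] <- list(A = fit$A,
                      eigs_discrete = ed,
                      eigs_continuous = log(as.complex(ed)) * fs,
                      residual_rms = fit$residual_rms,
                      residual_rms_pooled = fit$residual_rms_pooled,
                      start_time = (starts[k] - 1L) / fs,
                      flagged = flagged || fit$rank_deficient)
  }
  structure(list(windows = wins, window_len = wl, hop = hp, fs = fs,
                 n_channels = nrow(series$data),
                 series_provenance = series$provenance),
            class = "critical_modes")
}

## pooled continuous eigenvalues over clean (unflagged) windows
pooled_eigs <- function(fits, clean_only = TRUE) {
  keep <- if (clean_only) !vapply(fits$windows, `[[`, TRUE, "flagged")
          else rep(TRUE, length(fits$windows))
  if (!any(keep)) stop("no clean windows available")
  unlist(lapply(fits$windows[keep], `[[`, "eigs_continuous"))
}

#' @method print critical_modes
#' @export
print.critical_modes <- function(x, ...) {
  nfl <- sum(vapply(x$windows, `[[`, TRUE, "flagged"))
  cat(sprintf("Critical mode analysis: %d windows of %d samples (hop %d) @ %g Hz, %d channels\n",
              length(x$windows), x$window_len, x$hop, x$fs, x$n_channels))
  if (nfl) cat(sprintf("  %d window(s) flagged (conditioning)\n", nfl))
  ev <- pooled_eigs(x)
  cat(sprintf("  pooled eigenvalues: mean Re = %.4g 1/s, mean |Re| = %.4g 1/s\n",
              mean(Re(ev)), mean(abs(Re(ev)))))
  invisible(x)
}

#' @method summary critical_modes
#' @export
summary.critical_modes <- function(object, threshold = 1, ...) {
  ev <- pooled_eigs(object)
  ci <- criticality_index(object, threshold = threshold)
  out <- list(n_windows = length(object$windows),
              n_flagged = sum(vapply(object$windows, `[[`, TRUE, "flagged")),
              n_eigs = length(ev),
              mean_re = mean(Re(ev)),
              mean_abs_re = ci$mean_abs_re,
              fraction_near_axis = ci$fraction_near_axis,
              threshold = threshold,
              residual_rms = mean(vapply(object$windows, `[[`, 0,
                                         "residual_rms_pooled")))
  class(out) <- "summary.critical_modes"
  out
}

#' @method print summary.critical_modes
#' @export
print.summary.critical_modes <- function(x, ...) {
  cat(sprintf("Windows: %d (%d flagged), pooled eigenvalues: %d\n",
              x$n_windows, x$n_flagged, x$n_eigs))
  cat(sprintf("Mean Re: %.4g 1/s   Mean |Re|: %.4g 1/s\n",
              x$mean_re, x$mean_abs_re))
  cat(sprintf("Fraction with |Re| < %g 1/s: %.3f\n",
              x$threshold, x$fraction_near_axis))
  cat(sprintf("Mean residual RMS: %.4g\n", x$residual_rms))
  invisible(x)
}

#' @method coef critical_modes
#' @export
coef.critical_modes <- function(object, ...) {
  lapply(object$windows, `[[`, "A")
}

#' @method plot critical_modes
#' @export
plot.critical_modes <- function(x, ...) {
  ev <- pooled_eigs(x)
  graphics::plot(Re(ev), Im(ev) / (2 * pi), pch = 16,
                 cex = 0.4, xlab = "growth rate Re (1/s)",
                 ylab = "frequency (Hz)", ...)
  graphics::abline(v = 0, col = 2, lty = 2)
  invisible(x)
}

#' Distance of fitted modes from the instability line
#'
#' Pools the continuous-time eigenvalues of all clean windows and
#' summarizes how close they come to the imaginary axis (`Re = 0`):
#' the mean absolute real part (1/s) and the fraction of eigenvalues
#' with `|Re| < threshold`.
#'
#' @param fits A [critical_modes()] fit.
#' @param threshold Nearness threshold in 1/s (default 1).
#' @return List with `mean_abs_re`, `fraction_near_axis`, `n_eigs`.
#' @export
criticality_index <- function(fits, threshold = 1) {
  stopifnot(inherits(fits, "critical_modes"))
  ev <- pooled_eigs(fits)
  list(mean_abs_re = mean(abs(Re(ev))),
       fraction_near_axis = mean(abs(Re(ev)) < threshold),
       n_eigs = length(ev))
}

#' 2D histogram of fitted eigenvalues
#'
#' Pools continuous-time eigenvalues over clean windows and bins them in
#' the complex plane: real part (growth rate, 1/s) against imaginary
#' part expressed as frequency in Hz. Eigenvalues outside the edges are
#' counted in an overflow tally, not dropped silently.
#'
#' @param fits A [critical_modes()] fit.
#' @param re_edges,im_edges Monotone increasing bin edges (Re in 1/s,
#'   Im in Hz).
#' @param label Optional condition tag.
#' @return An `eigen_histogram`: `counts` matrix
#'   (re bins x im bins), edges, `overflow`, `label`.
#' @export
eigen_histogram <- function(fits, re_edges, im_edges, label = "") {
  stopifnot(all(diff(re_edges) > 0), all(diff(im_edges) > 0))
  ev <- tryCatch(pooled_eigs(fits), error = function(e) complex(0))
  re <- Re(ev); im <- Im(ev) / (2 * pi)
  inside <- re >= re_edges[1] & re <= re_edges[length(re_edges)] &
            im >= im_edges[1] & im <= im_edges[length(im_edges)]
  counts <- matrix(0L, length(re_edges) - 1L, length(im_edges) - 1L)
  if (any(inside)) {
    ri <- pmin(findInterval(re[inside], re_edges), length(re_edges) - 1L)
    ii <- pmin(findInterval(im[inside], im_edges), length(im_edges) - 1L)
    for (k in seq_along(ri))
      counts[ri[k], ii[k]] <- counts[ri[k], ii[k]] + 1L
  }
  structure(list(re_edges = re_edges, im_edges = im_edges,
                 counts = counts, overflow = sum(!inside),
                 label = label),
            class = "eigen_histogram")
}

#' @method print eigen_histogram
#' @export
print.eigen_histogram <- function(x, ...) {
  cat(sprintf("Eigenvalue histogram%s: %d x %d bins, %d counted, %d overflow\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$overflow))
  invisible(x)
}

## count-weighted mean Re of a histogram (bin centres)
hist_re_center <- function(h) {
  centres <- (h$re_edges[-1] + h$re_edges[-length(h$re_edges)]) / 2
  sum(rowSums(h$counts) * centres) / sum(h$counts)
}

#' Stability shift between two conditions
#'
#' Contrast of pooled eigenvalue growth rates between two fitted
#' conditions (e.g. awake-like vs anesthetized-like):
#' `delta_mean_re = mean Re(B) - mean Re(A)` over pooled continuous
#' eigenvalues, with a permutation p-value obtained by permuting window
#' labels — windows, not individual eigenvalues, are the exchangeable
#' unit, respecting within-window dependence. The p-value is two-sided
#' with the add-one correction `(1 + #{|delta*| >= |delta|}) / (n_perm + 1)`.
#'
#' @param fits_A,fits_B [critical_modes()] fits for the two conditions
#'   (each needs >= 2 clean windows).
#' @param n_perm Number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return List with `delta_mean_re` (1/s), `permutation_p`, `n_perm`.
#' @export
stability_shift <- function(fits_A, fits_B, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(fits_A, "critical_modes"),
            inherits(fits_B, "critical_modes"))
  win_re <- function(f) {
    keep <- !vapply(f$windows, `[[`, TRUE, "flagged")
    lapply(f$windows[keep], function(w) Re(w$eigs_continuous))
  }
  ra <- win_re(fits_A); rb <- win_re(fits_B)
  if (length(ra) < 2L || length(rb) < 2L)
    stop("need at least 2 clean windows per condition")
  sums <- c(vapply(ra, sum, 0), vapply(rb, sum, 0))
  cnts <- c(vapply(ra, length, 0L), vapply(rb, length, 0L))
  is_b <- c(rep(FALSE, length(ra)), rep(TRUE, length(rb)))
  delta_of <- function(b)
    sum(sums[b]) / sum(cnts[b]) - sum(sums[!b]) / sum(cnts[!b])
  obs <- delta_of(is_b)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    delta_of(sample(is_b)), 0))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(delta_mean_re = obs, permutation_p = p, n_perm = as.integer(n_perm))
}

#' Match fitted eigenvalues to generator targets
#'
#' For parameter-recovery assessment on synthetic data: for each target
#' continuous eigenvalue (upper half-plane representative), finds the
#' nearest fitted eigenvalue in each clean window and returns the
#' per-window recovered `(re, freq_hz)` values.
#'
#' @param fits A [critical_modes()] fit of a [synth_series()] output.
#' @param eig_spec Matrix/list of `(re 1/s, im Hz)` targets.
#' @return Data frame with columns `target_re`, `target_im_hz`,
#'   `window`, `re`, `freq_hz`.
#' @export
recovered_modes <- function(fits, eig_spec) {
  if (is.list(eig_spec)) eig_spec <- do.call(rbind, eig_spec)
  eig_spec <- matrix(as.numeric(eig_spec), ncol = 2L)
  keep <- which(!vapply(fits$windows, `[[`, TRUE, "flagged"))
  out <- list()
  for (k in keep) {
    ev <- fits$windows[[k]]$eigs_continuous
    ev <- ev[Im(ev) >= 0]  # upper half-plane representatives
    for (j in seq_len(nrow(eig_spec))) {
      target <- complex(real = eig_spec[j, 1],
                        imaginary = 2 * pi * eig_spec[j, 2])
      i <- which.min(Mod(ev - target))
      out[[length(out) + 1L]] <- data.frame(
        target_re = eig_spec[j, 1], target_im_hz = eig_spec[j, 2],
        window = k, re = Re(ev[i]), freq_hz = Im(ev[i]) / (2 * pi))
    }
  }
  do.call(rbind, out)
}
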