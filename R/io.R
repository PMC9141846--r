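## Serialization: delimited text with a JSON metadata sidecar.
## All numerics are written with 17 significant digits so that a
## write/read round trip reproduces the doubles exactly.

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(signif17(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

signif17 <- function(m) {
  out <- apply(m, c(1, 2), function(v) sprintf("%.17g", v))
  out
}

read_tsv_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Write / read a multichannel series as TSV + JSON sidecar
#'
#' The data matrix is written as `<prefix>.tsv` (rows = samples,
#' columns = channels, named header) and metadata — sampling rate in
#' Hz, channel names, provenance — as `<prefix>.json`. Numbers are
#' written with 17 significant digits so the round trip is exact.
#'
#' @param series An [mc_series()].
#' @param prefix Path prefix (without extension).
#' @return `write_mc_series` returns the prefix invisibly;
#'   `read_mc_series` returns the reconstructed `mc_series`.
#' @export
write_mc_series <- function(series, prefix) {
  stopifnot(inherits(series, "mc_series"))
  m <- t(series$data)
  colnames(m) <- series$channel_names
  write_tsv_matrix(m, paste0(prefix, ".tsv"))
  prov <- series$provenance
  prov$A_true <- NULL  # matrices do not belong in the sidecar
  write_sidecar(list(fs = series$fs, fs_units = "Hz",
                     channel_names = series$channel_names,
                     layout = "samples_x_channels",
                     provenance = prov),
                paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_mc_series
#' @export
read_mc_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- read_tsv_matrix(paste0(prefix, ".tsv"))
  mc_series(t(m), fs = as.numeric(meta$fs),
            channel_names = as.character(meta$channel_names),
            provenance = as.list(meta$provenance))
}

#' Write / read a lattice field series as TSV + JSON sidecar
#'
#' Values are written sites x time (`<prefix>.tsv`); geometry, map
#' parameters and transient go in `<prefix>.json`.
#'
#' @param series A `lattice_series` from [ccml_simulate()].
#' @param prefix Path prefix.
#' @export
write_lattice_series <- function(series, prefix) {
  stopifnot(inherits(series, "lattice_series"))
  m <- series$values
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  write_tsv_matrix(m, paste0(prefix, ".tsv"))
  g <- series$geometry
  write_sidecar(list(geometry = list(kind = g$kind, shape = g$shape,
                                     boundary = g$boundary),
                     c = series$params$c, lam = series$params$lam,
                     lam_units = "exposure time (dimensionless)",
                     transient = series$transient),
                paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_lattice_series
#' @export
read_lattice_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- read_tsv_matrix(paste0(prefix, ".tsv"))
  dimnames(m) <- NULL
  structure(list(values = m,
                 geometry = lattice_geometry(meta$geometry$kind,
                                             meta$geometry$shape),
                 params = list(c = meta$c, lam = meta$lam),
                 transient = as.integer(meta$transient)),
            class = "lattice_series")
}

#' Export a response curve as delimited text
#'
#' Two named columns: the swept abscissa (with its unit in the header)
#' and the steady response amplitude.
#'
#' @param curve A [response_curve()].
#' @param path Output file.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  ab_name <- if (attr(curve, "sweep_kind") == "forcing")
    "forcing_amplitude (dimensionless)" else
    "forcing_frequency (rad per unit time)"
  m <- cbind(curve$abscissa, curve$amplitude)
  colnames(m) <- c(ab_name, "amplitude (dimensionless)")
  write_tsv_matrix(m, path)
  invisible(path)
}

#' Write a phase diagram as delimited matrices + JSON sidecar
#'
#' `<prefix>_entropy.tsv` and `<prefix>_lowfreq.tsv` hold the two cell
#' matrices (rows = c, cols = lambda); `<prefix>.json` records the
#' grids, flags and run configuration.
#'
#' @param pd A [phase_diagram()].
#' @param prefix Path prefix.
#' @export
write_phase_diagram <- function(pd, prefix) {
  stopifnot(inherits(pd, "phase_diagram"))
  write_tsv_matrix(pd$entropy, paste0(prefix, "_entropy.tsv"))
  write_tsv_matrix(pd$low_freq_power, paste0(prefix, "_lowfreq.tsv"))
  write_sidecar(list(c_values = pd$c_values, lam_values = pd$lam_values,
                     entropy_units = "bits",
                     flags = as.vector(pd$flags),
                     run_config = pd$run_config),
                paste0(prefix, ".json"))
  invisible(prefix)
}
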