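# Data model and I/O for complex permittivity spectra, plus the heterogeneous
# (pore-filled membrane) parallel-capacitor composition and deconvolution.

#' Construct a dielectric spectrum
#'
#' One temperature's (or one time slice's) complex permittivity versus
#' frequency: `eps*(w) = eps'(w) - i eps''(w)`.
#'
#' Negative `eps_imag` values (possible in measured data at the noise floor)
#' are kept, not clipped; their rows are recorded in the `flagged_rows`
#' attribute so that downstream fits can decide how to treat them.
#'
#' @param freq frequencies in Hz, strictly increasing, positive, length >= 8.
#' @param eps_real real permittivity, > 0 everywhere.
#' @param eps_imag imaginary permittivity (dielectric loss).
#' @param T temperature in K (or `NA` for time-indexed spectra).
#' @param meta named list of metadata (sample label, protocol tag, `time_h`...).
#' @return object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(freq, eps_real, eps_imag, T = NA_real_,
                                meta = list()) {
  n <- length(freq)
  if (n < 8L) stop_amt("a spectrum needs at least 8 frequency points")
  if (length(eps_real) != n || length(eps_imag) != n)
    stop_amt("freq, eps_real, eps_imag must have equal length")
  bad <- which(freq <= 0)
  if (length(bad)) stop_amt("non-positive frequency at row %d", bad[1L])
  if (any(diff(freq) <= 0)) stop_amt("frequencies must be strictly increasing")
  if (any(eps_real <= 0)) stop_amt("eps_real must be > 0 everywhere")
  flagged <- which(eps_imag < 0)
  structure(list(freq = freq, eps_real = eps_real, eps_imag = eps_imag,
                 T = T, meta = meta, flagged_rows = flagged),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("Dielectric spectrum: %d points, %.3g-%.3g Hz, T = %s K\n",
              length(x$freq), min(x$freq), max(x$freq), format(x$T)))
  invisible(x)
}

#' Construct a series of dielectric spectra
#'
#' @param spectra list of [dielectric_spectrum()] objects.
#' @param protocol one of `"slow_cool"`, `"slow_heat"`, `"isothermal_time"`.
#'   For the isothermal protocol the series index is elapsed time in hours
#'   (taken from each spectrum's `meta$time_h`); otherwise it is temperature.
#' @return object of class `spectra_series`.
#' @export
spectra_series <- function(spectra,
                           protocol = c("slow_heat", "slow_cool",
                                        "isothermal_time")) {
  protocol <- match.arg(protocol)
  if (!length(spectra)) stop_amt("empty spectra series")
  idx <- if (protocol == "isothermal_time")
    vapply(spectra, function(s) s$meta$time_h %||% NA_real_, 0)
  else vapply(spectra, function(s) s$T, 0)
  if (anyNA(idx)) stop_amt("every spectrum needs its series index (T or time_h)")
  d <- diff(idx)
  if (!(all(d > 0) || all(d < 0)))
    stop_amt("series index must be strictly monotone")
  grids <- vapply(spectra, function(s)
    paste(signif(range(s$freq), 10), length(s$freq), collapse = ":"), "")
  structure(list(spectra = spectra, protocol = protocol, index = idx,
                 uniform_grid = length(unique(grids)) == 1L),
            class = "spectra_series")
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf("Spectra series: %d spectra, protocol %s, index %s to %s\n",
              length(x$spectra), x$protocol, format(min(x$index)),
              format(max(x$index))))
  invisible(x)
}

#' @export
length.spectra_series <- function(x) length(x$spectra)

#' Read / write dielectric spectra series ("bds-v1" CSV dialect)
#'
#' Columns: `temp_K` (or `time_h`), `freq_hz`, `eps_real`, `eps_imag`;
#' UTF-8, `.` decimal separator, values written to 9 significant digits so a
#' write/read round trip is lossless at that precision.
#'
#' @param path CSV file path.
#' @param resample `NULL`, or `"log-linear"` to interpolate all members onto a
#'   common log-spaced frequency grid when per-group grids differ.
#' @param protocol protocol tag for the series read from disk.
#' @return [spectra_series()] for `read_spectra`; invisibly `path` for
#'   `write_spectra`.
#' @export
read_spectra <- function(path, resample = NULL,
                         protocol = c("slow_heat", "slow_cool",
                                      "isothermal_time")) {
  protocol <- match.arg(protocol)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx_col <- if ("temp_K" %in% names(df)) "temp_K"
  else if ("time_h" %in% names(df)) "time_h"
  else stop_amt("missing column temp_K (or time_h) in %s", path)
  for (cn in c("freq_hz", "eps_real", "eps_imag"))
    if (!cn %in% names(df)) stop_amt("missing column %s in %s", cn, path)
  bad <- which(df$freq_hz <= 0)
  if (length(bad)) stop_amt("non-positive frequency at data row %d", bad[1L])
  if (idx_col == "time_h" && protocol != "isothermal_time")
    protocol <- "isothermal_time"
  groups <- split(df, df[[idx_col]])
  ord <- order(as.numeric(names(groups)))
  groups <- groups[ord]
  grids <- vapply(groups, function(g)
    paste(signif(range(g$freq_hz), 10), nrow(g), collapse = ":"), "")
  if (length(unique(grids)) > 1L && is.null(resample))
    stop_amt("mixed frequency grids in %s; pass resample = \"log-linear\"", path)
  spectra <- lapply(groups, function(g) {
    o <- order(g$freq_hz)
    g <- g[o, ]
    meta <- list()
    if (idx_col == "time_h") meta$time_h <- g$time_h[1L]
    dielectric_spectrum(g$freq_hz, g$eps_real, g$eps_imag,
                        T = if (idx_col == "temp_K") g$temp_K[1L] else NA_real_,
                        meta = meta)
  })
  ser <- spectra_series(unname(spectra), protocol = protocol)
  if (!is.null(resample) && !ser$uniform_grid)
    ser <- resample_series(ser)
  ser
}

#' @rdname read_spectra
#' @param series a [spectra_series()].
#' @export
write_spectra <- function(series, path) {
  stopifnot(inherits(series, "spectra_series"))
  idx_col <- if (series$protocol == "isothermal_time") "time_h" else "temp_K"
  rows <- lapply(seq_along(series$spectra), function(i) {
    s <- series$spectra[[i]]
    data.frame(idx = rep(series$index[i], length(s$freq)),
               freq_hz = s$freq, eps_real = s$eps_real, eps_imag = s$eps_imag)
  })
  df <- do.call(rbind, rows)
  names(df)[1L] <- idx_col
  df[] <- lapply(df, function(x) signif(x, 10))
  con <- file(path, open = "wb")  # fixed EOL for byte-identical reruns
  on.exit(close(con))
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Resample a series onto a common log-spaced frequency grid
#'
#' Log-linear interpolation (`eps` linear in `log10 f`) onto a log-spaced grid
#' spanning the overlap of all member grids.
#'
#' @param series a [spectra_series()].
#' @param n number of grid points (default: the largest member size).
#' @return a [spectra_series()] on a uniform grid.
#' @export
resample_series <- function(series, n = NULL) {
  fmin <- max(vapply(series$spectra, function(s) min(s$freq), 0))
  fmax <- min(vapply(series$spectra, function(s) max(s$freq), 0))
  if (fmax <= fmin) stop_amt("member grids do not overlap")
  n <- n %||% max(vapply(series$spectra, function(s) length(s$freq), 0L))
  grid <- log_grid(fmin, fmax, n)
  spectra <- lapply(series$spectra, function(s) {
    er <- stats::approx(log10(s$freq), s$eps_real, log10(grid))$y
    ei <- stats::approx(log10(s$freq), s$eps_imag, log10(grid))$y
    dielectric_spectrum(grid, er, ei, T = s$T, meta = s$meta)
  })
  spectra_series(spectra, protocol = series$protocol)
}

#' Composite geometry of a pore-filled membrane capacitor
#'
#' With the applied field parallel to the pore axes the filled membrane acts
#' as two capacitors in parallel (API in the pores, matrix walls), i.e.
#' admittances add: `eps*_total = f eps*_API + (1 - f) eps*_matrix`, where `f`
#' is the area fraction occupied by the API. `f` is never inferred silently:
#' supply it directly, or as `porosity * filling_degree`.
#'
#' @param fill_area_fraction area fraction `f` in (0, 1]; if `NULL`, computed
#'   as `porosity * filling_degree`.
#' @param matrix_eps matrix permittivity: a single complex (frequency
#'   independent) value or a reference [dielectric_spectrum()].
#' @param porosity,filling_degree optional fractions used to derive `f`.
#' @return object of class `composite_geometry`.
#' @export
composite_geometry <- function(fill_area_fraction = NULL,
                               matrix_eps = 3 + 0i,
                               porosity = NULL, filling_degree = NULL) {
  f <- fill_area_fraction
  if (is.null(f)) {
    if (is.null(porosity) || is.null(filling_degree))
      stop_amt("supply fill_area_fraction or porosity and filling_degree")
    f <- porosity * filling_degree
  }
  if (f <= 0 || f > 1) stop_amt("fill fraction f must be in (0, 1]")
  if (!inherits(matrix_eps, "dielectric_spectrum")) {
    matrix_eps <- as.complex(matrix_eps)
    if (Re(matrix_eps) <= 0) stop_amt("matrix eps' must be > 0")
  }
  structure(list(f = f, matrix_eps = matrix_eps,
                 porosity = porosity, filling_degree = filling_degree),
            class = "composite_geometry")
}

.matrix_eps_at <- function(geom, freq) {
  m <- geom$matrix_eps
  if (inherits(m, "dielectric_spectrum")) {
    er <- stats::approx(log10(m$freq), m$eps_real, log10(freq), rule = 2)$y
    ei <- stats::approx(log10(m$freq), m$eps_imag, log10(freq), rule = 2)$y
    complex(real = er, imaginary = -ei)
  } else rep(m, length(freq))
}

#' Compose a pore-filled composite spectrum from an API spectrum
#'
#' Parallel-capacitor mixing under shared electrode geometry:
#' `eps*_total = f eps*_API + (1 - f) eps*_matrix`.
#'
#' @param api [dielectric_spectrum()] of the pure API.
#' @param geom [composite_geometry()].
#' @return composite [dielectric_spectrum()].
#' @export
compose_composite <- function(api, geom) {
  stopifnot(inherits(api, "dielectric_spectrum"),
            inherits(geom, "composite_geometry"))
  em <- .matrix_eps_at(geom, api$freq)
  tot <- geom$f * complex(real = api$eps_real, imaginary = -api$eps_imag) +
    (1 - geom$f) * em
  dielectric_spectrum(api$freq, Re(tot), -Im(tot), T = api$T,
                      meta = c(api$meta, list(composite = TRUE, f = geom$f)))
}

#' Deconvolve the API contribution out of a composite spectrum
#'
#' Exact algebraic inverse of [compose_composite()]:
#' `eps*_API = (eps*_total - (1 - f) eps*_matrix) / f`. If the recovered
#' `eps'` is non-positive anywhere the result carries an
#' `implausible_geometry` attribute (with the offending rows) instead of
#' failing silently; the values are clamped to a tiny positive floor only to
#' keep the container invariant.
#'
#' @param total composite [dielectric_spectrum()].
#' @param geom [composite_geometry()].
#' @return API [dielectric_spectrum()].
#' @export
deconvolve_composite <- function(total, geom) {
  stopifnot(inherits(total, "dielectric_spectrum"),
            inherits(geom, "composite_geometry"))
  em <- .matrix_eps_at(geom, total$freq)
  api <- (complex(real = total$eps_real, imaginary = -total$eps_imag) -
            (1 - geom$f) * em) / geom$f
  er <- Re(api); ei <- -Im(api)
  bad <- which(er <= 0)
  if (length(bad)) {
    warn_amt("deconvolution gives eps' <= 0 at %d rows: implausible geometry",
             length(bad))
    er[bad] <- 1e-9
  }
  out <- dielectric_spectrum(total$freq, er, ei, T = total$T,
                             meta = c(total$meta, list(deconvolved = TRUE)))
  attr(out, "implausible_geometry") <- length(bad) > 0L
  attr(out, "implausible_rows") <- bad
  out
}

#' Normalize a loss peak to its maximum (master-curve superposition)
#'
#' Returns `eps''/eps''_max` versus `f/f_max` for shape comparison across
#' samples and temperatures. The peak position and height are refined by a
#' parabolic interpolation of `log10 eps''` in `log10 f` around the grid
#' argmax, so the normalization does not depend on the grid step.
#'
#' @param spectrum a [dielectric_spectrum()].
#' @param process_window `c(fmin, fmax)` in Hz; must contain an interior local
#'   maximum of the loss.
#' @return data.frame with columns `freq` (`f/f_max`), `loss`
#'   (`eps''/eps''_max`); attributes `f_max`, `loss_max`.
#' @export
normalize_peak <- function(spectrum, process_window = NULL) {
  f <- spectrum$freq; ei <- spectrum$eps_imag
  keep <- rep(TRUE, length(f))
  if (!is.null(process_window))
    keep <- f >= process_window[1] & f <= process_window[2]
  f <- f[keep]; ei <- ei[keep]
  if (length(f) < 5L) stop_amt("window contains too few points")
  i <- which.max(ei)
  if (i == 1L || i == length(f))
    stop_amt("no interior loss maximum in the window")
  # parabolic refinement in (log10 f, log10 eps'')
  lx <- log10(f[(i - 1L):(i + 1L)]); ly <- log10(ei[(i - 1L):(i + 1L)])
  d2 <- (ly[3L] - 2 * ly[2L] + ly[1L])
  x0 <- if (d2 < 0) lx[2L] - (ly[3L] - ly[1L]) / (2 * d2) * diff(lx)[1L]
  else lx[2L]
  y0 <- if (d2 < 0) ly[2L] - (ly[3L] - ly[1L])^2 / (8 * d2) else ly[2L]
  f_max <- 10^x0; loss_max <- 10^y0
  out <- data.frame(freq = f / f_max, loss = ei / loss_max)
  attr(out, "f_max") <- f_max
  attr(out, "loss_max") <- loss_max
  out
}
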