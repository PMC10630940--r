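# spectrum containers, CSV round trips, composite mixing/deconvolution,
# peak normalization

test_that("spectra CSV round-trip is lossless at 9 significant digits", {
  truth <- hn_fit(5, 1e-2, 0.8, 0.6, eps_inf = 3)
  spectra <- lapply(c(300, 310, 320), function(T)
    spectrum_from_truth(truth, T = T))
  ser <- spectra_series(spectra)
  path <- tempfile(fileext = ".csv")
  write_spectra(ser, path)
  back <- read_spectra(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back$spectra[[i]]$eps_real, spectra[[i]]$eps_real,
                 tolerance = 1e-9)
    expect_equal(back$spectra[[i]]$eps_imag, spectra[[i]]$eps_imag,
                 tolerance = 1e-9)
  }
  # writing twice gives byte-identical files (determinism contract)
  path2 <- tempfile(fileext = ".csv")
  write_spectra(ser, path2)
  expect_identical(readBin(path, "raw", 1e6), readBin(path2, "raw", 1e6))
})

test_that("reader rejects malformed input with the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("temp_K,freq_hz,eps_real,eps_imag",
               "300,1,3.5,0.1", "300,-2,3.4,0.2", "300,3,3.3,0.1"), path)
  expect_error(read_spectra(path), "row 2")
  writeLines(c("temp_K,freq_hz,eps_real", "300,1,3.5"), path)
  expect_error(read_spectra(path), "eps_imag")
})

test_that("mixed grids require an explicit resample and interpolate correctly", {
  # eps linear in log10 f, so log-linear interpolation is exact
  mk <- function(T, grid) {
    lf <- log10(grid)
    dielectric_spectrum(grid, 5 - 0.2 * lf, 2 + 0.1 * lf, T = T)
  }
  path <- tempfile(fileext = ".csv")
  g1 <- amorphotrack:::log_grid(1e-1, 1e5, 30)
  g2 <- amorphotrack:::log_grid(1e-2, 1e6, 40)
  df <- rbind(data.frame(temp_K = 300, freq_hz = g1,
                         eps_real = 5 - 0.2 * log10(g1),
                         eps_imag = 2 + 0.1 * log10(g1)),
              data.frame(temp_K = 310, freq_hz = g2,
                         eps_real = 5 - 0.2 * log10(g2),
                         eps_imag = 2 + 0.1 * log10(g2)))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra(path), "resample")
  ser <- read_spectra(path, resample = "log-linear")
  expect_true(ser$uniform_grid)
  s <- ser$spectra[[1L]]
  expect_equal(s$eps_real, 5 - 0.2 * log10(s$freq), tolerance = 1e-9)
})

test_that("parallel-capacitor composition follows the mixing arithmetic", {
  truth <- hn_fit(5, 1e-2, 0.8, 0.6, eps_inf = 3)
  api <- spectrum_from_truth(truth)
  # f = 1 is the identity
  g1 <- composite_geometry(1, 3 + 0i)
  c1 <- compose_composite(api, g1)
  expect_equal(c1$eps_real, api$eps_real)
  expect_equal(c1$eps_imag, api$eps_imag)
  # hand value: f = 0.5, matrix 3+0i, api 5-2i -> 4-1i
  flat <- dielectric_spectrum(api$freq, rep(5, length(api$freq)),
                              rep(2, length(api$freq)))
  ch <- compose_composite(flat, composite_geometry(0.5, 3 + 0i))
  expect_equal(unique(ch$eps_real), 4)
  expect_equal(unique(ch$eps_imag), 1)
  # lossless matrix: composite loss is exactly f * api loss
  g <- composite_geometry(0.35, 3.8 + 0i)
  cc <- compose_composite(api, g)
  expect_equal(cc$eps_imag, 0.35 * api$eps_imag, tolerance = 1e-14)
})

test_that("deconvolve_composite inverts compose_composite to 1e-12", {
  truth <- hn_fit(c(4, 1.5), c(1e-2, 1), c(0.8, 0.7), c(0.5, 0.5),
                  eps_inf = 3, sigma_dc = 1e-12)
  api <- spectrum_from_truth(truth)
  for (f in c(0.1, 0.35, 0.9, 1.0)) {
    geom <- composite_geometry(f, 3.8 + 0.02i)
    back <- deconvolve_composite(compose_composite(api, geom), geom)
    expect_lt(max(abs(back$eps_real - api$eps_real)), 1e-12)
    expect_lt(max(abs(back$eps_imag - api$eps_imag)), 1e-12)
  }
})

test_that("implausible geometry is flagged, not silent", {
  api <- dielectric_spectrum(default_grid(), rep(2, 65), rep(0.1, 65))
  geom_ok <- composite_geometry(0.5, 3 + 0i)
  tot <- compose_composite(api, geom_ok)
  # deconvolving with the wrong (too large) matrix permittivity drives eps' < 0
  geom_bad <- composite_geometry(0.5, 6 + 0i)
  expect_warning(out <- deconvolve_composite(tot, geom_bad), "implausible")
  expect_true(attr(out, "implausible_geometry"))
})

test_that("fill fraction is validated and derivable from porosity", {
  expect_error(composite_geometry(0), "f must be")
  expect_error(composite_geometry(1.2), "f must be")
  g <- composite_geometry(porosity = 0.3, filling_degree = 0.9)
  expect_equal(g$f, 0.27)
})

test_that("normalize_peak: Debye FWHM is 1.14 decades; scale invariance", {
  grid <- amorphotrack:::log_grid(1e-4, 1e4, 400)
  deb <- spectrum_from_truth(hn_fit(2, 1 / (2 * pi), 1, 1), freq = grid)
  nrm <- normalize_peak(deb)
  above <- which(nrm$loss >= 0.5)
  fwhm <- log10(nrm$freq[max(above)]) - log10(nrm$freq[min(above)])
  expect_equal(fwhm, 1.144, tolerance = 0.01)
  # the refined (off-grid) peak height slightly exceeds the grid maximum
  expect_equal(max(nrm$loss), 1, tolerance = 1e-3)
  # same shape, different tau: identical normalized curves on a shifted grid
  a <- normalize_peak(spectrum_from_truth(hn_fit(2, 1e-2, 0.8, 0.6),
                                          freq = grid))
  b <- normalize_peak(spectrum_from_truth(hn_fit(2, 1, 0.8, 0.6),
                                          freq = grid * 1e-2))
  expect_lt(max(abs(a$loss - b$loss)), 1e-10)
  expect_lt(max(abs(log10(a$freq) - log10(b$freq))), 1e-10)
})

test_that("normalize_peak rejects windows without an interior maximum", {
  deb <- spectrum_from_truth(hn_fit(2, 1 / (2 * pi), 1, 1))
  expect_error(normalize_peak(deb, c(1e2, 1e5)), "interior")
})
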