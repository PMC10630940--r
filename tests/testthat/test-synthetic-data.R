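# generators: spectra, spectra series, DSC thermograms, dissolution profiles

test_that("gen_spectrum reproduces the Debye closed form", {
  p <- process_spec("alpha", 2, 1, 1, law_arrhenius(1e-3 / exp(50e3 / (8.314462618 * 300)), 50))
  f0 <- 1 / (2 * pi * 1e-3)
  sp <- gen_spectrum(list(p), T = 300, freq_grid = default_grid(), noise_rel = 0)
  truth <- attr(sp, "ground_truth")
  expect_equal(truth$processes$tau_hn, 1e-3, tolerance = 1e-12)
  expect_equal(-Im(hn_eval(truth, f0)), 1, tolerance = 1e-12)
})

test_that("generated spectra obey the loss sum rule without conductivity", {
  preset <- scenario_preset("bulk_apz")
  procs <- Filter(function(p) inherits(p, "process_spec"), preset$processes)
  grid <- amorphotrack:::log_grid(1e-10, 1e12, 2000)  # full peak coverage
  sp <- gen_spectrum(procs, T = 313, freq_grid = grid, noise_rel = 0)
  truth <- attr(sp, "ground_truth")
  integral <- amorphotrack:::trapz(log(2 * pi * grid), sp$eps_imag)
  expect_rel(integral, (pi / 2) * sum(truth$processes$delta_eps), 0.01)
})

test_that("round trip: fit_hn recovers the bulk preset's alpha process", {
  preset <- scenario_preset("bulk_apz")
  alpha <- preset$processes[[1L]]
  sp <- gen_spectrum(list(alpha), T = 313, freq_grid = default_grid(),
                     noise_rel = 0, eps_inf = preset$eps_inf)
  truth <- attr(sp, "ground_truth")
  fit <- fit_hn(sp, 1)
  expect_rel(fit$processes$delta_eps, truth$processes$delta_eps, 0.02)
  expect_rel(fit$processes$tau_hn, truth$processes$tau_hn, 0.02)
  expect_rel(fit$processes$alpha, truth$processes$alpha, 0.02)
  expect_rel(fit$processes$gamma, truth$processes$gamma, 0.02)
})

test_that("VFT domain errors name the offending process", {
  p <- process_spec("alpha", 3, 0.8, 0.6, law_vft(1e-14, 8, 250))
  expect_error(gen_spectrum(list(p), T = 245, freq_grid = default_grid()),
               "alpha")
})

test_that("gen_spectra_series: count, peak ordering, determinism", {
  preset <- scenario_preset("bulk_apz")
  ser <- gen_spectra_series(preset, c(293, 337), step = 2, seed = 3)
  expect_equal(length(ser), 23L)
  # alpha-peak frequency strictly increases with T (monotone tau(T))
  taus <- vapply(ser$spectra, function(s)
    attr(s, "ground_truth")$processes$tau_hn[1L], 0)
  expect_true(all(diff(taus) < 0))
  # fixed seed: byte-identical CSV on rerun
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_spectra(gen_spectra_series(preset, c(300, 320), step = 5,
                                   noise_rel = 0.02, seed = 9), p1)
  write_spectra(gen_spectra_series(preset, c(300, 320), step = 5,
                                   noise_rel = 0.02, seed = 9), p2)
  expect_identical(readBin(p1, "raw", 1e7), readBin(p2, "raw", 1e7))
  # different seeds differ
  p3 <- tempfile(fileext = ".csv")
  write_spectra(gen_spectra_series(preset, c(300, 320), step = 5,
                                   noise_rel = 0.02, seed = 10), p3)
  expect_false(identical(readBin(p1, "raw", 1e7), readBin(p3, "raw", 1e7)))
  expect_error(gen_spectra_series(preset, c(300, 299)), "empty")
})

test_that("confined series are composites consistent with the geometry", {
  preset <- scenario_preset("native_sio2")
  ser <- gen_spectra_series(preset, c(315, 325), step = 5, seed = 1)
  api <- attr(ser, "api_series")
  expect_false(is.null(api))
  s_tot <- ser$spectra[[1L]]
  s_api <- api$spectra[[1L]]
  back <- deconvolve_composite(s_tot, preset$geometry)
  expect_lt(max(abs(back$eps_imag - s_api$eps_imag)), 1e-12)
})

test_that("gen_dsc places exotherms on the Kissinger line exactly", {
  kin <- kinetics_spec(Ea_cr = 100, Tc_at_10 = 363.4)
  rates <- c(2.5, 5, 10, 20)
  Tcs <- vapply(rates, function(r) attr(gen_dsc(kin, r), "ground_truth")$Tc, 0)
  expect_true(all(diff(Tcs) > 0))  # Tc increases with rate
  kf <- kissinger_fit(data.frame(phi = rates, Tc = Tcs))
  expect_rel(kf$E_cr, 100, 1e-3)
  expect_equal(attr(gen_dsc(kin, 10), "ground_truth")$Tc, 363.4,
               tolerance = 1e-6)
})

test_that("gen_dsc errors when the Kissinger root leaves the grid", {
  kin <- kinetics_spec(Ea_cr = 100, Tc_at_10 = 380)
  expect_error(gen_dsc(kin, 25, T_grid = seq(260, 390, 0.1)), "25")
})

test_that("Gibbs-Thomson option depresses melting peaks by c/d", {
  kin <- kinetics_spec(Ea_cr = 100, gibbs_thomson_c = 160)
  gt <- attr(gen_dsc(kin, 10, pore_diameter_nm = 8), "ground_truth")
  expect_equal(gt$Tm, c(406.6, 413.1) - 20, tolerance = 1e-9)
  # default constant 0: no depression
  kin0 <- kinetics_spec(Ea_cr = 100)
  gt0 <- attr(gen_dsc(kin0, 10, pore_diameter_nm = 8), "ground_truth")
  expect_equal(gt0$Tm, c(406.6, 413.1))
})

test_that("gen_dissolution shapes and reproducibility", {
  pr <- gen_dissolution("prolonged", noise_rel = 0)
  expect_true(all(diff(pr$conc) > 0))  # strictly nondecreasing, monotone model
  sc <- gen_dissolution("spring_crash", noise_rel = 0,
                        times = seq(1, 180, by = 1))
  m <- summary_metrics(sc)
  expect_lt(abs(m$t_Cmax - 30), 6)          # peak near 30 min
  expect_lt(abs(m$Cmax - 0.2), 0.02)        # ~0.2 mg/mL
  expect_lt(abs(sc$conc[length(sc$conc)] - 0.117), 0.02)  # decays toward ~0.1
  fl <- gen_dissolution("flat", noise_rel = 0)
  expect_equal(stats::sd(fl$conc), 0)
  expect_error(gen_dissolution("prolonged", params = list(k = -1)), "negative")
  a <- gen_dissolution("prolonged", noise_rel = 0.05, seed = 4)
  b <- gen_dissolution("prolonged", noise_rel = 0.05, seed = 4)
  expect_identical(a$conc, b$conc)
})

test_that("annealing series drifts tau upward monotonically", {
  preset <- scenario_preset("bulk_apz")
  ser <- gen_annealing_series(preset$processes[[1L]], T_anneal = 305,
                              times_h = c(1, 10, 50, 100, 250))
  expect_identical(ser$protocol, "isothermal_time")
  taus <- vapply(ser$spectra, function(s)
    attr(s, "ground_truth")$processes$tau_hn[1L], 0)
  expect_true(all(diff(taus) > 0))
})
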