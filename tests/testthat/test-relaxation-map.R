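# tau(T) maps, VFT/Arrhenius fits, Tg, crossover detection

test_that("build_tau_map extracts peak times from HN fits, sorted", {
  law <- law_vft(1e-14, 8, 250)
  Ts <- seq(280, 300, by = 5)
  fits <- lapply(rev(Ts), function(T)
    list(T = T, fit = hn_fit(3, tau_at(law, T), 0.8, 0.6, eps_inf = 3)))
  map <- build_tau_map(fits)
  expect_equal(map$index, Ts)
  expect_true(all(diff(map$tau) < 0))
  expect_error(build_tau_map(fits[1L]), "at least 5")
  expect_error(build_tau_map(c(fits, fits[1L])), "duplicate")
})

test_that("fit_vft recovers noiseless parameters essentially exactly", {
  law <- law_vft(1e-14, 8, 250)
  Ts <- seq(258, 310, length.out = 12)
  v <- suppressWarnings(fit_vft(tau_map(Ts, tau_at(law, Ts))))
  expect_rel(v$tau_vft, 1e-14, 1e-6)
  expect_rel(v$D_T, 8, 1e-6)
  expect_rel(v$T0, 250, 1e-6)
  expect_false(v$vft_unnecessary)
})

test_that("tg_from_vft solves tau(Tg) = tau_ref in closed form", {
  law <- law_vft(1e-14, 8, 250)
  Ts <- seq(258, 310, length.out = 12)
  v <- suppressWarnings(fit_vft(tau_map(Ts, tau_at(law, Ts))))
  Tg <- tg_from_vft(v)
  expect_rel(tau_at(law, Tg), 100, 1e-9)
  # algebraic identity: tau_ref = tau_vft * e^D  =>  Tg = 2 T0
  expect_equal(tg_from_vft(list(tau_vft = 1, D_T = 3, T0 = 100),
                           tau_ref = exp(3)), 200)
  expect_error(tg_from_vft(v, tau_ref = 1e-20), "exceed")
})

test_that("Tg is recovered within 0.5 K under 0.05-decade noise (20 seeds)", {
  law <- law_vft(1e-14, 8, 250)
  Ts <- seq(260, 306, length.out = 15)
  tg_true <- 250 * (1 + 8 / log(100 / 1e-14))
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    tau <- tau_at(law, Ts) * 10^rnorm(15, 0, 0.05)
    v <- fit_vft(tau_map(Ts, tau))
    abs(v$Tg - tg_true)
  }, 0)
  expect_lt(max(errs), 0.5)
})

test_that("pure Arrhenius data raises the 'VFT unnecessary' flag", {
  arr <- law_arrhenius(1e-18, 79.9)
  Ts <- seq(250, 300, length.out = 10)
  v <- suppressWarnings(fit_vft(tau_map(Ts, tau_at(arr, Ts))))
  expect_true(v$vft_unnecessary)
})

test_that("fit_arrhenius recovers the printed secondary activation energies", {
  Ts <- seq(250, 300, length.out = 8)
  for (Ea in c(79.9, 29.5)) {
    arr <- law_arrhenius(1e-16, Ea)
    a <- fit_arrhenius(tau_map(Ts, tau_at(arr, Ts)))
    expect_rel(a$Ea, Ea, 1e-9)
  }
  expect_error(fit_arrhenius(tau_map(c(250, 260), c(1, 0.1))), "at least 4")
  # tau decreasing with 1/T (increasing with T) is unphysical below Tg
  expect_error(fit_arrhenius(tau_map(Ts, rev(tau_at(law_arrhenius(1e-16, 50), Ts)))),
               "slope")
})

test_that("detect_crossover: null case, planted kink, annealed (erased) case", {
  vft <- law_vft(1e-14, 7.5, 250.1)
  law <- law_crossover(vft, T_cross = 320, Ea_low = 150)
  Ts <- seq(300, 344, length.out = 18)
  # planted kink recovered within +/- 2 K across seeds
  hits <- 0; errs <- c()
  for (seed in 1:10) {
    set.seed(seed)
    tau <- tau_at(law, Ts) * 10^rnorm(length(Ts), 0, 0.05)
    cr <- suppressWarnings(detect_crossover(tau_map(Ts, tau)))
    if (cr$detected) { hits <- hits + 1; errs <- c(errs, abs(cr$T_cross - 320)) }
  }
  expect_equal(hits, 10L)
  expect_lt(stats::median(errs), 2)
  # single planted VFT: not detected (null case)
  set.seed(99)
  tau0 <- tau_at(vft, Ts) * 10^rnorm(length(Ts), 0, 0.05)
  cr0 <- suppressWarnings(detect_crossover(tau_map(Ts, tau0)))
  expect_false(cr0$detected)
  # map measured after annealing follows a single bulk-like VFT
  bulk <- scenario_preset("bulk_apz")$processes[[1L]]$law
  Ts2 <- seq(309, 341, length.out = 15)
  set.seed(7)
  tau2 <- tau_at(bulk, Ts2) * 10^rnorm(15, 0, 0.05)
  cr2 <- suppressWarnings(detect_crossover(tau_map(Ts2, tau2)))
  expect_false(cr2$detected)
  expect_error(detect_crossover(tau_map(Ts[1:8], tau_at(law, Ts[1:8]))),
               "at least 10")
})

test_that("fitted laws are strictly decreasing in T over the data range", {
  law <- law_vft(1e-13, 9, 240)
  Ts <- seq(250, 300, length.out = 12)
  v <- suppressWarnings(fit_vft(tau_map(Ts, tau_at(law, Ts))))
  grid <- seq(250, 300, by = 0.5)
  tau_fit <- v$tau_vft * exp(v$D_T * v$T0 / (grid - v$T0))
  expect_true(all(diff(tau_fit) < 0))
})

test_that("tg_comparison formats the BDS/DSC table with tolerance annotation", {
  tb <- tg_comparison(c(bulk = 306.4), c(bulk = 306.7), tolerance = 2)
  expect_true(tb$agrees)
  expect_equal(tb$delta_K, -0.3, tolerance = 1e-9)
})

test_that("time-indexed (annealing) maps build and drift monotonically", {
  preset <- scenario_preset("bulk_apz")
  ser <- gen_annealing_series(preset$processes[[1L]], T_anneal = 305,
                              times_h = c(1, 25, 50, 100, 250))
  fits <- lapply(seq_along(ser$index), function(i)
    list(time_h = ser$index[i], fit = attr(ser$spectra[[i]], "ground_truth")))
  map <- build_tau_map(fits, index = "time_h")
  expect_identical(attr(map, "index_kind"), "time_h")
  expect_true(all(diff(map$tau) > 0))  # aging: tau nondecreasing over time
})
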