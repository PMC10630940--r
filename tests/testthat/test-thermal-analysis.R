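# DSC parsing, event extraction, double-event reports, Kissinger analysis

test_that("DSC CSV round trip and validation", {
  kin <- scenario_preset("bulk_apz")$dsc_kinetics
  tg <- gen_dsc(kin, 10, noise_abs = 0.002, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_dsc(tg, path)
  back <- read_dsc(path)
  expect_equal(back$rate, 10)
  expect_true(back$exo_up)
  expect_equal(back$heat_flow, tg$heat_flow, tolerance = 1e-8)
  # a cooling segment is rejected
  writeLines(c("# rate_K_min: 10", "# exo_up: TRUE", "temp_K,heat_flow",
               "300,1", "299,1.1", "298,1.2"), path)
  expect_error(read_dsc(path), "monotone")
  # missing rate metadata
  writeLines(c("# exo_up: TRUE", "temp_K,heat_flow", "300,1", "301,1.1"), path)
  expect_error(read_dsc(path), "rate_K_min")
})

test_that("bulk events are recovered at the planted temperatures", {
  kin <- scenario_preset("bulk_apz")$dsc_kinetics
  ev <- extract_events(gen_dsc(kin, 10, noise_abs = 0))
  expect_equal(nrow(ev$tg), 1L)
  expect_equal(ev$tg$midpoint_K, 306.7, tolerance = 0.1)
  expect_equal(ev$tc$peak_K, 363.4, tolerance = 0.1)
  expect_equal(ev$tm$peak_K, c(406.6, 413.1), tolerance = 0.1)
  # re-extraction after a disk round trip gives the same events
  path <- tempfile(fileext = ".csv")
  write_dsc(gen_dsc(kin, 10, noise_abs = 0.002, seed = 5), path)
  ev2 <- extract_events(read_dsc(path))
  expect_equal(ev2$tc$peak_K, 363.4, tolerance = 0.2)
})

test_that("flat noisy baseline yields no events", {
  T <- seq(260, 440, by = 0.1)
  set.seed(3)
  tg <- dsc_thermogram(T, 0.05 + 2e-4 * T + rnorm(length(T), 0, 0.003),
                       rate = 10)
  ev <- extract_events(tg)
  expect_equal(nrow(ev$tg), 0L)
  expect_equal(nrow(ev$tc), 0L)
  expect_equal(nrow(ev$tm), 0L)
})

test_that("confined thermograms show an ordered double glass transition", {
  kin <- scenario_preset("native_sio2")$dsc_kinetics
  ev <- extract_events(gen_dsc(kin, 10, noise_abs = 0.002, seed = 8))
  expect_equal(nrow(ev$tg), 2L)
  expect_lt(ev$tg$midpoint_K[1L], 306.7)  # core below bulk Tg
  expect_gt(ev$tg$midpoint_K[2L], 306.7)  # interfacial above bulk Tg
  expect_equal(ev$tg$midpoint_K, c(300, 318), tolerance = 0.3)
})

test_that("double-crystallization merging threshold lies in (7.5, 10]", {
  kin <- scenario_preset("native_sio2")$dsc_kinetics
  rates <- c(2.5, 5, 7.5, 10, 20)
  events <- lapply(seq_along(rates), function(i)
    extract_events(gen_dsc(kin, rates[i], noise_abs = 0.002, seed = i)))
  rep <- detect_double_events(events)
  expect_equal(rep$per_rate$n_tc, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(rep$merge_threshold, c(7.5, 10))
  expect_false(rep$always_double)
})

test_that("all-single and always-double rate sets report accordingly", {
  kin1 <- scenario_preset("bulk_apz")$dsc_kinetics
  ev1 <- lapply(c(5, 10, 20), function(r) extract_events(gen_dsc(kin1, r)))
  rep1 <- detect_double_events(ev1)
  expect_null(rep1$merge_threshold)
  kin2 <- scenario_preset("native_sio2")$dsc_kinetics
  ev2 <- lapply(c(2.5, 5, 7.5), function(r) extract_events(gen_dsc(kin2, r)))
  rep2 <- detect_double_events(ev2)
  expect_true(rep2$always_double)
  expect_equal(rep2$merge_threshold[1L], 7.5)
  expect_error(detect_double_events(ev2[1:2]), "3 rates")
})

test_that("kissinger_fit: exact recovery, noise robustness, unit invariance", {
  kin <- kinetics_spec(Ea_cr = 100, Tc_at_10 = 363.4)
  rates <- c(2.5, 5, 10, 20)
  Tcs <- vapply(rates, function(r) kissinger_tc(r, 100, kin$C_K), 0)
  kf <- kissinger_fit(data.frame(phi = rates, Tc = Tcs))
  expect_rel(kf$E_cr, 100, 1e-4)
  # declaring the rate unit changes nothing once converted internally;
  # E_cr is invariant to the unit convention in any case
  kf_s <- kissinger_fit(data.frame(phi = rates / 60, Tc = Tcs),
                        phi_unit = "K/s")
  expect_equal(kf$E_cr, kf_s$E_cr, tolerance = 1e-12)
  expect_equal(kf$C_K, kf_s$C_K, tolerance = 1e-9)
  # feeding K/min values as if they were K/s shifts only the intercept
  kf_m <- kissinger_fit(data.frame(phi = rates, Tc = Tcs), phi_unit = "K/s")
  expect_equal(kf_m$E_cr, kf$E_cr, tolerance = 1e-9)
  expect_equal(kf_m$C_K - kf$C_K, log(60), tolerance = 1e-9)
  # Gaussian Tc noise, sigma = 0.5 K: median error within 5% over 100 seeds
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    k <- kissinger_fit(data.frame(phi = rates, Tc = Tcs + rnorm(4, 0, 0.5)))
    abs(k$E_cr / 100 - 1)
  }, 0)
  expect_lt(stats::median(errs), 0.05)
  expect_error(kissinger_fit(data.frame(phi = c(5, 10), Tc = c(360, 365))),
               "at least 3")
  expect_error(kissinger_fit(data.frame(phi = c(5, 5, 10), Tc = c(360, 361, 365))),
               "repeated")
})

test_that("kissinger_multi fits per peak group and skips short groups", {
  kin <- scenario_preset("native_sio2")$dsc_kinetics  # Ea 74 and 95 kJ/mol
  rates <- c(2.5, 5, 7.5)
  pts <- do.call(rbind, lapply(rates, function(r) {
    gt <- attr(gen_dsc(kin, r), "ground_truth")
    data.frame(phi = r, Tc = gt$Tc, group = c("first", "second"))
  }))
  res <- kissinger_multi(pts)
  expect_rel(res$first$E_cr, 74, 1e-3)
  expect_rel(res$second$E_cr, 95, 1e-3)
  expect_warning(kissinger_multi(rbind(pts,
    data.frame(phi = c(10, 20), Tc = c(368, 375), group = "merged"))),
    "skipped")
  # a merged-only group equals a plain kissinger_fit
  m <- pts[pts$group == "first", ]
  m$group <- "merged"
  expect_equal(kissinger_multi(m)$merged$E_cr,
               kissinger_fit(m[, c("phi", "Tc")])$E_cr)
})

test_that("extraction is stable to a one-step grid shift", {
  kin <- scenario_preset("bulk_apz")$dsc_kinetics
  e1 <- extract_events(gen_dsc(kin, 10, T_grid = seq(260, 440, 0.1)))
  e2 <- extract_events(gen_dsc(kin, 10, T_grid = seq(260.05, 440.05, 0.1)))
  expect_equal(e1$tg$midpoint_K, e2$tg$midpoint_K, tolerance = 0.15)
  expect_equal(e1$tc$peak_K, e2$tc$peak_K, tolerance = 0.15)
})
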