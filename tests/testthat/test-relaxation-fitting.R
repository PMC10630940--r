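# HN evaluation/fitting, loss-peak times, KWW transform and fit, CM relation

test_that("hn_eval matches the closed Debye forms and static limit", {
  fit <- hn_fit(2, 1e-3, 1, 1, eps_inf = 3)
  # Debye: eps'' at w = 1/tau equals delta_eps / 2
  f0 <- 1 / (2 * pi * 1e-3)
  expect_equal(-Im(hn_eval(fit, f0)), 1, tolerance = 1e-12)
  # static limit: eps' -> eps_inf + sum(delta_eps)
  expect_equal(Re(hn_eval(fit, 1e-9)), 5, tolerance = 1e-6)
  # high-frequency limit
  expect_equal(Re(hn_eval(fit, 1e12)), 3, tolerance = 1e-4)
})

test_that("complex-power and polar-expansion routes agree to 1e-12", {
  set.seed(42)
  for (i in 1:10) {
    fit <- hn_fit(runif(1, 0.5, 8), 10^runif(1, -6, 0), runif(1, 0.2, 1),
                  runif(1, 0.2, 1), eps_inf = runif(1, 2, 4),
                  sigma_dc = 10^runif(1, -14, -10))
    freq <- 10^runif(20, -2, 6)
    a <- hn_eval(fit, freq, method = "complex")
    b <- hn_eval(fit, freq, method = "polar")
    expect_lt(max(Mod(a - b) / Mod(a)), 1e-12)
  }
})

test_that("tau_max closed form: Debye and Cole-Cole reduce to tau_HN", {
  expect_equal(tau_max_from_hn(hn_fit(1, 2e-2, 1, 1)), 2e-2)
  expect_equal(tau_max_from_hn(hn_fit(1, 2e-2, 0.5, 1)), 2e-2)
})

test_that("tau_max closed form equals numerical argmax for random shapes", {
  set.seed(7)
  grid <- amorphotrack:::log_grid(1e-7, 1e7, 1e4)
  step <- 14 / 1e4  # log10 grid step
  for (i in 1:100) {
    a <- runif(1, 0.2, 1); g <- runif(1, 0.2, 1)
    fit <- hn_fit(2, 1, a, g)
    tm <- tau_max_from_hn(fit)
    tnum <- 1 / (2 * pi * grid[which.max(-Im(hn_eval(fit, grid)))])
    expect_lt(abs(log10(tm) - log10(tnum)), step + 1e-12)
  }
})

test_that("fit_hn recovers noiseless parameters within 0.1%", {
  truth <- hn_fit(5, 1e-2, 0.8, 0.6, eps_inf = 3)
  fit <- fit_hn(spectrum_from_truth(truth), 1)
  expect_rel(fit$processes$delta_eps, 5, 1e-3)
  expect_rel(fit$processes$tau_hn, 1e-2, 1e-3)
  expect_rel(fit$processes$alpha, 0.8, 1e-3)
  expect_rel(fit$processes$gamma, 0.6, 1e-3)
  expect_rel(fit$eps_inf, 3, 1e-3)
  expect_false(fit$processes$unresolved)
})

test_that("fit_hn with conductivity and 1% noise stays within 5% (tau 10%)", {
  truth <- hn_fit(5, 1e-2, 0.8, 0.6, eps_inf = 3, sigma_dc = 1e-11)
  sp0 <- spectrum_from_truth(truth)
  worst <- c(de = 0, al = 0, ga = 0, sig = 0, tau = 0)
  for (seed in 1:20) {
    fit <- fit_hn(noisy_loss(sp0, 0.01, seed), 1, use_conductivity = TRUE)
    worst["de"] <- max(worst["de"], abs(fit$processes$delta_eps / 5 - 1))
    worst["al"] <- max(worst["al"], abs(fit$processes$alpha / 0.8 - 1))
    worst["ga"] <- max(worst["ga"], abs(fit$processes$gamma / 0.6 - 1))
    worst["sig"] <- max(worst["sig"], abs(fit$sigma_dc / 1e-11 - 1))
    worst["tau"] <- max(worst["tau"], abs(fit$processes$tau_hn / 1e-2 - 1))
  }
  expect_lt(worst[["de"]], 0.05)
  expect_lt(worst[["al"]], 0.05)
  expect_lt(worst[["ga"]], 0.05)
  expect_lt(worst[["sig"]], 0.05)
  expect_lt(worst[["tau"]], 0.10)
})

test_that("two overlapping processes: resolved at 1.5 decades, flagged at 0.3", {
  far <- hn_fit(c(4, 2), c(1e-2, 10^(-2 - 1.5)), c(0.85, 0.85), c(0.7, 0.7),
                eps_inf = 3)
  fit <- fit_hn(noisy_loss(spectrum_from_truth(far), 0.01, 1), 2)
  expect_false(any(fit$processes$unresolved))
  taus <- sort(fit$processes$tau_hn)
  expect_rel(taus[1], 10^(-3.5), 0.4)
  expect_rel(taus[2], 1e-2, 0.4)

  near <- hn_fit(c(4, 2), c(1e-2, 10^(-2.3)), c(0.85, 0.85), c(0.7, 0.7),
                 eps_inf = 3)
  fit2 <- fit_hn(noisy_loss(spectrum_from_truth(near), 0.01, 1), 2)
  expect_true(any(fit2$processes$unresolved))
})

test_that("fit_hn validates its window", {
  truth <- hn_fit(5, 1e-2, 0.8, 0.6, eps_inf = 3)
  sp <- spectrum_from_truth(truth)
  expect_error(fit_hn(sp, 1, window = c(1e4, 1e6)), "window")
  expect_error(fit_hn(sp, 1, window = c(1, 1.5)), "points")
})

test_that("kww_loss: beta = 1 is the exact Debye curve", {
  f <- amorphotrack:::log_grid(1e-3, 1e3, 40) / (2 * pi)
  out <- kww_loss(1, 1, f, normalize = FALSE)
  W <- 2 * pi * f
  expect_identical(out$loss, W / (1 + W^2))
  # normalized: peak exactly at W = 1 when the grid contains it
  f41 <- amorphotrack:::log_grid(1e-3, 1e3, 41) / (2 * pi)
  out41 <- kww_loss(1, 1, f41)
  expect_equal(2 * pi * out41$freq[which.max(out41$loss)], 1, tolerance = 1e-12)
  expect_equal(max(out41$loss), 1)
})

test_that("kww_loss half-period scheme matches contour-rotation oracle to 1e-6", {
  f <- amorphotrack:::log_grid(1e-3, 1e3, 31) / (2 * pi)
  for (beta in c(0.3, 0.56, 0.8)) {
    a <- kww_loss(beta, 1, f, method = "half_period", normalize = FALSE)
    b <- kww_loss(beta, 1, f, method = "reference", normalize = FALSE)
    expect_lt(max(abs(a$loss / b$loss - 1)), 1e-6)
  }
})

test_that("normalized KWW width grows monotonically as beta decreases", {
  fwhm <- function(beta) {
    f <- amorphotrack:::log_grid(1e-4, 1e4, 400)
    cv <- kww_loss(beta, 1 / (2 * pi), f)
    above <- which(cv$loss >= 0.5)
    log10(cv$freq[max(above)]) - log10(cv$freq[min(above)])
  }
  widths <- vapply(c(1, 0.8, 0.56, 0.4, 0.3), fwhm, 0)
  expect_true(all(diff(widths) > 0))
  # Debye half-height width is 1.144 decades
  expect_equal(widths[1], 1.144, tolerance = 1e-2)
})

test_that("fit_kww recovers beta = 0.56 within 0.02 under 1% noise", {
  f <- amorphotrack:::log_grid(1e-3, 1e3, 50)
  clean <- kww_loss(0.56, 1 / (2 * pi), f)
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- data.frame(freq = f,
                        loss = clean$loss * (1 + rnorm(50, 0, 0.01)))
    fit <- fit_kww(noisy)
    expect_lt(abs(fit$beta_kww - 0.56), 0.02)
    expect_false(fit$elevated_residual)
  }
})

test_that("fit_kww identifies a Debye input and flags un-KWW-like shapes", {
  f <- amorphotrack:::log_grid(1e-3, 1e3, 50)
  deb <- kww_loss(1, 1 / (2 * pi), f)
  fit <- fit_kww(deb)
  expect_lt(abs(fit$beta_kww - 1), 0.01)
  # a Cole-Cole peak much broader than any KWW cannot be fitted exactly
  broad <- hn_fit(2, 1 / (2 * pi), 0.4, 1)
  ei <- -Im(hn_eval(broad, f))
  fit2 <- fit_kww(data.frame(freq = f, loss = ei / max(ei)))
  expect_true(fit2$elevated_residual)
})

test_that("cm_jg_test reproduces the CM arithmetic and verdict logic", {
  # uncoupled limit: tau0 = tau_alpha
  r <- cm_jg_test(0.1, 1)
  expect_equal(r$n, 0)
  expect_equal(r$tau0, 0.1)
  # hand-computed: log10 tau0 = n log10 tc + (1-n) log10 tau_alpha
  r2 <- cm_jg_test(100, 0.56, t_c = 2e-12)
  expect_equal(log10(r2$tau0), 0.44 * log10(2e-12) + 0.56 * 2,
               tolerance = 1e-12)
  expect_identical(r2$verdict, "untested")
  expect_identical(cm_jg_test(100, 0.56, tau_beta_observed = r2$tau0 * 3)$verdict,
                   "consistent")
  expect_identical(cm_jg_test(100, 0.56, tau_beta_observed = r2$tau0 * 1e3)$verdict,
                   "inconsistent")
})
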