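# Relaxation maps tau(T): VFT and Arrhenius fits, Tg at tau = 100 s, and
# detection of the confinement-induced crossover in the temperature dependence
# of the structural relaxation time.

#' Build a tau(T) map from per-temperature HN fits
#'
#' Takes a list of `(T, hn_fit)` entries (or `(time_h, hn_fit)` for annealing
#' series), extracts the loss-peak relaxation time of the chosen process via
#' [tau_max_from_hn()], and returns the sorted map.
#'
#' @param fits list of `list(T = , fit = )` entries (use `time_h =` for
#'   time-indexed maps).
#' @param process process index or name passed to [tau_max_from_hn()].
#' @param index `"T"` (temperature, K) or `"time_h"` (annealing time, hours).
#' @param label process label stored on the map.
#' @return object of class `tau_map`: data.frame with columns `index`, `tau`.
#' @export
build_tau_map <- function(fits, process = 1L, index = c("T", "time_h"),
                          label = "alpha") {
  index <- match.arg(index)
  if (length(fits) < 5L) stop_amt("need at least 5 fits to build a map")
  idx <- vapply(fits, function(e) e[[index]] %||% NA_real_, 0)
  if (anyNA(idx)) stop_amt("every entry needs its %s value", index)
  if (anyDuplicated(idx)) stop_amt("duplicate %s values in the map", index)
  tau <- vapply(fits, function(e) tau_max_from_hn(e$fit, process), 0)
  o <- order(idx)
  tau_map(idx[o], tau[o], index = index, label = label)
}

#' @rdname build_tau_map
#' @param values index values (temperature [K] or time [h]).
#' @param tau relaxation times [s], > 0.
#' @export
tau_map <- function(values, tau, index = c("T", "time_h"), label = "alpha") {
  index <- match.arg(index)
  stopifnot(length(values) == length(tau))
  if (any(tau <= 0)) stop_amt("tau must be > 0")
  if (anyDuplicated(values)) stop_amt("duplicate index values")
  o <- order(values)
  structure(data.frame(index = values[o], tau = tau[o]),
            index_kind = index, label = label, class = c("tau_map", "data.frame"))
}

#' Fit the Vogel-Fulcher-Tammann law to a relaxation map
#'
#' Nonlinear least squares of `log10 tau = log10 tau_vft +
#' D_T T0 / ((T - T0) ln 10)` with a `T0` profile-grid initialization (for
#' each trial `T0` the remaining two parameters are linear). A pure-Arrhenius
#' comparison fit provides a curvature test: if VFT does not improve on the
#' straight line in `1/T` (F-ratio below `curvature_f`), the result is
#' flagged `vft_unnecessary`.
#'
#' @param map a [tau_map()] with >= 5 points spanning >= 3 decades in tau.
#' @param tau_ref reference time defining Tg (default 100 s).
#' @param curvature_f F-ratio threshold for the Arrhenius-vs-VFT test.
#' @return object of class `vft_params`: `tau_vft` [s], `D_T`, `T0` [K],
#'   `Tg` [K] (at `tau_ref`), `cov` (3x3, in fitting coordinates
#'   `log10 tau_vft, D_T, T0`), `se` (delta-method standard errors),
#'   `rss`, `vft_unnecessary`.
#' @export
fit_vft <- function(map, tau_ref = 100, curvature_f = 4) {
  T <- map$index; y <- log10(map$tau)
  if (length(T) < 5L) stop_amt("need at least 5 points for a VFT fit")
  if (diff(range(y)) < 3)
    warn_amt("tau spans %.2f decades (< 3): VFT parameters may be poorly determined",
             diff(range(y)))
  ln10 <- log(10)
  model <- function(p) p[1L] + p[2L] * p[3L] / ((T - p[3L]) * ln10)
  rssf <- function(p) if (p[3L] >= min(T) - 1e-9 || p[3L] < 0) Inf
  else sum((model(p) - y)^2)
  # profile initialization over T0
  best <- NULL
  for (T0 in seq(0.3 * min(T), 0.985 * min(T), length.out = 60L)) {
    x <- 1 / (T - T0)
    co <- stats::coef(stats::lm(y ~ x))
    p <- c(co[1L], co[2L] * ln10 / T0, T0)
    r <- rssf(p)
    if (is.null(best) || r < best$r) best <- list(p = p, r = r)
  }
  o <- stats::optim(best$p, rssf, control = list(maxit = 5000L,
                                                reltol = 1e-15))
  o <- stats::optim(o$par, rssf, control = list(maxit = 5000L,
                                                reltol = 1e-15))
  p <- o$par
  if (p[3L] >= min(T)) stop_amt("fitted T0 >= min(T): VFT fit invalid")
  if (!is.finite(o$value)) stop_amt("VFT fit did not converge")
  # curvature test against plain Arrhenius (straight line in 1/T)
  rss_arr <- sum(stats::resid(stats::lm(y ~ I(1 / T)))^2)
  n <- length(T)
  f_ratio <- ((rss_arr - o$value) / 1) / (o$value / max(n - 3L, 1L))
  J <- fd_jacobian(model, p)
  cov <- ls_covariance(model(p) - y, J)
  tau_vft <- 10^p[1L]
  Tg <- tg_from_vft_params(tau_vft, p[2L], p[3L], tau_ref)
  se <- sqrt(pmax(diag(cov), 0))
  out <- structure(list(
    tau_vft = tau_vft, D_T = p[2L], T0 = p[3L], Tg = Tg, tau_ref = tau_ref,
    cov = cov, se = c(log10_tau_vft = se[1L], D_T = se[2L], T0 = se[3L]),
    rss = o$value, n = n,
    vft_unnecessary = is.finite(f_ratio) && f_ratio < curvature_f,
    data_range = range(T)), class = "vft_params")
  out
}

#' @export
print.vft_params <- function(x, ...) {
  cat(sprintf("VFT fit: tau_vft = %.3g s, D_T = %.3f, T0 = %.2f K, Tg(tau=%g s) = %.2f K%s\n",
              x$tau_vft, x$D_T, x$T0, x$tau_ref, x$Tg,
              if (x$vft_unnecessary) " [VFT unnecessary: no curvature]" else ""))
  invisible(x)
}

tg_from_vft_params <- function(tau_vft, D_T, T0, tau_ref = 100) {
  if (tau_ref <= tau_vft) stop_amt("tau_ref must exceed the VFT prefactor")
  T0 * (1 + D_T / log(tau_ref / tau_vft))
}

#' Glass-transition temperature from VFT parameters
#'
#' Solves `tau(Tg) = tau_ref` in closed form:
#' `Tg = T0 (1 + D_T / ln(tau_ref / tau_vft))`. The conventional dielectric
#' Tg uses `tau_ref = 100 s` (`log10 tau = 2`).
#'
#' @param params a `vft_params` object from [fit_vft()] (or a `law_vft`).
#' @param tau_ref reference relaxation time [s].
#' @return Tg in K.
#' @export
tg_from_vft <- function(params, tau_ref = 100) {
  tg_from_vft_params(params$tau_vft, params$D_T, params$T0, tau_ref)
}

#' Fit an Arrhenius law to a relaxation map
#'
#' Linear regression of `ln tau` on `1/T`; `Ea = slope * R`. Intended for
#' sub-Tg secondary (beta, gamma) relaxations, so a nonpositive slope is an
#' error.
#'
#' @param map a [tau_map()] with >= 4 points.
#' @return object of class `arrhenius_params`: `tau_inf` [s], `Ea` [kJ/mol],
#'   `se_Ea` [kJ/mol], `rss`, `r_squared`.
#' @export
fit_arrhenius <- function(map) {
  T <- map$index; y <- log(map$tau)
  if (length(T) < 4L) stop_amt("need at least 4 points for an Arrhenius fit")
  fm <- stats::lm(y ~ I(1 / T))
  sl <- stats::coef(fm)[[2L]]
  if (sl <= 0)
    stop_amt("nonpositive Arrhenius slope: tau does not increase on cooling")
  se <- summary(fm)$coefficients[2L, 2L]
  structure(list(tau_inf = exp(stats::coef(fm)[[1L]]),
                 Ea = sl * RGAS / 1000, se_Ea = se * RGAS / 1000,
                 rss = sum(stats::resid(fm)^2),
                 r_squared = summary(fm)$r.squared), class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.2f +/- %.2f kJ/mol, tau_inf = %.3g s\n",
              x$Ea, x$se_Ea, x$tau_inf))
  invisible(x)
}

#' Detect a crossover (kink) in the temperature dependence of tau
#'
#' Grid search over candidate break temperatures; for each candidate a
#' continuous two-regime model (VFT above the break, Arrhenius below, pinned
#' to the VFT value at the break) is fitted to all points jointly. The
#' two-regime model adds 2 parameters (break temperature and low-T activation
#' energy) over the single VFT; the crossover is reported as detected when
#' the F-like ratio `((RSS0 - RSS1)/2) / (RSS1/(n - 5))` exceeds `threshold`.
#'
#' @param map a [tau_map()] with >= 10 points.
#' @param threshold detection threshold on the F-like ratio (default 4).
#' @param min_upper,min_lower minimum points required above/below a candidate
#'   break.
#' @return object of class `crossover_result`: `detected`, `T_cross`,
#'   `high_T_law` (`vft_params`-like list), `low_T_law` (Arrhenius list),
#'   `f_ratio`, `rss_single`, `rss_two`.
#' @export
detect_crossover <- function(map, threshold = 4, min_upper = 5L,
                             min_lower = 3L) {
  T <- map$index; y <- log10(map$tau)
  n <- length(T)
  if (n < 10L) stop_amt("need at least 10 points for crossover detection")
  single <- fit_vft(map, curvature_f = 0)
  rss0 <- single$rss
  ln10 <- log(10)
  model2 <- function(p, Tc) {
    # p = (log10 tau_vft, D_T, T0, Ea_low kJ/mol)
    vft <- p[1L] + p[2L] * p[3L] / ((pmax(T, p[3L] + 1e-6) - p[3L]) * ln10)
    yc <- p[1L] + p[2L] * p[3L] / ((Tc - p[3L]) * ln10)
    arr <- yc + p[4L] * 1000 / (RGAS * ln10) * (1 / T - 1 / Tc)
    ifelse(T > Tc, vft, arr)
  }
  best <- NULL
  cands <- (T[-1L] + T[-n]) / 2
  for (i in seq_along(cands)) {
    Tc <- cands[i]
    if (sum(T > Tc) < min_upper || sum(T <= Tc) < min_lower) next
    upper_map <- tau_map(T[T > Tc], 10^y[T > Tc])
    init <- tryCatch({
      v <- fit_vft(upper_map, curvature_f = 0)
      c(log10(v$tau_vft), v$D_T, v$T0)
    }, error = function(e) c(log10(single$tau_vft), single$D_T, single$T0))
    # initial low-T slope from the lower points
    low <- T <= Tc
    ea0 <- if (sum(low) >= 2L) {
      sl <- stats::coef(stats::lm(y[low] ~ I(1 / T[low])))[[2L]]
      max(sl * RGAS * ln10 / 1000, 10)
    } else 100
    rssf <- function(p) {
      if (p[3L] <= 0 || p[3L] >= Tc - 1 || p[4L] <= 0) return(Inf)
      sum((model2(p, Tc) - y)^2)
    }
    o <- stats::optim(c(init, ea0), rssf,
                      control = list(maxit = 4000L, reltol = 1e-14))
    if (is.null(best) || o$value < best$rss)
      best <- list(rss = o$value, p = o$par, Tc = Tc)
  }
  if (is.null(best))
    return(structure(list(detected = FALSE, T_cross = NA_real_,
                          f_ratio = NA_real_, rss_single = rss0,
                          rss_two = NA_real_, high_T_law = single,
                          low_T_law = NULL), class = "crossover_result"))
  f_ratio <- ((rss0 - best$rss) / 2) / (best$rss / max(n - 5L, 1L))
  detected <- is.finite(f_ratio) && f_ratio > threshold
  p <- best$p
  structure(list(
    detected = detected, T_cross = if (detected) best$Tc else NA_real_,
    f_ratio = f_ratio, rss_single = rss0, rss_two = best$rss,
    high_T_law = list(tau_vft = 10^p[1L], D_T = p[2L], T0 = p[3L]),
    low_T_law = list(Ea = p[4L]),
    single_vft = single), class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Crossover detected at T = %.1f K (F = %.2f); low-T Ea = %.1f kJ/mol\n",
                x$T_cross, x$f_ratio, x$low_T_law$Ea))
  else cat(sprintf("No crossover detected (F = %.2f)\n", x$f_ratio))
  invisible(x)
}

#' Tabulate dielectric vs calorimetric glass-transition temperatures
#'
#' Formats a comparison table (one row per sample) with the absolute
#' difference annotated; no statistical test is attempted since each entry is
#' a single measurement.
#'
#' @param tg_bds named numeric vector of dielectric Tg values [K].
#' @param tg_dsc named numeric vector of calorimetric Tg values [K].
#' @param tolerance annotation threshold [K] for the `agrees` column.
#' @return data.frame with columns `sample`, `Tg_BDS_K`, `Tg_DSC_K`,
#'   `delta_K`, `agrees`.
#' @export
tg_comparison <- function(tg_bds, tg_dsc, tolerance = 2) {
  samples <- union(names(tg_bds), names(tg_dsc))
  data.frame(sample = samples,
             Tg_BDS_K = as.numeric(tg_bds[samples]),
             Tg_DSC_K = as.numeric(tg_dsc[samples]),
             delta_K = as.numeric(tg_bds[samples]) - as.numeric(tg_dsc[samples]),
             agrees = abs(as.numeric(tg_bds[samples]) -
                            as.numeric(tg_dsc[samples])) <= tolerance)
}
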