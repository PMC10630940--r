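# Dissolution profiles: candidate release-model fitting, AICc selection,
# summary metrics, classification and ranking.

#' Construct a dissolution profile
#'
#' @param time sampling times [min], nonnegative increasing, >= 4 points
#'   (the compendial schedule used in the underlying study sampled at 15, 30,
#'   60, 120 and 180 min).
#' @param conc concentrations [mg/mL], >= 0.
#' @param medium dissolution medium label (default `"0.1 M HCl"`).
#' @param label sample label.
#' @return object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(time, conc, medium = "0.1 M HCl",
                                label = "sample") {
  if (length(time) < 4L) stop_amt("a profile needs at least 4 points")
  if (length(conc) != length(time)) stop_amt("time and conc lengths differ")
  if (any(time < 0) || any(diff(time) <= 0))
    stop_amt("time must be nonnegative and strictly increasing")
  if (any(conc < 0)) stop_amt("conc must be >= 0")
  structure(list(time = time, conc = conc, medium = medium, label = label),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("Dissolution profile '%s': %d points, 0-%.0f min, Cmax = %.3g mg/mL\n",
              x$label, length(x$time), max(x$time), max(x$conc)))
  invisible(x)
}

#' Read / write dissolution profiles ("diss-v1" CSV dialect)
#'
#' Columns `time_min`, `conc_mg_ml`.
#' @param path file path.
#' @export
read_dissolution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("time_min", "conc_mg_ml"))
    if (!cn %in% names(df)) stop_amt("missing column %s in %s", cn, path)
  dissolution_profile(df$time_min, df$conc_mg_ml, label = basename(path))
}

#' @rdname read_dissolution
#' @param profile a [dissolution_profile()].
#' @export
write_dissolution <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  df <- data.frame(time_min = signif(profile$time, 9),
                   conc_mg_ml = signif(profile$conc, 9))
  utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# candidate models: value and least-squares fit (returns rss, k, par)
.release_models <- function() {
  list(
    constant = list(
      k = 1L,
      fit = function(t, c) {
        par <- c(c0 = mean(c))
        list(par = par, rss = sum((c - par)^2),
             fn = function(t, p) rep(p[["c0"]], length(t)))
      }),
    first_order = list(
      k = 2L,
      fit = function(t, c) {
        fn <- function(t, p) p[["C_inf"]] * (1 - exp(-p[["k"]] * t))
        start <- c(C_inf = max(c) * 1.05 + 1e-9, k = 1 / max(t[1L], 1))
        .ls_fit(fn, t, c, start, lower = c(1e-12, 1e-8))
      }),
    log_rise = list(
      k = 2L,
      fit = function(t, c) {
        fn <- function(t, p) p[["a"]] * log1p(p[["b"]] * t)
        start <- c(a = max(c) / log1p(max(t) / 30), b = 1 / 30)
        .ls_fit(fn, t, c, start, lower = c(1e-12, 1e-8))
      }),
    rise_decay = list(
      k = 4L,
      fit = function(t, c) {
        fn <- function(t, p) p[["plateau"]] + p[["A"]] *
          (1 - exp(-p[["k_rise"]] * t)) * exp(-p[["k_decay"]] * t)
        ipk <- which.max(c)
        start <- c(plateau = max(min(c[t >= t[ipk]]), 1e-6),
                   A = max(max(c) - stats::median(c), 1e-6),
                   k_rise = 2 / max(t[ipk], 1), k_decay = 1 / max(t))
        .ls_fit(fn, t, c, start, lower = rep(1e-12, 4L))
      }))
}

.ls_fit <- function(fn, t, c, start, lower) {
  obj <- function(lp) sum((fn(t, stats::setNames(exp(lp), names(start))) - c)^2)
  lp0 <- log(pmax(start, lower))
  o <- stats::optim(lp0, obj, control = list(maxit = 2000L, reltol = 1e-13))
  o <- stats::optim(o$par, obj, control = list(maxit = 2000L, reltol = 1e-13))
  par <- stats::setNames(exp(o$par), names(start))
  list(par = par, rss = o$value, fn = fn)
}

.aicc <- function(rss, n, k) {
  # k model parameters + 1 variance parameter
  kk <- k + 1L
  if (n - kk - 1L <= 0L) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
}

#' Fit candidate release models to a dissolution profile and classify it
#'
#' Candidate models (least squares, positivity-constrained):
#' `constant`; `first_order` `C_inf (1 - e^(-k t))`; `log_rise`
#' `a ln(1 + b t)`; `rise_decay`
#' `plateau + A (1 - e^(-k_rise t)) e^(-k_decay t)`. The winner minimizes
#' the small-sample-corrected AICc. Classification: a winning `rise_decay`
#' with model peak/plateau ratio > `spring_ratio` is `spring_and_crash`; a
#' winning monotone model is `prolonged_release`; `constant` is `flat`.
#'
#' @param profile a [dissolution_profile()].
#' @param spring_ratio peak/plateau ratio above which a rise-decay winner is
#'   classified as spring-and-crash.
#' @return object of class `release_fit`: `model`, `parameters`, `aicc`
#'   (named vector for all candidates), `class_label`, `rss`, `fitted`.
#' @export
fit_release <- function(profile, spring_ratio = 1.2) {
  t <- profile$time; c <- profile$conc
  models <- .release_models()
  fits <- lapply(models, function(m)
    tryCatch(m$fit(t, c), error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop_amt("all release-model fits failed")
  aicc <- rep(Inf, length(models))
  names(aicc) <- names(models)
  for (i in which(ok))
    aicc[i] <- .aicc(fits[[i]]$rss, length(t), models[[i]]$k)
  # guard: if every AICc is Inf (tiny n), fall back to RSS per parameter
  if (all(!is.finite(aicc)))
    aicc[ok] <- vapply(fits[ok], `[[`, 0, "rss")
  winner <- names(which.min(aicc))
  # effect-size guards (F-tests against the constant model at alpha = 0.01):
  # AICc's small-sample penalty otherwise lets noise on a flat profile win as
  # a monotone model, and can crush a genuine rise-decay into "constant"
  n <- length(t)
  f_signif <- function(m) {
    rss0 <- fits$constant$rss
    dk <- models[[m]]$k - 1L
    df2 <- n - models[[m]]$k - 1L
    if (is.null(fits[[m]]) || dk < 1L || df2 < 1L) return(FALSE)
    Fv <- ((rss0 - fits[[m]]$rss) / dk) / (fits[[m]]$rss / df2)
    is.finite(Fv) && Fv > stats::qf(0.99, dk, df2)
  }
  if (winner == "constant") {
    alts <- setdiff(names(models)[ok], "constant")
    sig <- alts[vapply(alts, f_signif, TRUE)]
    if (length(sig)) winner <- sig[which.min(aicc[sig])]
  } else if (!f_signif(winner)) {
    winner <- "constant"
  }
  wf <- fits[[winner]]
  class_label <- switch(winner,
    constant = "flat",
    first_order = "prolonged_release",
    log_rise = "prolonged_release",
    rise_decay = {
      p <- wf$par
      tgrid <- seq(0, max(t) * 3, length.out = 600L)
      peak <- max(wf$fn(tgrid, p))
      ratio <- peak / max(p[["plateau"]], 1e-12)
      if (ratio > spring_ratio) "spring_and_crash" else "prolonged_release"
    })
  structure(list(model = winner, parameters = wf$par, aicc = aicc,
                 class_label = class_label, rss = wf$rss,
                 fitted = wf$fn(t, wf$par), profile = profile),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("Release fit: model %s -> class %s (rss = %.3g)\n",
              x$model, x$class_label, x$rss))
  print(signif(x$parameters, 4))
  invisible(x)
}

#' Summary metrics of a dissolution profile
#'
#' @param profile a [dissolution_profile()].
#' @return list: `Cmax` [mg/mL], `t_Cmax` [min], `AUC` (trapezoid,
#'   mg min/mL), `final_over_max`.
#' @export
summary_metrics <- function(profile) {
  t <- profile$time; c <- profile$conc
  i <- which.max(c)
  list(Cmax = c[i], t_Cmax = t[i], AUC = trapz(t, c),
       final_over_max = c[length(c)] / max(c[i], 1e-300))
}

#' Rank dissolution profiles by exposure
#'
#' Orders profiles by AUC (descending) with concentration at the final common
#' time as tie-breaker; profiles on different time grids are interpolated to
#' the common overlap with a warning.
#'
#' @param profiles named list of [dissolution_profile()] objects (>= 2).
#' @return data.frame ranking with columns `sample`, `AUC`, `C_final`,
#'   `rank`, `tied_with_next`.
#' @export
compare_profiles <- function(profiles) {
  if (length(profiles) < 2L) stop_amt("need at least 2 profiles to compare")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  grids <- vapply(profiles, function(p) paste(p$time, collapse = ","), "")
  if (length(unique(grids)) > 1L) {
    warn_amt("mismatched time grids: interpolating to the common overlap")
    t0 <- max(vapply(profiles, function(p) min(p$time), 0))
    t1 <- min(vapply(profiles, function(p) max(p$time), 0))
    grid <- seq(t0, t1, length.out = 50L)
    profiles <- lapply(profiles, function(p)
      dissolution_profile(grid, stats::approx(p$time, p$conc, grid)$y,
                          medium = p$medium, label = p$label))
  }
  auc <- vapply(profiles, function(p) trapz(p$time, p$conc), 0)
  cfin <- vapply(profiles, function(p) p$conc[length(p$conc)], 0)
  o <- order(-auc, -cfin)
  out <- data.frame(sample = names(profiles)[o], AUC = auc[o],
                    C_final = cfin[o], rank = seq_along(o))
  out$tied_with_next <- c(abs(diff(out$AUC)) < 1e-9 * pmax(out$AUC[-1L], 1e-12),
                          FALSE)
  out
}
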