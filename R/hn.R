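# Havriliak-Negami model: evaluation, loss-peak time, and spectrum fitting.
#
# eps*(w) = eps_inf + sum_k  d_eps_k / (1 + (i w tau_k)^alpha_k)^gamma_k
#           - i sigma_dc / (EPS0 w),      w = 2 pi f  [rad/s]
#
# alpha (0,1] controls symmetric broadening, gamma (0,1] the high-frequency
# asymmetry; alpha = gamma = 1 is the Debye response.

#' Construct a Havriliak-Negami parameter set
#'
#' Container for one or more HN processes sharing a high-frequency limit
#' `eps_inf` and an optional dc conductivity `sigma_dc`.
#'
#' @param delta_eps numeric vector of relaxation strengths (> 0), one per process.
#' @param tau_hn numeric vector of HN relaxation times in seconds (> 0).
#' @param alpha,gamma HN shape exponents, each in (0, 1].
#' @param eps_inf shared high-frequency permittivity limit (>= 1).
#' @param sigma_dc dc conductivity in S/m, or `NA` for none.
#' @param names optional process labels (e.g. `"alpha"`, `"beta"`).
#' @return An object of class `hn_fit`.
#' @export
hn_fit <- function(delta_eps, tau_hn, alpha, gamma, eps_inf = 1,
                   sigma_dc = NA_real_, names = NULL) {
  np <- length(delta_eps)
  stopifnot(length(tau_hn) == np, length(alpha) == np, length(gamma) == np)
  if (any(delta_eps <= 0)) stop_amt("delta_eps must be > 0")
  if (any(tau_hn <= 0)) stop_amt("tau_hn must be > 0")
  if (any(alpha <= 0 | alpha > 1)) stop_amt("alpha must be in (0, 1]")
  if (any(gamma <= 0 | gamma > 1)) stop_amt("gamma must be in (0, 1]")
  if (eps_inf < 1) stop_amt("eps_inf must be >= 1")
  if (!is.na(sigma_dc) && sigma_dc < 0) stop_amt("sigma_dc must be >= 0")
  if (is.null(names)) names <- paste0("p", seq_len(np))
  structure(list(
    processes = data.frame(
      name = names, delta_eps = delta_eps, tau_hn = tau_hn,
      alpha = alpha, gamma = gamma,
      se_delta_eps = NA_real_, se_tau_hn = NA_real_,
      se_alpha = NA_real_, se_gamma = NA_real_,
      unresolved = FALSE, stringsAsFactors = FALSE
    ),
    eps_inf = eps_inf, se_eps_inf = NA_real_,
    sigma_dc = sigma_dc, se_sigma_dc = NA_real_,
    residual_norm = NA_real_, converged = NA
  ), class = "hn_fit")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat("Havriliak-Negami fit:", nrow(x$processes), "process(es)\n")
  print(x$processes[, c("name", "delta_eps", "tau_hn", "alpha", "gamma",
                        "unresolved")], row.names = FALSE)
  cat(sprintf("eps_inf = %.4g", x$eps_inf))
  if (!is.na(x$sigma_dc)) cat(sprintf(", sigma_dc = %.4g S/m", x$sigma_dc))
  if (!is.na(x$residual_norm))
    cat(sprintf(", residual norm = %.4g", x$residual_norm))
  cat("\n")
  invisible(x)
}

#' Evaluate a Havriliak-Negami model at given frequencies
#'
#' @param fit an [hn_fit()] object.
#' @param freq frequencies in Hz.
#' @param method `"complex"` (default) evaluates the complex power directly;
#'   `"polar"` uses the textbook trigonometric real/imaginary expansion. The
#'   two routes are algebraically identical and serve as mutual cross-checks.
#' @return Complex permittivity `eps' - i eps''` at each frequency.
#' @export
hn_eval <- function(fit, freq, method = c("complex", "polar")) {
  method <- match.arg(method)
  w <- 2 * pi * freq
  p <- fit$processes
  eps <- rep(complex(real = fit$eps_inf, imaginary = 0), length(w))
  for (k in seq_len(nrow(p))) {
    if (method == "complex") {
      z <- (1i * w * p$tau_hn[k])^p$alpha[k]
      eps <- eps + p$delta_eps[k] / (1 + z)^p$gamma[k]
    } else {
      wt <- (w * p$tau_hn[k])^p$alpha[k]
      A <- 1 + wt * cos(pi * p$alpha[k] / 2)
      B <- wt * sin(pi * p$alpha[k] / 2)
      r <- (A^2 + B^2)^(-p$gamma[k] / 2)
      phi <- atan2(B, A)
      eps <- eps + p$delta_eps[k] * r *
        complex(real = cos(p$gamma[k] * phi),
                imaginary = -sin(p$gamma[k] * phi))
    }
  }
  if (!is.na(fit$sigma_dc)) eps <- eps - 1i * fit$sigma_dc / (EPS0 * w)
  eps
}

#' Loss-peak relaxation time of an HN process
#'
#' Closed-form position of the maximum of the dielectric loss for each process
#' in the fit:
#' `w_max = tau_hn^-1 * [sin(pi a / (2 + 2 g))]^(1/a) * [sin(pi a g / (2 + 2 g))]^(-1/a)`,
#' and `tau_max = 1 / w_max`. For Debye (`a = g = 1`) and Cole-Cole (`g = 1`)
#' shapes this reduces to `tau_max = tau_hn`.
#'
#' @param fit an [hn_fit()] object.
#' @param process process index or name (default: first).
#' @return Peak relaxation time in seconds.
#' @export
tau_max_from_hn <- function(fit, process = 1L) {
  p <- fit$processes
  if (is.character(process)) process <- match(process, p$name)
  if (is.na(process) || process < 1L || process > nrow(p))
    stop_amt("unknown process")
  a <- p$alpha[process]; g <- p$gamma[process]; tau <- p$tau_hn[process]
  w_max <- (1 / tau) * sin(pi * a / (2 + 2 * g))^(1 / a) /
    sin(pi * a * g / (2 + 2 * g))^(1 / a)
  1 / w_max
}

# model eps'' on log10 scale for the fitting objective
.hn_loss_model <- function(par, freq, n_proc, use_cond) {
  fit <- .par_to_hn(par, n_proc, use_cond, eps_inf = 1)
  pmax(-Im(hn_eval(fit, freq)), 1e-300)
}

.par_to_hn <- function(par, n_proc, use_cond, eps_inf) {
  idx <- 0L
  de <- tau <- al <- ga <- numeric(n_proc)
  for (k in seq_len(n_proc)) {
    de[k] <- 10^par[idx + 1L]
    tau[k] <- 10^par[idx + 2L]
    al[k] <- par[idx + 3L]
    ga[k] <- par[idx + 4L]
    idx <- idx + 4L
  }
  sig <- if (use_cond) 10^par[idx + 1L] else NA_real_
  # clamp: derivative-free steps and finite-difference probes may poke
  # marginally outside the box
  al <- pmin(pmax(al, 1e-3), 1)
  ga <- pmin(pmax(ga, 1e-3), 1)
  hn_fit(de, tau, al, ga, eps_inf = max(eps_inf, 1), sigma_dc = sig)
}

#' Fit Havriliak-Negami processes to a dielectric spectrum
#'
#' Least squares on `log10 eps''` over a frequency window (uniform weights on
#' the log scale, so the conductivity wing cannot dominate the peak), followed
#' by a closed-form estimate of the shared `eps_inf` from `eps'`. Parameter
#' standard errors come from the local curvature (Gauss-Newton covariance);
#' a process whose relaxation-strength error exceeds the strength itself is
#' flagged `unresolved`.
#'
#' Initialization: `tau` from the grid argmax of the loss, `delta_eps` from the
#' sum rule `(2/pi) * int eps'' dln(w)`, shape exponents 0.8; up to three
#' jittered restarts are attempted before reporting non-convergence.
#'
#' @param spectrum a [dielectric_spectrum()].
#' @param n_processes 1 or 2 HN processes.
#' @param use_conductivity include a dc-conductivity term.
#' @param window optional `c(fmin, fmax)` in Hz restricting the fit.
#' @param init optional named list overriding initial values
#'   (`delta_eps`, `tau_hn`, `alpha`, `gamma`, `sigma_dc` vectors).
#' @param restarts number of jittered restarts on poor convergence.
#' @return An [hn_fit()] with standard errors, residual norm and flags.
#' @export
fit_hn <- function(spectrum, n_processes = 1L, use_conductivity = FALSE,
                   window = NULL, init = NULL, restarts = 3L) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  n_processes <- as.integer(n_processes)
  if (!n_processes %in% c(1L, 2L)) stop_amt("n_processes must be 1 or 2")
  f <- spectrum$freq; ei <- spectrum$eps_imag; er <- spectrum$eps_real
  keep <- rep(TRUE, length(f))
  if (!is.null(window)) keep <- f >= window[1] & f <= window[2]
  keep <- keep & ei > 0
  f <- f[keep]; ei <- ei[keep]; er <- er[keep]
  if (length(f) < 8L * n_processes)
    stop_amt("need at least %d points in the fit window", 8L * n_processes)

  ytarget <- log10(ei)
  w <- 2 * pi * f
  # peak maximum must lie inside the window for each fitted process
  imax <- which.max(ei)
  if (imax %in% c(1L, length(f)) && !use_conductivity)
    stop_amt("loss maximum lies on the window edge; widen the window")

  # --- initialization -------------------------------------------------------
  sum_rule <- (2 / pi) * trapz(log(w), ei)
  tau0 <- 1 / w[imax]
  if (n_processes == 1L) {
    de0 <- max(sum_rule, 2 * ei[imax])
    p0 <- c(log10(de0), log10(tau0), 0.8, 0.8)
  } else {
    # second initial peak: most prominent secondary maximum of the smoothed loss
    ls <- savgol(ytarget, window = 7L)
    locmax <- which(diff(sign(diff(ls))) == -2) + 1L
    locmax <- locmax[order(ls[locmax], decreasing = TRUE)]
    i2 <- if (length(locmax) >= 2L) locmax[2L] else
      max(min(imax + round(length(f) / 4), length(f) - 1L), 2L)
    tau2 <- 1 / w[i2]
    p0 <- c(log10(0.7 * max(sum_rule, 1e-3)), log10(tau0), 0.8, 0.8,
            log10(0.3 * max(sum_rule, 1e-3)), log10(tau2), 0.8, 0.8)
  }
  if (use_conductivity) {
    sig0 <- ei[1L] * EPS0 * w[1L]
    p0 <- c(p0, log10(max(sig0, 1e-18)))
  }
  if (!is.null(init)) {
    ov <- function(slot, j, v) if (!is.null(v)) for (k in seq_along(v))
      p0[(k - 1L) * 4L + j] <<- slot(v[k])
    ov(log10, 1L, init$delta_eps); ov(log10, 2L, init$tau_hn)
    ov(identity, 3L, init$alpha); ov(identity, 4L, init$gamma)
    if (use_conductivity && !is.null(init$sigma_dc))
      p0[length(p0)] <- log10(init$sigma_dc)
  }

  lower <- rep(c(-8, log10(min(tau0, 1 / w[length(w)]) ) - 6, 0.02, 0.02),
               n_processes)
  upper <- rep(c(8, log10(tau0) + 8, 1, 1), n_processes)
  if (use_conductivity) { lower <- c(lower, -20); upper <- c(upper, 2) }

  obj <- function(par) {
    # soft barrier keeps the derivative-free polish inside the box
    viol <- sum(pmax(lower - par, 0)^2) + sum(pmax(par - upper, 0)^2)
    par <- pmin(pmax(par, lower), upper)
    m <- log10(.hn_loss_model(par, f, n_processes, use_conductivity))
    sum((m - ytarget)^2) + 1e3 * viol
  }

  run_once <- function(start) {
    o1 <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 800L, factr = 1e4))
    # Nelder-Mead polish off the bounds, then clamp
    o2 <- stats::optim(o1$par, obj,
                       control = list(maxit = 1500L, reltol = 1e-14))
    par <- pmin(pmax(o2$par, lower), upper)
    list(par = par, value = obj(par))
  }

  set_jitter <- function(start, mag) {
    j <- start + stats::rnorm(length(start), 0, mag)
    pmin(pmax(j, lower), upper)
  }
  best <- run_once(p0)
  scale2 <- stats::var(ytarget)
  tries <- 0L
  # restart only on evidence of a bad local minimum, not on noise-floor RSS
  while (best$value > 1e-3 * length(f) * scale2 && tries < restarts) {
    tries <- tries + 1L
    cand <- run_once(set_jitter(p0, 0.25 * tries))
    if (cand$value < best$value) best <- cand
  }
  par <- best$par

  # --- eps_inf from the real part (linear given the shape parameters) -------
  fit0 <- .par_to_hn(par, n_processes, use_conductivity, eps_inf = 1)
  model_re <- Re(hn_eval(fit0, f)) - 1  # eps_inf-free real part
  eps_inf <- mean(er - model_re)
  if (eps_inf < 1) eps_inf <- 1

  out <- .par_to_hn(par, n_processes, use_conductivity, eps_inf = eps_inf)
  out$residual_norm <- sqrt(best$value / length(f))
  out$converged <- TRUE

  # --- curvature-based standard errors --------------------------------------
  Jfun <- function(p) log10(.hn_loss_model(p, f, n_processes, use_conductivity))
  J <- fd_jacobian(Jfun, par)
  resid <- Jfun(par) - ytarget
  cv <- ls_covariance(resid, J)
  se <- sqrt(pmax(diag(cv), 0))
  ln10 <- log(10)
  for (k in seq_len(n_processes)) {
    i0 <- (k - 1L) * 4L
    out$processes$se_delta_eps[k] <- out$processes$delta_eps[k] * ln10 * se[i0 + 1L]
    out$processes$se_tau_hn[k] <- out$processes$tau_hn[k] * ln10 * se[i0 + 2L]
    out$processes$se_alpha[k] <- se[i0 + 3L]
    out$processes$se_gamma[k] <- se[i0 + 4L]
    out$processes$unresolved[k] <-
      is.na(se[i0 + 1L]) ||
      out$processes$se_delta_eps[k] > out$processes$delta_eps[k]
  }
  if (use_conductivity)
    out$se_sigma_dc <- out$sigma_dc * ln10 * se[length(se)]
  out$se_eps_inf <- stats::sd(er - model_re) / sqrt(length(er))
  if (!any(is.finite(se)) && best$value > 1e-3 * length(f) * scale2)
    stop_amt("fit_hn did not converge (best residual norm %.3g)",
             out$residual_norm)
  out
}
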