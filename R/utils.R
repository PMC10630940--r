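# Internal constants and small numeric helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# vacuum permittivity [F/m] and molar gas constant [J/(mol K)]
EPS0 <- 8.8541878128e-12
RGAS <- 8.314462618

# Gauss-Legendre nodes/weights on [-1, 1], Golub-Welsch on the Jacobi matrix.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1L)] <- b
  A[cbind(i + 1L, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
}

# cached rules used by the oscillatory quadratures
.gl16 <- gauss_legendre(16L)
.gl24 <- gauss_legendre(24L)

# log-spaced grid helper
log_grid <- function(from, to, n) 10^seq(log10(from), log10(to), length.out = n)

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

# Savitzky-Golay smoother: moving least-squares polynomial of given order.
savgol <- function(y, window = 11L, order = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= length(y)) return(y)
  h <- (window - 1L) %/% 2L
  X <- outer(-h:h, 0:order, `^`)
  cf <- solve(crossprod(X), t(X))[1L, ]
  n <- length(y)
  out <- stats::filter(y, rev(cf), sides = 2L)
  out <- as.numeric(out)
  # polynomial fits at the edges instead of NA padding
  for (i in seq_len(h)) {
    idx <- 1L:window
    out[i] <- stats::predict(stats::lm(y[idx] ~ poly(idx, order)),
                             data.frame(idx = i))
    idx2 <- (n - window + 1L):n
    out[n - i + 1L] <- stats::predict(stats::lm(y[idx2] ~ poly(idx2, order)),
                                      data.frame(idx2 = n - i + 1L))
  }
  out
}

# finite-difference Jacobian of fn (vector-valued) at par
fd_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

# covariance of least-squares parameters from residuals and Jacobian
ls_covariance <- function(resid, J) {
  n <- length(resid); p <- ncol(J)
  s2 <- sum(resid^2) / max(n - p, 1L)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * s2, error = function(e) {
    matrix(NA_real_, p, p)
  })
  cov
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_amt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_amt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
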