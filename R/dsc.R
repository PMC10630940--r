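# DSC thermograms: parsing, thermal-event extraction under the conventions
# used for the measured systems (Tg at the midpoint of the heat-capacity
# increment; Tc and Tm at the extremum of the exothermic/endothermic peaks),
# double-event detection across heating rates, and Kissinger analysis.

#' Construct a DSC thermogram
#'
#' @param T temperature [K], strictly increasing (single heating segment).
#' @param heat_flow heat-flow signal.
#' @param rate heating rate [K/min], > 0.
#' @param exo_up `TRUE` if exothermic events point up.
#' @param label sample label.
#' @return object of class `dsc_thermogram`.
#' @export
dsc_thermogram <- function(T, heat_flow, rate, exo_up = TRUE,
                           label = "sample") {
  if (length(T) < 100L) stop_amt("a thermogram needs at least 100 points")
  if (length(heat_flow) != length(T)) stop_amt("T and heat_flow lengths differ")
  if (any(diff(T) <= 0))
    stop_amt("T must be strictly increasing (single heating segment)")
  if (is.na(rate) || rate <= 0) stop_amt("heating rate must be > 0")
  structure(list(T = T, heat_flow = heat_flow, rate = rate,
                 exo_up = isTRUE(exo_up), label = label),
            class = "dsc_thermogram")
}

#' @export
print.dsc_thermogram <- function(x, ...) {
  cat(sprintf("DSC thermogram '%s': %d points, %.1f-%.1f K at %.3g K/min (%s)\n",
              x$label, length(x$T), min(x$T), max(x$T), x$rate,
              if (x$exo_up) "exo up" else "exo down"))
  invisible(x)
}

#' Read / write DSC thermograms ("dsc-v1" CSV dialect)
#'
#' Metadata header lines `# rate_K_min: <value>` and `# exo_up: <TRUE/FALSE>`
#' precede a CSV body with columns `temp_K`, `heat_flow`.
#'
#' @param path file path.
#' @return [dsc_thermogram()] for `read_dsc`; invisibly `path` for `write_dsc`.
#' @export
read_dsc <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  getm <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) stop_amt("missing metadata '%s' in %s", key, path)
    trimws(sub(".*:", "", m[1L]))
  }
  rate <- as.numeric(getm("rate_K_min"))
  exo_up <- toupper(getm("exo_up")) %in% c("TRUE", "T", "1", "UP")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cn in c("temp_K", "heat_flow"))
    if (!cn %in% names(df)) stop_amt("missing column %s in %s", cn, path)
  if (any(diff(df$temp_K) <= 0))
    stop_amt("non-monotone temperature in %s: not a single heating segment", path)
  dsc_thermogram(df$temp_K, df$heat_flow, rate = rate, exo_up = exo_up,
                 label = basename(path))
}

#' @rdname read_dsc
#' @param tg a [dsc_thermogram()].
#' @export
write_dsc <- function(tg, path) {
  stopifnot(inherits(tg, "dsc_thermogram"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_K_min: %.10g", tg$rate),
               sprintf("# exo_up: %s", tg$exo_up)), con)
  df <- data.frame(temp_K = signif(tg$T, 9), heat_flow = signif(tg$heat_flow, 9))
  utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# peak prominence: height above the higher of the two bounding minima reached
# before the signal next exceeds the peak value on either side
.peak_prominence <- function(y, p) {
  n <- length(y)
  lmin <- y[p]; i <- p
  while (i > 1L && y[i - 1L] <= y[p]) { i <- i - 1L; lmin <- min(lmin, y[i]) }
  rmin <- y[p]; i <- p
  while (i < n && y[i + 1L] <= y[p]) { i <- i + 1L; rmin <- min(rmin, y[i]) }
  y[p] - max(lmin, rmin)
}

# sliding-window linear fits via running sums: for every window of m
# consecutive points returns intercept a, slope b and residual sd, indexed by
# the window's first point. O(n).
.runlm <- function(x, y, m) {
  n <- length(x)
  S <- function(v) { cv <- cumsum(v); cv[m:n] - c(0, cv[seq_len(n - m)]) }
  sx <- S(x); sy <- S(y); sxx <- S(x * x); sxy <- S(x * y); syy <- S(y * y)
  det <- m * sxx - sx^2
  b <- (m * sxy - sx * sy) / det
  a <- (sy - b * sx) / m
  rss <- syy + m * a^2 + b^2 * sxx + 2 * a * b * sx - 2 * a * sy - 2 * b * sxy
  list(a = a, b = b, sd = sqrt(pmax(rss, 0) / max(m - 2L, 1L)))
}

#' Extract thermal events from a thermogram
#'
#' Pipeline, in order:
#' 1. moving-polynomial smoothing and a noise estimate from the high-pass
#'    residual;
#' 2. glass-transition steps located by a two-sided running-line detector:
#'    at each temperature a straight line is fitted over an `outer`-wide
#'    window on either side (offset by `inner` to skip the transition
#'    region); a step is declared where the extrapolated gap between the two
#'    lines peaks, both flanks are locally linear (residual small relative to
#'    the gap) and their slopes agree -- which rejects peak flanks. Tg is
#'    reported at the temperature where the signal crosses the midpoint
#'    between the two extrapolated baselines (the midpoint of the
#'    heat-capacity increment), with the step height as `dcp`;
#' 3. the detected steps are subtracted, a straight baseline anchored on the
#'    event-free scan ends is removed, and exo/endo peaks are found on the
#'    residual by local-maximum search with a prominence threshold of
#'    `prominence_mads` times the noise MAD. Crystallization (`Tc`) and
#'    melting (`Tm`) temperatures are the peak extrema; areas are trapezoidal
#'    integrals over the 5%-height region.
#'
#' @param tg a [dsc_thermogram()].
#' @param smooth_window smoothing window [K].
#' @param prominence_mads peak prominence threshold in noise-MAD units.
#' @param min_prominence absolute prominence floor (signal units).
#' @param inner,outer step-detector window geometry [K].
#' @param min_step absolute step-height floor (signal units).
#' @return object of class `thermal_events`: data.frames `tg` (columns
#'   `midpoint_K`, `onset_K`, `end_K`, `dcp`), `tc` (`peak_K`, `area`),
#'   `tm` (`peak_K`, `area`); plus `rate`.
#' @export
extract_events <- function(tg, smooth_window = 1.1, prominence_mads = 6,
                           min_prominence = 0.02, inner = 3.5, outer = 7,
                           min_step = 0.01) {
  T <- tg$T
  hf <- if (tg$exo_up) tg$heat_flow else -tg$heat_flow
  n <- length(T)
  dT <- stats::median(diff(T))
  sw <- max(2L * floor(smooth_window / dT / 2) + 1L, 5L)
  s <- savgol(hf, window = sw)
  noise <- stats::mad(hf - s)

  # ---- step (glass transition) detection ----------------------------------
  k_in <- max(round(inner / dT), 1L)
  m <- max(round(outer / dT), 6L)
  rl <- .runlm(T, s, m)
  # for center i: left window starts at i - k_in - m + 1, right at i + k_in
  lo <- k_in + m
  hi <- n - k_in - m + 1L
  tg_rows <- data.frame(midpoint_K = numeric(0), onset_K = numeric(0),
                        end_K = numeric(0), dcp = numeric(0))
  if (hi > lo) {
    ic <- lo:hi
    iL <- ic - k_in - m + 1L
    iR <- ic + k_in
    med_b <- stats::median(rl$b, na.rm = TRUE)   # scan-wide baseline slope
    Tbar <- (T[1L:(n - m + 1L)] + T[m:n]) / 2     # window centre temperatures
    wmean <- rl$a + rl$b * Tbar                   # window mean levels
    # pooled-slope level difference: low-variance step statistic
    gap <- (wmean[iR] - wmean[iL]) - med_b * (Tbar[iR] - Tbar[iL])
    flank_tol <- 3 * noise + 0.02 * abs(gap)
    # both flanks must be locally linear, agree in slope, and have a slope
    # close to the scan-wide baseline slope (a peak flank is a steep ramp)
    ok <- rl$sd[iL] < flank_tol & rl$sd[iR] < flank_tol &
      abs(rl$b[iL] - rl$b[iR]) * (outer + 2 * inner) <
        0.15 * abs(gap) + 6 * noise &
      pmax(abs(rl$b[iL] - med_b), abs(rl$b[iR] - med_b)) * outer <
        0.15 * abs(gap) + 6 * noise
    g <- ifelse(ok, gap, 0)
    # null scale of the pooled-slope statistic: var = 2 sigma^2 / m
    gthr <- max(5.5 * noise * sqrt(2 / m), min_step)
    cand <- which(g > gthr)
    if (length(cand)) {
      # greedy: strongest candidate first, suppressing neighbours closer than
      # one window span (steps that close are unresolvable anyway)
      picks <- integer(0)
      avail <- cand
      while (length(avail)) {
        p0 <- avail[which.max(g[avail])]
        picks <- c(picks, p0)
        avail <- avail[abs(avail - p0) > k_in + m]
      }
      for (p in sort(picks)) {
        i <- ic[p]
        lv <- wmean[iL[p]] + med_b * (T - Tbar[iL[p]])
        rv <- wmean[iR[p]] + med_b * (T - Tbar[iR[p]])
        # persistence: one further window out on each side, the signal must
        # still lie on the extrapolated flanking line. A heat-capacity step
        # has flat shifted baselines; a peak flank keeps moving away.
        # a second Delta-cp step in the look-ahead window is tolerated
        # (deviation comparable to the gap); a peak flank runs away from the
        # baseline by much more than the candidate step height
        ptol <- 4 * noise + 0.1 * abs(gap[p])
        runaway <- max(1.5 * abs(gap[p]), 6 * noise)
        iR2 <- i + k_in + m
        if (iR2 <= n - m + 1L) {
          dev <- abs(wmean[iR2] - rv[1L] - med_b * (Tbar[iR2] - T[1L]))
          if (dev > ptol && dev > runaway) next
        }
        iL2 <- i - k_in - 2L * m + 1L
        if (iL2 >= 1L) {
          dev <- abs(wmean[iL2] - lv[1L] - med_b * (Tbar[iL2] - T[1L]))
          if (dev > ptol && dev > runaway) next
        }
        # containment: within the inner zone the signal must stay between the
        # two extrapolated baselines (a sigmoid does; a peak does not)
        iz <- max(i - k_in, 1L):min(i + k_in, n)
        ctol <- 3 * noise + 0.15 * abs(gap[p])
        if (any(s[iz] > pmax(lv[iz], rv[iz]) + ctol) ||
            any(s[iz] < pmin(lv[iz], rv[iz]) - ctol)) next
        half <- (lv + rv) / 2
        win <- max(i - k_in, 1L):min(i + k_in, n)
        d <- s[win] - half[win]
        cr <- win[which(d[-1L] >= 0 & d[-length(d)] < 0)[1L]]
        if (is.na(cr)) next
        tmid <- T[cr] - d[cr - win[1L] + 1L] /
          (d[cr - win[1L] + 2L] - d[cr - win[1L] + 1L]) * dT
        dcp <- gap[p]
        on_i <- which(T < tmid & s < lv + 0.1 * dcp)
        end_i <- which(T > tmid & s > rv - 0.1 * dcp)
        tg_rows <- rbind(tg_rows, data.frame(
          midpoint_K = tmid,
          onset_K = if (length(on_i)) T[max(on_i)] else NA_real_,
          end_K = if (length(end_i)) T[min(end_i)] else NA_real_,
          dcp = dcp))
      }
    }
  }

  # steps closer than one detector span are echoes of one transition: keep
  # the strongest
  if (nrow(tg_rows) > 1L) {
    keep <- rep(FALSE, nrow(tg_rows))
    o <- order(-tg_rows$dcp)
    for (j in o)
      if (!any(keep & abs(tg_rows$midpoint_K - tg_rows$midpoint_K[j]) <
                 inner + outer)) keep[j] <- TRUE
    tg_rows <- tg_rows[keep, , drop = FALSE]
    tg_rows <- tg_rows[order(tg_rows$midpoint_K), , drop = FALSE]
  }

  # ---- peak detection on the step-corrected, end-anchored residual --------
  s_corr <- s
  for (j in seq_len(nrow(tg_rows)))
    s_corr <- s_corr - tg_rows$dcp[j] *
      stats::plogis(T, tg_rows$midpoint_K[j], inner / 3)
  edge <- seq_len(max(round(0.08 * n), m))
  anchor <- c(edge, n + 1L - edge)
  fm <- stats::lm(s_corr[anchor] ~ T[anchor])
  r <- s_corr - (stats::coef(fm)[1L] + stats::coef(fm)[2L] * T)
  thr <- max(prominence_mads * noise, min_prominence)
  # suppress only small maxima near a detected step (subtraction glitches);
  # a genuine peak larger than the step height survives
  near_step <- function(idx, y) vapply(idx, function(p)
    any(abs(T[p] - tg_rows$midpoint_K) < 2 * inner &
          y[p] < tg_rows$dcp), TRUE)
  find_peaks <- function(y) {
    cand <- which(diff(sign(diff(y))) == -2) + 1L
    cand <- cand[y[cand] > thr]
    keep <- cand[vapply(cand, function(p) .peak_prominence(y, p) > thr, TRUE)]
    if (nrow(tg_rows) && length(keep)) keep <- keep[!near_step(keep, y)]
    keep[order(T[keep])]
  }
  region <- function(p, y) {
    h <- y[p]
    i <- p; while (i > 1L && y[i] > 0.05 * h) i <- i - 1L
    j <- p; while (j < n && y[j] > 0.05 * h) j <- j + 1L
    c(i, j)
  }
  peak_rows <- function(pks, y) {
    out <- data.frame(peak_K = numeric(0), area = numeric(0))
    for (p in pks) {
      rg <- region(p, y)
      out <- rbind(out, data.frame(
        peak_K = T[p],
        area = trapz(T[rg[1L]:rg[2L]], abs(y[rg[1L]:rg[2L]]))))
    }
    out
  }
  endo_pk <- find_peaks(-r)
  tm_df <- peak_rows(endo_pk, -r)
  # bridge endotherm regions before exotherm search, so dips carved into a
  # broad exotherm tail do not masquerade as extra crystallization peaks
  r2 <- r
  pad <- max(round(inner / dT), 1L)
  for (p in endo_pk) {
    rg <- region(p, -r)
    rg <- c(max(rg[1L] - pad, 1L), min(rg[2L] + pad, n))
    r2[rg[1L]:rg[2L]] <- r[rg[1L]] + (r[rg[2L]] - r[rg[1L]]) *
      (T[rg[1L]:rg[2L]] - T[rg[1L]]) / max(T[rg[2L]] - T[rg[1L]], 1e-12)
  }
  tc_df <- peak_rows(find_peaks(r2), r2)
  # a "step" whose midpoint falls inside a peak region is a flank artifact
  if (nrow(tg_rows)) {
    all_pk <- rbind(tc_df, tm_df)
    in_peak <- vapply(tg_rows$midpoint_K, function(Tm0)
      any(vapply(seq_len(nrow(all_pk)), function(j) {
        y <- if (j <= nrow(tc_df)) r2 else -r
        p <- which.min(abs(T - all_pk$peak_K[j]))
        rg <- region(p, y)
        Tm0 >= T[rg[1L]] - inner && Tm0 <= T[rg[2L]] + inner
      }, TRUE)), TRUE)
    tg_rows <- tg_rows[!in_peak, , drop = FALSE]
  }
  structure(list(tg = tg_rows, tc = tc_df, tm = tm_df, rate = tg$rate,
                 noise = noise, label = tg$label), class = "thermal_events")
}

#' @export
print.thermal_events <- function(x, ...) {
  cat(sprintf("Thermal events (%.3g K/min): %d Tg, %d Tc, %d Tm\n",
              x$rate, nrow(x$tg), nrow(x$tc), nrow(x$tm)))
  if (nrow(x$tg)) cat("  Tg midpoint [K]:", sprintf("%.2f", x$tg$midpoint_K), "\n")
  if (nrow(x$tc)) cat("  Tc peak [K]:", sprintf("%.2f", x$tc$peak_K), "\n")
  if (nrow(x$tm)) cat("  Tm peak [K]:", sprintf("%.2f", x$tm$peak_K), "\n")
  invisible(x)
}

#' Detect double events across heating rates
#'
#' Reports, per heating rate, how many crystallization peaks (and glass
#' transitions) were resolved, and the rate threshold at which two
#' crystallization peaks merge into one: the interval between the fastest
#' rate still showing two peaks and the slowest rate showing one.
#'
#' @param events_list list of `thermal_events` from >= 3 rates.
#' @return object of class `double_event_report`: data.frame `per_rate`
#'   (`rate`, `n_tc`, `n_tg`), `merge_threshold` (`c(low, high)` in K/min or
#'   `NULL`), `always_double` flag.
#' @export
detect_double_events <- function(events_list) {
  if (length(events_list) < 3L) stop_amt("need events from at least 3 rates")
  rates <- vapply(events_list, function(e) e$rate, 0)
  o <- order(rates)
  per <- data.frame(rate = rates[o],
                    n_tc = vapply(events_list[o], function(e) nrow(e$tc), 0L),
                    n_tg = vapply(events_list[o], function(e) nrow(e$tg), 0L))
  dbl <- per$rate[per$n_tc >= 2L]
  sgl <- per$rate[per$n_tc == 1L]
  merge_threshold <- NULL
  always_double <- FALSE
  if (length(dbl) && length(sgl) && max(dbl) < min(sgl)) {
    merge_threshold <- c(max(dbl), min(sgl))
  } else if (length(dbl) && !length(sgl)) {
    always_double <- TRUE
    merge_threshold <- c(max(dbl), Inf)
  }
  structure(list(per_rate = per, merge_threshold = merge_threshold,
                 always_double = always_double),
            class = "double_event_report")
}

#' @export
print.double_event_report <- function(x, ...) {
  print(x$per_rate, row.names = FALSE)
  if (is.null(x$merge_threshold)) cat("No double-to-single merging observed\n")
  else if (x$always_double)
    cat(sprintf("Double peaks at every rate up to %.3g K/min\n",
                x$merge_threshold[1L]))
  else cat(sprintf("Peaks merge between %.3g and %.3g K/min\n",
                   x$merge_threshold[1L], x$merge_threshold[2L]))
  invisible(x)
}

#' Kissinger analysis of crystallization peak temperatures
#'
#' Ordinary least squares of `ln(phi / Tc^2)` on `1/Tc` with the heating rate
#' converted to K/s internally (the unit convention affects only the
#' intercept `C_K`; the activation energy is invariant, which the test suite
#' asserts). `E_cr = -slope * R`, reported in kJ/mol.
#'
#' @param points data.frame with columns `phi` (K/min) and `Tc` (K), >= 3
#'   distinct rates.
#' @param phi_unit `"K/min"` (default) or `"K/s"` declaring the unit of the
#'   `phi` column.
#' @return object of class `kissinger_result`: `E_cr`, `se_E_cr` [kJ/mol],
#'   `C_K`, `se_C_K`, `r_squared`, `points`.
#' @export
kissinger_fit <- function(points, phi_unit = c("K/min", "K/s")) {
  phi_unit <- match.arg(phi_unit)
  stopifnot(all(c("phi", "Tc") %in% names(points)))
  if (nrow(points) < 3L) stop_amt("need at least 3 (phi, Tc) points")
  if (anyDuplicated(points$phi)) stop_amt("repeated heating rates")
  phi_s <- if (phi_unit == "K/min") points$phi / 60 else points$phi
  y <- log(phi_s / points$Tc^2)
  x <- 1 / points$Tc
  fm <- stats::lm(y ~ x)
  co <- summary(fm)$coefficients
  structure(list(E_cr = -co[2L, 1L] * RGAS / 1000,
                 se_E_cr = co[2L, 2L] * RGAS / 1000,
                 C_K = co[1L, 1L], se_C_K = co[1L, 2L],
                 r_squared = summary(fm)$r.squared,
                 points = points), class = "kissinger_result")
}

#' @export
print.kissinger_result <- function(x, ...) {
  cat(sprintf("Kissinger: E_cr = %.2f +/- %.2f kJ/mol (C_K = %.3f, r2 = %.4f, n = %d)\n",
              x$E_cr, x$se_E_cr, x$C_K, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Kissinger analysis per peak group
#'
#' One regression per labelled peak group (e.g. `"first"`, `"second"`,
#' `"merged"` branches when a double crystallization merges at fast rates).
#' Groups with fewer than 3 points are skipped with a warning.
#'
#' @param points data.frame with columns `phi`, `Tc`, `group`.
#' @return named list of `kissinger_result` objects.
#' @export
kissinger_multi <- function(points) {
  stopifnot(all(c("phi", "Tc", "group") %in% names(points)))
  out <- list()
  for (g in unique(points$group)) {
    sub <- points[points$group == g, c("phi", "Tc")]
    if (nrow(sub) < 3L) {
      warn_amt("group '%s' has %d < 3 points: skipped", g, nrow(sub))
      next
    }
    out[[as.character(g)]] <- kissinger_fit(sub)
  }
  out
}
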