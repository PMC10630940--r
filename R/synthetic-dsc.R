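# Synthetic nonisothermal DSC thermograms with Kissinger-consistent
# crystallization exotherms.

#' Specify the thermal-event kinetics for the DSC generator
#'
#' Crystallization peak temperatures are placed where the Kissinger relation
#' `ln(phi / Tc^2) = C_K - Ea_cr / (R Tc)` (phi in K/s) holds for the given
#' heating rate, so refitting the generated peak positions recovers `Ea_cr`
#' by construction. Peak widths follow `sigma(phi) = width_coef * phi^width_exp`
#' (heat-rate broadening), which makes two nearby exotherms merge above a
#' rate threshold.
#'
#' @param Ea_cr crystallization activation energy [kJ/mol]; length `n_steps`.
#' @param C_K Kissinger intercepts (phi in K/s); if `NULL`, chosen so that
#'   `Tc(10 K/min) = Tc_at_10` for each step.
#' @param Tc_at_10 anchor peak temperature(s) [K] at 10 K/min.
#' @param n_steps 1 or 2 crystallization events.
#' @param Tg_list glass-transition midpoint(s) [K] (1 or 2 values).
#' @param dcp_list heat-capacity step height(s), signal units per (K/min)/10.
#' @param Tm_list melting peak temperature(s) [K].
#' @param dH_list melting peak areas (signal K units, > 0).
#' @param dH_cr crystallization areas at 10 K/min (> 0); scale linearly
#'   with phi.
#' @param gibbs_thomson_c optional Gibbs-Thomson constant [K nm]: melting
#'   peaks are depressed by `c / d` when a pore diameter `d` [nm] is given to
#'   [gen_dsc()]. Default 0 (no depression).
#' @param width_coef,width_exp exotherm width law parameters.
#' @return object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(Ea_cr, C_K = NULL, Tc_at_10 = 363.4,
                          n_steps = length(Ea_cr),
                          Tg_list = 306.7, dcp_list = rep(0.35, length(Tg_list)),
                          Tm_list = c(406.6, 413.1),
                          dH_list = rep(18, length(Tm_list)),
                          dH_cr = rep(30, n_steps),
                          gibbs_thomson_c = 0,
                          width_coef = 0.16, width_exp = 1.45) {
  stopifnot(all(Ea_cr > 0), n_steps %in% c(1L, 2L),
            length(Ea_cr) == n_steps, length(Tc_at_10) %in% c(1L, n_steps),
            length(Tg_list) %in% 1:2, gibbs_thomson_c >= 0)
  if (length(Tc_at_10) == 1L) Tc_at_10 <- rep(Tc_at_10, n_steps)
  if (is.null(C_K))
    C_K <- log((10 / 60) / Tc_at_10^2) + Ea_cr * 1000 / (RGAS * Tc_at_10)
  if (any(Tg_list >= min(Tc_at_10)) || any(Tc_at_10 >= min(Tm_list)))
    stop_amt("events must be ordered Tg < Tc < Tm")
  structure(list(Ea_cr = Ea_cr, C_K = C_K, n_steps = as.integer(n_steps),
                 Tg_list = Tg_list, dcp_list = dcp_list, Tm_list = Tm_list,
                 dH_list = dH_list, dH_cr = dH_cr,
                 gibbs_thomson_c = gibbs_thomson_c,
                 width_coef = width_coef, width_exp = width_exp),
            class = "kinetics_spec")
}

#' Solve the Kissinger relation for the peak temperature
#'
#' Finds the `Tc` at which `ln(phi/Tc^2) = C_K - Ea/(R Tc)` for heating rate
#' `phi` (K/min; converted to K/s internally, matching the `C_K` convention
#' used throughout the package). The left side minus the right side is
#' strictly decreasing in `Tc`, so the root is unique; it is located by
#' bisection after bracketing.
#'
#' @param phi heating rate [K/min].
#' @param Ea activation energy [kJ/mol].
#' @param C_K Kissinger intercept (phi in K/s).
#' @param bracket search interval [K].
#' @return peak temperature [K].
#' @export
kissinger_tc <- function(phi, Ea, C_K, bracket = c(150, 700)) {
  phi_s <- phi / 60
  g <- function(Tc) C_K - Ea * 1000 / (RGAS * Tc) - log(phi_s / Tc^2)
  if (g(bracket[1]) * g(bracket[2]) > 0)
    stop_amt("Kissinger root not bracketed for rate %.3g K/min", phi)
  stats::uniroot(g, bracket, tol = 1e-10)$root
}

.asym_gauss <- function(T, center, sL, sR, area) {
  h <- area / (sqrt(pi / 2) * (sL + sR))
  s <- ifelse(T < center, sL, sR)
  h * exp(-(T - center)^2 / (2 * s^2))
}

#' Generate a DSC thermogram
#'
#' Heat flow (exo-up) = linear baseline + sigmoidal heat-capacity step(s) at
#' `Tg` + asymmetric-Gaussian exotherm(s) centered at the Kissinger-consistent
#' `Tc(phi)` with area proportional to `phi` + endothermic melting peaks at
#' `Tm` (Gibbs-Thomson depressed by `c/d` if a pore diameter is supplied) +
#' additive Gaussian noise.
#'
#' @param kinetics a [kinetics_spec()].
#' @param rate heating rate [K/min], > 0.
#' @param T_grid temperature grid [K] spanning all events.
#' @param noise_abs additive noise standard deviation (signal units).
#' @param seed integer seed.
#' @param pore_diameter_nm optional pore diameter for Gibbs-Thomson melting
#'   depression.
#' @param label sample label.
#' @return a [dsc_thermogram()] with attribute `"ground_truth"` (list with the
#'   planted `Tg`, `Tc(phi)` and effective `Tm` values).
#' @export
gen_dsc <- function(kinetics, rate, T_grid = seq(260, 440, by = 0.1),
                    noise_abs = 0, seed = 1L, pore_diameter_nm = NULL,
                    label = "synthetic") {
  stopifnot(inherits(kinetics, "kinetics_spec"))
  if (rate <= 0) stop_amt("rate must be > 0")
  Tc <- vapply(seq_len(kinetics$n_steps), function(k)
    kissinger_tc(rate, kinetics$Ea_cr[k], kinetics$C_K[k],
                 bracket = range(T_grid)), 0)
  Tm_eff <- kinetics$Tm_list
  if (!is.null(pore_diameter_nm) && kinetics$gibbs_thomson_c > 0)
    Tm_eff <- Tm_eff - kinetics$gibbs_thomson_c / pore_diameter_nm
  if (any(Tc < min(T_grid)) || any(Tc > max(T_grid)))
    stop_amt("Kissinger root outside T_grid for rate %.3g K/min", rate)

  hf <- 0.02 + 1e-4 * (T_grid - min(T_grid))          # instrument baseline
  for (i in seq_along(kinetics$Tg_list))               # cp steps, midpoint = Tg
    hf <- hf + kinetics$dcp_list[i] * (rate / 10) *
      stats::plogis(T_grid, kinetics$Tg_list[i], 0.8)
  sphi <- kinetics$width_coef * rate^kinetics$width_exp
  for (k in seq_len(kinetics$n_steps))                 # exotherms (positive)
    hf <- hf + .asym_gauss(T_grid, Tc[k], sphi, 1.6 * sphi,
                           kinetics$dH_cr[k] * rate / 10)
  for (i in seq_along(Tm_eff))                         # endotherms (negative)
    hf <- hf - .asym_gauss(T_grid, Tm_eff[i], 2.2, 1.1, kinetics$dH_list[i])
  if (noise_abs > 0) {
    set.seed(as.integer(seed))
    hf <- hf + stats::rnorm(length(hf), 0, noise_abs)
  }
  tg <- dsc_thermogram(T_grid, hf, rate = rate, exo_up = TRUE, label = label)
  attr(tg, "ground_truth") <- list(Tg = kinetics$Tg_list, Tc = Tc,
                                   Tm = Tm_eff, Ea_cr = kinetics$Ea_cr,
                                   C_K = kinetics$C_K)
  tg
}
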