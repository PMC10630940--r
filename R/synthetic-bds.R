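# Synthetic broadband dielectric spectra with known ground truth.
#
# Each relaxation process is an HN shape whose relaxation time follows a
# temperature law: VFT (super-Arrhenius, structural relaxations), Arrhenius
# (secondary relaxations), or a continuous VFT-above / Arrhenius-below
# crossover emulating the quasi-isochoric flattening seen for pore-confined
# samples. A conductivity spec adds sigma_dc/(EPS0 w) to the loss; its
# temperature dependence is slaved to a relaxation-time law so the dc wing
# shifts with the structural process as in real spectra.

#' Temperature laws for relaxation times
#'
#' * `law_vft(tau_vft, D_T, T0)`: `tau(T) = tau_vft * exp(D_T T0 / (T - T0))`.
#' * `law_arrhenius(tau_inf, Ea)`: `tau(T) = tau_inf * exp(Ea / (R T))`,
#'   `Ea` in kJ/mol.
#' * `law_crossover(vft, T_cross, Ea_low)`: VFT above `T_cross`, Arrhenius with
#'   activation energy `Ea_low` (kJ/mol) below, continuous at the kink.
#'
#' @param tau_vft,D_T,T0 VFT prefactor [s], strength parameter, Vogel
#'   temperature [K].
#' @param tau_inf,Ea Arrhenius prefactor [s] and activation energy [kJ/mol].
#' @param vft a `law_vft()` object; `T_cross` kink temperature [K];
#'   `Ea_low` low-temperature activation energy [kJ/mol].
#' @return a timescale-law object with class `timescale_law`.
#' @export
law_vft <- function(tau_vft, D_T, T0) {
  stopifnot(tau_vft > 0, D_T > 0, T0 > 0)
  structure(list(kind = "vft", tau_vft = tau_vft, D_T = D_T, T0 = T0),
            class = "timescale_law")
}

#' @rdname law_vft
#' @export
law_arrhenius <- function(tau_inf, Ea) {
  stopifnot(tau_inf > 0, Ea > 0)
  structure(list(kind = "arrhenius", tau_inf = tau_inf, Ea = Ea),
            class = "timescale_law")
}

#' @rdname law_vft
#' @export
law_crossover <- function(vft, T_cross, Ea_low) {
  stopifnot(inherits(vft, "timescale_law"), vft$kind == "vft",
            T_cross > vft$T0, Ea_low > 0)
  structure(list(kind = "crossover", vft = vft, T_cross = T_cross,
                 Ea_low = Ea_low),
            class = "timescale_law")
}

#' Evaluate a timescale law
#'
#' @param law a `timescale_law`.
#' @param T temperature(s) in K.
#' @param process label used in error messages.
#' @return relaxation time(s) in seconds.
#' @export
tau_at <- function(law, T, process = "process") {
  switch(law$kind,
    vft = {
      if (any(T <= law$T0))
        stop_amt("temperature %.6g K is at/below the Vogel temperature %.6g K of %s",
                 min(T), law$T0, process)
      law$tau_vft * exp(law$D_T * law$T0 / (T - law$T0))
    },
    arrhenius = law$tau_inf * exp(law$Ea * 1000 / (RGAS * T)),
    crossover = {
      tx <- tau_at(law$vft, law$T_cross, process)
      hi <- T > law$T_cross
      out <- numeric(length(T))
      out[hi] <- tau_at(law$vft, T[hi], process)
      out[!hi] <- tx * exp(law$Ea_low * 1000 / RGAS *
                             (1 / T[!hi] - 1 / law$T_cross))
      out
    })
}

#' Specify a relaxation process for the spectrum generator
#'
#' @param name label: `"alpha"`, `"alpha_core"`, `"alpha_interfacial"`,
#'   `"beta"`, `"gamma"`, `"mws"`, ...
#' @param delta_eps relaxation strength at `Tref` (>= 0).
#' @param alpha,gamma HN shape exponents, each in (0, 1], `alpha * gamma <= 1`.
#' @param law a `timescale_law` for `tau_HN(T)`.
#' @param delta_eps_slope optional linear temperature coefficient of
#'   `delta_eps` (per K, relative to `Tref`).
#' @param Tref reference temperature [K] for the amplitude law.
#' @return object of class `process_spec`.
#' @export
process_spec <- function(name, delta_eps, alpha, gamma, law,
                         delta_eps_slope = 0, Tref = 313) {
  stopifnot(delta_eps >= 0, alpha > 0, alpha <= 1, gamma > 0, gamma <= 1,
            alpha * gamma <= 1, inherits(law, "timescale_law"))
  structure(list(name = name, delta_eps = delta_eps, alpha = alpha,
                 gamma = gamma, law = law,
                 delta_eps_slope = delta_eps_slope, Tref = Tref),
            class = "process_spec")
}

#' Specify a dc-conductivity contribution
#'
#' `sigma(T) = sigma_ref * tau_law(Tref) / tau_law(T)`: conductivity scales
#' inversely with the slaved relaxation time, so the dc wing tracks the
#' structural process through the glass transition.
#'
#' @param sigma_ref conductivity [S/m] at `Tref`.
#' @param Tref reference temperature [K].
#' @param law `timescale_law` the conductivity is slaved to.
#' @return object of class `conductivity_spec`.
#' @export
conductivity_spec <- function(sigma_ref, Tref, law) {
  stopifnot(sigma_ref >= 0, inherits(law, "timescale_law"))
  structure(list(sigma_ref = sigma_ref, Tref = Tref, law = law),
            class = "conductivity_spec")
}

.proc_delta_eps <- function(p, T) {
  max(p$delta_eps + p$delta_eps_slope * (T - p$Tref), 0)
}

#' Generate one dielectric spectrum from process specifications
#'
#' Sums the HN responses of all processes (each evaluated at `tau(T)` from its
#' timescale law), adds `sigma_dc/(EPS0 w)` to the loss when a conductivity
#' spec is present, and applies multiplicative lognormal noise of relative
#' scale `noise_rel` to `eps''`. Reproducible per `seed`.
#'
#' @param process_specs list of [process_spec()] (a [conductivity_spec()] may
#'   be included in the list).
#' @param T temperature in K.
#' @param freq_grid frequencies in Hz, strictly increasing, positive.
#' @param noise_rel relative noise scale (>= 0) on the loss.
#' @param seed integer seed.
#' @param eps_inf high-frequency permittivity limit.
#' @return a [dielectric_spectrum()]; the noise-free ground truth [hn_fit()]
#'   is attached as attribute `"ground_truth"`.
#' @export
gen_spectrum <- function(process_specs, T, freq_grid, noise_rel = 0,
                         seed = 1L, eps_inf = 3) {
  if (any(freq_grid <= 0) || any(diff(freq_grid) <= 0))
    stop_amt("freq_grid must be strictly increasing and positive")
  if (noise_rel < 0) stop_amt("noise_rel must be >= 0")
  if (inherits(process_specs, "process_spec")) process_specs <- list(process_specs)
  procs <- Filter(function(p) inherits(p, "process_spec"), process_specs)
  conds <- Filter(function(p) inherits(p, "conductivity_spec"), process_specs)
  if (!length(procs)) stop_amt("no relaxation process specified")
  de <- vapply(procs, .proc_delta_eps, 0, T = T)
  tau <- vapply(procs, function(p) tau_at(p$law, T, p$name), 0)
  sig <- if (length(conds)) {
    cs <- conds[[1L]]
    cs$sigma_ref * tau_at(cs$law, cs$Tref) / tau_at(cs$law, T)
  } else NA_real_
  truth <- hn_fit(pmax(de, 1e-12), tau,
                  vapply(procs, `[[`, 0, "alpha"),
                  vapply(procs, `[[`, 0, "gamma"),
                  eps_inf = eps_inf, sigma_dc = sig,
                  names = vapply(procs, `[[`, "", "name"))
  eps <- hn_eval(truth, freq_grid)
  ei <- -Im(eps)
  if (noise_rel > 0) {
    set.seed(as.integer(seed))
    ei <- ei * exp(stats::rnorm(length(ei), 0, noise_rel))
  }
  out <- dielectric_spectrum(freq_grid, Re(eps), ei, T = T,
                             meta = list(synthetic = TRUE, seed = seed))
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a temperature series of spectra for a scenario preset
#'
#' For confined presets the pure-API spectrum is composed with the inert
#' matrix through the parallel-capacitor rule ([compose_composite()]); the
#' pure-API series is attached as attribute `"api_series"` so recovery tests
#' can compare against the planted truth.
#'
#' @param preset a [scenario_preset()] or preset name.
#' @param T_range `c(Tmin, Tmax)` in K.
#' @param step temperature step in K.
#' @param protocol `"slow_heat"` (ascending) or `"slow_cool"` (descending).
#' @param noise_rel relative loss noise.
#' @param seed integer seed (each temperature uses a derived sub-seed).
#' @param freq_grid frequency grid in Hz (default: 8 points per decade over
#'   1e-2 to 1e6 Hz, the usual measurement window).
#' @return a [spectra_series()] with attribute `"ground_truth"` (the preset).
#' @export
gen_spectra_series <- function(preset, T_range, step = 2,
                               protocol = c("slow_heat", "slow_cool"),
                               noise_rel = 0, seed = 1L,
                               freq_grid = log_grid(1e-2, 1e6, 65L)) {
  protocol <- match.arg(protocol)
  if (is.character(preset)) preset <- scenario_preset(preset)
  if (length(T_range) != 2L || T_range[2] < T_range[1])
    stop_amt("empty temperature range")
  Ts <- seq(T_range[1], T_range[2], by = step)
  if (protocol == "slow_cool") Ts <- rev(Ts)
  spectra <- lapply(seq_along(Ts), function(i) {
    s <- gen_spectrum(preset$processes, Ts[i], freq_grid,
                      noise_rel = noise_rel,
                      seed = as.integer(seed) * 1000L + i,
                      eps_inf = preset$eps_inf)
    s$meta$preset <- preset$name
    s
  })
  if (!is.null(preset$geometry)) {
    api <- spectra_series(spectra, protocol = protocol)
    spectra <- lapply(spectra, compose_composite, geom = preset$geometry)
    ser <- spectra_series(spectra, protocol = protocol)
    attr(ser, "api_series") <- api
  } else {
    ser <- spectra_series(spectra, protocol = protocol)
  }
  attr(ser, "ground_truth") <- preset
  ser
}

#' Generate an isothermal annealing (aging) series
#'
#' Emulates physical aging of a confined sample held at `T_anneal`: the
#' structural relaxation time drifts upward (spectra shift to lower
#' frequencies) towards the bulk-like value, by `drift_decades` over the full
#' annealing window with an exponential approach.
#'
#' @param process a [process_spec()] for the structural relaxation.
#' @param T_anneal annealing temperature [K].
#' @param times_h sampling times in hours, increasing.
#' @param drift_decades total upward drift of `log10 tau` (>= 0).
#' @param tau_settle_h e-folding time of the approach, hours.
#' @param noise_rel,seed,freq_grid,eps_inf as in [gen_spectrum()].
#' @return a [spectra_series()] with protocol `"isothermal_time"`.
#' @export
gen_annealing_series <- function(process, T_anneal, times_h,
                                 drift_decades = 1.5, tau_settle_h = 80,
                                 noise_rel = 0, seed = 1L,
                                 freq_grid = log_grid(1e-2, 1e6, 65L),
                                 eps_inf = 3) {
  stopifnot(all(diff(times_h) > 0), drift_decades >= 0)
  tau0 <- tau_at(process$law, T_anneal, process$name)
  spectra <- lapply(seq_along(times_h), function(i) {
    shift <- drift_decades * (1 - exp(-times_h[i] / tau_settle_h))
    # constant-in-T law pinned at the drifted tau for this time slice
    drifted <- law_arrhenius(tau_inf = tau0 * 10^shift *
                               exp(-1e-6 * 1000 / (RGAS * T_anneal)),
                             Ea = 1e-6)
    s <- gen_spectrum(list(process_spec(process$name, process$delta_eps,
                                        process$alpha, process$gamma,
                                        drifted, Tref = T_anneal)),
                      T_anneal, freq_grid, noise_rel = noise_rel,
                      seed = as.integer(seed) * 1000L + i, eps_inf = eps_inf)
    s$meta$time_h <- times_h[i]
    s
  })
  spectra_series(spectra, protocol = "isothermal_time")
}
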