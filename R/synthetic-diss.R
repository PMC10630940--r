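# Synthetic dissolution profiles: prolonged release, spring-and-crash,
# and flat (no-release) shapes.

#' Generate a dissolution profile
#'
#' Shapes:
#' * `prolonged`: `C(t) = C_inf (1 - exp(-k t))` -- monotone rise to a stable
#'   maximum (the extended-release pattern of pore-confined drug).
#' * `spring_crash`: `C(t) = plateau + A (1 - exp(-k_rise t)) exp(-k_decay t)`
#'   -- supersaturation spike followed by precipitation to a lower plateau,
#'   the behaviour of the bulk amorphous drug.
#' * `flat`: constant concentration.
#'
#' Default `spring_crash` parameters reproduce a peak of ~0.2 mg/mL near
#' 30 min decaying towards a ~0.1 mg/mL plateau. Additive Gaussian noise of
#' relative scale `noise_rel` (of the profile maximum) is applied and the
#' result clipped at zero.
#'
#' @param kind `"prolonged"`, `"spring_crash"` or `"flat"`.
#' @param params named list of model parameters (see above; `C_inf`, `k` for
#'   prolonged; `plateau`, `A`, `k_rise`, `k_decay` for spring_crash; `c0` for
#'   flat).
#' @param times sampling times in minutes, nonnegative increasing. The default
#'   grid is denser than a 5-point compendial schedule so that release-model
#'   selection is well posed.
#' @param noise_rel relative noise scale.
#' @param seed integer seed.
#' @param label sample label.
#' @return a [dissolution_profile()] with attribute `"ground_truth"`.
#' @export
gen_dissolution <- function(kind = c("prolonged", "spring_crash", "flat"),
                            params = list(),
                            times = c(5, 10, 15, 30, 45, 60, 90, 120, 150, 180),
                            noise_rel = 0, seed = 1L, label = kind) {
  kind <- match.arg(kind)
  if (any(times < 0) || any(diff(times) <= 0))
    stop_amt("times must be nonnegative and increasing")
  if (any(unlist(params) < 0)) stop_amt("negative model parameters")
  p <- switch(kind,
    prolonged = utils::modifyList(list(C_inf = 0.3, k = 0.02), params),
    spring_crash = utils::modifyList(
      list(plateau = 0.1, A = 0.174, k_rise = 0.06, k_decay = 0.013), params),
    flat = utils::modifyList(list(c0 = 0.05), params))
  conc <- switch(kind,
    prolonged = p$C_inf * (1 - exp(-p$k * times)),
    spring_crash = p$plateau + p$A * (1 - exp(-p$k_rise * times)) *
      exp(-p$k_decay * times),
    flat = rep(p$c0, length(times)))
  if (noise_rel > 0) {
    set.seed(as.integer(seed))
    conc <- conc + stats::rnorm(length(conc), 0, noise_rel * max(conc))
    conc <- pmax(conc, 0)
  }
  out <- dissolution_profile(times, conc, label = label[1L])
  attr(out, "ground_truth") <- c(list(kind = kind), p)
  out
}
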