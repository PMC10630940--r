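# shared fixtures built in code

default_grid <- function(n = 65L) amorphotrack:::log_grid(1e-2, 1e6, n)

# noiseless spectrum from an hn_fit truth
spectrum_from_truth <- function(truth, freq = default_grid(), T = 313) {
  eps <- hn_eval(truth, freq)
  dielectric_spectrum(freq, Re(eps), -Im(eps), T = T)
}

# multiplicative lognormal noise on the loss, reproducible
noisy_loss <- function(sp, rel, seed) {
  set.seed(seed)
  dielectric_spectrum(sp$freq, sp$eps_real,
                      sp$eps_imag * exp(stats::rnorm(length(sp$freq), 0, rel)),
                      T = sp$T, meta = sp$meta)
}

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
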