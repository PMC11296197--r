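# shared fixtures, built in code

# canonical q grid for synthetic curves
test_q_grid <- function(n = 300) seq(0.02, 0.25, length.out = n)

# the reference parameter set used across fit tests
test_params <- function() {
  peak_params(c = 2, a1 = 100, q1 = 0.045, h1 = 0.007,
              alpha = 0.3, beta = 5 / 3, h2 = 0.012)
}

# noiseless intensity-space curve generated from the Porod-space peak model
noiseless_curve <- function(params = test_params(), q = test_q_grid(),
                            sample = "T01") {
  scattering_curve(q, peak_model(params, q) / q^4, sample = sample)
}

# relative parameter error between a fit and the generating truth
param_rel_err <- function(fit, truth) {
  est <- unlist(fit$params)
  tru <- unlist(truth)
  abs(est - tru) / abs(tru)
}
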