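# Shared fixtures, all generated in code under fixed seeds.

# Figure-style worked sequence used throughout the compression tests
fig_tokens <- c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L)
fig_seq <- function() obs_seq(fig_tokens, alphabet_size = 2L)

# i.i.d. random sequence over an alphabet of size m
random_tokens <- function(n, m, seed, prob = NULL) {
  withr::with_seed(seed, sample(0:(m - 1L), n, replace = TRUE, prob = prob))
}

# a calibration whose stopping behaviour is fully deterministic
injected_calibration <- function(thresholds = integer(0), e = 1,
                                 t_mv = 1e-6, t_mm = 1e-5) {
  if (length(thresholds) == 0L) return(compression_calibration(e = e))
  compression_calibration(thresholds, e = e, t_mv = t_mv, t_mm = t_mm,
                          fixed_round_time = 0)
}

# symmetric two-state switch model with symmetric emission accuracy q
switch_model <- function(rate, q = 0.9) {
  hmm(c(0.5, 0.5),
      matrix(c(1 - rate, rate, rate, 1 - rate), 2L, byrow = TRUE),
      matrix(c(q, 1 - q, 1 - q, q), 2L, byrow = TRUE))
}

# logit parameterization of switch_model: par = (logit rate, logit q)
switch_parameterization <- function() {
  inv_logit <- function(z) 1 / (1 + exp(-z))
  function(par) switch_model(inv_logit(par[1L]), inv_logit(par[2L]))
}
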