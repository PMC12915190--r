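# Shared fixture builders. Everything is generated in code at test time.

# A corrected trace built directly from a dff vector (bypasses the control fit
# when a test targets downstream stages only).
make_trace <- function(dff, fs = 20) {
  structure(list(dff = dff, time = (seq_along(dff) - 1) / fs,
                 sampling_rate = fs),
            class = "corrected_trace")
}

# Noiseless simulator world used by the detection-recovery tests: equal bleach
# taus (the affine control fit cancels proportional bleaching exactly), no
# artifact, no channel noise, fixed transient amplitude.
noiseless_sim_params <- function(seed, amplitude = 0.05, event_rate = 0.3,
                                 duration = 600) {
  photometry_sim_params(duration = duration, event_rate = event_rate,
                        amplitude_mean = amplitude, amplitude_sd = 0,
                        noise_sd = 0, artifact_sd = 0,
                        bleach_tau_signal = 1200, bleach_tau_control = 1200,
                        seed = seed)
}

# Seed 6 realizes exactly 3 Poisson events at rate 0.3/min over 600 s with
# minimum onset gap > 10 s (verified once; the seed selects the stated
# scenario, the assertions below do the checking).
SEED_3_EVENTS <- 6L

# Independent upper-tail hypergeometric oracle: direct sum of the printed
# combinatorial formula, no distribution functions.
hyper_tail_oracle <- function(k, M, N, n) {
  if (k > min(M, n)) return(0)
  i <- max(k, 0):min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
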