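# Shared fixture builders, all generated in code.

noiseless_params <- function(duration = 10, rdsym = 0.5, peak_exp = 1,
                             trough_exp = 1, fs = 512, osc_freq = 20) {
  synth_params(duration = duration, fs = fs, osc_freq = osc_freq,
               rdsym = rdsym, peak_exp = peak_exp, trough_exp = trough_exp,
               alpha_amp = 0, noise_amp = 0, gamma_amp = 0)
}

# Asymmetric oscillation plus a little 1/f noise: a generic artifact-free
# test signal with nontrivial shape.
asym_noisy_signal <- function(duration = 10, seed = 7, rdsym = 0.62,
                              peak_exp = 2, noise_amp = 0.3) {
  p <- synth_params(duration = duration, fs = 512, rdsym = rdsym,
                    peak_exp = peak_exp, alpha_amp = 0,
                    noise_amp = 0, gamma_amp = 0)
  as.numeric(simulate_oscillation(p)) +
    noise_amp * simulate_aperiodic(floor(duration * 512), 512, 2, seed = seed)
}
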