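# Shared fixtures, built in code.  Envelope-only checks run at 20 kHz
# (plenty above the EODf Nyquist); P-unit checks run at 100 kHz to match
# the 0.01 ms integration grid.

static_pair <- function(f1 = 827, f2 = 763, a2 = 0.143) {
  list(eod_source(f1), eod_source(f2, mean_amplitude = a2))
}

static_triplet <- function(a2 = 0.10, a3 = 0.08) {
  list(eod_source(831), eod_source(740, mean_amplitude = a2),
       eod_source(889, mean_amplitude = a3))
}

moving_pair <- function(a2 = 0.143, sigma2 = 0.56, tau_c = 0.5) {
  list(eod_source(827),
       eod_source(763, mean_amplitude = a2, amplitude_sd = sigma2,
                  motion_correlation_time = tau_c))
}

# frequency of the largest PSD bin
psd_argmax <- function(spec, f_min = 0) {
  keep <- spec$frequencies > f_min
  spec$frequencies[keep][which.max(spec$power[keep])]
}
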