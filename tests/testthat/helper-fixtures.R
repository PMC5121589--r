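# Small cohort configurations used across tests. Signal sizes are kept tiny;
# the statistical structure (groups, IAF laws) is what matters.

tiny_config <- function(seed = 1, ...) {
  args <- list(
    group_sizes = c(noSCD = 4, MCI = 4),
    iaf_mean = c(noSCD = 9.8, MCI = 9.0),
    iaf_sd = c(noSCD = 0.9, MCI = 0.9),
    alpha_relpower_mean = c(noSCD = 0.32, MCI = 0.25),
    age_mean = c(noSCD = 70.4, MCI = 73.0),
    age_sd = c(noSCD = 3.7, MCI = 3.7),
    n_per_axis = 2, epoch_count = 6, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# single-group config with degenerate variances for exact-recovery tests
fixed_iaf_config <- function(iaf = 9.8, relpower = 0.5, n = 3, seed = 5, ...) {
  args <- list(
    group_sizes = c(g = n), iaf_mean = c(g = iaf), iaf_sd = c(g = 0),
    alpha_relpower_mean = c(g = relpower), alpha_relpower_sd = 0,
    age_mean = c(g = 70), age_sd = c(g = 4),
    n_per_axis = 2, epoch_count = 10, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# spectrum row generated exactly by the Gaussian-peak/power-law model
model_spectrum_row <- function(freqs, A = 1, B = 1, C = 0.5, fp = 10,
                               delta = 1) {
  A * freqs^(-B) + C * exp(-(freqs - fp)^2 / delta^2)
}

make_sinusoid_epochs <- function(freq, fs = 250, n_samples = 1000,
                                 n_epochs = 3, n_channels = 1, amp = 1,
                                 space = "source") {
  t_axis <- (seq_len(n_samples) - 1) / fs
  dat <- array(0, c(n_epochs, n_channels, n_samples))
  for (e in seq_len(n_epochs)) {
    for (ch in seq_len(n_channels)) {
      dat[e, ch, ] <- amp * sin(2 * pi * freq * t_axis)
    }
  }
  epoch_array(dat, fs, space)
}
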