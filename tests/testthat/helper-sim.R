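# small configurations and hand-built fixtures shared across tests

tiny_config <- function(...) {
  sim_config(n_participants = 2, seed = 101, ...)
}

# noiseless configuration: every stochastic pupil/RT component switched off
quiet_config <- function(...) {
  sim_config(n_participants = 1, seed = 202,
             pupil_drift_sd_mm = 0, pupil_noise_sd_mm = 0,
             anticip_effect_reward_mm = 0, anticip_effect_neutral_mm = 0,
             anticip_sd_mm = 0, blink_rate_hz = 0, rt_sd_ms = 0, ...)
}

# a single constant 40-Hz trace with marker table, built by hand
const_trace <- function(value = 5.7, dur = 14, fs = 40) {
  n <- round(dur * fs)
  list(
    traces = tibble::tibble(
      participant = 1L, trial_index = 1L,
      t_s = (seq_len(n) - 1) / fs,
      diameter_mm = value, valid = TRUE
    ),
    events = tibble::tibble(
      participant = 1L, trial_index = 1L, condition = "reward",
      item_onset_s = 4, choice_onset_s = 7, anticip_onset_s = 10,
      anticip_offset_s = 13
    )
  )
}

# independent power-series evaluation of the modified Bessel function I0,
# used as an oracle against besselI-based code paths
i0_series <- function(kappa, terms = 60) {
  k <- 0:terms
  sum((kappa / 2)^(2 * k) / factorial(k)^2)
}
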