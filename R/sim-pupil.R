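#' Simulate event-locked pupil traces for a trial design
#'
#' Builds a 40-Hz (configurable) pupil-diameter trace per trial spanning
#' fixation through feedback. Each trace is the sum of: the tonic baseline,
#' a slow sinusoidal drift, an event-locked dilation ramp across the
#' anticipation period whose amplitude is drawn per trial from a normal
#' distribution with condition-specific mean (reward > neutral), and white
#' measurement noise. Blinks arrive as a Poisson process; blink samples are
#' flagged invalid and their diameter set to `NA` (the missing-data
#' sentinel). The ramp is flat over the first and final 0.2 s of the
#' anticipation period so the late-minus-early change measure recovers the
#' drawn amplitude exactly in the noise-free limit.
#'
#' Trial timeline (seconds from trial start): fixation (`fixation_s`), item
#' alone (3 s), choice display + response + hold (6 s), anticipation
#' (`anticipation_s`), then number, blank and feedback (1.6 s).
#'
#' @param design Trial table from [generate_design()].
#' @param config The matching [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @return A list of class `pupil_sim` with elements:
#'   \describe{
#'     \item{traces}{Long tibble: `participant`, `trial_index`, `t_s`,
#'       `diameter_mm`, `valid`.}
#'     \item{events}{One row per trial with marker times `item_onset_s`,
#'       `choice_onset_s`, `anticip_onset_s`, `anticip_offset_s`, the latent
#'       ramp amplitude `anticip_true_mm`, and `trial_dur_s`.}
#'   }
#' @export
simulate_pupil <- function(design, config, seed = config$seed + 2L) {
  validate_sim_config(config)
  set.seed(seed)
  fs <- config$sample_rate_hz
  n_trials <- nrow(design)

  effect_mean <- ifelse(design$condition == "reward",
                        config$anticip_effect_reward_mm,
                        config$anticip_effect_neutral_mm)
  amplitude <- rnorm(n_trials, effect_mean, config$anticip_sd_mm)

  events <- tibble::tibble(
    participant = design$participant,
    trial_index = design$trial_index,
    condition = design$condition,
    item_onset_s = design$fixation_s,
    choice_onset_s = design$fixation_s + 3,
    anticip_onset_s = design$fixation_s + 9,
    anticip_offset_s = design$fixation_s + 9 + design$anticipation_s,
    anticip_true_mm = amplitude,
    trial_dur_s = design$fixation_s + 9 + design$anticipation_s + 1.6
  )

  one_trace <- function(i) {
    dur <- events$trial_dur_s[i]
    n <- round(dur * fs)
    t_s <- (seq_len(n) - 1) / fs
    drift <- config$pupil_drift_sd_mm *
      sin(2 * pi * t_s / 20 + runif(1, 0, 2 * pi))
    # dilation ramp: flat in the first/final 0.2 s of anticipation
    a_on <- events$anticip_onset_s[i]
    a_off <- events$anticip_offset_s[i]
    ramp <- ramp_profile(t_s, a_on, a_off, amplitude[i])
    diam <- config$pupil_baseline_mm + drift + ramp +
      rnorm(n, 0, config$pupil_noise_sd_mm)

    valid <- rep(TRUE, n)
    if (config$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, config$blink_rate_hz * dur)
      if (n_blinks > 0) {
        onsets <- runif(n_blinks, 0, dur)
        durs <- runif(n_blinks, config$blink_dur_range_ms[1],
                      config$blink_dur_range_ms[2]) / 1000
        for (b in seq_len(n_blinks)) {
          valid[t_s >= onsets[b] & t_s < onsets[b] + durs[b]] <- FALSE
        }
      }
    }
    diam[!valid] <- NA_real_

    tibble::tibble(
      participant = design$participant[i],
      trial_index = design$trial_index[i],
      t_s = t_s,
      diameter_mm = diam,
      valid = valid
    )
  }

  traces <- dplyr::bind_rows(lapply(seq_len(n_trials), one_trace))
  structure(list(traces = traces, events = events), class = "pupil_sim")
}

# piecewise-linear dilation profile: 0 before the anticipation onset and
# through its first 0.2 s, rising linearly, flat at `amplitude` over the
# final 0.2 s, decaying back to 0 over 1 s after offset
ramp_profile <- function(t_s, a_on, a_off, amplitude) {
  rise_start <- a_on + 0.2
  rise_end <- max(a_off - 0.2, rise_start + 1e-9)
  ramp <- numeric(length(t_s))
  rising <- t_s >= rise_start & t_s < rise_end
  ramp[rising] <- amplitude * (t_s[rising] - rise_start) / (rise_end - rise_start)
  ramp[t_s >= rise_end & t_s < a_off] <- amplitude
  decay <- t_s >= a_off & t_s < a_off + 1
  ramp[decay] <- amplitude * (1 - (t_s[decay] - a_off))
  ramp
}

#' @export
print.pupil_sim <- function(x, ...) {
  cat(sprintf("<pupil_sim> %d trials, %d samples\n",
              nrow(x$events), nrow(x$traces)))
  invisible(x)
}
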