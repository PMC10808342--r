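#' Simulation configuration for the synthetic reward-memory experiment
#'
#' Bundles every generative parameter of the synthetic task: design counts,
#' condition-wise mixture parameters of the recall-error distribution, pupil
#' trace components, reaction-time coupling, and the adaptive deadline
#' staircase. Defaults reproduce the study conditions the analysis pipeline
#' targets: 36 participants, 84 trials in six blocks of 14 (half reward,
#' half neutral), memory success 0.58 / 0.55 and concentration 13.67 / 17.02
#' for reward / neutral, anticipatory pupil dilation of 0.10 / 0.03 mm,
#' reaction times coupled to pupil dilation at -30 ms per mm, and a deadline
#' staircase targeting positive feedback on 70 percent of reward trials.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Study-test blocks per participant.
#' @param trials_per_block Trials per block (half reward, half neutral).
#' @param p_t_reward,p_t_neutral Probability of successful retrieval per
#'   condition (mixture weight on the von Mises component), in \[0, 1\].
#' @param kappa_reward,kappa_neutral Von Mises concentration per condition
#'   (unitless, >= 0); higher values give tighter recall errors.
#' @param class_accuracy Probability that the study-phase item
#'   classification is correct; incorrectly classified trials are excluded
#'   from model fitting downstream.
#' @param num_accuracy Probability that the number-classification response
#'   is correct (a timing hit only earns reward when the response is also
#'   correct).
#' @param pupil_baseline_mm Tonic pupil diameter in mm.
#' @param pupil_drift_sd_mm Standard deviation of the slow sinusoidal
#'   baseline drift, mm.
#' @param pupil_noise_sd_mm Standard deviation of additive white measurement
#'   noise per 40-Hz sample, mm.
#' @param anticip_effect_reward_mm,anticip_effect_neutral_mm Mean amplitude
#'   of the event-locked dilation ramp across the anticipation period, mm.
#' @param anticip_sd_mm Trial-to-trial standard deviation of the ramp
#'   amplitude, mm.
#' @param rt_mean_ms Mean number-classification reaction time on neutral
#'   trials, ms.
#' @param rt_offset_reward_ms Additive reaction-time offset on reward
#'   trials, ms (negative = faster under reward).
#' @param rt_pupil_slope_ms_per_mm Coupling of reaction time to the
#'   anticipatory pupil change, ms per mm (negative = faster with larger
#'   dilation).
#' @param rt_sd_ms Reaction-time noise standard deviation, ms.
#' @param rt_floor_ms Lower truncation for simulated reaction times, ms.
#' @param blink_rate_hz Blink events per second of trace.
#' @param blink_dur_range_ms Range (min, max) of blink durations, ms.
#' @param sample_rate_hz Pupil sampling rate, Hz.
#' @param target_reward_rate Positive-feedback proportion the deadline
#'   staircase is titrated towards.
#' @param deadline_start_ms Initial response deadline, ms.
#' @param staircase_step_ms Total staircase step budget, ms; after positive
#'   feedback the deadline tightens by `(1 - target_reward_rate) *
#'   staircase_step_ms` and after negative feedback it relaxes by
#'   `target_reward_rate * staircase_step_ms`, so the zero-drift equilibrium
#'   sits at the target rate.
#' @param deadline_range_ms Clamp (min, max) on the deadline, ms.
#' @param seed Integer seed making every simulated table reproducible.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 3, seed = 1)
#' cfg$trials_per_block * cfg$n_blocks  # 84 trials per participant
#' @export
sim_config <- function(n_participants = 36,
                       n_blocks = 6,
                       trials_per_block = 14,
                       p_t_reward = 0.58,
                       p_t_neutral = 0.55,
                       kappa_reward = 13.67,
                       kappa_neutral = 17.02,
                       class_accuracy = 0.93,
                       num_accuracy = 0.90,
                       pupil_baseline_mm = 3.5,
                       pupil_drift_sd_mm = 0.05,
                       pupil_noise_sd_mm = 0.05,
                       anticip_effect_reward_mm = 0.10,
                       anticip_effect_neutral_mm = 0.03,
                       anticip_sd_mm = 0.40,
                       rt_mean_ms = 422,
                       rt_offset_reward_ms = -44,
                       rt_pupil_slope_ms_per_mm = -30,
                       rt_sd_ms = 60,
                       rt_floor_ms = 150,
                       blink_rate_hz = 0.10,
                       blink_dur_range_ms = c(100, 400),
                       sample_rate_hz = 40,
                       target_reward_rate = 0.70,
                       deadline_start_ms = 400,
                       staircase_step_ms = 30,
                       deadline_range_ms = c(200, 1500),
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    p_t_reward = p_t_reward,
    p_t_neutral = p_t_neutral,
    kappa_reward = kappa_reward,
    kappa_neutral = kappa_neutral,
    class_accuracy = class_accuracy,
    num_accuracy = num_accuracy,
    pupil_baseline_mm = pupil_baseline_mm,
    pupil_drift_sd_mm = pupil_drift_sd_mm,
    pupil_noise_sd_mm = pupil_noise_sd_mm,
    anticip_effect_reward_mm = anticip_effect_reward_mm,
    anticip_effect_neutral_mm = anticip_effect_neutral_mm,
    anticip_sd_mm = anticip_sd_mm,
    rt_mean_ms = rt_mean_ms,
    rt_offset_reward_ms = rt_offset_reward_ms,
    rt_pupil_slope_ms_per_mm = rt_pupil_slope_ms_per_mm,
    rt_sd_ms = rt_sd_ms,
    rt_floor_ms = rt_floor_ms,
    blink_rate_hz = blink_rate_hz,
    blink_dur_range_ms = blink_dur_range_ms,
    sample_rate_hz = sample_rate_hz,
    target_reward_rate = target_reward_rate,
    deadline_start_ms = as.numeric(deadline_start_ms),
    staircase_step_ms = as.numeric(staircase_step_ms),
    deadline_range_ms = as.numeric(deadline_range_ms),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  stop_if(is.na(cfg$n_participants) || cfg$n_participants <= 0,
          "`n_participants` must be a positive count")
  stop_if(is.na(cfg$n_blocks) || cfg$n_blocks <= 0,
          "`n_blocks` must be a positive count")
  stop_if(is.na(cfg$trials_per_block) || cfg$trials_per_block <= 0,
          "`trials_per_block` must be a positive count")
  stop_if(cfg$trials_per_block %% 2 != 0,
          "`trials_per_block` must be even so conditions balance within block")
  probs <- c(cfg$p_t_reward, cfg$p_t_neutral, cfg$class_accuracy,
             cfg$num_accuracy, cfg$target_reward_rate)
  stop_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  stop_if(cfg$kappa_reward < 0 || cfg$kappa_neutral < 0,
          "von Mises concentrations must be >= 0")
  stop_if(cfg$sample_rate_hz <= 0, "`sample_rate_hz` must be positive")
  stop_if(cfg$blink_rate_hz < 0, "`blink_rate_hz` must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants x %d trials (%d blocks of %d)\n",
              x$n_participants, x$n_blocks * x$trials_per_block,
              x$n_blocks, x$trials_per_block))
  cat(sprintf("  mixture: p_t %0.2f/%0.2f, kappa %0.2f/%0.2f (reward/neutral)\n",
              x$p_t_reward, x$p_t_neutral, x$kappa_reward, x$kappa_neutral))
  cat(sprintf("  pupil: anticipation effect %0.2f/%0.2f mm, %g Hz\n",
              x$anticip_effect_reward_mm, x$anticip_effect_neutral_mm,
              x$sample_rate_hz))
  cat(sprintf("  RT: %g ms (reward %+g), slope %g ms/mm, target hit rate %0.2f\n",
              x$rt_mean_ms, x$rt_offset_reward_ms,
              x$rt_pupil_slope_ms_per_mm, x$target_reward_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Serialize / restore a simulation configuration
#'
#' @param cfg A [sim_config()] object.
#' @param path File path for the JSON representation.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
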