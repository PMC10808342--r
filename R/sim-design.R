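#' Generate the trial design of the synthetic location-memory task
#'
#' Lays out the study trials for every simulated participant: six blocks of
#' fourteen trials (by default), each block balanced between reward and
#' neutral trials in randomized order. Target locations are drawn on a
#' circle segmented in 4-degree steps; the two cue dots on a trial sit 180
#' degrees apart, and angles are consumed from a shuffled cycle over all
#' ninety 4-degree positions so no angle repeats until the cycle is
#' exhausted. Fixation (3-6 s) and anticipation (2-4 s) durations are
#' uniformly distributed; the target number for the speeded classification
#' is drawn from {1, 4, 6, 9}.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per trial: `participant`, `block`,
#'   `trial_index` (1-based within participant), `condition`
#'   (`"reward"`/`"neutral"`), `target_angle_deg`, `paired_angle_deg`,
#'   `fixation_s`, `anticipation_s`, `target_number`, `deadline_ms`
#'   (initial deadline; the staircase in [simulate_rt_and_titration()]
#'   updates it trial by trial).
#' @examples
#' design <- generate_design(sim_config(n_participants = 2, seed = 42))
#' dplyr::count(design, participant, condition)
#' @export
generate_design <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_trials <- config$n_blocks * config$trials_per_block
  all_angles <- seq(4, 360, by = 4)

  one_participant <- function(pid) {
    # balanced conditions within each block, order randomized
    cond <- unlist(lapply(seq_len(config$n_blocks), function(b) {
      sample(rep(c("reward", "neutral"), config$trials_per_block / 2))
    }))
    # shuffled 4-degree angle cycles, restarted when exhausted
    n_cycles <- ceiling(n_trials / length(all_angles))
    angles <- unlist(lapply(seq_len(n_cycles), function(i) sample(all_angles)))
    angles <- angles[seq_len(n_trials)]
    tibble::tibble(
      participant = pid,
      block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
      trial_index = seq_len(n_trials),
      condition = cond,
      target_angle_deg = angles,
      paired_angle_deg = wrap_position_deg(angles + 180),
      fixation_s = runif(n_trials, 3, 6),
      anticipation_s = runif(n_trials, 2, 4),
      target_number = sample(c(1, 4, 6, 9), n_trials, replace = TRUE),
      deadline_ms = config$deadline_start_ms
    )
  }

  dplyr::bind_rows(lapply(seq_len(config$n_participants), one_participant))
}
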