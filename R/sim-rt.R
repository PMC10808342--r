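#' Adaptive response-deadline staircase
#'
#' Runs the deadline titration over a fixed sequence of reaction times:
#' after positive feedback the deadline tightens by
#' `(1 - target_rate) * step_ms`, after negative feedback it relaxes by
#' `target_rate * step_ms`. The asymmetric steps put the zero-drift
#' equilibrium of the resulting random walk at a positive-feedback rate of
#' `target_rate`, so the long-run hit rate converges there for any
#' stationary reaction-time distribution.
#'
#' @param rt_ms Reaction times in ms, in trial order.
#' @param correct Logical, whether the classification response was correct
#'   (a timing hit only earns positive feedback when also correct).
#'   Defaults to all correct.
#' @param target_rate Positive-feedback proportion to titrate towards.
#' @param start_ms Initial deadline, ms.
#' @param step_ms Total step budget, ms (split asymmetrically as above).
#' @param range_ms Clamp (min, max) on the deadline, ms.
#' @return Tibble with `rt_ms`, `deadline_ms` (deadline in force on that
#'   trial), `hit` (RT at or below deadline) and `positive` (hit and
#'   correct).
#' @examples
#' rts <- rnorm(500, 400, 60)
#' mean(titrate_deadline(rts)$positive)  # close to 0.70
#' @export
titrate_deadline <- function(rt_ms, correct = rep(TRUE, length(rt_ms)),
                             target_rate = 0.70, start_ms = 500,
                             step_ms = 10, range_ms = c(200, 1500)) {
  stopifnot(length(correct) == length(rt_ms), target_rate > 0, target_rate < 1)
  n <- length(rt_ms)
  deadline <- numeric(n)
  d <- start_ms
  step_down <- (1 - target_rate) * step_ms
  step_up <- target_rate * step_ms
  hit <- logical(n)
  positive <- logical(n)
  for (i in seq_len(n)) {
    deadline[i] <- d
    hit[i] <- rt_ms[i] <= d
    positive[i] <- hit[i] && correct[i]
    d <- if (positive[i]) d - step_down else d + step_up
    d <- min(max(d, range_ms[1]), range_ms[2])
  }
  tibble::tibble(rt_ms = rt_ms, deadline_ms = deadline,
                 hit = hit, positive = positive)
}

#' Simulate reaction times, deadline titration and feedback
#'
#' Generates number-classification reaction times coupled to the
#' anticipatory pupil change (`RT = rt_mean + slope * pupil_change +
#' reward offset + noise`, truncated at the floor), then runs the adaptive
#' deadline staircase over the reward trials of each participant and
#' assigns feedback: +15c for a correct response within the deadline on a
#' reward trial, -10c otherwise on reward trials, 0c on neutral trials.
#'
#' @param design Trial table from [generate_design()].
#' @param pupil_changes Numeric vector of per-trial anticipatory pupil
#'   changes in mm, aligned with `design` rows (e.g. the `anticip_true_mm`
#'   column of [simulate_pupil()]'s events, or measured epochs). `NA`
#'   entries generate the RT without the coupling term and are flagged.
#' @param config The matching [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 3`.
#' @return `design` with columns added: `rt_ms`, `num_correct`,
#'   `deadline_ms` (as titrated), `feedback_cents`, `positive_feedback`,
#'   and `rt_uncoupled` (flag for missing pupil change).
#' @export
simulate_rt_and_titration <- function(design, pupil_changes, config,
                                      seed = config$seed + 3L) {
  validate_sim_config(config)
  if (length(pupil_changes) != nrow(design)) {
    stop("`pupil_changes` must have one entry per design row", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(design)
  uncoupled <- !is.finite(pupil_changes)
  coupling <- ifelse(uncoupled, 0,
                     config$rt_pupil_slope_ms_per_mm * pupil_changes)
  offset <- ifelse(design$condition == "reward", config$rt_offset_reward_ms, 0)
  rt <- config$rt_mean_ms + offset + coupling + rnorm(n, 0, config$rt_sd_ms)
  rt <- pmax(rt, config$rt_floor_ms)
  num_correct <- runif(n) < config$num_accuracy

  out <- design |>
    dplyr::mutate(
      rt_ms = rt,
      num_correct = num_correct,
      rt_uncoupled = uncoupled,
      deadline_ms = NA_real_,
      feedback_cents = 0,
      positive_feedback = NA
    )
  # staircase runs over the reward trials of each participant, in order
  for (pid in unique(out$participant)) {
    idx <- which(out$participant == pid & out$condition == "reward")
    st <- titrate_deadline(out$rt_ms[idx], out$num_correct[idx],
                           target_rate = config$target_reward_rate,
                           start_ms = config$deadline_start_ms,
                           step_ms = config$staircase_step_ms,
                           range_ms = config$deadline_range_ms)
    out$deadline_ms[idx] <- st$deadline_ms
    out$positive_feedback[idx] <- st$positive
    out$feedback_cents[idx] <- ifelse(st$positive, 15, -10)
  }
  out
}
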