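#' Exclude participants performing at chance on the memory test
#'
#' A participant whose mean absolute recall error is 75 degrees or more is
#' considered to perform at chance (the expected absolute error of uniform
#' guessing is 90 degrees) and is removed from all analyses. The threshold
#' is inclusive: a mean absolute error of exactly 75 is excluded.
#'
#' @param trials Tibble with at least `participant` and `error_deg`.
#' @param threshold_deg Exclusion threshold on the mean absolute error.
#' @return A list with `retained` (the filtered trial tibble), `excluded`
#'   (participant ids removed) and `report` (per-participant mean absolute
#'   error and exclusion flag).
#' @export
exclude_chance_participants <- function(trials, threshold_deg = 75) {
  if (nrow(trials) == 0) stop("`trials` is empty", call. = FALSE)
  report <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(mean_abs_error = mean(abs(.data$error_deg)),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(excluded = .data$mean_abs_error >= threshold_deg)
  excluded <- report$participant[report$excluded]
  list(
    retained = dplyr::filter(trials, !(.data$participant %in% excluded)),
    excluded = excluded,
    report = report
  )
}

#' Flag outlying parameter estimates within condition
#'
#' Screens participant-level estimates (e.g. fitted kappa) for values more
#' than `k_sd` sample standard deviations from their condition mean; used
#' for the sensitivity re-analysis that drops participants with aberrant
#' fits. The SD is the sample (n - 1) estimator.
#'
#' @param estimates Tibble with `participant`, `condition` and the column
#'   named by `value`.
#' @param value Name of the estimate column to screen (string).
#' @param k_sd Threshold in standard deviations.
#' @return Tibble of flagged rows with the condition mean, SD and z score;
#'   zero rows when nothing is flagged. Zero-variance conditions flag
#'   nothing (with a warning).
#' @export
detect_outlier_estimates <- function(estimates, value = "kappa", k_sd = 2.5) {
  counts <- table(estimates$condition)
  if (any(counts < 3)) {
    stop("need at least 3 estimates per condition", call. = FALSE)
  }
  scored <- estimates |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(
      cond_mean = mean(.data[[value]]),
      cond_sd = sd(.data[[value]]),
      z = dplyr::if_else(.data$cond_sd > 0,
                         (.data[[value]] - .data$cond_mean) / .data$cond_sd,
                         0)
    ) |>
    dplyr::ungroup()
  if (any(scored$cond_sd == 0)) {
    warning("zero-variance condition: no outliers flagged there",
            call. = FALSE)
  }
  dplyr::filter(scored, abs(.data$z) > k_sd)
}

#' Keep trials usable for mixture fitting
#'
#' Drops incorrectly classified study trials and then removes participants
#' left with fewer than `min_trials` trials in either condition, mirroring
#' the fitting rule that a participant with too few remaining trials is
#' excluded from model fitting.
#'
#' @param trials Tibble with `participant`, `condition`, `error_deg` and
#'   `classified_correct`.
#' @param min_trials Minimum remaining trials per condition.
#' @return A list with `retained` (filtered tibble) and
#'   `excluded_few_trials` (participant ids dropped for low counts).
#' @export
filter_fit_trials <- function(trials, min_trials = 10) {
  kept <- dplyr::filter(trials, .data$classified_correct)
  counts <- kept |>
    dplyr::count(.data$participant, .data$condition) |>
    tidyr::complete(.data$participant, .data$condition,
                    fill = list(n = 0L))
  low <- counts |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(min_n = min(.data$n), .groups = "drop") |>
    dplyr::filter(.data$min_n < min_trials)
  list(
    retained = dplyr::filter(kept, !(.data$participant %in% low$participant)),
    excluded_few_trials = low$participant
  )
}
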