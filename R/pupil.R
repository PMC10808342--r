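#' Pupil preprocessing pipeline
#'
#' The preprocessing chain mirrors standard pupillometry practice for
#' event-related designs: (optional) foreshortening correction hook, blink
#' interpolation, zero-phase low-pass filtering, event epoching, epoch QC
#' and baseline correction — applied in that order. Each step is exposed
#' individually; [preprocess_pupil()] runs the whole chain.
#'
#' All functions operate on a long trace tibble with columns `t_s`,
#' `diameter_mm`, `valid` and (when present) grouping columns
#' `participant` and `trial_index`.
#'
#' @name pupil-pipeline
NULL

trace_groups <- function(traces) {
  intersect(c("participant", "trial_index"), names(traces))
}

#' Pass-through hook for pupil foreshortening-error correction
#'
#' Geometric correction of gaze-dependent pupil foreshortening is
#' performed by specialised external tooling; this hook lets an externally
#' corrected trace (or a user-supplied function) slot into the pipeline.
#' With `fun = NULL` the trace passes through unchanged.
#'
#' @param traces Long trace tibble.
#' @param fun Optional function `traces -> traces` applying a correction.
#' @return The (possibly corrected) trace tibble.
#' @export
correct_foreshortening <- function(traces, fun = NULL) {
  if (is.null(fun)) traces else fun(traces)
}

#' Interpolate blink gaps in a pupil trace
#'
#' Samples flagged invalid, widened from `pre_ms` before each blink onset
#' to `post_ms` after its offset, are replaced by linear interpolation
#' between the nearest valid neighbours; blinks touching a trace edge are
#' extended from the nearest valid sample. Samples outside the widened
#' windows are untouched. Interpolated samples are flagged in a new
#' `interpolated` column (and remain "invalid" for epoch QC purposes).
#'
#' @param traces Long trace tibble (grouped per trial internally).
#' @param pre_ms,post_ms Widening of each blink window, ms.
#' @return The trace tibble with `diameter_mm` filled and an
#'   `interpolated` logical column.
#' @export
interpolate_blinks <- function(traces, pre_ms = 100, post_ms = 400) {
  grp <- trace_groups(traces)
  if (length(grp) == 0) return(interpolate_blinks_one(traces, pre_ms, post_ms))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ interpolate_blinks_one(.x, pre_ms, post_ms)) |>
    dplyr::ungroup()
}

interpolate_blinks_one <- function(tr, pre_ms, post_ms) {
  tr$interpolated <- FALSE
  if (all(tr$valid)) return(tr)
  runs <- rle(!tr$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fill <- logical(nrow(tr))
  for (k in which(runs$values)) {
    t_on <- tr$t_s[starts[k]] - pre_ms / 1000
    t_off <- tr$t_s[ends[k]] + post_ms / 1000
    fill[tr$t_s >= t_on & tr$t_s <= t_off] <- TRUE
  }
  anchor <- !fill & tr$valid
  if (sum(anchor) < 2) {
    # nearly the whole trace is a blink; hold at the overall valid mean
    tr$diameter_mm[fill] <- mean(tr$diameter_mm[tr$valid], na.rm = TRUE)
  } else {
    tr$diameter_mm[fill] <- approx(tr$t_s[anchor], tr$diameter_mm[anchor],
                                   xout = tr$t_s[fill], rule = 2)$y
  }
  tr$interpolated <- fill
  tr
}

#' Zero-phase low-pass filter for pupil traces
#'
#' Fourth-order Butterworth low-pass at 10 Hz by default, applied
#' forward-backward (`signal::filtfilt`) for zero net phase shift. The
#' trace must be gap-free (run [interpolate_blinks()] first).
#'
#' @param traces Long trace tibble.
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order (of each pass).
#' @param sample_rate_hz Sampling rate; inferred from `t_s` when `NULL`.
#' @return The trace tibble with `diameter_mm` filtered.
#' @export
lowpass_pupil <- function(traces, cutoff_hz = 10, order = 4,
                          sample_rate_hz = NULL) {
  grp <- trace_groups(traces)
  apply_one <- function(tr, ...) {
    fs <- sample_rate_hz %||% (1 / median(diff(tr$t_s)))
    if (cutoff_hz >= fs / 2) {
      stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
    }
    min_len <- 3 * (2 * order + 1)
    if (nrow(tr) < min_len) {
      stop(sprintf("trace too short to filter: need >= %d samples", min_len),
           call. = FALSE)
    }
    if (anyNA(tr$diameter_mm)) {
      stop("trace contains NA; interpolate blinks before filtering",
           call. = FALSE)
    }
    bw <- signal::butter(order, cutoff_hz / (fs / 2))
    # odd-reflection padding keeps the forward-backward pass free of the
    # zero-state edge transient (and makes the DC gain exactly 1)
    x <- tr$diameter_mm
    n <- length(x)
    p <- min(max(24, round(2 * fs)), n - 1)
    x_ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- as.numeric(signal::filtfilt(bw, x_ext))
    tr$diameter_mm <- y[(p + 1):(p + n)]
    tr
  }
  if (length(grp) == 0) return(apply_one(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ apply_one(.x)) |>
    dplyr::ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quality control for an event epoch
#'
#' An epoch is excluded when more than half of its samples are marked
#' invalid (strictly greater than 50 percent; exactly half is retained).
#' Surviving epochs have samples more than 3 sample-SDs from the epoch
#' mean removed in a single pass before averaging.
#'
#' @param values Sample values within the epoch.
#' @param invalid Logical, which samples are invalid (blinked or
#'   interpolated).
#' @param max_invalid_frac Exclusion threshold on the invalid fraction.
#' @param z_cut Spurious-sample cutoff in standard deviations.
#' @return A list: `mean` (epoch mean, `NA` if excluded), `ok`,
#'   `n_samples`, `n_used`, `reason` (`""`, `"invalid_fraction"`,
#'   `"no_samples"` or `"all_removed"`).
#' @export
qc_epoch <- function(values, invalid = rep(FALSE, length(values)),
                     max_invalid_frac = 0.5, z_cut = 3) {
  n <- length(values)
  if (n == 0) {
    return(list(mean = NA_real_, ok = FALSE, n_samples = 0L, n_used = 0L,
                reason = "no_samples"))
  }
  if (mean(invalid) > max_invalid_frac) {
    return(list(mean = NA_real_, ok = FALSE, n_samples = n, n_used = 0L,
                reason = "invalid_fraction"))
  }
  m <- mean(values)
  s <- sd(values)
  keep <- if (is.na(s) || s == 0) rep(TRUE, n) else abs(values - m) <= z_cut * s
  if (!any(keep)) {
    return(list(mean = NA_real_, ok = FALSE, n_samples = n, n_used = 0L,
                reason = "all_removed"))
  }
  list(mean = mean(values[keep]), ok = TRUE, n_samples = n,
       n_used = sum(keep), reason = "")
}

#' Extract the three event epochs from preprocessed traces
#'
#' Computes, per trial, the three pupil measures used by the analysis:
#' `pre_item_mm` (mean over the 0.2 s before item onset), `choice_mm`
#' (mean over 0 to 0.2 s after the choice display, baseline-corrected by
#' subtracting the pre-item mean) and `anticip_change_mm` (mean of the
#' final 0.2 s of the anticipation period minus the mean of its first
#' 0.2 s). Windows are half-open `[start, start + 0.2)` on the sampling
#' grid (8 samples at 40 Hz). Each window passes through [qc_epoch()];
#' flagged windows yield `NA` and a QC flag rather than a value, and
#' `anticip_change_mm` requires both of its sub-windows to pass. The
#' previous trial's condition and the current inter-trial fixation
#' duration are attached as carry-over covariates.
#'
#' @param traces Long trace tibble after blink interpolation and
#'   filtering (an `interpolated` column, if present, counts as invalid
#'   for QC).
#' @param events One row per trial with marker times (`item_onset_s`,
#'   `choice_onset_s`, `anticip_onset_s`, `anticip_offset_s`), as produced
#'   by [simulate_pupil()]. A missing marker flags the trial rather than
#'   dropping it.
#' @param window_s Epoch window length, seconds.
#' @param ... Passed to [qc_epoch()].
#' @return Tibble, one row per trial: the three measures, per-event QC
#'   flags `pre_item_ok` / `choice_ok` / `anticip_ok`, `qc_note`, and
#'   covariates `prev_condition` and `iti_s`.
#' @export
extract_epochs <- function(traces, events, window_s = 0.2, ...) {
  key <- trace_groups(traces)
  if (length(key) == 0) key <- NULL
  split_traces <- dplyr::group_split(
    dplyr::group_by(traces, dplyr::across(dplyr::all_of(key))))
  trace_index <- dplyr::bind_rows(lapply(split_traces, function(tr) tr[1, key]))

  one_trial <- function(i) {
    ev <- events[i, ]
    j <- which(trace_index$participant == ev$participant &
                 trace_index$trial_index == ev$trial_index)
    if (length(j) != 1) {
      return(tibble::tibble(pre_item_mm = NA_real_, choice_mm = NA_real_,
                            anticip_change_mm = NA_real_, pre_item_ok = FALSE,
                            choice_ok = FALSE, anticip_ok = FALSE,
                            qc_note = "missing_trace"))
    }
    tr <- split_traces[[j]]
    invalid <- !tr$valid | (tr$interpolated %||ifcol% FALSE)

    win <- function(start) {
      if (is.na(start)) {
        return(list(mean = NA_real_, ok = FALSE, reason = "missing_marker"))
      }
      sel <- tr$t_s >= start & tr$t_s < start + window_s
      qc_epoch(tr$diameter_mm[sel], invalid[sel], ...)
    }
    pre <- win(ev$item_onset_s - window_s)
    cho <- win(ev$choice_onset_s)
    ant_early <- win(ev$anticip_onset_s)
    ant_late <- win(ev$anticip_offset_s - window_s)
    anticip_ok <- ant_early$ok && ant_late$ok
    notes <- c(pre$reason, cho$reason, ant_early$reason, ant_late$reason)
    tibble::tibble(
      pre_item_mm = pre$mean,
      choice_mm = if (pre$ok && cho$ok) cho$mean - pre$mean else NA_real_,
      anticip_change_mm = if (anticip_ok) ant_late$mean - ant_early$mean
                          else NA_real_,
      pre_item_ok = pre$ok,
      choice_ok = pre$ok && cho$ok,
      anticip_ok = anticip_ok,
      qc_note = paste(unique(notes[notes != ""]), collapse = ";")
    )
  }

  measures <- dplyr::bind_rows(lapply(seq_len(nrow(events)), one_trial))
  out <- dplyr::bind_cols(
    events[, intersect(c("participant", "trial_index", "condition"),
                       names(events))],
    measures
  )
  # carry-over covariates from the trial sequence
  out |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(
      prev_condition = dplyr::lag(.data$condition),
      iti_s = events$item_onset_s[match(
        paste(.data$participant, .data$trial_index),
        paste(events$participant, events$trial_index))]
    ) |>
    dplyr::ungroup()
}

# column-or-default helper: tr$interpolated when the column exists
`%||ifcol%` <- function(x, default) if (is.null(x)) default else x

#' Run the full pupil preprocessing chain
#'
#' Foreshortening hook, blink interpolation, zero-phase low-pass
#' filtering, epoching with QC and baseline correction, in that order.
#'
#' @param traces Raw long trace tibble.
#' @param events Per-trial marker table (see [extract_epochs()]).
#' @param foreshortening_fun Optional correction hook for
#'   [correct_foreshortening()].
#' @param cutoff_hz,order Filter settings for [lowpass_pupil()].
#' @param despike_jump_mm Optional amplitude-jump artifact heuristic:
#'   samples whose first difference exceeds this many mm are marked
#'   invalid before interpolation (a deterministic stand-in for manual
#'   artifact checking). `NULL` disables it.
#' @param ... Passed to [extract_epochs()].
#' @return The epoch tibble from [extract_epochs()].
#' @export
preprocess_pupil <- function(traces, events, foreshortening_fun = NULL,
                             cutoff_hz = 10, order = 4,
                             despike_jump_mm = NULL, ...) {
  traces <- correct_foreshortening(traces, foreshortening_fun)
  if (!is.null(despike_jump_mm)) {
    grp <- trace_groups(traces)
    traces <- traces |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::mutate(valid = .data$valid &
                      c(TRUE, abs(diff(.data$diameter_mm)) <= despike_jump_mm |
                          is.na(diff(.data$diameter_mm)))) |>
      dplyr::ungroup()
  }
  traces <- interpolate_blinks(traces)
  traces <- lowpass_pupil(traces, cutoff_hz = cutoff_hz, order = order)
  extract_epochs(traces, events, ...)
}
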