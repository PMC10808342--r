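#' Von Mises probability density
#'
#' Density of the circular normal distribution with mean 0 and
#' concentration `kappa`, `exp(kappa * cos(x)) / (2 * pi * I0(kappa))`,
#' evaluated with the exponentially scaled Bessel function so large
#' concentrations do not overflow. `kappa = 0` gives the uniform density
#' `1 / (2 * pi)`.
#'
#' @param x_rad Angle(s) in radians.
#' @param kappa Concentration, >= 0.
#' @param mu Mean direction, radians.
#' @return Density value(s).
#' @export
vonmises_density <- function(x_rad, kappa, mu = 0) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0", call. = FALSE)
  exp(kappa * (cos(x_rad - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Log-likelihood of the uniform + von Mises mixture
#'
#' The two-component model of continuous-report recall errors: with
#' probability `1 - p_u` a response is drawn from a zero-mean von Mises
#' with concentration `kappa` (successful retrieval); with probability
#' `p_u` it is uniform on the circle (a guess). Returns the summed log
#' density over the supplied errors, with a machine-tiny floor on the
#' per-trial density so the result is always finite.
#'
#' @param errors_rad Signed recall errors in radians, in (-pi, pi].
#' @param p_u Guess proportion in \[0, 1\].
#' @param kappa Von Mises concentration, >= 0.
#' @return Log-likelihood in nats.
#' @export
mixture_loglik <- function(errors_rad, p_u, kappa) {
  if (length(errors_rad) == 0) stop("no errors supplied", call. = FALSE)
  if (p_u < 0 || p_u > 1) stop("`p_u` must be in [0, 1]", call. = FALSE)
  dens <- (1 - p_u) * vonmises_density(errors_rad, kappa) + p_u / (2 * pi)
  sum(log(pmax(dens, .Machine$double.xmin)))
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit the uniform + von Mises mixture by maximum likelihood
#'
#' Maximizes [mixture_loglik()] over `(p_u, kappa)` with a deterministic
#' multi-start strategy: box-constrained quasi-Newton (`L-BFGS-B`) runs
#' from a grid of starting values (`p_u` in {0.2, 0.5, 0.8} crossed with
#' `kappa` in {2, 8, 32}) on the transformed scale `(logit(p_u),
#' log(kappa))`, and the best converged start wins. The concentration is
#' constrained to `kappa_bounds`; the guess proportion to (0.0025,
#' 0.9975) via the logit bound.
#'
#' @param errors_rad Signed recall errors in radians.
#' @param kappa_bounds Permitted range for the concentration.
#' @param min_trials Minimum number of errors required to attempt a fit.
#' @return An object of class `mixture_fit`: a list with `p_u`, `p_t`
#'   (`= 1 - p_u`), `kappa`, `loglik`, `n_trials`, `converged` and
#'   `n_starts`. Use [tidy()] / [glance()] for tibble output and
#'   [crossover_threshold()] for the density-ratio classification bound.
#' @examples
#' set.seed(1)
#' err <- c(rvonmises(60, 0, 14), runif(40, -pi, pi))
#' fit_mixture(err)
#' @export
fit_mixture <- function(errors_rad, kappa_bounds = c(0.5, 500),
                        min_trials = 10) {
  if (length(errors_rad) < min_trials) {
    stop(sprintf("need at least %d trials to fit the mixture", min_trials),
         call. = FALSE)
  }
  if (any(abs(errors_rad) > pi + 1e-9)) {
    stop("`errors_rad` must be wrapped to (-pi, pi]", call. = FALSE)
  }
  nll <- function(par) {
    -mixture_loglik(errors_rad, inv_logit(par[1]), exp(par[2]))
  }
  starts <- expand.grid(p_u = c(0.2, 0.5, 0.8), kappa = c(2, 8, 32))
  lower <- c(-6, log(kappa_bounds[1]))
  upper <- c(6, log(kappa_bounds[2]))

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(c(logit(starts$p_u[i]), log(starts$kappa[i])), nll,
            method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  if (!any_converged) {
    warning("mixture fit did not converge from any start", call. = FALSE)
  }
  p_u <- inv_logit(best$par[1])
  structure(list(
    p_u = p_u,
    p_t = 1 - p_u,
    kappa = exp(best$par[2]),
    loglik = -best$value,
    n_trials = length(errors_rad),
    converged = any_converged,
    n_starts = nrow(starts)
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> p_t = %.3f, kappa = %.2f (loglik %.2f, n = %d%s)\n",
    x$p_t, x$kappa, x$loglik, x$n_trials,
    if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p_t", "p_u", "kappa"),
    estimate = c(x$p_t, x$p_u, x$kappa)
  )
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    p_t = x$p_t, p_u = x$p_u, kappa = x$kappa,
    loglik = x$loglik, n_trials = x$n_trials,
    converged = x$converged, n_starts = x$n_starts
  )
}

#' Fit the mixture per participant and condition
#'
#' Maps [fit_mixture()] over every participant-by-condition cell of a
#' trial table (and optionally the aggregate of all trials), returning one
#' tidy row per fit.
#'
#' @param trials Tibble with `participant`, `condition` and `error_deg`.
#' @param ... Passed to [fit_mixture()].
#' @return Tibble with `participant`, `condition` and the [glance()]
#'   columns of each fit. Cells whose fit errors (e.g. too few trials) are
#'   dropped with a message.
#' @export
fit_mixture_by <- function(trials, ...) {
  trials |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      fit <- tryCatch(fit_mixture(deg2rad(df$error_deg), ...),
                      error = function(e) {
                        message(sprintf("skipping %s/%s: %s",
                                        key$participant, key$condition,
                                        conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) tibble::tibble() else glance(fit)
    }) |>
    dplyr::ungroup()
}

#' Density-ratio crossover threshold of a mixture fit
#'
#' The absolute error at which the weighted von Mises component density
#' equals the uniform component density, `(1 - p_u) * f_vm(x; kappa) =
#' p_u / (2 * pi)`, found by bracketed root-finding on (0, pi). Errors
#' smaller than the threshold are more likely under successful retrieval
#' than under guessing and are classified as correct. Degenerate cases:
#' if the von Mises component dominates everywhere the threshold is `Inf`
#' (every trial correct); if nowhere, 0.
#'
#' @param fit A `mixture_fit`, or anything with `p_u` and `kappa` fields.
#' @return Threshold in degrees (scalar; possibly 0 or `Inf`).
#' @export
crossover_threshold <- function(fit) {
  p_u <- fit$p_u
  kappa <- fit$kappa
  if (p_u <= 0) {
    warning("p_u <= 0: von Mises dominates everywhere", call. = FALSE)
    return(Inf)
  }
  if (p_u >= 1 || kappa <= 0) {
    warning("degenerate fit: uniform dominates everywhere", call. = FALSE)
    return(0)
  }
  g <- function(x) (1 - p_u) * vonmises_density(x, kappa) - p_u / (2 * pi)
  if (g(0) <= 0) return(0)       # von Mises never exceeds the uniform
  if (g(pi) >= 0) return(Inf)    # von Mises exceeds it on the whole circle
  root <- uniroot(g, c(0, pi), tol = 1e-10)$root
  rad2deg(root)
}

#' Classify trials and score trial-level precision
#'
#' `classify_trials()` marks a trial correct when its absolute recall
#' error does not exceed the density-ratio threshold (ties count as
#' correct). `trial_precision()` scores the correct trials as the inverse
#' absolute error in 1/degrees, so higher values mean more precise
#' retrieval; absolute errors below `cap_deg` are capped at
#' `1 / cap_deg` to keep zero-error trials finite. Incorrect trials get
#' `NA` precision.
#'
#' @param errors_deg Signed recall errors in degrees.
#' @param threshold_deg Threshold from [crossover_threshold()].
#' @param correct Logical vector from `classify_trials()`.
#' @param cap_deg Absolute errors below this are treated as `cap_deg`.
#' @return `classify_trials()`: logical vector. `trial_precision()`:
#'   numeric vector in 1/degrees.
#' @export
classify_trials <- function(errors_deg, threshold_deg) {
  abs(errors_deg) <= threshold_deg
}

#' @rdname classify_trials
#' @export
trial_precision <- function(errors_deg, correct, cap_deg = 0.5) {
  ifelse(correct, 1 / pmax(abs(errors_deg), cap_deg), NA_real_)
}
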