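#' Draw from a von Mises distribution
#'
#' Random deviates from the circular normal distribution with mean
#' direction `mu` and concentration `kappa`, via the Best-Fisher rejection
#' sampler (wrapped-Cauchy envelope). `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of deviates.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, >= 0.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (kappa == 0) {
    theta <- runif(n, -pi, pi)
  } else {
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    theta <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u1 <- runif(1); u2 <- runif(1)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
          theta[i] <- sign(runif(1) - 0.5) * acos(f)
          break
        }
      }
    }
  }
  out <- (theta + mu + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Simulate recall responses from the two-component mixture
#'
#' For each design trial the retrieval outcome is drawn from the generative
#' model the analysis assumes: with probability `p_t(condition)` the signed
#' recall error comes from a zero-mean von Mises distribution with
#' concentration `kappa(condition)` (successful retrieval); otherwise the
#' response is uniform on the circle (a guess). Study-phase item
#' classification is simulated as an independent Bernoulli with the
#' configured accuracy; downstream fitting uses only correctly classified
#' trials.
#'
#' @param design Trial table from [generate_design()].
#' @param config The [sim_config()] used to build `design`.
#' @param seed Integer seed; defaults to `config$seed + 1` so design and
#'   responses come from distinct, reproducible streams.
#' @return `design` with columns added: `retrieval_success` (latent
#'   generative component), `error_deg` (signed, in (-180, 180]),
#'   `response_deg` (position on the circle, in (0, 360]), and
#'   `classified_correct`.
#' @examples
#' cfg <- sim_config(n_participants = 1, seed = 7)
#' trials <- simulate_recall(generate_design(cfg), cfg)
#' mean(abs(trials$error_deg) <= 33)
#' @export
simulate_recall <- function(design, config, seed = config$seed + 1L) {
  validate_sim_config(config)
  set.seed(seed)
  n <- nrow(design)
  p_t <- ifelse(design$condition == "reward",
                config$p_t_reward, config$p_t_neutral)
  success <- runif(n) < p_t

  err <- numeric(n)
  for (cond in c("reward", "neutral")) {
    kap <- if (cond == "reward") config$kappa_reward else config$kappa_neutral
    idx <- which(success & design$condition == cond)
    if (length(idx)) err[idx] <- rvonmises(length(idx), 0, kap)
  }
  guess <- which(!success)
  if (length(guess)) err[guess] <- runif(length(guess), -pi, pi)

  design |>
    dplyr::mutate(
      retrieval_success = success,
      error_deg = wrap_signed_deg(rad2deg(err)),
      response_deg = wrap_position_deg(.data$target_angle_deg + rad2deg(err)),
      classified_correct = runif(n) < config$class_accuracy
    )
}
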