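test_that("von Mises density matches a power-series Bessel oracle", {
  expect_equal(vonmises_density(0, 0), 1 / (2 * pi), tolerance = 1e-12)
  # oracle: I0 by power series, density = exp(k cos x) / (2 pi I0(k))
  for (kappa in c(0.5, 2, 13.67)) {
    for (x in c(0, 0.4, pi / 2, pi)) {
      oracle <- exp(kappa * cos(x)) / (2 * pi * i0_series(kappa))
      expect_equal(vonmises_density(x, kappa), oracle, tolerance = 1e-10)
    }
  }
  expect_equal(vonmises_density(0, 2), 0.5159, tolerance = 1e-4)
  expect_error(vonmises_density(0, -1), "kappa")
})

test_that("von Mises density normalizes to 1 over the circle", {
  for (kappa in c(0, 1, 13.67, 200)) {
    z <- integrate(vonmises_density, -pi, pi, kappa = kappa,
                   rel.tol = 1e-12)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
})

test_that("mixture log-likelihood agrees with direct evaluation", {
  err <- c(0.3, -1.2, 2.9)
  # pure uniform: n * log(1/2pi), for any kappa
  expect_equal(mixture_loglik(err, 1, 5), 3 * log(1 / (2 * pi)),
               tolerance = 1e-12)
  # p_u = 0, kappa = 0 also reduces to the uniform
  expect_equal(mixture_loglik(err, 0, 0), mixture_loglik(err, 1, 3),
               tolerance = 1e-12)
  # hand-computed sum at p_u = 0.5, kappa = 2 with the series oracle
  errs <- c(0, pi / 2, pi)
  dens <- 0.5 * exp(2 * cos(errs)) / (2 * pi * i0_series(2)) +
    0.5 / (2 * pi)
  expect_equal(mixture_loglik(errs, 0.5, 2), sum(log(dens)),
               tolerance = 1e-10)
  expect_error(mixture_loglik(numeric(0), 0.5, 2), "no errors")
  expect_error(mixture_loglik(errs, 1.4, 2), "p_u")
})

test_that("maximum-likelihood fit recovers pure-component data", {
  set.seed(71)
  uniform <- runif(10000, -pi, pi)
  fit_u <- fit_mixture(uniform)
  expect_lte(fit_u$p_t, 0.05)

  vm <- rvonmises(10000, 0, 15)
  fit_v <- fit_mixture(vm)
  expect_gte(fit_v$p_t, 0.95)
  expect_gt(fit_v$kappa, 13.5)
  expect_lt(fit_v$kappa, 16.5)
  expect_true(fit_v$converged)
  expect_error(fit_mixture(vm[1:5]), "at least")
})

test_that("fitted likelihood beats a dense grid-search oracle", {
  for (seed in c(72, 73, 74)) {
    set.seed(seed)
    err <- c(rvonmises(250, 0, 13.67), runif(180, -pi, pi))
    fit <- fit_mixture(err)
    grid <- expand.grid(p_u = seq(0.005, 0.995, length.out = 200),
                        kappa = exp(seq(log(0.5), log(500),
                                        length.out = 200)))
    best <- -Inf
    for (kap in unique(grid$kappa)) {
      vm <- vonmises_density(err, kap)
      for (pu in unique(grid$p_u)) {
        ll <- sum(log((1 - pu) * vm + pu / (2 * pi)))
        if (ll > best) best <- ll
      }
    }
    expect_gte(fit$loglik + 1e-8, best)
    # and never below the generating parameters on the same data
    expect_gte(fit$loglik, mixture_loglik(err, 180 / 430, 13.67))
  }
})

test_that("parameter recovery at study-scale trial counts is calibrated", {
  # 200 simulated datasets of 42 trials at the reward-condition values
  set.seed(75)
  p_t <- 0.58; kappa <- 13.67
  fits <- t(replicate(200, {
    n_succ <- rbinom(1, 42, p_t)
    err <- c(rvonmises(n_succ, 0, kappa), runif(42 - n_succ, -pi, pi))
    f <- fit_mixture(err)
    c(p_t = f$p_t, kappa = f$kappa)
  }))
  expect_lt(abs(median(fits[, "p_t"]) - p_t), 0.03)
  kap_med <- median(fits[, "kappa"])
  expect_lt(abs(kap_med - kappa) / kappa, 0.20)
  # report the small-sample concentration bias rather than hiding it
  cat(sprintf("\n  kappa median at n=42: %.2f (truth %.2f, bias %+.1f%%)\n",
              kap_med, kappa, 100 * (kap_med - kappa) / kappa))
})

test_that("crossover threshold solves the density-ratio equation", {
  # closed-form oracle: cos(x*) = (log(p_u/(1-p_u)) + log I0(k)) / k
  closed_form <- function(p_u, kappa) {
    c0 <- log(p_u / (1 - p_u)) +
      log(besselI(kappa, 0, TRUE)) + kappa
    rad2deg(acos(c0 / kappa))
  }
  fit <- list(p_u = 0.435, kappa = 15.3)
  thr <- crossover_threshold(fit)
  expect_equal(thr, closed_form(0.435, 15.3), tolerance = 1e-6)
  expect_gt(thr, 33); expect_lt(thr, 34.5)

  # monotone: larger kappa or larger p_u shrink the threshold
  kaps <- c(2, 5, 10, 20, 50, 100)
  ths <- sapply(kaps, function(k) crossover_threshold(list(p_u = 0.4, kappa = k)))
  expect_true(all(diff(ths) < 0))
  pus <- seq(0.1, 0.9, by = 0.1)
  ths2 <- sapply(pus, function(p) crossover_threshold(list(p_u = p, kappa = 15)))
  expect_true(all(diff(ths2) < 0))

  # degenerate limits
  expect_warning(thr0 <- crossover_threshold(list(p_u = 0, kappa = 15)))
  expect_equal(thr0, Inf)
  expect_warning(thr1 <- crossover_threshold(list(p_u = 1, kappa = 15)))
  expect_equal(thr1, 0)
  # tiny p_u: von Mises dominates the whole circle
  expect_equal(crossover_threshold(list(p_u = 1e-8, kappa = 5)), Inf)
})

test_that("trial classification and precision follow the threshold", {
  flags <- classify_trials(c(-33, 33, -34, 34), 33)
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE))
  prec <- trial_precision(c(0, 10, 50), c(TRUE, TRUE, FALSE))
  expect_equal(prec, c(2, 0.1, NA_real_))

  # classified-correct fraction matches the mixture mass inside the threshold
  set.seed(76)
  p_t <- 0.58; kappa <- 13.67
  n <- 10000
  n_succ <- rbinom(1, n, p_t)
  err <- rad2deg(c(rvonmises(n_succ, 0, kappa), runif(n - n_succ, -pi, pi)))
  fit <- fit_mixture(deg2rad(err))
  thr <- crossover_threshold(fit)
  frac <- mean(classify_trials(err, thr))
  mass <- 2 * integrate(function(x) p_t * vonmises_density(x, kappa) +
                          (1 - p_t) / (2 * pi),
                        0, deg2rad(thr), rel.tol = 1e-10)$value
  expect_equal(frac, mass, tolerance = 3 * sqrt(mass * (1 - mass) / n))
})

test_that("per-cell fitting returns tidy rows and skips sparse cells", {
  cfg <- sim_config(n_participants = 3, seed = 78)
  trials <- simulate_recall(generate_design(cfg), cfg)
  fits <- fit_mixture_by(trials)
  expect_equal(nrow(fits), 6)
  expect_true(all(c("participant", "condition", "p_t", "kappa",
                    "loglik", "converged") %in% names(fits)))
  expect_true(all(fits$p_t >= 0 & fits$p_t <= 1))
  # a sparse cell is skipped with a message, not an error
  sparse <- trials[trials$participant == 1 & trials$condition == "reward", ][1:4, ]
  expect_message(out <- fit_mixture_by(dplyr::bind_rows(
    trials[trials$participant == 2, ], sparse)), "skipping")
  expect_equal(nrow(out), 2)
})

test_that("tidy and glance methods expose the fit as tibbles", {
  set.seed(79)
  fit <- fit_mixture(c(rvonmises(80, 0, 12), runif(40, -pi, pi)))
  td <- tidy(fit)
  expect_equal(td$term, c("p_t", "p_u", "kappa"))
  expect_equal(sum(td$estimate[1:2]), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_trials, 120)
  expect_true(is.finite(gl$loglik))
})
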