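#' Two-tailed paired-samples t-test with Bayes factor
#'
#' Classical paired t-test on the within-participant differences, reported
#' as a one-row tibble with mean difference, SEM, 95 percent CI, t, df,
#' two-sided p, and the JZS Bayes factor from [jzs_bf10()] (default Cauchy
#' prior scale r = 0.707).
#'
#' @param x,y Equal-length paired numeric vectors (e.g. reward and neutral
#'   condition values per participant). Pairs with missing values are
#'   dropped.
#' @param r Cauchy prior scale for the Bayes factor.
#' @return Tibble: `n`, `mean_diff`, `sem`, `ci_lo`, `ci_hi`, `t_stat`,
#'   `df`, `p_value`, `bf10`, `evidence`.
#' @examples
#' paired_ttest(c(1, 2, 3, 5), c(0, 1, 1, 2))
#' @export
paired_ttest <- function(x, y, r = 0.707) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  keep <- complete.cases(x, y)
  d <- (x - y)[keep]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(d) == 0) stop("differences have zero variance", call. = FALSE)
  tt <- t.test(d)
  t_stat <- unname(tt$statistic)
  bf <- jzs_bf10(t_stat, n, r = r)
  tibble::tibble(
    n = n,
    mean_diff = mean(d),
    sem = sd(d) / sqrt(n),
    ci_lo = tt$conf.int[1],
    ci_hi = tt$conf.int[2],
    t_stat = t_stat,
    df = n - 1,
    p_value = tt$p.value,
    bf10 = bf,
    evidence = bf_evidence_label(bf)
  )
}

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayes factor comparing the alternative (Cauchy prior with scale
#' `r` on standardized effect size) against the point null, computed by
#' adaptive quadrature of the Zellner-Siow marginal likelihood: the
#' g-prior mixture integral over the inverse-gamma(1/2, r^2/2) density.
#' `jzs_bf01()` is the reciprocal evidence for the null.
#'
#' @param t_stat Observed t statistic.
#' @param n Number of (paired) observations; degrees of freedom `n - 1`.
#' @param r Cauchy prior scale (default 0.707, i.e. sqrt(2)/2).
#' @return The Bayes factor (positive scalar).
#' @examples
#' jzs_bf10(3.0, 36)
#' @export
jzs_bf10 <- function(t_stat, n, r = 0.707) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  nu <- n - 1
  marg1 <- integrate(
    function(g) {
      (1 + n * g * r^2)^(-0.5) *
        (1 + t_stat^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
        (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
    },
    lower = 0, upper = Inf, rel.tol = 1e-10, abs.tol = 0
  )
  if (marg1$message != "OK") {
    stop("JZS integration failed: ", marg1$message, call. = FALSE)
  }
  marg0 <- (1 + t_stat^2 / nu)^(-(nu + 1) / 2)
  marg1$value / marg0
}

#' @rdname jzs_bf10
#' @export
jzs_bf01 <- function(t_stat, n, r = 0.707) 1 / jzs_bf10(t_stat, n, r = r)

#' Verbal evidence category for a Bayes factor
#'
#' Conventional Jeffreys-style labels: anecdotal (1-3), moderate (3-10),
#' strong (10-100) and extreme (>100) evidence for the alternative, with
#' the mirrored categories below 1 supporting the null.
#'
#' @param bf10 Bayes factor(s) for the alternative over the null.
#' @return Character vector of labels.
#' @examples
#' bf_evidence_label(c(0.27, 73.5))
#' @export
bf_evidence_label <- function(bf10) {
  side <- ifelse(bf10 >= 1, "alternative", "null")
  b <- ifelse(bf10 >= 1, bf10, 1 / bf10)
  strength <- cut(b, c(1, 3, 10, 100, Inf),
                  labels = c("anecdotal", "moderate", "strong", "extreme"),
                  right = FALSE)
  ifelse(b == 1, "no evidence",
         paste(as.character(strength), "evidence for", side))
}

#' Per-participant regression slopes with a group-level test
#'
#' A transparent two-stage summary of trial-level associations: an
#' ordinary least-squares regression of `outcome` on `predictors` within
#' each participant, then a one-sample t-test (with JZS Bayes factor) of
#' the per-participant slopes against zero. Participants with too few
#' usable trials or a rank-deficient design (e.g. a constant predictor)
#' are dropped and listed.
#'
#' @param trials Trial-level tibble including a `participant` column.
#' @param outcome Name of the outcome column (string).
#' @param predictors Character vector of predictor column names; the
#'   group-level test is reported for the first one.
#' @param min_trials Minimum complete trials per participant.
#' @return A list with `slopes` (tibble: participant x term estimates),
#'   `group` (one-row tibble: mean slope, SEM, t, df, p, bf10 for the
#'   first predictor) and `dropped` (participant ids).
#' @export
per_participant_slopes <- function(trials, outcome, predictors,
                                   min_trials = 5) {
  fml <- stats::as.formula(
    paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit_one <- function(df) {
    df <- df[complete.cases(df[, c(outcome, predictors)]), , drop = FALSE]
    if (nrow(df) < min_trials) return(NULL)
    X <- stats::model.matrix(fml, df)
    if (qr(X)$rank < ncol(X)) return(NULL)
    fit <- lm(fml, data = df)
    tibble::tibble(term = names(coef(fit)), estimate = unname(coef(fit)),
                   n_trials = nrow(df))
  }
  pieces <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(function(df, key) {
      res <- fit_one(df)
      if (is.null(res)) {
        return(tibble::tibble(participant = key$participant, dropped = TRUE))
      }
      dplyr::mutate(res, participant = key$participant, dropped = FALSE)
    })
  pieces <- dplyr::bind_rows(pieces)
  dropped <- unique(pieces$participant[pieces$dropped])
  slopes <- dplyr::filter(pieces, !.data$dropped) |>
    dplyr::select("participant", "term", "estimate", "n_trials")
  b1 <- dplyr::filter(slopes, .data$term == predictors[1])$estimate
  if (length(b1) < 3) stop("fewer than 3 participants with usable fits",
                           call. = FALSE)
  tt <- t.test(b1)
  t_stat <- unname(tt$statistic)
  group <- tibble::tibble(
    term = predictors[1],
    n = length(b1),
    mean_slope = mean(b1),
    sem = sd(b1) / sqrt(length(b1)),
    t_stat = t_stat,
    df = length(b1) - 1,
    p_value = tt$p.value,
    bf10 = jzs_bf10(t_stat, length(b1))
  )
  list(slopes = slopes, group = group, dropped = dropped)
}
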