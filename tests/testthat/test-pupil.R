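make_trace <- function(values, valid = rep(TRUE, length(values)), fs = 40) {
  tibble::tibble(t_s = (seq_along(values) - 1) / fs,
                 diameter_mm = ifelse(valid, values, NA_real_),
                 valid = valid)
}

test_that("blink interpolation is the identity on clean traces", {
  tr <- make_trace(rnorm(200, 5, 0.1))
  out <- interpolate_blinks(tr)
  expect_identical(out$diameter_mm, tr$diameter_mm)
  expect_false(any(out$interpolated))
})

test_that("a blink in a constant trace interpolates to the constant", {
  valid <- rep(TRUE, 100); valid[40:42] <- FALSE
  tr <- make_trace(rep(5, 100), valid)
  out <- interpolate_blinks(tr)
  expect_true(all(out$diameter_mm == 5))
  expect_true(all(out$interpolated[40:42]))
})

test_that("interpolated samples lie on the line between anchors", {
  # 40-Hz ramp 4.0 -> 5.0; gap widened by 4 samples before, 16 after
  n <- 200
  ramp <- seq(4, 5, length.out = n)
  valid <- rep(TRUE, n); valid[80:85] <- FALSE
  out <- interpolate_blinks(make_trace(ramp, valid))
  widened <- 76:101  # 100 ms pre = 4 samples, 400 ms post = 16 samples
  expect_true(all(out$interpolated[widened]))
  expect_false(any(out$interpolated[-widened]))
  # anchors sit on the ramp, so the fill reproduces it
  expect_equal(out$diameter_mm, ramp, tolerance = 1e-12)
  # samples outside the widened window are bit-identical
  expect_identical(out$diameter_mm[-widened], ramp[-widened])
})

test_that("a blink at the trace edge extends from the nearest valid sample", {
  valid <- rep(TRUE, 60); valid[1:5] <- FALSE
  vals <- seq(5, 6, length.out = 60)
  out <- interpolate_blinks(make_trace(vals, valid))
  filled <- which(out$interpolated)
  expect_equal(min(filled), 1)
  first_anchor <- min(which(!out$interpolated))
  expect_true(all(out$diameter_mm[filled] == vals[first_anchor]))
})

test_that("zero-phase filter preserves DC and is symmetric", {
  const <- make_trace(rep(4.2, 400))
  out <- lowpass_pupil(const)
  expect_lt(max(abs(out$diameter_mm - 4.2)), 1e-8)

  imp <- rep(0, 401); imp[201] <- 1
  resp <- lowpass_pupil(make_trace(imp))$diameter_mm
  expect_equal(resp, rev(resp), tolerance = 1e-10)

  expect_error(lowpass_pupil(make_trace(rep(1, 10))), "samples")
  expect_error(lowpass_pupil(make_trace(c(1, NA, rep(1, 40)))), "NA")
})

test_that("a 15-Hz tone is attenuated by the squared Butterworth gain", {
  fs <- 40; f <- 15
  t <- (0:4799) / fs
  tone <- make_trace(sin(2 * pi * f * t), fs = fs)
  out <- lowpass_pupil(tone, cutoff_hz = 10, order = 4)
  mid <- t > 20 & t < 100
  amp <- sqrt(2 * mean(out$diameter_mm[mid]^2))
  # analytic magnitude of the bilinear-transform Butterworth, squared by
  # the forward-backward pass
  gain <- 1 / (1 + (tan(pi * f / fs) / tan(pi * 10 / fs))^(2 * 4))
  expect_equal(amp, gain, tolerance = 0.02)
})

test_that("epochs from a constant trace give zero change measures", {
  fx <- const_trace(5.7)
  ep <- extract_epochs(interpolate_blinks(fx$traces), fx$events)
  expect_equal(ep$pre_item_mm, 5.7)
  expect_equal(ep$choice_mm, 0)
  expect_equal(ep$anticip_change_mm, 0)
  expect_true(ep$pre_item_ok && ep$choice_ok && ep$anticip_ok)
})

test_that("a constructed anticipation ramp is recovered as the change", {
  fx <- const_trace(5.0)
  tr <- fx$traces
  # add 0.10 mm linearly across the anticipation window, flat at the ends
  a_on <- fx$events$anticip_onset_s; a_off <- fx$events$anticip_offset_s
  sel <- tr$t_s >= a_on + 0.2 & tr$t_s < a_off - 0.2
  tr$diameter_mm[sel] <- 5 + 0.10 * (tr$t_s[sel] - (a_on + 0.2)) /
    (a_off - 0.2 - (a_on + 0.2))
  tr$diameter_mm[tr$t_s >= a_off - 0.2] <- 5.10
  ep <- extract_epochs(interpolate_blinks(tr), fx$events)
  expect_equal(ep$anticip_change_mm, 0.10, tolerance = 1e-9)
})

test_that("baseline correction is exact subtraction", {
  fx <- const_trace(5.0)
  set.seed(81)
  tr <- fx$traces
  tr$diameter_mm <- tr$diameter_mm + rnorm(nrow(tr), 0, 0.05)
  ep1 <- extract_epochs(interpolate_blinks(tr), fx$events)
  tr2 <- tr; tr2$diameter_mm <- tr2$diameter_mm + 1.3
  ep2 <- extract_epochs(interpolate_blinks(tr2), fx$events)
  expect_equal(ep2$pre_item_mm, ep1$pre_item_mm + 1.3, tolerance = 1e-12)
  expect_equal(ep2$choice_mm, ep1$choice_mm, tolerance = 1e-12)
  expect_equal(ep2$anticip_change_mm, ep1$anticip_change_mm,
               tolerance = 1e-12)
})

test_that("epoch QC applies the strict majority and 3-SD rules", {
  # 5 of 8 invalid -> excluded; exactly 4 of 8 -> retained
  bad <- qc_epoch(rep(5, 8), c(rep(TRUE, 5), rep(FALSE, 3)))
  expect_false(bad$ok)
  expect_equal(bad$reason, "invalid_fraction")
  half <- qc_epoch(rep(5, 8), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_true(half$ok)

  # {5,5,5,5,5,50}: z(50) = 2.04 < 3, so nothing is removed
  kept <- qc_epoch(c(5, 5, 5, 5, 5, 50))
  expect_equal(kept$n_used, 6)
  expect_equal(kept$mean, mean(c(5, 5, 5, 5, 5, 50)))

  # a clear spurious sample is removed before averaging
  spur <- qc_epoch(c(rep(5, 30), 50))
  expect_equal(spur$n_used, 30)
  expect_equal(spur$mean, 5)

  expect_false(qc_epoch(numeric(0))$ok)
})

test_that("missing markers flag the trial instead of dropping it", {
  fx <- const_trace(5.0)
  ev <- fx$events
  ev$anticip_offset_s <- NA_real_
  ep <- extract_epochs(interpolate_blinks(fx$traces), ev)
  expect_equal(nrow(ep), 1)
  expect_false(ep$anticip_ok)
  expect_true(ep$pre_item_ok)
  expect_match(ep$qc_note, "missing_marker")
})

test_that("epoch retention is full on clean data, high with blinks", {
  clean <- sim_config(n_participants = 2, blink_rate_hz = 0, seed = 82)
  d <- generate_design(clean)[1:30, ]
  ps <- simulate_pupil(d, clean)
  ep <- preprocess_pupil(ps$traces, ps$events)
  expect_true(all(ep$pre_item_ok & ep$choice_ok & ep$anticip_ok))

  blinky <- sim_config(n_participants = 2, seed = 83)
  d2 <- generate_design(blinky)
  ps2 <- simulate_pupil(d2, blinky)
  ep2 <- preprocess_pupil(ps2$traces, ps2$events)
  retention <- mean(ep2$anticip_ok)
  expect_gte(retention, 0.80)
  expect_lte(retention, 1.0)
})
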