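test_that("bleach correction cancels shared decay and preserves evoked signal", {
  # stim identical to the single blank: output is the blank grand mean
  fr <- const_frames(8, 10, 20) * rep(exp(-(0:19) / 10), each = 80)
  stim <- make_stack(fr)
  blank <- make_stack(fr)
  out <- bleach_correct(stim, list(blank))
  expect_equal(out$frames, array(mean(fr), dim(fr)), tolerance = 1e-12)

  # shared noiseless decay cancels; the blob survives
  cfg <- clean_config(bleach_tau_s = 20,
                      blobs = list(elec_5p_100uA = list(
                        center = c(10, 8), sigma_px = 3, peak_dFF = 0.1)))
  st <- generate_trial(cfg, electrical_stimulus(), seed = 1)
  bl <- generate_trial(cfg, blank_stimulus(), seed = 2)
  corr <- bleach_correct(st, list(bl))
  # baseline frames are flat in time after correction
  base <- corr$frames[, , 1:10]
  expect_lt(max(apply(base, c(1, 2), sd)), 1e-9 * mean(base))
  # evoked frames exceed baseline at the blob centre
  expect_gt(corr$frames[8, 10, 15], corr$frames[8, 10, 1] * 1.05)
  expect_equal(corr$trial_id, st$trial_id)

  expect_error(bleach_correct(stim, list()), "blank")
  short <- make_stack(const_frames(8, 10, 19))
  expect_error(bleach_correct(stim, list(short)), "shape")
})

test_that("differential images implement windowed ratio minus one", {
  # temporally constant stack: dff is zero
  st <- make_stack(const_frames(8, 10, 25))
  expect_equal(max(abs(differential_image(st))), 0)

  # baseline 100, stimulus window 110: dff = 0.10; doubling gives 1.0
  fr <- const_frames(8, 10, 25, 100)
  fr[, , 13:18] <- 110
  fr[5, 5, 13:18] <- 200
  d <- differential_image(make_stack(fr))
  expect_equal(d[1, 1], 0.10, tolerance = 1e-12)
  expect_equal(d[5, 5], 1.0, tolerance = 1e-12)

  # empty or out-of-range window errors
  expect_error(differential_image(make_stack(const_frames(4, 4, 12)),
                                  analysis_windows(stim_start_s = 2,
                                                   stim_end_s = 3)),
               "window")
  expect_error(analysis_windows(stim_start_s = 1.5, stim_end_s = 0.5))
})

test_that("differential images are invariant to global rescaling", {
  cfg <- small_config()
  st <- generate_trial(cfg, blank_stimulus(), seed = 9)
  d1 <- differential_image(st)
  st2 <- st
  st2$frames <- st$frames * 7.3
  d2 <- differential_image(st2)
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
})

test_that("band-pass filter matches its closed-form transfer function", {
  p <- filter_params()
  mm <- 0.02
  # constant image: DC fully rejected
  out <- bandpass_filter(matrix(5, 64, 64), p, mm_per_px = mm)
  expect_lt(max(abs(out)), 5 * 1e-10)

  # periodic sinusoids are attenuated by H(f) within 1%
  H <- function(f) exp(-f^2 / (2 * p$sigma_hi_per_mm^2)) *
    (1 - exp(-f^2 / (2 * p$sigma_lo_per_mm^2)))
  for (k in c(2, 8, 16, 24)) {
    img <- matrix(rep(sin(2 * pi * k * (0:63) / 64), each = 64), 64, 64)
    f0 <- (k / 64) / mm
    got <- max(abs(bandpass_filter(img, p, mm_per_px = mm)))
    expect_equal(got, H(f0), tolerance = 0.01)
  }

  # white noise loses variance (H <= 1 everywhere, H(0) = 0)
  set.seed(1)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(var(as.vector(bandpass_filter(noise, p, mm_per_px = mm))),
            var(as.vector(noise)))

  expect_error(bandpass_filter(matrix(c(NA, 1, 2, 3), 2, 2), p,
                               mm_per_px = mm), "finite")
})

test_that("band-pass filter is linear", {
  set.seed(2)
  x <- matrix(rnorm(32 * 48), 32, 48)
  y <- matrix(rnorm(32 * 48), 32, 48)
  p <- filter_params()
  lhs <- bandpass_filter(2.5 * x - 1.3 * y, p, mm_per_px = 0.02)
  rhs <- 2.5 * bandpass_filter(x, p, mm_per_px = 0.02) -
    1.3 * bandpass_filter(y, p, mm_per_px = 0.02)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("trial averaging is the pixel-wise mean", {
  a <- matrix(1:12, 3, 4)
  expect_equal(unclass(average_trials(list(a))), a, ignore_attr = TRUE)
  expect_equal(max(abs(average_trials(list(a, -a)))), 0)
  expect_error(average_trials(list(a, matrix(0, 2, 2))), "shape")

  # seeded noisy copies concentrate around the noiseless blob
  set.seed(3)
  blob <- 0.05 * exp(-outer((1:10 - 5)^2, (1:10 - 5)^2, "+") / 8)
  sdn <- 0.01
  copies <- lapply(1:10, function(i) blob + matrix(rnorm(100, sd = sdn), 10))
  avg <- average_trials(copies)
  se <- sdn / sqrt(10)
  expect_true(mean(abs(avg - blob) <= 3 * se) >= 0.95)
  expect_true(all(abs(avg - blob) <= 5 * se))
  expect_equal(attr(avg, "n"), 10L)
})

test_that("pixel t-test equals the textbook pooled statistic", {
  set.seed(4)
  h <- 8; w <- 8
  stim <- lapply(1:5, function(i) matrix(rnorm(h * w, mean = 0.01), h, w))
  blank <- lapply(1:6, function(i) matrix(rnorm(h * w), h, w))
  map <- pixel_ttest(stim, blank, alpha = 0.01)
  for (px in seq_len(h * w)) {
    r <- ((px - 1) %% h) + 1; c <- ((px - 1) %/% h) + 1
    x <- vapply(stim, function(m) m[r, c], numeric(1))
    y <- vapply(blank, function(m) m[r, c], numeric(1))
    expect_equal(map$t_stat[r, c], oracle_pooled_t(x, y),
                 tolerance = 1e-12)
    expect_equal(map$p_value[r, c],
                 2 * pt(-abs(oracle_pooled_t(x, y)), 9),
                 tolerance = 1e-12)
  }
  # hand-computed case: {1,2,3,4} vs the same shifted by 10
  s2 <- lapply(c(11, 12, 13, 14), function(v) matrix(v, 1, 1))
  b2 <- lapply(c(1, 2, 3, 4), function(v) matrix(v, 1, 1))
  m2 <- pixel_ttest(s2, b2)
  expect_equal(m2$t_stat[1, 1],
               10 / sqrt(var(c(1, 2, 3, 4)) * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
})

test_that("pixel t-test symmetry and degeneracies behave", {
  set.seed(5)
  g1 <- lapply(1:4, function(i) matrix(rnorm(16), 4, 4))
  g2 <- lapply(1:4, function(i) matrix(rnorm(16), 4, 4))
  a <- pixel_ttest(g1, g2)
  b <- pixel_ttest(g2, g1)
  expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # identical groups: nothing significant
  same <- pixel_ttest(g1, g1)
  expect_false(any(same$sig_mask))
  expect_true(all(same$p_value == 1))

  # zero variance in both groups
  c1 <- lapply(1:3, function(i) matrix(1, 2, 2))
  c2 <- lapply(1:3, function(i) matrix(c(1, 2, 1, 2), 2, 2))
  m <- pixel_ttest(c1, c2)
  expect_equal(m$p_value[1, 1], 1)  # equal constants
  expect_equal(m$p_value[2, 1], 0)  # different constants

  expect_error(pixel_ttest(g1[1], g2), "at least 2")
})

test_that("overlays colorize exactly the masked pixels", {
  anatomy <- matrix(seq(0, 1, length.out = 20), 4, 5)
  none <- fake_map(matrix(0.05, 4, 5), matrix(FALSE, 4, 5))
  rgb0 <- make_overlay(none, anatomy)
  for (ch in 1:3) expect_equal(rgb0[, , ch], anatomy)

  all_sig <- fake_map(matrix(0.05, 4, 5), matrix(TRUE, 4, 5))
  rgb1 <- make_overlay(all_sig, anatomy)
  expect_true(all(rgb1[, , 1] == 1) && all(rgb1[, , 3] == 0))

  one <- matrix(FALSE, 4, 5); one[2, 3] <- TRUE
  rgb2 <- make_overlay(fake_map(matrix(0.05, 4, 5), one), anatomy)
  colored <- rgb2[, , 1] != anatomy
  expect_equal(which(colored), which(one))

  expect_error(make_overlay(none, matrix(0, 2, 2)), "shape")
})
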