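test_that("chase simulation follows half-life arithmetic in the noise-free limit", {
  sim <- simulate_chase_series(chase_sim_config(
    I0 = 100, decay_rates = c(CHX = log(2) / 2), timepoints = c(0, 2, 4),
    noise_cv = 0, n_replicates = 2))
  m <- sim$measurements
  corrected <- m$band_mean - m$background_mean
  expect_equal(unique(corrected[m$timepoint == 2]), 50)
  expect_equal(unique(corrected[m$timepoint == 4]), 25)
  # no decay: all timepoints at I0
  s0 <- simulate_chase_series(chase_sim_config(decay_rates = c(NT = 0),
                                               noise_cv = 0))
  expect_true(all(s0$measurements$band_mean - s0$measurements$background_mean == 100))
  expect_error(chase_sim_config(decay_rates = c(CHX = -0.1)), "parameter")
  expect_error(chase_sim_config(timepoints = c(1, 2)), "include 0")
})

test_that("band boxing subtracts background and floors at zero", {
  img <- matrix(50, 40, 40)
  img[10:20, 5:15] <- 150
  b <- band_intensity(img, c(10, 20, 5, 15), c(25, 35, 5, 15))
  expect_equal(b$band_mean, 150)
  expect_equal(b$background_mean, 50)
  expect_equal(b$corrected, 100)
  # null signal
  b0 <- band_intensity(img, c(25, 35, 20, 30), c(25, 35, 5, 15))
  expect_equal(b0$corrected, 0)
  expect_error(band_intensity(img, c(10, 20, 38, 45), c(1, 5, 1, 5)),
               "geometry")
  expect_warning(band_intensity(img, c(10, 20, 5, 15), c(15, 25, 5, 15)),
                 "overlap")
})

test_that("planted band amplitudes are recovered from rendered blot images", {
  blot <- simulate_blot_image(c(100, 60, 25), noise_sd = 2, seed = 5)
  for (i in 1:3) {
    bx <- blot$boxes[i, ]
    b <- band_intensity(blot$image,
                        c(bx$row_min, bx$row_max, bx$col_min, bx$col_max),
                        c(1, 8, bx$col_min, bx$col_max))
    expect_lt(abs(b$corrected - c(100, 60, 25)[i]) / c(100, 60, 25)[i], 0.02)
  }
})

test_that("loading normalization gives percent of reference and its invariances", {
  s <- list(corrected = 80, loading_value = 2)
  r <- list(corrected = 100, loading_value = 1)
  expect_equal(loading_normalize(s, r), 40)
  expect_equal(loading_normalize(r, r), 100)
  s2 <- list(corrected = 160, loading_value = 4)
  expect_equal(loading_normalize(s2, r), loading_normalize(s, r))
  expect_error(loading_normalize(s, list(corrected = 0, loading_value = 1)),
               "undefined")
  expect_error(loading_normalize(list(corrected = 1, loading_value = 0), r),
               "loading_value")
})

test_that("percent remaining is anchored at 100% and scale-invariant", {
  series <- tibble::tibble(replicate = 1, timepoint = c(0, 2, 4),
                           intensity = c(200, 100, 50))
  out <- chase_percent_remaining(series)
  expect_equal(out$percent$percent_remaining, c(100, 50, 25))
  # constant intensities: 100% throughout, SEM 0 with identical replicates
  flat <- tidyr::crossing(replicate = 1:3, timepoint = c(0, 1, 2))
  flat$intensity <- 7
  outf <- chase_percent_remaining(flat)
  expect_true(all(outf$summary$mean_percent == 100))
  expect_true(all(outf$summary$sem == 0))
  # rescaling one replicate leaves its percent curve unchanged
  two <- tidyr::crossing(replicate = 1:2, timepoint = c(0, 1, 2))
  two$intensity <- c(100, 80, 60, 100, 80, 60)
  two$intensity[two$replicate == 2] <- two$intensity[two$replicate == 2] * 13
  outt <- chase_percent_remaining(two)
  expect_equal(outt$percent$percent_remaining[outt$percent$replicate == 1],
               outt$percent$percent_remaining[outt$percent$replicate == 2])
  # replicates without positive t=0 intensity are dropped
  bad <- tibble::tibble(replicate = c(1, 1, 2, 2), timepoint = c(0, 2, 0, 2),
                        intensity = c(100, 50, 0, 10))
  expect_warning(outb <- chase_percent_remaining(bad), "t = 0")
  expect_equal(unique(outb$percent$replicate), 1)
})

test_that("planted decay rates are recovered by the log-linear fit", {
  sim <- simulate_chase_series(chase_sim_config(
    decay_rates = c(CHX = 0.35), noise_cv = 0.05, n_replicates = 4,
    seed = 13))
  fit <- fit_decay_rate(chase_percent_remaining(sim$measurements))
  expect_lt(abs(fit$k_per_hour - 0.35) / 0.35, 0.15)
  expect_equal(fit$half_life_hours, log(2) / fit$k_per_hour)
})

test_that("cleavage ratios divide corrected free GFP by full-length signal", {
  expect_equal(cleavage_ratio(30, 60), 0.5)
  expect_equal(cleavage_ratio(0, 60), 0)
  expect_equal(cleavage_ratio(list(corrected = 45), list(corrected = 45)), 1)
  expect_error(cleavage_ratio(10, 0), "positive")
})

test_that("steady-state fold changes pair the mean ratio with a Welch test", {
  out <- steady_state_fold_change(c(10, 12), c(20, 24))
  expect_equal(out$fold_change, 2)
  idn <- steady_state_fold_change(c(5, 6, 7), c(5, 6, 7))
  expect_equal(idn$fold_change, 1)
  expect_equal(idn$welch$t, 0)
  expect_equal(idn$welch$p, 1)
  # planted 3-fold difference: Welch result matches the closed form to 1e-9
  set.seed(21)
  a <- rnorm(3, 10, 1); b <- rnorm(3, 30, 2)
  out3 <- steady_state_fold_change(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(out3$welch$t, oracle$t, tolerance = 1e-9)
  expect_equal(out3$welch$df, oracle$df, tolerance = 1e-9)
  expect_equal(out3$welch$p, oracle$p, tolerance = 1e-9)
  # both groups constant: fold reported, test undefined
  expect_message(z <- steady_state_fold_change(c(2, 2), c(4, 4)),
                 "zero variance")
  expect_equal(z$fold_change, 2)
  expect_null(z$welch)
})
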