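m <- proteus_one()

# Calibration field: one layer whose first line has irregular x gaps spanning
# the 30 mm softplus turn, plus pure-y single-spot lines for the slow axis.
calibration_field <- function(energy = 150, mu = 0.5) {
  x <- cumsum(c(0, 2, 5, 8, 12, 20, 28, 35, 45, 60, 80))
  line1 <- tibble::tibble(x_mm = x, y_mm = 0)
  ycol <- tibble::tibble(x_mm = max(x), y_mm = cumsum(c(10, 1, 3, 7, 20, 60)))
  pbs_field(dplyr::mutate(dplyr::bind_rows(line1, ycol),
                          layer_index = 1, energy_MeV = energy, mu = mu))
}

# A multi-layer field giving distinct BST count sums across layers.
bst_field <- function() {
  spots <- lapply(1:4, function(i) {
    tibble::tibble(layer_index = i, energy_MeV = 210 - 5 * i,
                   x_mm = seq(0, by = 7, length.out = 2 + 2 * i), y_mm = 0,
                   mu = 0.3 * i)
  })
  pbs_field(dplyr::bind_rows(spots))
}

test_that("noiseless observations equal the model predictions exactly", {
  obs <- synth_observations(bst_field(), m, noise_spec())
  expect_equal(obs$bst$observed_s,
               m$bst$mu_coeff * obs$bst$count_sum + m$bst$dead_time,
               tolerance = 1e-12)
  xobs <- obs$switch[obs$switch$axis == "x", ]
  expect_equal(xobs$observed_ms, xswitch_time(xobs$distance_mm, m),
               tolerance = 1e-12)
  expect_equal(obs$elst$observed_s,
               elst(obs$elst$e_from, obs$elst$e_to, m), tolerance = 1e-12)
})

test_that("the same seed reproduces the same observation draw", {
  ns <- noise_spec(bst_sd = 0.01, switch_sd = 0.5, elst_sd = 0.05, seed = 11)
  a <- synth_observations(bst_field(), m, ns)
  b <- synth_observations(bst_field(), m, ns)
  expect_identical(a, b)
  c <- synth_observations(bst_field(), m,
                          noise_spec(bst_sd = 0.01, switch_sd = 0.5,
                                     elst_sd = 0.05, seed = 12))
  expect_false(identical(a$bst$observed_s, c$bst$observed_s))
})

test_that("noise magnitudes are realized at the requested scale", {
  f <- test_field_y_interval(rep(c(1, 4, 9, 2), 250), energy = 150)
  ns <- noise_spec(switch_sd = 0.5, seed = 3)
  obs <- synth_observations(f, m, ns)
  yobs <- obs$switch[obs$switch$axis == "y", ]
  resid <- yobs$observed_ms - yswitch_time(yobs$distance_mm, m)
  expect_gt(nrow(yobs), 900)
  expect_lt(abs(sd(resid) - 0.5) / 0.5, 0.2)
})

test_that("burst-switching regression recovers slope and dead time", {
  obs <- synth_observations(bst_field(), m, noise_spec())
  fit <- fit_bst(obs$bst)
  expect_equal(fit$mu_coeff, 5e-5, tolerance = 1e-6)
  expect_equal(fit$dead_time, 0.2228, tolerance = 1e-6)

  two_pts <- tibble::tibble(count_sum = c(0, 1000),
                            observed_s = c(0.2228, 0.2728))
  fit2 <- fit_bst(two_pts)
  expect_equal(fit2$mu_coeff, 5e-5, tolerance = 1e-12)
  expect_equal(fit2$dead_time, 0.2228, tolerance = 1e-12)

  expect_error(fit_bst(tibble::tibble(count_sum = c(5, 5),
                                      observed_s = c(0.2, 0.3))),
               "degenerate")
})

test_that("burst-switching fit is scale-consistent", {
  obs <- synth_observations(bst_field(), m,
                            noise_spec(bst_sd = 0.005, seed = 21))$bst
  f1 <- fit_bst(obs)
  obs$observed_s <- obs$observed_s * 3
  f3 <- fit_bst(obs)
  expect_equal(f3$mu_coeff, 3 * f1$mu_coeff, tolerance = 1e-9)
  expect_equal(f3$dead_time, 3 * f1$dead_time, tolerance = 1e-9)
})

test_that("fast-axis fit recovers baseline and slope", {
  obs <- synth_observations(calibration_field(), m, noise_spec())
  fit <- fit_xswitch(obs$switch, m)
  expect_equal(fit$t_min, 6, tolerance = 1e-6)
  expect_equal(fit$slope, 0.26, tolerance = 1e-6)

  short <- tibble::tibble(distance_mm = c(1, 2, 5), axis = "x",
                          observed_ms = xswitch_time(c(1, 2, 5), m))
  expect_error(fit_xswitch(short, m), "span")
})

test_that("noisy seeded recovery stays within 5% for BST and x-switch", {
  # layers span few-spot/low-MU to many-spot/high-MU so the transmitted-count
  # sums cover the range seen clinically (tens to thousands)
  big <- pbs_field(dplyr::bind_rows(lapply(1:32, function(i) {
    n <- 2 + 2 * i
    tibble::tibble(layer_index = i, energy_MeV = 225 - 1.5 * i,
                   x_mm = cumsum(c(0, rep(c(3, 9, 17, 33, 51),
                                          length.out = n - 1))),
                   y_mm = 0, mu = 0.02 + 0.5 * (i - 1))
  })))
  obs <- synth_observations(big, m, noise_spec(bst_sd = 0.01,
                                               switch_sd = 0.5, seed = 5))
  fb <- fit_bst(obs$bst)
  expect_lt(abs(fb$mu_coeff - 5e-5) / 5e-5, 0.05)
  expect_lt(abs(fb$dead_time - 0.2228) / 0.2228, 0.05)
  fx <- fit_xswitch(obs$switch, m)
  expect_lt(abs(fx$t_min - 6) / 6, 0.05)
  expect_lt(abs(fx$slope - 0.26) / 0.26, 0.05)
})

test_that("burst MU fractions are recovered from emitted logs", {
  f <- test_field_square(c(0.5, 1, 2, 4), energy = 160)
  log <- emit_log(build_timeline(f, m))
  fit <- fit_burst_fractions(log)
  expect_equal(fit$fraction, c(0.609, 0.330, 0.061), tolerance = 1e-9)
  expect_equal(sum(fit$fraction), 1, tolerance = 1e-12)

  single <- emit_log(build_timeline(test_field_iso_repeat(2), m))
  fs <- fit_burst_fractions(single)
  expect_equal(fs$sd, rep(0, 3))

  truncated <- log[!(log$burst %in% 3), ]
  expect_error(fit_burst_fractions(truncated), "incomplete")
})

test_that("averaging noisy per-layer fractions recovers the burst weights", {
  # per-layer fraction spread at the scale reported for the machine (a few
  # percentage points); averaging across layers is the estimator
  lad <- test_field_elst_ladder(seq(220, 70, length.out = 250), mu = 1)
  obs <- synth_observations(lad, m, noise_spec(fraction_sd = 0.026, seed = 9))
  est <- tapply(obs$fractions$fraction, obs$fractions$burst, mean)
  est <- est / sum(est)
  expect_lt(max(abs(est - c(0.609, 0.330, 0.061))), 0.005)
})

test_that("tidiers expose fit parameters in broom shape", {
  obs <- synth_observations(bst_field(), m, noise_spec(bst_sd = 1e-4, seed = 2))
  fb <- fit_bst(obs$bst)
  td <- tidy(fb)
  expect_equal(td$term, c("dead_time", "mu_coeff"))
  expect_equal(nrow(glance(fb)), 1)
  fx <- fit_xswitch(synth_observations(calibration_field(), m,
                                       noise_spec())$switch, m)
  expect_equal(tidy(fx)$term, c("t_min", "slope"))
  expect_true(all(c("t_min", "slope") %in% names(glance(fx))))
})

test_that("observations extracted from a log match the model to quantization", {
  f <- calibration_field()
  log <- emit_log(build_timeline(f, m))
  obs <- extract_observations(log)
  xobs <- obs$switch[obs$switch$axis == "x", ]
  expect_gt(nrow(xobs), 5)
  # each gap is quantized to whole log rows: within half a millisecond
  expect_lt(max(abs(xobs$observed_ms - xswitch_time(xobs$distance_mm, m))),
            0.5 + 1e-9)
  yobs <- obs$switch[obs$switch$axis == "y", ]
  expect_gt(nrow(yobs), 3)
  expect_lt(max(abs(yobs$observed_ms - yswitch_time(yobs$distance_mm, m))),
            0.5 + 1e-9)
  expect_equal(nrow(obs$bst), 2)
  expect_lt(max(abs(obs$bst$observed_s -
                      (5e-5 * obs$bst$count_sum + 0.2228))), 0.0005 + 1e-9)
  # fitting the extracted observations recovers the x-switch model closely
  fx <- fit_xswitch(obs$switch, m)
  expect_lt(abs(fx$t_min - 6) / 6, 0.05)
  expect_lt(abs(fx$slope - 0.26) / 0.26, 0.05)
})

test_that("calibrate_machine returns a refit model and report", {
  f <- bst_field()
  obs <- synth_observations(f, m, noise_spec())
  log <- emit_log(build_timeline(test_field_square(c(0.5, 1), energy = 160), m))
  out <- calibrate_machine(obs, log, base = m)
  expect_s3_class(out$machine, "machine_model")
  expect_equal(out$machine$bst$mu_coeff, 5e-5, tolerance = 1e-6)
  expect_equal(out$machine$burst$fractions, c(0.609, 0.330, 0.061),
               tolerance = 1e-9)
  expect_true("bst" %in% names(out$report))
})
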