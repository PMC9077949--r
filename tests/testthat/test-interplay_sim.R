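m <- proteus_one()

test_that("displacement follows the sinusoid and its phase offset", {
  mo <- motion_model(amplitude = 5, period = 4, n_phases = 10)
  expect_equal(displacement(0, mo), 0)
  expect_equal(displacement(1, mo), 5)       # quarter period at peak
  expect_equal(displacement(2, mo), 0, tolerance = 1e-12)
  still <- motion_model(amplitude = 0)
  expect_equal(displacement(c(0, 0.3, 2.7), still), c(0, 0, 0))
  shifted <- motion_model(amplitude = 5, period = 4, n_phases = 10,
                          start_phase = 5)
  expect_equal(displacement(0, shifted), 5 * sin(pi), tolerance = 1e-12)
  expect_error(displacement(-1, mo), "non-negative")
  expect_error(motion_model(start_phase = 10), "start_phase")
})

test_that("zero motion reproduces the static dose exactly", {
  sc <- interplay_scenario()
  small <- pbs_field(dplyr::filter(tibble::as_tibble(sc$field),
                                   layer_index == 1))
  tl <- build_timeline(small, m)
  static <- motion_model(amplitude = 0)
  d1 <- accumulate_4d(tl, static, sc$phantom)
  d2 <- accumulate_4d(tl, motion_model(amplitude = 0, start_phase = 3),
                      sc$phantom)
  expect_identical(d1, d2)
})

test_that("integrated dose is conserved under any motion", {
  sc <- interplay_scenario()
  small <- pbs_field(dplyr::filter(tibble::as_tibble(sc$field),
                                   layer_index == 1))
  tl <- build_timeline(small, m)
  total_mu <- sum(tl$mu[tl$kind == "pulse"])
  for (amp in c(0, 5, 12)) {
    dose <- accumulate_4d(tl, motion_model(amplitude = amp), sc$phantom)
    expect_equal(sum(dose), total_mu, tolerance = 1e-9)
  }
})

test_that("dose deposition is linear in pulse MU", {
  ph <- toy_phantom()
  mk_tl <- function(mu, times_ms) {
    tibble::tibble(start_ms = times_ms, duration_ms = 1, kind = "pulse",
                   layer_index = 1, burst = 1, spot = 1,
                   x_mm = 3, y_mm = -2, mu = mu)
  }
  still <- motion_model(amplitude = 0)
  one <- accumulate_4d(mk_tl(1, 0), still, ph)
  two <- accumulate_4d(mk_tl(c(0.5, 0.5), c(0, 4000)), still, ph)
  expect_equal(two, one, tolerance = 1e-12)
})

test_that("phase shifts relabel a period-spanning uniform delivery", {
  # pulses evenly spaced at period/n_phases over exactly one period: shifting
  # the starting phase permutes which pulse sees which displacement, so the
  # accumulated dose (and d99) is invariant
  ph <- toy_phantom()
  times <- seq(0, 3600, by = 400)          # 10 pulses over 4 s
  tl <- tibble::tibble(start_ms = times, duration_ms = 1, kind = "pulse",
                       layer_index = 1, burst = 1, spot = 1,
                       x_mm = 0, y_mm = 0, mu = 0.1)
  d99s <- vapply(0:9, function(p) {
    mo <- motion_model(amplitude = 5, period = 4, n_phases = 10,
                       start_phase = p)
    dose_d99(accumulate_4d(tl, mo, ph), ph)
  }, numeric(1))
  expect_equal(d99s, rep(d99s[1], 10), tolerance = 1e-12)
})

test_that("non-burst machine delivers one spill pass per layer", {
  f <- test_field_iso_repeat(1, energy = 100)
  nb <- nonburst_machine()
  tl_nb <- build_timeline(f, nb)
  expect_equal(sum(tl_nb$kind == "burst_switch"), 0)
  expect_equal(unique(tl_nb$burst[tl_nb$kind == "pulse"]), 1)
  tl_b <- build_timeline(f, m)
  expect_equal(sort(unique(tl_b$burst[tl_b$kind == "pulse"])), 1:3)
  # spill duration tracks mu / rate at the 1 ms clock
  f2 <- test_field_iso_repeat(1, energy = 100)
  f2$mu <- 2
  tl2 <- build_timeline(f2, nb)
  expect_equal(sum(tl2$kind == "pulse"),
               round(2 / nb$spill_rate_mu_s * 1000))
})

test_that("non-burst reference BDT is comparable to the burst machine", {
  sc <- interplay_scenario()
  b <- breakdown(build_timeline(sc$field, m))$t_bdt_s
  nb <- breakdown(build_timeline(sc$field, nonburst_machine()))$t_bdt_s
  expect_lt(abs(nb - b) / b, 0.2)
})

test_that("interplay run is deterministic and spans all phases", {
  sc <- interplay_scenario()
  small <- pbs_field(dplyr::filter(tibble::as_tibble(sc$field),
                                   layer_index == 1))
  r1 <- run_interplay(small, m, sc$motion, 1, sc$phantom)
  r2 <- run_interplay(small, m, sc$motion, 1, sc$phantom)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$start_phase, 0:9)
  g <- glance(r1)
  expect_equal(g$n_phases, 10)
  # zero-amplitude motion: every phase equals the static reference
  still <- motion_model(amplitude = 0)
  r0 <- run_interplay(small, m, still, 1, sc$phantom)
  expect_equal(r0$d99, rep(attr(r0, "static_d99"), 10), tolerance = 1e-12)
})

test_that("spot patterns that leave the grid are rejected", {
  far <- pbs_field(tibble::tibble(layer_index = 1, energy_MeV = 100,
                                  x_mm = 100, y_mm = 0, mu = 0.5))
  expect_error(run_interplay(far, m, motion_model(), 1, toy_phantom()),
               "outside the dose grid")
  expect_error(toy_phantom(target_radius = 70), "inside the grid")
})
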