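test_that("plan CSV round-trip preserves layer order, spot order and values", {
  f <- pbs_field(tibble::tibble(
    layer_index = c(1, 1, 2),
    energy_MeV = c(160.123456, 160.123456, 155),
    x_mm = c(-3.5, 4.25, 0),
    y_mm = c(0, 0, 5.123456),
    mu = c(0.02, 1.234567, 0.5)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plan(f, path)
  g <- read_plan(path)
  expect_equal(n_layers(g), 2)
  expect_equal(g$layer_index, f$layer_index)
  expect_equal(g$x_mm, f$x_mm, tolerance = 1e-6)
  expect_equal(g$mu, f$mu, tolerance = 1e-6)
  expect_equal(g$energy_MeV, f$energy_MeV, tolerance = 1e-6)
})

test_that("structured-text plan formats carry the same schema", {
  f <- test_field_y_interval(c(1, 2, 3), energy = 150)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_plan(f, path)
    g <- read_plan(path)
    expect_equal(g$y_mm, f$y_mm, tolerance = 1e-9)
    expect_equal(g$mu, f$mu, tolerance = 1e-9)
  }
})

test_that("reader reports schema and parse errors but not physics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("layer_index,energy_MeV,x_mm,y_mm,mu", path)
  expect_error(read_plan(path), "empty")
  writeLines(c("layer_index,energy_MeV,x_mm", "1,100,0"), path)
  expect_error(pbs_field(readr::read_csv(path, show_col_types = FALSE)),
               "missing plan column")
  # sub-minimum MU loads fine; validation flags it later
  writeLines(c("layer_index,energy_MeV,x_mm,y_mm,mu", "1,100,0,0,0.005"), path)
  f <- read_plan(path)
  expect_equal(f$mu, 0.005)
  expect_false(is_deliverable(validate_field(f)))
  expect_error(read_plan(withr::local_tempfile(fileext = ".csv")), "not found")
})

test_that("validation reports one error per violated rule", {
  ok <- pbs_field(tibble::tibble(layer_index = c(1, 2), energy_MeV = c(100, 150),
                                 x_mm = 0, y_mm = 0, mu = 0.02))
  expect_true(is_deliverable(validate_field(ok)))
  expect_equal(nrow(validate_field(ok)), 0)

  low_mu <- pbs_field(tibble::tibble(layer_index = 1, energy_MeV = 100,
                                     x_mm = 0, y_mm = 0, mu = 0.005))
  rep <- validate_field(low_mu)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$rule, "mu_min")
  expect_match(rep$message, "0.01")

  hot <- pbs_field(tibble::tibble(layer_index = 1, energy_MeV = 250,
                                  x_mm = 0, y_mm = 0, mu = 0.02))
  rep <- validate_field(hot)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$rule, "energy_range")
  expect_match(rep$message, "70")

  nan_xy <- pbs_field(tibble::tibble(layer_index = 1, energy_MeV = 100,
                                     x_mm = NaN, y_mm = 0, mu = 0.02))
  expect_equal(validate_field(nan_xy)$rule, "finite_coordinates")
})

test_that("test-field recipes reproduce the experimental designs", {
  lad <- test_field_elst_ladder(c(200, 195, 190))
  expect_equal(n_layers(lad), 3)
  expect_true(all(lad$x_mm == 0 & lad$y_mm == 0 & lad$mu == 0.02))
  expect_equal(nrow(lad), 3)

  iso <- test_field_iso_repeat(10, energy = 200)
  expect_equal(n_layers(iso), 1)
  expect_equal(nrow(iso), 10)
  expect_true(all(iso$x_mm == 0 & iso$y_mm == 0 & iso$mu == 0.02))

  yi <- test_field_y_interval(c(1, 2, 3), energy = 150)
  expect_equal(unique(yi$x_mm), 0)
  expect_equal(diff(yi$y_mm), c(1, 2, 3))

  sq <- test_field_square(c(0.1, 0.2, 0.3), energy = 150)
  expect_equal(nrow(sq), 9)
  expect_equal(length(unique(sq$y_mm)), 3)

  expect_error(make_test_field("no_such_recipe"), "unknown")
})

test_that("recipes are deterministic and validate cleanly", {
  recipes <- list(
    make_test_field("elst_ladder", energies = c(200, 150, 100)),
    make_test_field("iso_repeat", n_spots = 5),
    make_test_field("y_interval", distances = 1:5),
    make_test_field("rect_diagonal"),
    make_test_field("square", mu_per_line = rep(0.5, 4))
  )
  again <- list(
    make_test_field("elst_ladder", energies = c(200, 150, 100)),
    make_test_field("iso_repeat", n_spots = 5),
    make_test_field("y_interval", distances = 1:5),
    make_test_field("rect_diagonal"),
    make_test_field("square", mu_per_line = rep(0.5, 4))
  )
  for (i in seq_along(recipes)) {
    expect_identical(as.data.frame(recipes[[i]]), as.data.frame(again[[i]]))
    expect_true(is_deliverable(validate_field(recipes[[i]])))
  }
})

test_that("repainting repeats the whole layer sequence at reduced MU", {
  f <- test_field_elst_ladder(c(200, 190), mu = 0.1)
  r <- repaint_field(f, 2)
  expect_equal(nrow(r), 4)
  expect_equal(n_layers(r), 4)
  expect_equal(r$energy_MeV, c(200, 190, 200, 190))
  expect_equal(sum(r$mu), sum(f$mu))
})
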