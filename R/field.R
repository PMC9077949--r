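#' Create a treatment field from a spot table
#'
#' A treatment field is a tibble with one row per spot and columns
#' `layer_index`, `energy_MeV`, `x_mm`, `y_mm`, `mu`. Layers are delivered
#' in order of first appearance of `layer_index`; spot order within a layer
#' is the row order as authored. Coordinates are beam's-eye-view with x the
#' fast scan axis and y the slow scan axis, in mm.
#'
#' @param spots A data frame with the five schema columns (extra columns
#'   are kept but ignored by the models).
#' @param label Free-text field label.
#' @param gantry_angle Gantry angle in degrees. Carried as metadata only:
#'   the timing models are angle-independent.
#' @return A `pbs_field` tibble.
#' @export
#' @examples
#' f <- pbs_field(data.frame(
#'   layer_index = c(1, 1, 2), energy_MeV = c(160, 160, 155),
#'   x_mm = c(0, 5, 0), y_mm = 0, mu = 0.02
#' ))
#' n_layers(f)
pbs_field <- function(spots, label = "", gantry_angle = NA_real_) {
  required <- c("layer_index", "energy_MeV", "x_mm", "y_mm", "mu")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    stop("missing plan column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(spots) == 0) stop("a field needs at least one spot", call. = FALSE)
  f <- tibble::as_tibble(spots)
  f <- dplyr::mutate(f, dplyr::across(dplyr::all_of(required), as.numeric))
  attr(f, "label") <- label
  attr(f, "gantry_angle") <- gantry_angle
  class(f) <- c("pbs_field", class(f))
  f
}

#' @rdname pbs_field
#' @param field A `pbs_field` (or compatible data frame).
#' @export
n_layers <- function(field) length(unique(field$layer_index))

#' Split a field into its energy layers, in delivery order
#'
#' @inheritParams n_layers
#' @return A list of per-layer tibbles, ordered by first appearance of
#'   `layer_index`; each element carries its energy as attribute `energy`.
#' @export
field_layers <- function(field) {
  idx <- unique(field$layer_index)
  lapply(idx, function(i) {
    layer <- field[field$layer_index == i, , drop = FALSE]
    energies <- unique(layer$energy_MeV)
    if (length(energies) != 1) {
      stop("layer ", i, " has multiple energies", call. = FALSE)
    }
    attr(layer, "energy") <- energies
    layer
  })
}

#' Read and write treatment plan files
#'
#' The plan schema is one CSV row per spot with columns `layer_index`,
#' `energy_MeV`, `x_mm`, `y_mm`, `mu`; layer order is first-appearance
#' order. A YAML/JSON structured-text equivalent with the same field names
#' is accepted by extension (`.yaml`/`.yml`/`.json`). Readers preserve
#' authored order and do not enforce physics constraints; use
#' [validate_field()] for that.
#'
#' @param path File path.
#' @inheritParams pbs_field
#' @return `read_plan()` returns a `pbs_field`; `write_plan()` returns
#'   `path` invisibly.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml", "json")) {
    raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    spots <- tibble::as_tibble(raw$spots)
    return(pbs_field(spots,
                     label = raw$label %||% "",
                     gantry_angle = raw$gantry_angle %||% NA_real_))
  }
  spots <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("malformed plan file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(spots) == 0) stop("empty plan file: ", path, call. = FALSE)
  bad <- which(!stats::complete.cases(
    spots[intersect(names(spots), c("layer_index", "energy_MeV", "x_mm", "y_mm", "mu"))]
  ))
  if (length(bad) > 0) {
    stop("malformed plan row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  pbs_field(spots)
}

#' @rdname read_plan
#' @export
write_plan <- function(field, path) {
  ext <- tolower(tools::file_ext(path))
  cols <- c("layer_index", "energy_MeV", "x_mm", "y_mm", "mu")
  if (ext %in% c("yaml", "yml", "json")) {
    payload <- list(
      label = attr(field, "label") %||% "",
      gantry_angle = attr(field, "gantry_angle") %||% NA_real_,
      spots = as.data.frame(field[cols])
    )
    if (ext == "json") {
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    } else {
      yaml::write_yaml(payload, path, precision = 12)
    }
  } else {
    readr::write_csv(field[cols], path, progress = FALSE)
  }
  invisible(path)
}

#' Validate a treatment field against machine constraints
#'
#' Checks every spot against the deliverability rules — minimum MU, energy
#' range, finite coordinates, non-empty layers — and reports violations
#' without throwing: an empty `errors` table means the field is deliverable.
#'
#' @inheritParams n_layers
#' @inheritParams critical_interval
#' @return A `validation_report`: a tibble with columns `severity`
#'   (`"error"` or `"warning"`), `layer_index`, `spot`, `rule`, `message`.
#' @export
validate_field <- function(field, machine = proteus_one()) {
  rows <- list()
  add <- function(severity, layer, spot, rule, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      severity = severity, layer_index = layer, spot = spot,
      rule = rule, message = message
    )
  }
  spot_in_layer <- stats::ave(field$mu, field$layer_index,
                              FUN = seq_along)
  for (r in seq_len(nrow(field))) {
    li <- field$layer_index[r]; k <- spot_in_layer[r]
    if (is.finite(field$mu[r]) && field$mu[r] < machine$mu_min) {
      add("error", li, k, "mu_min",
          sprintf("spot MU %.4g below minimum %.4g", field$mu[r], machine$mu_min))
    }
    e <- field$energy_MeV[r]
    if (!is.finite(e) || e < machine$energy_range[1] || e > machine$energy_range[2]) {
      add("error", li, k, "energy_range",
          sprintf("energy %.4g MeV outside [%g, %g]",
                  e, machine$energy_range[1], machine$energy_range[2]))
    }
    if (!is.finite(field$x_mm[r]) || !is.finite(field$y_mm[r])) {
      add("error", li, k, "finite_coordinates", "non-finite spot coordinate")
    }
  }
  report <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(severity = character(), layer_index = numeric(),
                   spot = numeric(), rule = character(), message = character())
  }
  class(report) <- c("validation_report", class(report))
  report
}

#' @rdname validate_field
#' @param report A `validation_report`.
#' @export
is_deliverable <- function(report) {
  !any(report$severity == "error")
}

#' Generate the standard experimental test-field patterns
#'
#' Deterministic generators for the spot patterns used to isolate each
#' timing component on the machine:
#'
#' * `elst_ladder`: one single spot at isocenter per layer (0.02 MU), one
#'   layer per requested energy — isolates layer switching.
#' * `iso_repeat`: one layer of `n` identical isocenter spots (0.02 MU) —
#'   isolates the zero-distance spot-switching dead time.
#' * `y_interval`: single-spot-per-line column of spots moving in y only,
#'   with the requested inter-spot distances — isolates slow-axis switching.
#' * `rect_diagonal`: rectangular grid whose alternate lines are offset in
#'   x so line entry is diagonal — exercises the max(x, y) line-switch rule.
#' * `square`: square grid with one MU value per line — the burst-fraction
#'   and spill experiment layout.
#'
#' @param pattern Recipe name, one of `"elst_ladder"`, `"iso_repeat"`,
#'   `"y_interval"`, `"rect_diagonal"`, `"square"`.
#' @param ... Passed to the matching `test_field_*()` generator.
#' @return A `pbs_field`.
#' @export
#' @examples
#' make_test_field("elst_ladder", energies = c(200, 195, 190))
#' test_field_y_interval(c(1, 2, 3), energy = 150)
make_test_field <- function(pattern, ...) {
  gen <- switch(pattern,
    elst_ladder = test_field_elst_ladder,
    iso_repeat = test_field_iso_repeat,
    y_interval = test_field_y_interval,
    rect_diagonal = test_field_rect_diagonal,
    square = test_field_square,
    stop("unknown test-field recipe: ", pattern, call. = FALSE)
  )
  gen(...)
}

#' @rdname make_test_field
#' @param energies Layer energies in delivery order, MeV.
#' @param mu MU per spot.
#' @export
test_field_elst_ladder <- function(energies, mu = 0.02) {
  pbs_field(tibble::tibble(
    layer_index = seq_along(energies),
    energy_MeV = as.numeric(energies),
    x_mm = 0, y_mm = 0, mu = mu
  ), label = "elst-ladder")
}

#' @rdname make_test_field
#' @param n_spots Number of identical isocenter spots.
#' @param energy Layer energy, MeV.
#' @export
test_field_iso_repeat <- function(n_spots, energy = 200, mu = 0.02) {
  pbs_field(tibble::tibble(
    layer_index = 1, energy_MeV = energy,
    x_mm = 0, y_mm = 0, mu = mu
  )[rep(1, n_spots), ], label = "iso-repeat")
}

#' @rdname make_test_field
#' @param distances Successive slow-axis travel distances, mm.
#' @param x Common fast-axis coordinate, mm.
#' @export
test_field_y_interval <- function(distances, energy = 150, x = 0, mu = 0.02) {
  pbs_field(tibble::tibble(
    layer_index = 1, energy_MeV = energy,
    x_mm = x, y_mm = cumsum(c(0, as.numeric(distances))), mu = mu
  ), label = "y-interval")
}

#' @rdname make_test_field
#' @param width Line length, mm.
#' @param dx Intra-line spot spacing, mm.
#' @param dy Line spacing, mm.
#' @param n_lines Number of lines.
#' @param x_offset Alternate-line x offset forcing diagonal entry, mm.
#' @export
test_field_rect_diagonal <- function(width = 100, dx = 10, dy = 5,
                                     n_lines = 5, x_offset = 2.5,
                                     energy = 150, mu = 0.02) {
  lines <- lapply(seq_len(n_lines), function(r) {
    off <- if (r %% 2 == 0) x_offset else 0
    tibble::tibble(x_mm = seq(0, width, by = dx) + off,
                   y_mm = (r - 1) * dy)
  })
  spots <- dplyr::bind_rows(lines)
  pbs_field(dplyr::mutate(spots, layer_index = 1, energy_MeV = energy,
                          mu = mu),
            label = "rect-diagonal")
}

#' @rdname make_test_field
#' @param mu_per_line MU value for each line (length = number of lines).
#' @param spacing Spot and line spacing, mm.
#' @param spots_per_line Spots per line.
#' @export
test_field_square <- function(mu_per_line, energy = 150, spacing = 5,
                              spots_per_line = length(mu_per_line)) {
  n_lines <- length(mu_per_line)
  xs <- (seq_len(spots_per_line) - (spots_per_line + 1) / 2) * spacing
  ys <- (seq_len(n_lines) - (n_lines + 1) / 2) * spacing
  spots <- tidyr::expand_grid(line = seq_len(n_lines), col = seq_len(spots_per_line))
  pbs_field(tibble::tibble(
    layer_index = 1, energy_MeV = energy,
    x_mm = xs[spots$col], y_mm = ys[spots$line],
    mu = mu_per_line[spots$line]
  ), label = "square")
}

#' Repeat a field for volumetric repainting
#'
#' Volumetric repainting delivers the whole field `n` times at `1/n` of the
#' planned MU per spot, averaging delivery over more of the motion cycle.
#'
#' @inheritParams n_layers
#' @param n Number of paintings (>= 1).
#' @return A `pbs_field` with the full layer sequence repeated `n` times.
#' @export
repaint_field <- function(field, n) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(field)
  max_layer <- max(field$layer_index)
  copies <- lapply(seq_len(n), function(p) {
    dplyr::mutate(tibble::as_tibble(field),
                  layer_index = .data$layer_index + (p - 1) * max_layer,
                  mu = .data$mu / n)
  })
  pbs_field(dplyr::bind_rows(copies),
            label = paste0(attr(field, "label") %||% "", "-repaint", n),
            gantry_angle = attr(field, "gantry_angle") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
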