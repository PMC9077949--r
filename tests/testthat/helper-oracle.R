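# Independent closed-form recomputation of the four delivery-time component
# sums, assembled directly from the per-layer formulas (line-structured
# spot-switching sum, per-burst-pair burst switching, pulse-count spill,
# per-transition layer switching) rather than by walking timeline events.
oracle_breakdown <- function(field, machine = proteus_one(), y_tol = 1e-3) {
  layers <- field_layers(field)
  energies <- vapply(layers, function(l) attr(l, "energy"), numeric(1))
  t_lsw <- if (length(energies) > 1) {
    sum(elst(energies[-length(energies)], energies[-1], machine))
  } else 0
  n_burst <- machine$burst$n_burst
  t_ssw_ms <- 0; t_ssp_ms <- 0; t_bsw <- 0
  for (li in seq_along(layers)) {
    ord <- order_spots(layers[[li]], y_tol)
    e <- energies[li]
    # line-structured spot-switching sum for one pass over the layer
    lines <- split(ord, factor(ord$line, levels = unique(ord$line)))
    pass_ssw <- 0
    for (r in seq_along(lines)) {
      ln <- lines[[r]]
      if (r > 1) {
        prev <- lines[[r - 1]]
        exit <- prev[nrow(prev), ]
        entry <- ln[1, ]
        pass_ssw <- pass_ssw +
          line_switch_time(abs(entry$x_mm - exit$x_mm),
                           abs(entry$y_mm - exit$y_mm), machine)
      }
      if (nrow(ln) > 1) {
        pass_ssw <- pass_ssw + sum(xswitch_time(abs(diff(ln$x_mm)), machine))
      }
    }
    n_pulse_j <- vapply(seq_len(n_burst), function(j) {
      sum(pulses_for_spot(ord$mu, j, e, machine))
    }, numeric(1))
    n_spot <- nrow(ord)
    n_ssw <- round(pass_ssw / machine$pulse_period_ms)
    t_ssw_ms <- t_ssw_ms + n_burst * pass_ssw
    t_ssp_ms <- t_ssp_ms + sum(n_pulse_j) * machine$pulse_period_ms
    if (n_burst > 1) {
      for (j in seq_len(n_burst - 1)) {
        t_bsw <- t_bsw + bst(n_ssw, n_pulse_j[j], n_pulse_j[j + 1], n_spot,
                             machine)
      }
    }
  }
  c(t_lsw_s = t_lsw, t_bsw_s = t_bsw, t_ssw_s = t_ssw_ms / 1000,
    t_ssp_s = t_ssp_ms / 1000)
}

# Random small field generator for property tests (<= 3 layers, <= 5 spots
# per layer, descending-ish energies, coordinates on a loose grid).
random_small_field <- function() {
  n_layer <- sample(1:3, 1)
  energies <- sort(runif(n_layer, 70, 227), decreasing = sample(c(TRUE, FALSE), 1))
  spots <- lapply(seq_len(n_layer), function(i) {
    n_spot <- sample(1:5, 1)
    tibble::tibble(
      layer_index = i,
      energy_MeV = energies[i],
      x_mm = round(runif(n_spot, -50, 50), 1),
      y_mm = sample(seq(-20, 20, by = 5), n_spot, replace = TRUE),
      mu = round(runif(n_spot, 0.02, 2), 3)
    )
  })
  pbs_field(dplyr::bind_rows(spots))
}

# Total scan path length of one pass over a layer under a given entry rule:
# "shortest" follows order_spots; "left" always enters lines at their left
# end. Used as the enumeration oracle for the shortest-route property.
scan_path_length <- function(layer, entry = c("shortest", "left"),
                             y_tol = 1e-3) {
  entry <- match.arg(entry)
  grouped <- group_lines(layer, y_tol)
  lines <- split(grouped, factor(grouped$line, levels = unique(grouped$line)))
  total <- 0
  exit <- NULL
  for (r in seq_along(lines)) {
    ln <- lines[[r]]
    if (r == 1) {
      dir <- "l2r"
    } else if (entry == "left") {
      dir <- "l2r"
    } else {
      d_left <- sqrt((ln$x_mm[1] - exit$x_mm)^2 + (ln$y_mm[1] - exit$y_mm)^2)
      d_right <- sqrt((ln$x_mm[nrow(ln)] - exit$x_mm)^2 +
                      (ln$y_mm[nrow(ln)] - exit$y_mm)^2)
      dir <- if (d_left <= d_right) "l2r" else "r2l"
    }
    if (dir == "r2l") ln <- ln[rev(seq_len(nrow(ln))), ]
    if (!is.null(exit)) {
      total <- total + sqrt((ln$x_mm[1] - exit$x_mm)^2 +
                            (ln$y_mm[1] - exit$y_mm)^2)
    }
    if (nrow(ln) > 1) {
      total <- total + sum(sqrt(diff(ln$x_mm)^2 + diff(ln$y_mm)^2))
    }
    exit <- ln[nrow(ln), ]
  }
  total
}
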