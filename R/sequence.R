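#' Group a layer's spots into scan lines
#'
#' Spots are partitioned by slow-axis coordinate: after sorting by y, a new
#' line starts wherever the gap to the previous spot exceeds `y_tol`. Lines
#' are ordered bottom-to-top and each line's spots left-to-right (the base
#' order before serpentine traversal). The tolerance only guards floating
#' noise in exported plans, where rows share exact y values.
#'
#' @param layer A per-layer spot tibble (see [field_layers()]).
#' @param y_tol Clustering tolerance, mm (> 0).
#' @return The layer tibble with columns `line` (1 = bottom) and `line_y`
#'   (mean member y), sorted by line then x.
#' @export
group_lines <- function(layer, y_tol = 1e-3) {
  stopifnot(y_tol > 0)
  out <- layer[order(layer$y_mm, layer$x_mm), , drop = FALSE]
  line <- cumsum(c(1L, as.integer(diff(out$y_mm) > y_tol)))
  out <- out[order(line, out$x_mm), , drop = FALSE]
  out$line <- sort(line)
  out$line_y <- stats::ave(out$y_mm, out$line, FUN = mean)
  out
}

#' Serpentine scan order with shortest-route line entry
#'
#' Reproduces the scanning controller's delivery order: start at the lower
#' left corner of the field, deliver the bottom line left-to-right, then for
#' each subsequent line enter at whichever end (left-most or right-most
#' spot) is closer to the previous line's exit spot, traversing the line
#' from that end. Ties go to the left end.
#'
#' @inheritParams group_lines
#' @return The layer tibble in delivery order, with columns `seq` (1-based
#'   delivery index), `line`, and `direction` (`"l2r"` or `"r2l"`).
#' @export
order_spots <- function(layer, y_tol = 1e-3) {
  grouped <- group_lines(layer, y_tol)
  x <- grouped$x_mm
  y <- grouped$y_mm
  line_idx <- split(seq_len(nrow(grouped)), grouped$line)
  dirs <- character(length(line_idx))
  exit_x <- NA_real_
  exit_y <- NA_real_
  for (r in seq_along(line_idx)) {
    ids <- line_idx[[r]]
    if (r == 1) {
      dirs[r] <- "l2r"
    } else {
      first <- ids[1]
      last <- ids[length(ids)]
      d_left <- sqrt((x[first] - exit_x)^2 + (y[first] - exit_y)^2)
      d_right <- sqrt((x[last] - exit_x)^2 + (y[last] - exit_y)^2)
      dirs[r] <- if (d_left <= d_right) "l2r" else "r2l"
    }
    if (dirs[r] == "r2l") line_idx[[r]] <- ids <- rev(ids)
    exit_x <- x[ids[length(ids)]]
    exit_y <- y[ids[length(ids)]]
  }
  out <- grouped[unlist(line_idx, use.names = FALSE), , drop = FALSE]
  out$direction <- rep(dirs, lengths(line_idx))
  out$seq <- seq_len(nrow(out))
  out
}

#' Maximum efficiency: MU per pulse at a given energy
#'
#' Maximum charge per pulse (expressed in MU) achievable at full Dee
#' voltage, as a function of beam energy: linear below the 123 MeV seam
#' (where the degrader configuration changes) and a degree-5 polynomial at
#' or above it, with coefficients as fitted.
#'
#' @param energy Beam energy, MeV. Vectorized.
#' @inheritParams critical_interval
#' @return MU per pulse (positive).
#' @export
#' @examples
#' max_efficiency(100)  # 0.0887
max_efficiency <- function(energy, machine = proteus_one()) {
  check_energy(energy, machine)
  p <- machine$efficiency
  poly_val <- vapply(energy, function(e) sum(p$poly * e^(seq_along(p$poly) - 1)),
                     numeric(1))
  out <- ifelse(energy < p$seam,
                p$lin_slope * energy + p$lin_intercept,
                poly_val)
  if (any(out <= 0)) stop("non-positive efficiency; check parameters",
                          call. = FALSE)
  out
}

#' Pulse count for one spot in one burst
#'
#' The number of pulses needed to deliver a spot's share of MU in a given
#' burst, assuming every pulse carries the maximum efficiency for the
#' layer's energy: `ceil(mu * S_j / v_i)`, never less than one pulse.
#' For a non-burst continuous-spill machine the count is instead the spill
#' duration `mu / rate` discretized at the pulse clock.
#'
#' @param mu Planned spot MU (> 0). Vectorized.
#' @param burst_index Burst number, 1-based.
#' @param energy Layer energy, MeV.
#' @inheritParams critical_interval
#' @return Integer pulse count (>= 1).
#' @export
#' @examples
#' pulses_for_spot(1.0, 1, 100)  # ceil(0.609 / 0.0887) = 7
#' pulses_for_spot(1.0, 3, 100)  # 1: third burst is a single pulse
pulses_for_spot <- function(mu, burst_index, energy, machine = proteus_one()) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (burst_index < 1 || burst_index > machine$burst$n_burst) {
    stop("burst_index must be in 1..", machine$burst$n_burst, call. = FALSE)
  }
  s <- machine$burst$fractions[burst_index]
  if (!is.null(machine$spill_rate_mu_s)) {
    ms <- mu * s / machine$spill_rate_mu_s * 1000
    return(pmax(1L, as.integer(round(ms / machine$pulse_period_ms))))
  }
  pmax(1L, as.integer(ceiling(mu * s / max_efficiency(energy, machine))))
}

#' Decompose a layer into its radiation bursts
#'
#' Every spot of the layer appears in every burst, in scan order, carrying
#' its burst MU share (`mu * S_j`) and the pulse count from
#' [pulses_for_spot()]. The burst mechanism acts like an adaptive layer
#' repainting: a 3-burst layer paints each spot three times.
#'
#' @param order A layer in delivery order, from [order_spots()].
#' @inheritParams critical_interval
#' @return A tibble with one row per (burst, spot): columns `burst`, `seq`,
#'   `line`, `x_mm`, `y_mm`, `mu`, `mu_burst`, `n_pulse`.
#' @export
split_bursts <- function(order, machine = proteus_one()) {
  energy <- unique(order$energy_MeV)
  stopifnot(length(energy) == 1)
  fr <- machine$burst$fractions
  nb <- machine$burst$n_burst
  k <- nrow(order)
  idx <- rep(seq_len(k), nb)
  burst <- rep(seq_len(nb), each = k)
  n_pulse <- unlist(lapply(seq_len(nb), function(j) {
    pulses_for_spot(order$mu, j, energy, machine)
  }), use.names = FALSE)
  tibble::new_tibble(list(
    burst = burst,
    seq = order$seq[idx],
    line = order$line[idx],
    x_mm = order$x_mm[idx],
    y_mm = order$y_mm[idx],
    mu = order$mu[idx],
    energy_MeV = rep(energy, length(idx)),
    mu_burst = order$mu[idx] * fr[burst],
    n_pulse = n_pulse
  ), nrow = length(idx))
}

#' Full delivery sequence of a field
#'
#' Applies [order_spots()] and [split_bursts()] to every layer: the
#' complete machine delivery order, one row per (layer, burst, spot).
#'
#' @inheritParams n_layers
#' @inheritParams critical_interval
#' @inheritParams group_lines
#' @return A tibble with columns `layer_index`, `energy_MeV`, `burst`,
#'   `seq`, `line`, `x_mm`, `y_mm`, `mu`, `mu_burst`, `n_pulse`, in
#'   delivery order.
#' @export
sequence_field <- function(field, machine = proteus_one(), y_tol = 1e-3) {
  layers <- field_layers(field)
  per_layer <- lapply(layers, function(layer) {
    ord <- order_spots(layer, y_tol)
    bursts <- split_bursts(ord, machine)
    bursts$layer_index <- layer$layer_index[1]
    bursts
  })
  out <- dplyr::bind_rows(per_layer)
  out[c("layer_index", "energy_MeV",
        setdiff(names(out), c("layer_index", "energy_MeV")))]
}
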