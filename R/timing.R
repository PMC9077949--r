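#' Critical descending energy interval S(E)
#'
#' Piecewise-linear threshold (MeV, negative over the valid range) separating
#' the short and long energy-layer switching regimes for a descending switch
#' that starts at `energy`. A descending switch whose interval is smaller
#' (more negative) than `S(E)` requires the long reconfiguration.
#'
#' @param energy Initial layer energy, MeV. Vectorized.
#' @param machine A [machine_model()].
#' @return Critical interval in MeV (negative).
#' @export
#' @examples
#' critical_interval(100)  # -19.5
#' critical_interval(200)  # -11
critical_interval <- function(energy, machine = proteus_one()) {
  check_energy(energy, machine)
  p <- machine$elst
  branch <- findInterval(energy, p$s_seams) + 1L
  p$s_slopes[branch] * energy + p$s_intercepts[branch]
}

#' Energy-layer switching time (ELST)
#'
#' Step model of the time to switch between two consecutive energy layers.
#' Descending switches within the critical interval [critical_interval()]
#' take the short time; deeper descents take the long time; any ascending
#' switch takes a constant long time. A repeated energy (zero interval) is
#' treated as a short descending switch (it does not occur clinically).
#'
#' @param e_from,e_to Energies of the current and next layer, MeV. Vectorized.
#' @inheritParams critical_interval
#' @return Switching time in seconds.
#' @export
#' @examples
#' elst(160, 155)  # 0.7
#' elst(150, 160)  # 5.5
#' elst(200, 170)  # 3.75
elst <- function(e_from, e_to, machine = proteus_one()) {
  check_energy(c(e_from, e_to), machine)
  p <- machine$elst
  de <- e_to - e_from
  s <- critical_interval(e_from, machine)
  dplyr::case_when(
    de > 0 ~ p$t_ascend,
    de < s ~ p$t_long,
    .default = p$t_short
  )
}

# log(1 + exp(z)) without overflow; for z > ~30 softplus(z) == z to < 1e-13
softplus <- function(z) {
  out <- numeric(length(z))
  hi <- z > 30
  out[hi] <- z[hi]
  out[!hi] <- log1p(exp(z[!hi]))
  out
}

#' Fast-axis (x) spot-switching time
#'
#' Modified-softplus model of the time to steer the beam a given distance
#' along the fast scan axis: a smoothed ramp turning on at `turn` mm with
#' asymptotic slope `slope` ms/mm, plus a Gaussian bump centered at the
#' turning point, plus the magnet-preparation baseline `t_min`.
#'
#' @param distance Scan distance, mm (non-negative). Vectorized.
#' @inheritParams critical_interval
#' @return Switching time in ms.
#' @export
#' @examples
#' xswitch_time(30)   # 0.26*log(2) + 1 + 6 = 7.18 ms
#' xswitch_time(130)  # ~32 ms (ramp regime)
xswitch_time <- function(distance, machine = proteus_one()) {
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  p <- machine$xswitch
  p$slope * softplus(distance - p$turn) +
    p$gauss_amp * exp(-0.5 * ((distance - p$turn) / p$gauss_width)^2) +
    p$t_min
}

#' Slow-axis (y) spot-switching time
#'
#' Three-piece model of the time to steer a given distance along the slow
#' scan axis: constant below `seam_low` mm, a degree-7 polynomial between
#' the seams, and linear at or above `seam_high` mm. Branches are evaluated
#' exactly as parameterized; no smoothing is applied at the seams.
#'
#' @inheritParams xswitch_time
#' @return Switching time in ms.
#' @export
#' @examples
#' yswitch_time(10)   # 10 ms (constant branch)
#' yswitch_time(200)  # 0.2399*200 + 34.809 ms
yswitch_time <- function(distance, machine = proteus_one()) {
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  p <- machine$yswitch
  poly_val <- vapply(distance, function(d) sum(p$poly * d^(seq_along(p$poly) - 1)),
                     numeric(1))
  dplyr::case_when(
    distance < p$seam_low ~ p$t_const,
    distance < p$seam_high ~ poly_val,
    .default = p$lin_slope * distance + p$lin_intercept
  )
}

#' Line-switching (diagonal) time
#'
#' Time to move between scan lines, covering `dx` on the fast axis and `dy`
#' on the slow axis simultaneously: the slower of the two axis movements
#' governs.
#'
#' @param dx,dy Absolute axis distances, mm. Vectorized.
#' @inheritParams critical_interval
#' @return Switching time in ms.
#' @export
line_switch_time <- function(dx, dy, machine = proteus_one()) {
  pmax(xswitch_time(dx, machine), yswitch_time(dy, machine))
}

#' Spot spill time
#'
#' Beam-on time for a spot delivered as `n_pulse` pulses at the machine's
#' pulse repetition period.
#'
#' @param n_pulse Pulse count (non-negative). Vectorized.
#' @inheritParams critical_interval
#' @return Spill time in ms.
#' @export
spill_time <- function(n_pulse, machine = proteus_one()) {
  if (any(n_pulse < 0)) stop("n_pulse must be non-negative", call. = FALSE)
  n_pulse * machine$pulse_period_ms
}

#' Burst-switching time (BST)
#'
#' Linear model of the gap between two consecutive radiation bursts of a
#' layer: proportional to the amount of delivery data exchanged between the
#' controller and the delivery system — the previous burst's irradiation
#' record (its spot-switching row count plus its pulse count) and the next
#' burst's command file (its pulse count plus its spot count) — plus a
#' constant dead time.
#'
#' @param n_ssw_prev Spot-switching row count of the previous burst.
#' @param n_pulse_prev Pulse count of the previous burst.
#' @param n_pulse_next Pulse count of the next burst.
#' @param n_spot_next Spot count of the next burst.
#' @inheritParams critical_interval
#' @return Switching time in seconds.
#' @export
#' @examples
#' bst(0, 0, 0, 0)  # dead time alone, 0.2228 s
bst <- function(n_ssw_prev, n_pulse_prev, n_pulse_next, n_spot_next,
                machine = proteus_one()) {
  counts <- c(n_ssw_prev, n_pulse_prev, n_pulse_next, n_spot_next)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- n_ssw_prev + n_pulse_prev + n_pulse_next + n_spot_next
  machine$bst$mu_coeff * total + machine$bst$dead_time
}

check_energy <- function(energy, machine) {
  r <- machine$energy_range
  if (any(!is.finite(energy)) || any(energy < r[1]) || any(energy > r[2])) {
    stop(sprintf("energy must lie in [%g, %g] MeV", r[1], r[2]), call. = FALSE)
  }
  invisible(energy)
}
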