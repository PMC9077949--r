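#' Periodic respiratory motion model
#'
#' One-dimensional sinusoidal target motion along a scan axis, parameterized
#' by peak amplitude and breathing period. The cycle is discretized into
#' `n_phases` phases; the starting phase shifts the waveform so that
#' delivery may begin anywhere in the cycle.
#'
#' @param amplitude Peak displacement, mm.
#' @param period Breathing period, s.
#' @param n_phases Number of breathing phases in the cycle.
#' @param start_phase Starting phase index, `0 .. n_phases - 1`.
#' @param axis Motion axis, `"x"` or `"y"`.
#' @return A `motion_model` list.
#' @export
motion_model <- function(amplitude = 5, period = 4, n_phases = 10,
                         start_phase = 0, axis = c("x", "y")) {
  stopifnot(amplitude >= 0, period > 0, n_phases >= 1,
            start_phase >= 0, start_phase < n_phases)
  structure(list(amplitude = amplitude, period = period,
                 n_phases = n_phases, start_phase = start_phase,
                 axis = match.arg(axis)),
            class = "motion_model")
}

#' Target displacement at a delivery instant
#'
#' @param t Time since delivery start, s. Vectorized.
#' @param motion A [motion_model()].
#' @return Displacement along the motion axis, mm.
#' @export
#' @examples
#' displacement(1, motion_model(amplitude = 5, period = 4))  # 5 mm
displacement <- function(t, motion) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  motion$amplitude *
    sin(2 * pi * (t / motion$period + motion$start_phase / motion$n_phases))
}

#' Rigid 2D toy phantom for interplay evaluation
#'
#' A square dose grid with a circular target mask and a Gaussian pencil-beam
#' dose kernel. Deliberately simple: dose is deposited on a rigid grid with
#' the spot position shifted by the instantaneous target displacement, so
#' directional interplay comparisons (burst vs non-burst, repainting
#' trends) are meaningful while absolute doses are in arbitrary MU-weighted
#' units.
#'
#' @param spacing Grid spacing, mm.
#' @param half_extent Grid half-width, mm (grid spans ±`half_extent`).
#' @param target_radius Circular target radius, mm; must fit inside the
#'   grid.
#' @param sigma Gaussian kernel width, mm.
#' @return A `toy_phantom` list with grid coordinates `xs`, `ys`, logical
#'   target `mask`, and parameters.
#' @export
toy_phantom <- function(spacing = 2, half_extent = 60, target_radius = 20,
                        sigma = 4) {
  stopifnot(spacing > 0, sigma > 0)
  if (target_radius >= half_extent) {
    stop("target must lie fully inside the grid", call. = FALSE)
  }
  xs <- seq(-half_extent, half_extent, by = spacing)
  ys <- seq(-half_extent, half_extent, by = spacing)
  mask <- outer(xs, ys, function(x, y) x^2 + y^2 <= target_radius^2)
  structure(list(xs = xs, ys = ys, mask = mask, spacing = spacing,
                 half_extent = half_extent, target_radius = target_radius,
                 sigma = sigma),
            class = "toy_phantom")
}

#' Accumulate 4D dynamic dose on the toy phantom
#'
#' Deposits every pulse of the timeline at its planned spot position shifted
#' by the target displacement at the pulse's start time: the 4D dynamic
#' dose under the assumption of an unchanged breathing pattern. Each pulse
#' contributes its delivered MU times a unit-mass Gaussian kernel, so the
#' integrated dose is conserved for any motion as long as kernels stay
#' inside the grid.
#'
#' @inheritParams breakdown
#' @inheritParams displacement
#' @param phantom A [toy_phantom()].
#' @return A dose matrix (rows = x grid, cols = y grid), in MU.
#' @export
accumulate_4d <- function(timeline, motion, phantom) {
  pulses <- timeline[timeline$kind == "pulse", ]
  dose <- matrix(0, nrow = length(phantom$xs), ncol = length(phantom$ys))
  if (nrow(pulses) == 0) return(dose)
  shift <- displacement(pulses$start_ms / 1000, motion)
  cx <- pulses$x_mm + if (motion$axis == "x") shift else 0
  cy <- pulses$y_mm + if (motion$axis == "y") shift else 0
  s2 <- phantom$sigma^2
  norm <- phantom$spacing^2 / (2 * pi * s2)
  for (p in seq_len(nrow(pulses))) {
    kx <- exp(-0.5 * (phantom$xs - cx[p])^2 / s2)
    ky <- exp(-0.5 * (phantom$ys - cy[p])^2 / s2)
    dose <- dose + (pulses$mu[p] * norm) * outer(kx, ky)
  }
  dose
}

#' Target D99 of a dose grid
#'
#' Dose received by 99% of the target volume: the 1st percentile of the
#' dose values inside the target mask.
#'
#' @param dose Dose matrix from [accumulate_4d()].
#' @inheritParams accumulate_4d
#' @return D99 in the dose grid's units.
#' @export
dose_d99 <- function(dose, phantom) {
  unname(quantile(dose[phantom$mask], probs = 0.01))
}

#' Interplay-effect evaluation over all starting phases
#'
#' Builds the delivery timeline once (optionally with volumetric
#' repainting), then accumulates the 4D dynamic dose for every starting
#' phase of the motion cycle and records the target D99 of each, alongside
#' the static (no motion) reference. The spread of D99 across starting
#' phases quantifies the interplay effect.
#'
#' @inheritParams n_layers
#' @inheritParams critical_interval
#' @inheritParams accumulate_4d
#' @param n_repaint Volumetric repainting number (>= 1).
#' @return An `interplay_result`: a tibble with one row per starting phase
#'   (`start_phase`, `d99`), with attributes `static_d99`, `mean_d99`,
#'   `sd_d99`, `machine_label`, `n_repaint`. Supports [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
run_interplay <- function(field, machine = proteus_one(),
                          motion = motion_model(), n_repaint = 1,
                          phantom = toy_phantom()) {
  stopifnot(n_repaint >= 1)
  reach <- max(abs(c(field$x_mm, field$y_mm))) + motion$amplitude +
    3 * phantom$sigma
  if (reach > phantom$half_extent + 1e-9) {
    stop("target/spot pattern (plus motion and kernel reach) extends ",
         "outside the dose grid", call. = FALSE)
  }
  timeline <- build_timeline(field, machine, n_repaint = n_repaint)
  static <- motion_model(amplitude = 0, period = motion$period,
                         n_phases = motion$n_phases, axis = motion$axis)
  static_d99 <- dose_d99(accumulate_4d(timeline, static, phantom), phantom)
  d99 <- vapply(seq_len(motion$n_phases) - 1L, function(ph) {
    m <- motion_model(amplitude = motion$amplitude, period = motion$period,
                      n_phases = motion$n_phases, start_phase = ph,
                      axis = motion$axis)
    dose_d99(accumulate_4d(timeline, m, phantom), phantom)
  }, numeric(1))
  out <- tibble::tibble(start_phase = seq_len(motion$n_phases) - 1L,
                        d99 = d99)
  attr(out, "static_d99") <- static_d99
  attr(out, "mean_d99") <- mean(d99)
  attr(out, "sd_d99") <- sd(d99)
  attr(out, "machine_label") <- machine$label
  attr(out, "n_repaint") <- n_repaint
  class(out) <- c("interplay_result", class(out))
  out
}

#' @rdname calibration-tidiers
#' @export
glance.interplay_result <- function(x, ...) {
  tibble::tibble(
    machine = attr(x, "machine_label"),
    n_repaint = attr(x, "n_repaint"),
    static_d99 = attr(x, "static_d99"),
    mean_d99 = attr(x, "mean_d99"),
    sd_d99 = attr(x, "sd_d99"),
    n_phases = nrow(x)
  )
}

#' @export
print.interplay_result <- function(x, ...) {
  cat(sprintf(
    "<interplay_result> %s, N_vol=%d: D99 %.4g +/- %.3g (static %.4g) over %d phases\n",
    attr(x, "machine_label"), attr(x, "n_repaint"),
    attr(x, "mean_d99"), attr(x, "sd_d99"), attr(x, "static_d99"), nrow(x)
  ))
  NextMethod()
}

#' Default interplay comparison scenario
#'
#' The fixed scenario used to compare burst and non-burst delivery under
#' motion: a two-layer square field (spot and line spacing 5 mm, 9 x 9
#' spots, 0.5 MU per spot, 160 and 155 MeV) covering the 20 mm circular
#' target, 5 mm / 4 s sinusoidal motion with 10 phases along x, and the
#' default toy phantom.
#'
#' @return A list with elements `field`, `motion`, `phantom`.
#' @export
interplay_scenario <- function() {
  square <- function(layer, energy) {
    f <- test_field_square(rep(0.5, 9), energy = energy, spacing = 5)
    dplyr::mutate(tibble::as_tibble(f), layer_index = layer,
                  energy_MeV = energy)
  }
  field <- pbs_field(dplyr::bind_rows(square(1, 160), square(2, 155)),
                     label = "interplay-default")
  list(field = field, motion = motion_model(), phantom = toy_phantom())
}
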