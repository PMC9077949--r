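#' Construct a machine timing model
#'
#' A `machine_model` bundles every parameter of the four delivery-time
#' sub-models for a pulsed synchrocyclotron pencil-beam-scanning system:
#' the energy-layer-switching step function, the x/y spot-switching curves,
#' the burst-switching linear model, the burst MU fractions, and the
#' maximum-efficiency (MU per pulse) curve. Defaults are the fitted values
#' for the modeled clinical system; [proteus_one()] returns them unchanged.
#'
#' All switching and spill times are handled in milliseconds internally;
#' layer- and burst-switching parameters are in seconds at the API surface
#' (matching how they are usually quoted) and converted explicitly during
#' timeline assembly. Distances are millimeters, energies MeV.
#'
#' @param elst Energy-layer switching parameters: `t_short`, `t_long`,
#'   `t_ascend` (s) and the piecewise-linear critical interval `S(E)`
#'   (`s_slopes`, `s_intercepts` per branch, `s_seams` in MeV).
#' @param xswitch Fast-axis (x) spot-switching parameters: `t_min` (ms),
#'   `slope` (ms/mm, numerically s/m), `turn` (mm), `gauss_width` (mm),
#'   `gauss_amp` (ms).
#' @param yswitch Slow-axis (y) spot-switching parameters: constant branch
#'   `t_const` (ms), degree-7 polynomial coefficients `poly` (p0..p7),
#'   branch seams `seam_low`/`seam_high` (mm), and the linear tail
#'   `lin_slope` (ms/mm), `lin_intercept` (ms).
#' @param bst Burst-switching parameters: data-transmission coefficient
#'   `mu_coeff` (s per transmitted count) and `dead_time` (s).
#' @param burst Burst constants: MU `fractions` (must sum to 1) and
#'   `n_burst` (number of bursts per layer).
#' @param efficiency Maximum-efficiency curve (MU/pulse): linear branch
#'   `lin_slope`/`lin_intercept` below `seam` MeV and degree-5 polynomial
#'   coefficients `poly` (a0..a5) at or above it.
#' @param pulse_period_ms Pulse repetition period, ms (1 kHz machine).
#' @param pulse_duration_us Beam-on time within one pulse, microseconds
#'   (metadata only; not used in timing).
#' @param mu_min Minimum deliverable MU per spot.
#' @param energy_range Valid nominal beam energy range, MeV.
#' @param spill_rate_mu_s Continuous spill rate in MU/s for a non-burst
#'   (cyclotron-style) reference machine, or `NULL` for the pulsed burst
#'   machine. See [nonburst_machine()].
#' @param label Free-text machine label.
#'
#' @return An object of class `machine_model`.
#' @seealso [proteus_one()], [nonburst_machine()], [read_machine()],
#'   [write_machine()]
#' @export
#' @examples
#' m <- proteus_one()
#' elst(160, 155, m)       # short descending switch, s
#' xswitch_time(30, m)     # fast-axis switch at the turning point, ms
machine_model <- function(elst = list(),
                          xswitch = list(),
                          yswitch = list(),
                          bst = list(),
                          burst = list(),
                          efficiency = list(),
                          pulse_period_ms = 1,
                          pulse_duration_us = 7,
                          mu_min = 0.01,
                          energy_range = c(70, 227),
                          spill_rate_mu_s = NULL,
                          label = "synchrocyclotron-pbs") {
  defaults <- machine_defaults()
  m <- list(
    elst       = utils::modifyList(defaults$elst, elst),
    xswitch    = utils::modifyList(defaults$xswitch, xswitch),
    yswitch    = utils::modifyList(defaults$yswitch, yswitch),
    bst        = utils::modifyList(defaults$bst, bst),
    burst      = utils::modifyList(defaults$burst, burst),
    efficiency = utils::modifyList(defaults$efficiency, efficiency),
    pulse_period_ms = pulse_period_ms,
    pulse_duration_us = pulse_duration_us,
    mu_min = mu_min,
    energy_range = energy_range,
    spill_rate_mu_s = spill_rate_mu_s,
    label = label
  )
  class(m) <- "machine_model"
  validate_machine(m)
  m
}

machine_defaults <- function() {
  list(
    elst = list(
      t_short = 0.7, t_long = 3.75, t_ascend = 5.5,
      s_seams = c(110, 150),
      s_slopes = c(0.2, 0.1, 0.05),
      s_intercepts = c(-39.5, -28.5, -21)
    ),
    xswitch = list(t_min = 6, slope = 0.26, turn = 30,
                   gauss_width = 10, gauss_amp = 1),
    yswitch = list(
      t_const = 10, seam_low = 15.35, seam_high = 100,
      poly = c(3.701164361860537, -1.431281202229966,
               0.1760201780078124, -4.965471530006315e-3,
               6.520478442495668e-5, -4.408172810657032e-7,
               1.484166290834395e-9, -1.967097213355599e-12),
      lin_slope = 0.2399, lin_intercept = 34.809
    ),
    bst = list(mu_coeff = 5e-5, dead_time = 0.2228),
    burst = list(fractions = c(0.609, 0.330, 0.061), n_burst = 3),
    efficiency = list(
      lin_slope = 0.001971, lin_intercept = -0.1084, seam = 123,
      poly = c(34.91785611467123, -0.9845329482724059,
               0.01098029030171986, -0.00006048892122110666,
               0.000000165088904656624, -0.0000000001789254400704347)
    )
  )
}

validate_machine <- function(m) {
  stopifnot(
    m$pulse_period_ms > 0,
    m$mu_min >= 0,
    m$elst$t_short > 0, m$elst$t_long > 0, m$elst$t_ascend > 0,
    m$xswitch$t_min >= 0, m$xswitch$slope > 0,
    m$bst$mu_coeff >= 0, m$bst$dead_time >= 0,
    length(m$burst$fractions) == m$burst$n_burst,
    all(m$burst$fractions > 0)
  )
  if (abs(sum(m$burst$fractions) - 1) > 1e-9) {
    stop("burst MU fractions must sum to 1 (got ",
         sum(m$burst$fractions), ")", call. = FALSE)
  }
  if (!is.null(m$spill_rate_mu_s) && m$spill_rate_mu_s <= 0) {
    stop("spill_rate_mu_s must be positive", call. = FALSE)
  }
  invisible(m)
}

#' Default pulsed three-burst machine model
#'
#' Returns the [machine_model()] with every parameter at its fitted default:
#' the three-burst pulsed synchrocyclotron delivery model.
#'
#' @return A `machine_model`.
#' @export
proteus_one <- function() machine_model()

#' Non-burst continuous-spill reference machine
#'
#' A simplified cyclotron-style reference model used for interplay-effect
#' comparison: one pass per energy layer (no bursts, hence no burst
#' switching) with a continuous spill whose duration is `mu / rate`,
#' discretized at the 1 kHz clock. Scan ordering and the spot/line
#' switching models are shared with the burst machine.
#'
#' The default rate is chosen so that the total delivery time of the
#' non-burst reference is within 20% of the burst machine on the package's
#' default interplay scenario, keeping the comparison about delivery
#' structure rather than duration.
#'
#' @param spill_rate_mu_s Continuous spill rate, MU/s.
#' @return A `machine_model` with `n_burst = 1`.
#' @export
nonburst_machine <- function(spill_rate_mu_s = 20) {
  machine_model(
    burst = list(fractions = 1, n_burst = 1),
    spill_rate_mu_s = spill_rate_mu_s,
    label = "nonburst-reference"
  )
}

#' @export
print.machine_model <- function(x, ...) {
  kind <- if (is.null(x$spill_rate_mu_s)) {
    sprintf("%d-burst pulsed", x$burst$n_burst)
  } else {
    sprintf("non-burst continuous spill (%.3g MU/s)", x$spill_rate_mu_s)
  }
  cat("<machine_model> ", x$label, " [", kind, "]\n", sep = "")
  cat(sprintf("  ELST steps: %.3g / %.3g / %.3g s (short/long/ascend)\n",
              x$elst$t_short, x$elst$t_long, x$elst$t_ascend))
  cat(sprintf("  x-switch: t_min %.3g ms, slope %.4g ms/mm, turn %g mm\n",
              x$xswitch$t_min, x$xswitch$slope, x$xswitch$turn))
  cat(sprintf("  BST: %.3g s/count + %.4g s dead time\n",
              x$bst$mu_coeff, x$bst$dead_time))
  cat(sprintf("  burst MU fractions: %s\n",
              paste(format(x$burst$fractions), collapse = " / ")))
  invisible(x)
}

#' Read or write a machine model as YAML
#'
#' The machine parameter file is a plain YAML document listing every
#' parameter of [machine_model()] under the same names; absent entries
#' fall back to the defaults.
#'
#' @param path File path.
#' @return `read_machine()` returns a `machine_model`; `write_machine()`
#'   returns `path` invisibly.
#' @export
read_machine <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(machine_model)))]
  do.call(machine_model, args)
}

#' @param machine A `machine_model`.
#' @rdname read_machine
#' @export
write_machine <- function(machine, path) {
  stopifnot(inherits(machine, "machine_model"))
  yaml::write_yaml(unclass(machine), path, precision = 17)
  invisible(path)
}
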