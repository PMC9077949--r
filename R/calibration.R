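#' Noise specification for synthetic observations
#'
#' Zero-mean Gaussian measurement noise applied per observation kind when
#' synthesizing log-style observations. All standard deviations default to
#' zero (noiseless).
#'
#' @param bst_sd Burst-switching observation sd, s.
#' @param switch_sd Spot-switching observation sd, ms.
#' @param elst_sd Layer-switching observation sd, s.
#' @param fraction_sd Per-layer burst MU fraction sd (dimensionless).
#' @param seed Integer seed making the draw reproducible.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(bst_sd = 0, switch_sd = 0, elst_sd = 0,
                       fraction_sd = 0, seed = 1L) {
  stopifnot(bst_sd >= 0, switch_sd >= 0, elst_sd >= 0, fraction_sd >= 0)
  structure(list(bst_sd = bst_sd, switch_sd = switch_sd, elst_sd = elst_sd,
                 fraction_sd = fraction_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthesize log-style calibration observations from a field
#'
#' Generates the observation tables that would be extracted from machine
#' delivery logs of the given field: burst-switching gaps against the
#' transmitted-count sums, spot-switching times against travel distance
#' (fast axis for intra-line moves, slow axis for pure-y line entries),
#' inter-layer gaps, and per-layer burst MU fractions. Observations are the
#' timing model's true values plus zero-mean Gaussian noise per
#' [noise_spec()]; the same seed reproduces the same draw.
#'
#' @inheritParams n_layers
#' @inheritParams critical_interval
#' @param noise A [noise_spec()].
#' @return A list of tibbles: `bst` (`count_sum`, `observed_s`), `switch`
#'   (`distance_mm`, `axis`, `observed_ms`), `elst` (`e_from`, `e_to`,
#'   `observed_s`), `fractions` (`layer_index`, `burst`, `fraction`).
#' @export
synth_observations <- function(field, machine = proteus_one(),
                               noise = noise_spec()) {
  seq_tbl <- sequence_field(field, machine)
  withr::with_seed(noise$seed, {
    layers <- split(seq_tbl, factor(seq_tbl$layer_index,
                                    levels = unique(seq_tbl$layer_index)))
    bst_rows <- list(); switch_rows <- list(); frac_rows <- list()
    for (layer_seq in layers) {
      st <- burst_stats(layer_seq, machine)
      nb <- machine$burst$n_burst
      if (nb > 1) {
        for (j in seq_len(nb - 1)) {
          cs <- st$n_ssw[j] + st$n_pulse[j] + st$n_pulse[j + 1] + st$n_spot[j + 1]
          bst_rows[[length(bst_rows) + 1]] <- tibble::tibble(
            layer_index = layer_seq$layer_index[1],
            count_sum = cs,
            observed_s = bst(st$n_ssw[j], st$n_pulse[j], st$n_pulse[j + 1],
                             st$n_spot[j + 1], machine) +
              rnorm(1, 0, noise$bst_sd)
          )
        }
      }
      b1 <- layer_seq[layer_seq$burst == 1, ]
      if (nrow(b1) > 1) {
        same_line <- b1$line[-1] == b1$line[-nrow(b1)]
        dx <- abs(diff(b1$x_mm)); dy <- abs(diff(b1$y_mm))
        x_moves <- which(same_line)
        y_moves <- which(!same_line & dx < 1e-9)
        if (length(x_moves) > 0) {
          switch_rows[[length(switch_rows) + 1]] <- tibble::tibble(
            distance_mm = dx[x_moves], axis = "x",
            observed_ms = xswitch_time(dx[x_moves], machine) +
              rnorm(length(x_moves), 0, noise$switch_sd)
          )
        }
        if (length(y_moves) > 0) {
          switch_rows[[length(switch_rows) + 1]] <- tibble::tibble(
            distance_mm = dy[y_moves], axis = "y",
            observed_ms = line_switch_time(dx[y_moves], dy[y_moves], machine) +
              rnorm(length(y_moves), 0, noise$switch_sd)
          )
        }
      }
      mu_by_burst <- vapply(split(layer_seq$mu_burst, layer_seq$burst), sum,
                            numeric(1))
      frac <- mu_by_burst / sum(mu_by_burst) +
        rnorm(length(mu_by_burst), 0, noise$fraction_sd)
      frac_rows[[length(frac_rows) + 1]] <- tibble::tibble(
        layer_index = layer_seq$layer_index[1],
        burst = seq_along(frac), fraction = frac
      )
    }
    energies <- vapply(layers, function(l) l$energy_MeV[1], numeric(1))
    elst_tbl <- if (length(energies) > 1) {
      e_from <- energies[-length(energies)]
      e_to <- energies[-1]
      tibble::tibble(
        e_from = e_from, e_to = e_to,
        observed_s = elst(e_from, e_to, machine) +
          rnorm(length(energies) - 1, 0, noise$elst_sd)
      )
    } else {
      tibble::tibble(e_from = numeric(), e_to = numeric(),
                     observed_s = numeric())
    }
    list(
      bst = dplyr::bind_rows(bst_rows),
      switch = dplyr::bind_rows(switch_rows),
      elst = elst_tbl,
      fractions = dplyr::bind_rows(frac_rows)
    )
  })
}

#' Extract calibration observations from a delivery log
#'
#' The log-analysis counterpart of [synth_observations()]: reads switching
#' gaps and burst-switching gaps directly off a recorded log table. Each
#' maximal run of switch rows between two pulse runs within a burst is one
#' switching observation (duration = run length at the log quantum,
#' distance from the flanking pulse positions; intra-line runs are fast-axis
#' observations, pure-y line entries slow-axis ones, diagonal entries
#' dropped as unattributable). Each burst gap is one burst-switching
#' observation with its transmitted-count sum reconstructed from the
#' per-burst row counts.
#'
#' @inheritParams parse_log
#' @param x_tol Fast-axis distance below which a line entry counts as a
#'   pure slow-axis move, mm.
#' @return A list of tibbles `bst` and `switch`, shaped as in
#'   [synth_observations()].
#' @export
extract_observations <- function(log, period_ms = 1, x_tol = 1e-6) {
  parsed <- parse_log(log, period_ms)
  switch_rows <- list()
  in_burst <- log[log$kind %in% c("pulse", "spot_switch", "line_switch"), ]
  groups <- split(seq_len(nrow(in_burst)),
                  paste(in_burst$layer_index, in_burst$burst))
  for (ids in groups) {
    rows <- in_burst[ids, ]
    runs <- rle(rows$kind)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (ri in seq_along(runs$values)) {
      if (runs$values[ri] == "pulse" || ri == 1 ||
          ri == length(runs$values)) {
        next
      }
      prev_pulse <- rows[ends[ri - 1], ]
      next_pulse <- rows[starts[ri + 1], ]
      dx <- abs(next_pulse$x_mm - prev_pulse$x_mm)
      dy <- abs(next_pulse$y_mm - prev_pulse$y_mm)
      obs_ms <- runs$lengths[ri] * period_ms
      if (runs$values[ri] == "spot_switch") {
        switch_rows[[length(switch_rows) + 1]] <-
          tibble::tibble(distance_mm = dx, axis = "x", observed_ms = obs_ms)
      } else if (dx <= x_tol) {
        switch_rows[[length(switch_rows) + 1]] <-
          tibble::tibble(distance_mm = dy, axis = "y", observed_ms = obs_ms)
      }
    }
  }
  bursts <- parsed$bursts
  bst_rows <- list()
  gap_rows <- log[log$kind == "burst_switch", ]
  if (nrow(gap_rows) > 0) {
    gaps <- dplyr::summarise(
      dplyr::group_by(gap_rows, .data$layer_index, .data$burst),
      observed_s = dplyr::n() * period_ms / 1000, .groups = "drop"
    )
    for (r in seq_len(nrow(gaps))) {
      prev <- bursts[bursts$layer_index == gaps$layer_index[r] &
                     bursts$burst == gaps$burst[r], ]
      nxt <- bursts[bursts$layer_index == gaps$layer_index[r] &
                    bursts$burst == gaps$burst[r] + 1, ]
      if (nrow(prev) == 1 && nrow(nxt) == 1) {
        bst_rows[[length(bst_rows) + 1]] <- tibble::tibble(
          layer_index = gaps$layer_index[r],
          count_sum = prev$n_ssw + prev$n_pulse + nxt$n_pulse + nxt$n_spot,
          observed_s = gaps$observed_s[r]
        )
      }
    }
  }
  list(bst = dplyr::bind_rows(bst_rows), switch = dplyr::bind_rows(switch_rows))
}

#' Fit the burst-switching linear model
#'
#' Ordinary least squares of observed burst-switching gaps against the
#' transmitted-count sum, recovering the data-transmission coefficient
#' (slope) and the dead time (intercept).
#'
#' @param obs A tibble with columns `count_sum` and `observed_s` (as
#'   produced by [synth_observations()]`$bst` or extracted from logs).
#' @return A `bst_fit` with elements `mu_coeff`, `dead_time`, `r_squared`,
#'   `n`, and the underlying `lm` fit. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_bst <- function(obs) {
  stopifnot(all(c("count_sum", "observed_s") %in% names(obs)))
  if (length(unique(obs$count_sum)) < 2) {
    stop("degenerate design: need at least 2 distinct count sums",
         call. = FALSE)
  }
  fit <- lm(observed_s ~ count_sum, data = obs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((obs$observed_s - mean(obs$observed_s))^2)
  structure(list(
    mu_coeff = unname(coef(fit)["count_sum"]),
    dead_time = unname(coef(fit)["(Intercept)"]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    n = nrow(obs),
    fit = fit
  ), class = "bst_fit")
}

#' Fit the fast-axis spot-switching model
#'
#' Least-squares recovery of the baseline `t_min` and ramp `slope` of the
#' modified-softplus switching model, with the nonlinear shape constants
#' (turning point, Gaussian width and amplitude) held fixed at their model
#' values — after subtracting the fixed Gaussian bump the model is linear
#' in the two free parameters.
#'
#' @param obs A tibble with columns `distance_mm`, `axis`, `observed_ms`;
#'   only `axis == "x"` rows are used.
#' @inheritParams critical_interval
#' @return An `xswitch_fit` with elements `t_min`, `slope`,
#'   `residual_norm`, `n`, and the underlying `lm` fit. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_xswitch <- function(obs, machine = proteus_one()) {
  obs <- obs[obs$axis == "x", ]
  p <- machine$xswitch
  if (nrow(obs) < 2 ||
      !any(obs$distance_mm < p$turn) || !any(obs$distance_mm > p$turn)) {
    stop("insufficient distance span: need observations below and above ",
         p$turn, " mm", call. = FALSE)
  }
  sp <- softplus(obs$distance_mm - p$turn)
  y <- obs$observed_ms -
    p$gauss_amp * exp(-0.5 * ((obs$distance_mm - p$turn) / p$gauss_width)^2)
  fit <- lm(y ~ sp)
  structure(list(
    t_min = unname(coef(fit)["(Intercept)"]),
    slope = unname(coef(fit)["sp"]),
    residual_norm = sqrt(sum(fit$residuals^2)),
    n = nrow(obs),
    fit = fit
  ), class = "xswitch_fit")
}

#' Estimate burst MU fractions from a delivery log
#'
#' Sums delivered MU per burst within each complete layer, normalizes per
#' layer, and averages across layers; the averaged fractions are
#' renormalized to sum to one. The per-burst standard deviation across
#' layers is reported alongside.
#'
#' @inheritParams parse_log
#' @param n_burst Expected number of bursts per layer; layers with fewer
#'   recorded bursts are reported as incomplete.
#' @return A `burst_fraction_fit`: a tibble with columns `burst`,
#'   `fraction`, `sd`, `n_layers`.
#' @export
fit_burst_fractions <- function(log, n_burst = 3) {
  parsed <- parse_log(log)
  per_burst <- parsed$bursts
  if (nrow(per_burst) == 0) stop("log contains no bursts", call. = FALSE)
  counts <- table(per_burst$layer_index)
  if (any(counts < n_burst)) {
    stop("incomplete layer(s) in log: ",
         paste(names(counts)[counts < n_burst], collapse = ", "),
         call. = FALSE)
  }
  frac <- dplyr::mutate(dplyr::group_by(per_burst, .data$layer_index),
                        fraction = .data$mu / sum(.data$mu))
  out <- dplyr::summarise(dplyr::group_by(dplyr::ungroup(frac), .data$burst),
                          sd = sd(.data$fraction),
                          fraction = mean(.data$fraction),
                          n_layers = dplyr::n(),
                          .groups = "drop")
  out$sd[is.na(out$sd)] <- 0
  out$fraction <- out$fraction / sum(out$fraction)
  out <- out[c("burst", "fraction", "sd", "n_layers")]
  class(out) <- c("burst_fraction_fit", class(out))
  out
}

#' Estimate layer-switching times from a single-spot ladder log
#'
#' For a log recorded from a ladder field (one single-spot layer per
#' energy), the gap between consecutive layers' pulse blocks is the
#' energy-layer switching time directly: measured here as the time from the
#' end of one layer's last pulse row to the start of the next layer's first
#' pulse row.
#'
#' @inheritParams parse_log
#' @return A tibble with columns `from_layer`, `to_layer`, `gap_s`.
#' @export
estimate_elst <- function(log, period_ms = 1) {
  parsed <- parse_log(log, period_ms)
  if (any(parsed$bursts$n_spot > 1)) {
    stop("multi-spot layers present; ELST extraction needs a ",
         "single-spot-per-layer ladder field", call. = FALSE)
  }
  pulses <- log[log$kind == "pulse", ]
  layer_ids <- unique(pulses$layer_index)
  if (length(layer_ids) < 2) {
    return(tibble::tibble(from_layer = numeric(), to_layer = numeric(),
                          gap_s = numeric()))
  }
  blocks <- dplyr::summarise(dplyr::group_by(pulses, .data$layer_index),
                             first_ms = min(.data$time_ms),
                             last_ms = max(.data$time_ms),
                             .groups = "drop")
  blocks <- blocks[match(layer_ids, blocks$layer_index), ]
  n <- nrow(blocks)
  tibble::tibble(
    from_layer = blocks$layer_index[-n],
    to_layer = blocks$layer_index[-1],
    gap_s = (blocks$first_ms[-1] - (blocks$last_ms[-n] + period_ms)) / 1000
  )
}

#' Re-fit a machine model from log-style observations
#'
#' Convenience wrapper running the individual fitters over an observation
#' set (and, if given, a delivery log for the burst fractions) and
#' returning an updated [machine_model()] plus a fit report.
#'
#' @param obs Observation list as from [synth_observations()].
#' @param log Optional `pbs_log` for [fit_burst_fractions()].
#' @param base A `machine_model` supplying every parameter not re-fitted.
#' @return A list with elements `machine` (updated model) and `report`
#'   (named list of fit summaries).
#' @export
calibrate_machine <- function(obs, log = NULL, base = proteus_one()) {
  report <- list()
  machine <- base
  if (!is.null(obs$bst) && nrow(obs$bst) > 0 &&
      length(unique(obs$bst$count_sum)) >= 2) {
    fb <- fit_bst(obs$bst)
    machine$bst$mu_coeff <- fb$mu_coeff
    machine$bst$dead_time <- fb$dead_time
    report$bst <- glance(fb)
  }
  if (!is.null(obs$switch) && any(obs$switch$axis == "x")) {
    fx <- tryCatch(fit_xswitch(obs$switch, base), error = function(e) NULL)
    if (!is.null(fx)) {
      machine$xswitch$t_min <- fx$t_min
      machine$xswitch$slope <- fx$slope
      report$xswitch <- glance(fx)
    }
  }
  if (!is.null(log)) {
    ff <- fit_burst_fractions(log)
    machine$burst$fractions <- ff$fraction
    report$burst_fractions <- tibble::as_tibble(ff)
  }
  validate_machine(machine)
  list(machine = machine, report = report)
}

#' @export
print.bst_fit <- function(x, ...) {
  cat(sprintf("<bst_fit> slope %.6g s/count, dead time %.6g s, R^2 %.4f (n=%d)\n",
              x$mu_coeff, x$dead_time, x$r_squared, x$n))
  invisible(x)
}

#' @export
print.xswitch_fit <- function(x, ...) {
  cat(sprintf("<xswitch_fit> t_min %.6g ms, slope %.6g ms/mm, ||resid|| %.4g (n=%d)\n",
              x$t_min, x$slope, x$residual_norm, x$n))
  invisible(x)
}

#' Tidiers for calibration fits
#'
#' [generics::tidy()] returns one row per fitted parameter;
#' [generics::glance()] returns a one-row model summary.
#'
#' @param x A `bst_fit` or `xswitch_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name calibration-tidiers
NULL

#' @rdname calibration-tidiers
#' @export
tidy.bst_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("dead_time", "mu_coeff"),
    estimate = c(x$dead_time, x$mu_coeff),
    std.error = s[, "Std. Error"]
  )
}

#' @rdname calibration-tidiers
#' @export
glance.bst_fit <- function(x, ...) {
  tibble::tibble(mu_coeff = x$mu_coeff, dead_time = x$dead_time,
                 r.squared = x$r_squared, nobs = x$n)
}

#' @rdname calibration-tidiers
#' @export
tidy.xswitch_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("t_min", "slope"),
    estimate = c(x$t_min, x$slope),
    std.error = s[, "Std. Error"]
  )
}

#' @rdname calibration-tidiers
#' @export
glance.xswitch_fit <- function(x, ...) {
  tibble::tibble(t_min = x$t_min, slope = x$slope,
                 residual_norm = x$residual_norm, nobs = x$n)
}
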