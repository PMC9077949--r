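#' Build the full delivery timeline of a field
#'
#' Assembles the machine's delivery events in order: within each layer the
#' bursts run in sequence, each burst visiting every spot in serpentine scan
#' order — pulses at the pulse period, intra-line gaps from
#' [xswitch_time()], line-entry gaps from [line_switch_time()] — with a
#' burst-switching gap ([bst()]) between consecutive bursts and a
#' layer-switching gap ([elst()]) between layers. The first spot of every
#' burst has no preceding switch gap; travel back to a burst's first spot is
#' absorbed in the burst-switching time. Total delivery time is measured
#' from the first pulse's start to the last pulse's end.
#'
#' @inheritParams n_layers
#' @inheritParams critical_interval
#' @inheritParams group_lines
#' @param n_repaint Volumetric repainting number: the whole field is
#'   delivered `n_repaint` times at `1/n_repaint` MU (see [repaint_field()]).
#' @return A `pbs_timeline`: a tibble of delivery events with columns
#'   `start_ms`, `duration_ms`, `kind` (`pulse`, `spot_switch`,
#'   `line_switch`, `burst_switch`, `layer_switch`), `layer_index`, `burst`,
#'   `spot` (delivery index within burst), `x_mm`, `y_mm`, `mu` (delivered
#'   MU, pulse events only). The generating machine model is attached as
#'   attribute `machine`.
#' @export
#' @examples
#' f <- test_field_elst_ladder(c(160, 155))
#' tl <- build_timeline(f)
#' breakdown(tl)
build_timeline <- function(field, machine = proteus_one(), y_tol = 1e-3,
                           n_repaint = 1) {
  report <- validate_field(field, machine)
  if (!is_deliverable(report)) {
    stop("field fails validation: ",
         paste(unique(report$message[report$severity == "error"]),
               collapse = "; "),
         call. = FALSE)
  }
  field <- repaint_field(field, n_repaint)
  seq_tbl <- sequence_field(field, machine, y_tol)
  layers <- split(seq_tbl, factor(seq_tbl$layer_index,
                                  levels = unique(seq_tbl$layer_index)))
  period <- machine$pulse_period_ms
  n_burst <- machine$burst$n_burst

  chunks <- vector("list", 0)
  t <- 0
  gap_row <- function(start, duration, kind, layer, burst) {
    tibble::new_tibble(list(
      start_ms = start, duration_ms = duration, kind = kind,
      layer_index = layer, burst = as.numeric(burst), spot = NA_integer_,
      x_mm = NA_real_, y_mm = NA_real_, mu = NA_real_
    ), nrow = 1L)
  }

  for (li in seq_along(layers)) {
    layer_seq <- layers[[li]]
    layer_id <- layer_seq$layer_index[1]
    bursts <- split(layer_seq, layer_seq$burst)
    stats <- burst_stats(layer_seq, machine)
    for (j in seq_len(n_burst)) {
      bs <- bursts[[j]]
      k <- nrow(bs)
      np <- bs$n_pulse
      if (k > 1) {
        same_line <- bs$line[-1] == bs$line[-k]
        dx <- abs(diff(bs$x_mm))
        dy <- abs(diff(bs$y_mm))
        gap_dur <- ifelse(same_line, xswitch_time(dx, machine),
                          line_switch_time(dx, dy, machine))
        gap_kind <- ifelse(same_line, "spot_switch", "line_switch")
      } else {
        gap_dur <- numeric(0)
        gap_kind <- character(0)
      }
      # interleave: per spot an entry gap (except the first) then its pulses
      spot_of <- c(seq_len(k)[-1], rep(seq_len(k), np))
      within <- c(rep(0L, k - 1), sequence(np))
      o <- order(spot_of, within)
      dur <- c(gap_dur, rep(period, sum(np)))[o]
      kind <- c(gap_kind, rep("pulse", sum(np)))[o]
      spot <- spot_of[o]
      is_pulse <- kind == "pulse"
      mu_pulse <- (bs$mu_burst / np)[spot]
      n_ev <- length(dur)
      chunks[[length(chunks) + 1]] <- tibble::new_tibble(list(
        start_ms = t + cumsum(c(0, dur[-n_ev])),
        duration_ms = dur, kind = kind,
        layer_index = rep(layer_id, n_ev), burst = rep(as.numeric(j), n_ev),
        spot = spot,
        x_mm = ifelse(is_pulse, bs$x_mm[spot], NA_real_),
        y_mm = ifelse(is_pulse, bs$y_mm[spot], NA_real_),
        mu = ifelse(is_pulse, mu_pulse, NA_real_)
      ), nrow = n_ev)
      t <- t + sum(dur)
      if (j < n_burst) {
        gap_s <- unname(bst(stats$n_ssw[j], stats$n_pulse[j],
                            stats$n_pulse[j + 1], stats$n_spot[j + 1],
                            machine))
        chunks[[length(chunks) + 1]] <-
          gap_row(t, gap_s * 1000, "burst_switch", layer_id, j)
        t <- t + gap_s * 1000
      }
    }
    if (li < length(layers)) {
      e_from <- layer_seq$energy_MeV[1]
      e_to <- layers[[li + 1]]$energy_MeV[1]
      gap_s <- elst(e_from, e_to, machine)
      chunks[[length(chunks) + 1]] <-
        gap_row(t, gap_s * 1000, "layer_switch", layer_id, NA_integer_)
      t <- t + gap_s * 1000
    }
  }

  tl <- dplyr::bind_rows(chunks)
  attr(tl, "machine") <- machine
  attr(tl, "label") <- attr(field, "label")
  class(tl) <- c("pbs_timeline", class(tl))
  tl
}

# Per-burst bookkeeping for the BST model: pulse counts, spot counts, and
# the spot-switching row count N_SSW = round(summed switch time / 1 ms).
burst_stats <- function(layer_seq, machine) {
  bursts <- split(layer_seq, layer_seq$burst)
  n_pulse <- vapply(bursts, function(b) sum(b$n_pulse), numeric(1))
  n_spot <- vapply(bursts, nrow, numeric(1))
  n_ssw <- vapply(bursts, function(b) {
    if (nrow(b) < 2) return(0)
    same_line <- b$line[-1] == b$line[-nrow(b)]
    dx <- abs(diff(b$x_mm))
    dy <- abs(diff(b$y_mm))
    gaps <- ifelse(same_line,
                   xswitch_time(dx, machine),
                   line_switch_time(dx, dy, machine))
    round(sum(gaps) / machine$pulse_period_ms)
  }, numeric(1))
  list(n_pulse = unname(n_pulse), n_spot = unname(n_spot),
       n_ssw = unname(n_ssw))
}

#' Four-component delivery-time breakdown
#'
#' Sums the timeline's event durations by kind into the four delivery-time
#' components — layer switching, burst switching, spot switching (intra-line
#' plus line entry), and spot spill — whose sum is the total beam delivery
#' time.
#'
#' @param timeline A `pbs_timeline` from [build_timeline()].
#' @return A one-row tibble with columns `t_lsw_s`, `t_bsw_s`, `t_ssw_s`,
#'   `t_ssp_s`, `t_bdt_s` and the component percentages `pct_lsw`,
#'   `pct_bsw`, `pct_ssw`, `pct_ssp`.
#' @export
breakdown <- function(timeline) {
  ms <- function(kinds) {
    sum(timeline$duration_ms[timeline$kind %in% kinds])
  }
  t_lsw <- ms("layer_switch") / 1000
  t_bsw <- ms("burst_switch") / 1000
  t_ssw <- ms(c("spot_switch", "line_switch")) / 1000
  t_ssp <- ms("pulse") / 1000
  t_bdt <- t_lsw + t_bsw + t_ssw + t_ssp
  tibble::tibble(
    t_lsw_s = t_lsw, t_bsw_s = t_bsw, t_ssw_s = t_ssw, t_ssp_s = t_ssp,
    t_bdt_s = t_bdt,
    pct_lsw = 100 * t_lsw / t_bdt, pct_bsw = 100 * t_bsw / t_bdt,
    pct_ssw = 100 * t_ssw / t_bdt, pct_ssp = 100 * t_ssp / t_bdt
  )
}

#' Compare a model prediction against an observed delivery log
#'
#' Runs the prediction for a field and sets it against the component
#' breakdown reconstructed from a delivery log table, reporting absolute
#' and relative differences per component — the standard validation of the
#' timing model against recorded deliveries.
#'
#' @inheritParams n_layers
#' @param log A log table (see [emit_log()] / [read_log()]).
#' @inheritParams critical_interval
#' @return A tibble with one row per component: `component`, `predicted_s`,
#'   `observed_s`, `diff_s`, `diff_pct`.
#' @export
compare_to_log <- function(field, log, machine = proteus_one()) {
  pred <- breakdown(build_timeline(field, machine))
  obs <- parse_log(log)$breakdown
  comp <- c("t_lsw_s", "t_bsw_s", "t_ssw_s", "t_ssp_s", "t_bdt_s")
  tibble::tibble(
    component = c("layer_switch", "burst_switch", "spot_switch",
                  "spot_spill", "total"),
    predicted_s = as.numeric(pred[1, comp]),
    observed_s = as.numeric(obs[1, comp]),
    diff_s = .data$predicted_s - .data$observed_s,
    diff_pct = 100 * .data$diff_s / .data$observed_s
  )
}

#' @export
print.pbs_timeline <- function(x, ...) {
  b <- breakdown(x)
  cat(sprintf("<pbs_timeline> %d events, total %.3f s\n", nrow(x), b$t_bdt_s))
  cat(sprintf("  layer switch %.3f s | burst switch %.3f s | spot switch %.3f s | spill %.3f s\n",
              b$t_lsw_s, b$t_bsw_s, b$t_ssw_s, b$t_ssp_s))
  NextMethod()
}
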