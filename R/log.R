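#' Emit a 1 kHz delivery-log table from a timeline
#'
#' Emulates the machine irradiation log: one row per pulse (carrying the
#' delivered MU and spot position) and one marker row per millisecond of
#' each switching interval, so that a burst's row count equals its
#' spot-switching row count plus its pulse count. The log dialect is this
#' package's own documented CSV; vendor binary dialects are out of scope.
#'
#' @inheritParams breakdown
#' @return A `pbs_log` tibble with columns `time_ms`, `kind`, `layer_index`,
#'   `burst`, `x_mm`, `y_mm`, `mu`.
#' @export
#' @examples
#' tl <- build_timeline(test_field_iso_repeat(2))
#' emit_log(tl)
emit_log <- function(timeline) {
  if (nrow(timeline) == 0) {
    return(empty_log())
  }
  period <- timeline_machine(timeline)$pulse_period_ms
  rows_per_event <- ifelse(timeline$kind == "pulse", 1L,
                           round(timeline$duration_ms / period))
  keep <- rows_per_event > 0
  tl <- timeline[keep, ]
  nrep <- rows_per_event[keep]
  offsets <- unlist(lapply(nrep, function(n) (seq_len(n) - 1) * period))
  log <- tibble::tibble(
    time_ms = rep(tl$start_ms, nrep) + offsets,
    kind = rep(tl$kind, nrep),
    layer_index = rep(tl$layer_index, nrep),
    burst = rep(tl$burst, nrep),
    x_mm = rep(tl$x_mm, nrep),
    y_mm = rep(tl$y_mm, nrep),
    mu = rep(tl$mu, nrep)
  )
  class(log) <- c("pbs_log", class(log))
  log
}

empty_log <- function() {
  log <- tibble::tibble(
    time_ms = numeric(), kind = character(), layer_index = numeric(),
    burst = numeric(), x_mm = numeric(), y_mm = numeric(), mu = numeric()
  )
  class(log) <- c("pbs_log", class(log))
  log
}

timeline_machine <- function(timeline) {
  attr(timeline, "machine") %||% proteus_one()
}

#' Parse a delivery log into component totals and per-burst counts
#'
#' Reconstructs the four delivery-time components from a log table by
#' counting rows per kind (each row is one millisecond quantum), and
#' recovers the per-burst bookkeeping counts used by the burst-switching
#' model: the pulse count, the spot-switching row count, and the spot count
#' (the number of maximal runs of consecutive pulse rows, since any two
#' spots within a burst are separated by at least one switch row).
#'
#' @param log A `pbs_log` (from [emit_log()] or [read_log()]).
#' @param period_ms Log row quantum, ms.
#' @return A list with elements `breakdown` (as [breakdown()]) and `bursts`
#'   (a tibble with `layer_index`, `burst`, `n_pulse`, `n_ssw`, `n_spot`,
#'   `mu`).
#' @export
parse_log <- function(log, period_ms = 1) {
  if (nrow(log) == 0) {
    return(list(
      breakdown = tibble::tibble(t_lsw_s = 0, t_bsw_s = 0, t_ssw_s = 0,
                                 t_ssp_s = 0, t_bdt_s = 0),
      bursts = tibble::tibble(layer_index = numeric(), burst = numeric(),
                              n_pulse = integer(), n_ssw = integer(),
                              n_spot = integer(), mu = numeric())
    ))
  }
  if (is.unsorted(log$time_ms)) {
    stop("log rows are not monotone in time", call. = FALSE)
  }
  n_by_kind <- function(kinds) sum(log$kind %in% kinds)
  t_lsw <- n_by_kind("layer_switch") * period_ms / 1000
  t_bsw <- n_by_kind("burst_switch") * period_ms / 1000
  t_ssw <- n_by_kind(c("spot_switch", "line_switch")) * period_ms / 1000
  t_ssp <- n_by_kind("pulse") * period_ms / 1000
  bd <- tibble::tibble(
    t_lsw_s = t_lsw, t_bsw_s = t_bsw, t_ssw_s = t_ssw, t_ssp_s = t_ssp,
    t_bdt_s = t_lsw + t_bsw + t_ssw + t_ssp
  )
  in_burst <- log[log$kind %in% c("pulse", "spot_switch", "line_switch"), ]
  bursts <- dplyr::summarise(
    dplyr::group_by(in_burst, .data$layer_index, .data$burst),
    n_pulse = sum(.data$kind == "pulse"),
    n_ssw = sum(.data$kind != "pulse"),
    n_spot = n_pulse_runs(.data$kind),
    mu = sum(.data$mu[.data$kind == "pulse"]),
    .groups = "drop"
  )
  list(breakdown = bd, bursts = bursts)
}

# number of maximal runs of consecutive "pulse" rows
n_pulse_runs <- function(kind) {
  is_pulse <- kind == "pulse"
  sum(is_pulse & !c(FALSE, is_pulse[-length(is_pulse)]))
}

#' Read and write delivery-log CSV files
#'
#' The log CSV has the columns of [emit_log()]: `time_ms`, `kind`,
#' `layer_index`, `burst`, `x_mm`, `y_mm`, `mu`.
#'
#' @param path File path.
#' @return `read_log()` returns a `pbs_log`; `write_log()` returns `path`
#'   invisibly.
#' @export
read_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(kind = readr::col_character()))
  required <- c("time_ms", "kind", "layer_index", "burst", "x_mm", "y_mm", "mu")
  missing <- setdiff(required, names(log))
  if (length(missing) > 0) {
    stop("missing log column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(log) <- c("pbs_log", class(log))
  log
}

#' @rdname read_log
#' @param log A `pbs_log`.
#' @export
write_log <- function(log, path) {
  readr::write_csv(log, path, progress = FALSE)
  invisible(path)
}
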