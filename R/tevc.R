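## Two-electrode voltage-clamp analysis: window currents, deactivation,
## IV assembly/normalization, reversal potentials and the semilog
## concentration fit. Units: current uA, voltage mV, time s,
## concentration mM.

#' Voltage-step protocol
#'
#' The default protocol steps 1 s pulses from +20 mV to -160 mV in -15 mV
#' decrements (13 steps) with a 1.5 s resting interval at the zero-current
#' holding level between pulses.
#'
#' @param start_voltage first step voltage, mV.
#' @param decrement step decrement, mV (negative for descending ladders).
#' @param n_steps number of voltage steps.
#' @param pulse_duration pulse length, s.
#' @param inter_pulse resting interval between pulses, s.
#' @return object of class `sweep_protocol`; `$voltages` holds the step
#'   ladder.
#' @export
sweep_protocol <- function(start_voltage = 20, decrement = -15,
                           n_steps = 13, pulse_duration = 1.0,
                           inter_pulse = 1.5) {
  stopifnot(n_steps >= 1L, pulse_duration > 0)
  structure(list(start_voltage = start_voltage, decrement = decrement,
                 n_steps = as.integer(n_steps),
                 pulse_duration = pulse_duration, inter_pulse = inter_pulse,
                 voltages = start_voltage + (seq_len(n_steps) - 1L) *
                   decrement),
            class = "sweep_protocol")
}

#' A single voltage-step current sweep
#'
#' @param step_voltage command voltage of the pulse, mV.
#' @param samples current samples in uA covering the pulse.
#' @param sample_rate sampling rate, Hz.
#' @param pulse_start,pulse_end sample indices (1-based, inclusive)
#'   bounding the pulse; default the whole trace.
#' @return object of class `current_sweep`.
#' @export
current_sweep <- function(step_voltage, samples, sample_rate,
                          pulse_start = 1L, pulse_end = length(samples)) {
  stopifnot(sample_rate > 0, length(samples) >= 1L,
            pulse_start >= 1L, pulse_end <= length(samples),
            pulse_start <= pulse_end)
  structure(list(step_voltage = step_voltage, samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 pulse_start = as.integer(pulse_start),
                 pulse_end = as.integer(pulse_end)),
            class = "current_sweep")
}

#' A recording: one sweep per protocol voltage in one solution
#'
#' @param solution solution label, e.g. `"Na30K1"` (30 mM NaCl + 1 mM
#'   KCl).
#' @param na_mm,k_mm Na+ and K+ concentrations, mM.
#' @param sweeps list of [current_sweep()]s, one per protocol voltage, in
#'   protocol order.
#' @param protocol the [sweep_protocol()] used.
#' @param cell_id oocyte/cell identifier (recordings sharing a `cell_id`
#'   share a gain and are normalized together).
#' @return object of class `tevc_recording`.
#' @export
tevc_recording <- function(solution, na_mm, k_mm, sweeps,
                           protocol = sweep_protocol(), cell_id = "cell1") {
  stopifnot(length(sweeps) == protocol$n_steps)
  vs <- vapply(sweeps, `[[`, 0, "step_voltage")
  if (!isTRUE(all.equal(vs, protocol$voltages)))
    stop("sweep voltages do not match the protocol ladder")
  structure(list(solution = solution, na_mm = na_mm, k_mm = k_mm,
                 sweeps = sweeps, protocol = protocol, cell_id = cell_id),
            class = "tevc_recording")
}

#' Window currents of a sweep
#'
#' Three within-pulse statistics: `I_begin`, the mean over
#' `[settle, settle + window]` after pulse onset (the settle delay skips
#' the capacitive transient); `I_end`, the mean over the last `window`
#' seconds of the pulse; and `I_avg`, the mean from `settle` to the pulse
#' end.
#'
#' @param sweep a [current_sweep()].
#' @param settle settle delay after pulse onset, s (default 25 ms).
#' @param window window width, s (default 25 ms).
#' @return named numeric: `I_begin`, `I_end`, `I_avg` in uA.
#' @export
window_currents <- function(sweep, settle = 0.025, window = 0.025) {
  stopifnot(inherits(sweep, "current_sweep"), settle >= 0, window > 0)
  idx <- sweep$pulse_start:sweep$pulse_end
  t <- (idx - sweep$pulse_start) / sweep$sample_rate
  dur <- (sweep$pulse_end - sweep$pulse_start + 1L) / sweep$sample_rate
  if (settle + window > dur)
    stop("settle + window (", settle + window,
         " s) exceeds pulse duration (", dur, " s)")
  x <- sweep$samples[idx]
  begin_sel <- t >= settle & t < settle + window
  end_sel <- t >= dur - window
  avg_sel <- t >= settle
  if (!any(begin_sel) || !any(end_sel))
    stop("window of ", window, " s is empty at sample rate ",
         sweep$sample_rate, " Hz")
  c(I_begin = mean(x[begin_sel]), I_end = mean(x[end_sel]),
    I_avg = mean(x[avg_sel]))
}

#' Deactivation percentage
#'
#' Percent reduction of current magnitude from the beginning to the end
#' of the voltage pulse: `(|I_begin| - |I_end|) / |I_begin| * 100`.
#' Magnitudes make the statistic sign-convention free for inward
#' (negative) currents, and invariant to any positive gain.
#'
#' @param I_begin,I_end window currents in uA (see [window_currents()]).
#' @return percent; `NA` with a warning when `I_begin` is zero.
#' @examples
#' deactivation_pct(-2.0, -1.76)  # 12
#' @export
deactivation_pct <- function(I_begin, I_end) {
  if (abs(I_begin) == 0) {
    warning("I_begin is zero; deactivation undefined")
    return(NA_real_)
  }
  (abs(I_begin) - abs(I_end)) / abs(I_begin) * 100
}

#' Deactivation statistics for every sweep of a recording
#'
#' @param rec a [tevc_recording()].
#' @inheritParams window_currents
#' @return data.frame: `voltage`, `I_begin`, `I_end`, `I_avg`,
#'   `deactivation_pct`.
#' @export
deactivation_stats <- function(rec, settle = 0.025, window = 0.025) {
  stopifnot(inherits(rec, "tevc_recording"))
  rows <- lapply(rec$sweeps, function(sw) {
    w <- window_currents(sw, settle, window)
    data.frame(voltage = sw$step_voltage, I_begin = w[["I_begin"]],
               I_end = w[["I_end"]], I_avg = w[["I_avg"]],
               deactivation_pct = suppressWarnings(
                 deactivation_pct(w[["I_begin"]], w[["I_end"]])))
  })
  do.call(rbind, rows)
}

#' Assemble normalized IV curves across recordings
#'
#' Extracts one within-pulse current statistic per sweep, normalizes each
#' cell's currents by the magnitude of that cell's current at the
#' reference (solution, voltage) point, and averages across cells. The
#' reference point of the reference solution therefore has normalized
#' magnitude 1, and the curves are invariant to per-cell gain.
#'
#' @param recordings list of [tevc_recording()]s (one or more cells, one
#'   or more solutions per cell).
#' @param statistic which window current forms the IV: `"avg"` (default),
#'   `"begin"` or `"end"`.
#' @param normalize_to list with `solution` and `voltage` naming the
#'   reference point, e.g. `list(solution = "Na30K1", voltage = -145)`;
#'   `NULL` skips normalization.
#' @inheritParams window_currents
#' @return data.frame with one row per (solution, voltage): `current`
#'   (mean normalized), `sd`, `n`, plus raw means; class `iv_curve_set`.
#' @export
build_iv <- function(recordings, statistic = c("avg", "begin", "end"),
                     normalize_to = list(solution = "Na30K1",
                                         voltage = -145),
                     settle = 0.025, window = 0.025) {
  statistic <- match.arg(statistic)
  stat_name <- c(avg = "I_avg", begin = "I_begin", end = "I_end")[statistic]
  pts <- do.call(rbind, lapply(recordings, function(rec) {
    do.call(rbind, lapply(rec$sweeps, function(sw) {
      w <- window_currents(sw, settle, window)
      data.frame(cell_id = rec$cell_id, solution = rec$solution,
                 voltage = sw$step_voltage, raw = w[[stat_name]])
    }))
  }))
  if (!is.null(normalize_to)) {
    pts$norm <- NA_real_
    for (cell in unique(pts$cell_id)) {
      sel <- pts$cell_id == cell
      ref <- pts$raw[sel & pts$solution == normalize_to$solution &
                       abs(pts$voltage - normalize_to$voltage) < 1e-9]
      if (length(ref) != 1L)
        stop("cell ", cell, " lacks the normalization reference point (",
             normalize_to$solution, " at ", normalize_to$voltage, " mV)")
      if (ref == 0) stop("zero reference current for cell ", cell)
      pts$norm[sel] <- pts$raw[sel] / abs(ref)
    }
  } else pts$norm <- pts$raw
  agg <- do.call(rbind, lapply(split(pts, pts[c("voltage", "solution")],
                                     drop = TRUE), function(g)
    data.frame(solution = g$solution[1], voltage = g$voltage[1],
               current = mean(g$norm),
               sd = if (nrow(g) > 1L) stats::sd(g$norm) else 0,
               n = nrow(g), raw_mean = mean(g$raw))))
  agg <- agg[order(agg$solution, agg$voltage), ]
  rownames(agg) <- NULL
  structure(agg, class = c("iv_curve_set", "data.frame"),
            statistic = statistic, normalize_to = normalize_to)
}

#' Reversal potential from an IV curve
#'
#' Linear interpolation between the adjacent IV points bracketing zero
#' current. A point lying exactly on zero is returned as is. With several
#' sign changes (noisy curves) the crossing at the least-negative voltage
#' is returned with a warning.
#'
#' @param voltage,current numeric vectors of IV points (any order; sorted
#'   internally by voltage).
#' @return `V_rev` in mV, or `NA` with a warning when the curve does not
#'   change sign.
#' @examples
#' estimate_vrev(c(-60, -45), c(-0.5, 0.5))  # -52.5
#' @export
estimate_vrev <- function(voltage, current) {
  stopifnot(length(voltage) == length(current), length(voltage) >= 2L)
  ord <- order(voltage)
  v <- voltage[ord]; i <- current[ord]
  zero <- which(i == 0)
  crossings <- which(i[-length(i)] * i[-1L] < 0)
  cand <- sort(c(v[zero], vapply(crossings, function(k)
    v[k] - i[k] * (v[k + 1L] - v[k]) / (i[k + 1L] - i[k]), 0)))
  if (length(cand) == 0L) {
    warning("IV curve does not change sign; V_rev undefined")
    return(NA_real_)
  }
  if (length(cand) > 1L)
    warning("multiple zero crossings; reporting the least-negative (",
            format(max(cand), digits = 5), " mV)")
  max(cand)
}

#' Semilog fit of reversal potentials against concentration
#'
#' Least-squares fit of `V_rev = slope * log10(c) + intercept`, the
#' classical Nernstian analysis of how the reversal potential shifts with
#' the external concentration of the permeant ion. The ideal Nernst slope
#' `(R*T/F) * ln(10)` at the configured temperature is reported alongside
#' for comparison (58.6 mV/decade at the default 22 C, a typical oocyte
#' recording-room temperature).
#'
#' @param concentration concentrations in mM (> 0).
#' @param vrev reversal potentials in mV.
#' @param temperature bath temperature in degrees Celsius.
#' @return list of class `reversal_fit`: `slope` (mV/decade),
#'   `intercept`, `residuals`, `ideal_slope`, `temperature`.
#' @export
fit_vrev_semilog <- function(concentration, vrev, temperature = 22) {
  stopifnot(length(concentration) == length(vrev))
  if (any(concentration <= 0)) stop("concentrations must be positive (mM)")
  if (length(unique(concentration)) < 2L)
    stop("need at least two distinct concentrations for a semilog fit")
  lc <- log10(concentration)
  fit <- stats::lm(vrev ~ lc)
  tk <- temperature + 273.15
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residuals = unname(stats::residuals(fit)),
    ideal_slope = 8.314462618 * tk / 96485.33212 * log(10) * 1000,
    temperature = temperature,
    n = length(vrev)),
    class = "reversal_fit")
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat("<reversal_fit> slope ", format(x$slope, digits = 4),
      " mV/decade (ideal Nernst ", format(x$ideal_slope, digits = 4),
      " at ", x$temperature, " C), intercept ",
      format(x$intercept, digits = 4), " mV, n = ", x$n, "\n", sep = "")
  invisible(x)
}

## ---- sweep CSV + manifest I/O --------------------------------------------

#' Write / read a recording as sweep CSVs plus a manifest
#'
#' Each sweep becomes a CSV with columns `time_s`, `current_uA`; a JSON
#' manifest ties the files to the protocol and solution composition.
#'
#' @param rec a [tevc_recording()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return path to the manifest JSON.
#' @export
write_recording <- function(rec, dir, prefix = rec$solution) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(rec$sweeps))
  for (k in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[k]]
    files[k] <- sprintf("%s_step%02d_%+dmV.csv", prefix, k,
                        round(sw$step_voltage))
    utils::write.csv(
      data.frame(time_s = (seq_along(sw$samples) - 1L) / sw$sample_rate,
                 current_uA = sw$samples),
      file.path(dir, files[k]), row.names = FALSE)
  }
  manifest <- list(
    solution = rec$solution, na_mm = rec$na_mm, k_mm = rec$k_mm,
    cell_id = rec$cell_id,
    sample_rate = rec$sweeps[[1]]$sample_rate,
    protocol = rec$protocol[c("start_voltage", "decrement", "n_steps",
                              "pulse_duration", "inter_pulse")],
    files = files)
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_recording
#' @param manifest_path path to a manifest JSON written by
#'   [write_recording()].
#' @export
read_recording <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  proto <- sweep_protocol(m$protocol$start_voltage, m$protocol$decrement,
                          m$protocol$n_steps, m$protocol$pulse_duration,
                          m$protocol$inter_pulse)
  dir <- dirname(manifest_path)
  sweeps <- lapply(seq_along(m$files), function(k) {
    tab <- utils::read.csv(file.path(dir, m$files[k]))
    current_sweep(proto$voltages[k], tab$current_uA, m$sample_rate)
  })
  tevc_recording(m$solution, m$na_mm, m$k_mm, sweeps, proto, m$cell_id)
}
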