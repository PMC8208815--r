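# Voltage-step analysis: steady-state I-V, linear leak subtraction,
# transient inward (sodium) current detection, pharmacological difference
# currents, passive-property estimation.

#' Voltage-step protocol
#'
#' @param holding holding potential, mV.
#' @param levels strictly increasing step command levels, mV.
#' @param onset_ms,offset_ms step epoch boundaries, ms (`offset > onset`).
#' @param sampling_khz sampling rate, kHz.
#' @param total_ms total sweep duration, ms (default `offset_ms + 20`).
#' @return a `step_protocol` with precomputed sample times `time_ms`.
#' @export
step_protocol <- function(holding = -80, levels = seq(-120, 40, by = 10),
                          onset_ms = 10, offset_ms = 110, sampling_khz = 5,
                          total_ms = offset_ms + 20) {
  levels <- as.numeric(levels)
  if (length(levels) < 1L || is.unsorted(levels, strictly = TRUE)) {
    stop("step levels must be strictly increasing", call. = FALSE)
  }
  if (offset_ms <= onset_ms) stop("offset_ms must exceed onset_ms", call. = FALSE)
  if (sampling_khz <= 0) stop("sampling rate must be positive", call. = FALSE)
  n <- floor(total_ms * sampling_khz)
  structure(
    list(holding = holding, levels = levels, onset_ms = onset_ms,
         offset_ms = offset_ms, sampling_khz = sampling_khz,
         total_ms = total_ms, time_ms = (seq_len(n) - 1L) / sampling_khz),
    class = "step_protocol"
  )
}

#' Voltage-step recording container
#'
#' @param protocol a [step_protocol()].
#' @param traces numeric matrix, one column per step level, rows = samples
#'   at `protocol$time_ms` (pA).
#' @return a `voltage_step_recording`.
#' @export
voltage_step_recording <- function(protocol, traces) {
  stopifnot(inherits(protocol, "step_protocol"))
  traces <- as.matrix(traces)
  if (ncol(traces) != length(protocol$levels)) {
    stop("one trace per step level required", call. = FALSE)
  }
  if (nrow(traces) != length(protocol$time_ms)) {
    stop("trace length must match the protocol's sample times", call. = FALSE)
  }
  colnames(traces) <- format(protocol$levels)
  structure(list(protocol = protocol, traces = traces),
            class = "voltage_step_recording")
}

#' Current-voltage curve container
#'
#' @param voltages mV; @param currents pA (same length).
#' @param leak_subtracted has linear leak been removed?
#' @param leak_fit optional list(slope_pa_per_mv, intercept_pa).
#' @return an `iv_curve`.
#' @export
iv_curve <- function(voltages, currents, leak_subtracted = FALSE,
                     leak_fit = NULL) {
  if (length(voltages) != length(currents)) {
    stop("voltages and currents must have equal length", call. = FALSE)
  }
  structure(list(voltages = as.numeric(voltages),
                 currents = as.numeric(currents),
                 leak_subtracted = isTRUE(leak_subtracted),
                 leak_fit = leak_fit),
            class = "iv_curve")
}

#' Steady-state I-V curve from a voltage-step recording
#'
#' Averages each step's current over a window near the end of the step
#' epoch (default: the final 10% of the epoch), where capacitive transients
#' have settled and slowly activating conductances have reached plateau.
#'
#' @param rec a `voltage_step_recording`.
#' @param window length-2 window in ms, inside `[onset, offset]`; `NULL`
#'   for the default.
#' @return an `iv_curve` (not leak-subtracted).
#' @export
measure_steady_state <- function(rec, window = NULL) {
  stopifnot(inherits(rec, "voltage_step_recording"))
  p <- rec$protocol
  if (is.null(window)) {
    window <- c(p$offset_ms - 0.1 * (p$offset_ms - p$onset_ms), p$offset_ms)
  }
  if (window[1L] < p$onset_ms || window[2L] > p$offset_ms ||
      window[2L] <= window[1L]) {
    stop("measurement window must lie within the step epoch", call. = FALSE)
  }
  sel <- p$time_ms >= window[1L] & p$time_ms < window[2L]
  if (!any(sel)) stop("measurement window contains no samples", call. = FALSE)
  iv_curve(p$levels, colMeans(rec$traces[sel, , drop = FALSE]))
}

#' Linear leak subtraction
#'
#' Fits a least-squares line to the curve over a hyperpolarized voltage
#' range where voltage-gated conductances are closed (default -120 to
#' -70 mV), extrapolates it across all voltages and subtracts it, exposing
#' the voltage-gated component. The fitted slope and intercept are recorded
#' on the returned curve.
#'
#' @param curve an `iv_curve` (not already subtracted).
#' @param leak_range length-2 voltage interval, mV, containing >= 2 points.
#' @return leak-subtracted `iv_curve`.
#' @export
leak_subtract <- function(curve, leak_range = c(-120, -70)) {
  stopifnot(inherits(curve, "iv_curve"))
  if (curve$leak_subtracted) {
    stop("curve is already leak-subtracted", call. = FALSE)
  }
  sel <- curve$voltages >= leak_range[1L] & curve$voltages <= leak_range[2L]
  if (sum(sel) < 2L) {
    stop("need at least 2 points inside the leak range", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, curve$voltages[sel]), curve$currents[sel])
  coefs <- fit$coefficients
  leak <- coefs[1L] + coefs[2L] * curve$voltages
  iv_curve(curve$voltages, curve$currents - leak, leak_subtracted = TRUE,
           leak_fit = list(slope_pa_per_mv = unname(coefs[2L]),
                           intercept_pa = unname(coefs[1L])))
}

#' Detect transient inward (sodium-like) currents
#'
#' Searches steps more positive than `min_step_mv` for an early, transient
#' inward deflection. Each trace is first stripped of its passive component
#' by subtracting a scaled template built from the most hyperpolarized step
#' (where voltage-gated conductances are closed), the classic P/N approach:
#' the template removes both the linear leak and the capacitive transient,
#' so outwardly rectifying potassium currents leave a non-negative residual
#' while a nascent sodium current appears as a negative dip. A step is
#' flagged when the residual dips below `-threshold_pa` inside the search
#' window after onset and then recovers to at least 50% of the peak
#' deflection before the window ends (the transience criterion). Detection
#' is invariant to a constant offset added to all traces. If the protocol
#' has no step away from the holding potential to serve as a template, only
#' the per-trace pre-onset baseline is subtracted (documented fallback; leak
#' and capacitive components then remain).
#'
#' @param rec a `voltage_step_recording`.
#' @param min_step_mv only steps with level strictly above this are
#'   searched (default -30 mV).
#' @param threshold_pa minimum inward peak deflection, pA (positive number).
#' @param search_window_ms length-2 window after step onset, ms.
#' @return list: `detected` (logical), `peaks` (data.frame step_mV,
#'   peak_deflection_pA, transient, detected).
#' @export
detect_transient_inward <- function(rec, min_step_mv = -30,
                                    threshold_pa = 50,
                                    search_window_ms = c(0, 10)) {
  stopifnot(inherits(rec, "voltage_step_recording"))
  if (threshold_pa <= 0) stop("threshold must be positive", call. = FALSE)
  p <- rec$protocol
  w <- p$onset_ms + search_window_ms
  if (w[2L] > p$offset_ms) {
    stop("search window must lie within the step epoch", call. = FALSE)
  }
  sel <- p$time_ms >= w[1L] & p$time_ms < w[2L]
  pre <- p$time_ms < p$onset_ms
  base_hold <- if (any(pre)) colMeans(rec$traces[pre, , drop = FALSE]) else
    rec$traces[1L, ]
  # passive template: most hyperpolarized step distinct from holding
  tmpl_j <- which(p$levels != p$holding)
  tmpl_j <- if (length(tmpl_j) > 0L) tmpl_j[which.min(p$levels[tmpl_j])] else NA_integer_
  res <- lapply(seq_along(p$levels), function(j) {
    level <- p$levels[j]
    if (!is.na(tmpl_j)) {
      scale <- (level - p$holding) / (p$levels[tmpl_j] - p$holding)
      passive <- base_hold[j] +
        (rec$traces[, tmpl_j] - base_hold[tmpl_j]) * scale
    } else {
      passive <- rep(base_hold[j], nrow(rec$traces))
    }
    seg <- (rec$traces[, j] - passive)[sel]
    k <- which.min(seg)
    deflection <- max(0, -seg[k])         # inward dip below the residual baseline
    recovered <- if (k < length(seg)) {
      any(seg[(k + 1L):length(seg)] >= seg[k] + 0.5 * deflection)
    } else FALSE
    data.frame(step_mV = level, peak_deflection_pA = deflection,
               transient = recovered,
               detected = level > min_step_mv & deflection > threshold_pa &
                 recovered)
  })
  peaks <- do.call(rbind, res)
  list(detected = any(peaks$detected), peaks = peaks)
}

#' Difference of two I-V curves (pharmacological isolation)
#'
#' Point-wise `control - treated` over identical voltage grids: with a
#' selective channel blocker as the treated condition, the difference is the
#' blocker-sensitive current.
#'
#' @param control,treated `iv_curve`s on identical voltage vectors.
#' @return `iv_curve` of the difference current.
#' @export
subtract_conditions <- function(control, treated) {
  stopifnot(inherits(control, "iv_curve"), inherits(treated, "iv_curve"))
  if (length(control$voltages) != length(treated$voltages) ||
      any(control$voltages != treated$voltages)) {
    stop("control and treated curves must share the same voltage grid",
         call. = FALSE)
  }
  iv_curve(control$voltages, control$currents - treated$currents,
           leak_subtracted = control$leak_subtracted && treated$leak_subtracted)
}

#' Estimate input resistance from an I-V curve
#'
#' Local linear fit of current against voltage over a small interval around
#' rest; the input resistance is the inverse slope converted to MOhm
#' (slope in pA/mV is a conductance in nS; R = 1000/slope MOhm).
#'
#' @param curve an `iv_curve`.
#' @param range length-2 voltage interval, mV, containing >= 2 points.
#' @return list: `r_mohm`, `slope_pa_per_mv`, `infinite` (flag set instead
#'   of erroring when the slope is zero).
#' @export
estimate_input_resistance <- function(curve, range = c(-90, -70)) {
  stopifnot(inherits(curve, "iv_curve"))
  sel <- curve$voltages >= range[1L] & curve$voltages <= range[2L]
  if (sum(sel) < 2L) {
    stop("need at least 2 points inside the fitting range", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, curve$voltages[sel]), curve$currents[sel])
  slope <- unname(fit$coefficients[2L])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps^0.5) {
    return(list(r_mohm = Inf, slope_pa_per_mv = slope, infinite = TRUE))
  }
  list(r_mohm = 1000 / slope, slope_pa_per_mv = slope, infinite = FALSE)
}

#' Write a voltage-step recording as long-format CSV plus protocol sidecar
#'
#' The trace table has columns (step_mV, time_ms, current_pA); the protocol
#' is written next to it as JSON (`<path>.protocol.json`).
#'
#' @param rec a `voltage_step_recording`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_voltage_steps <- function(rec, path) {
  stopifnot(inherits(rec, "voltage_step_recording"))
  p <- rec$protocol
  long <- data.frame(
    step_mV = rep(p$levels, each = length(p$time_ms)),
    time_ms = rep(p$time_ms, times = length(p$levels)),
    current_pA = as.vector(rec$traces)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  side <- list(holding = p$holding, levels = p$levels, onset_ms = p$onset_ms,
               offset_ms = p$offset_ms, sampling_khz = p$sampling_khz,
               total_ms = p$total_ms)
  jsonlite::write_json(side, paste0(path, ".protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage-step recording written by [write_voltage_steps()]
#' @param path CSV path (expects `<path>.protocol.json` alongside).
#' @return a `voltage_step_recording`.
#' @export
read_voltage_steps <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".protocol.json"),
                              simplifyVector = TRUE)
  p <- step_protocol(holding = side$holding, levels = side$levels,
                     onset_ms = side$onset_ms, offset_ms = side$offset_ms,
                     sampling_khz = side$sampling_khz,
                     total_ms = side$total_ms)
  long <- utils::read.csv(path)
  traces <- matrix(long$current_pA[order(match(long$step_mV, p$levels),
                                         long$time_ms)],
                   nrow = length(p$time_ms), ncol = length(p$levels))
  voltage_step_recording(p, traces)
}

#' Write an I-V curve as CSV
#' @param curve an `iv_curve`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_iv_curve <- function(curve, path) {
  stopifnot(inherits(curve, "iv_curve"))
  utils::write.csv(
    data.frame(voltage_mV = curve$voltages, current_pA = curve$currents,
               leak_subtracted = curve$leak_subtracted),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
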