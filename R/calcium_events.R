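# Calcium-trace analysis: dF/F_min normalization, event detection,
# per-event peak and area, stimulus-aligned evoked responses, and
# group normalization of total activity.

#' Background-subtracted fluorescence trace
#'
#' @param t_s time vector (strictly increasing, constant step).
#' @param f_raw region mean intensity.
#' @param f_bg paired background mean (scalar or vector).
#' @param source_id identifier of the region (one mitochondrion / neuron).
#' @return a `fluorescence_trace` with `f_corr = f_raw - f_bg` and `dt_s`.
#' @export
fluorescence_trace <- function(t_s, f_raw, f_bg = 0, source_id = "trace") {
  f_bg <- rep_len(f_bg, length(f_raw))
  if (length(t_s) != length(f_raw))
    nm_stop("t_s and f_raw must have equal length", "nm_validation_error")
  dt <- diff(t_s)
  if (any(dt <= 0) || (length(dt) && diff(range(dt)) > 1e-6 * dt[1]))
    nm_stop("t_s must be strictly increasing with a constant step", "nm_validation_error")
  f_corr <- f_raw - f_bg
  if (any(!is.finite(f_corr)))
    nm_stop("f_corr must be finite", "nm_validation_error")
  structure(list(t_s = t_s, f_raw = f_raw, f_bg = f_bg, f_corr = f_corr,
                 source_id = source_id, dt_s = dt[1]),
            class = "fluorescence_trace")
}

#' dF/F_min normalization
#'
#' `F_min` is the mean of the lowest `baseline_fraction` of the
#' background-corrected samples (default 5%, robust to single-frame
#' dropouts); `dff = (f_corr - F_min) / F_min`. Invariant under a common
#' positive gain applied to `f_raw` and `f_bg`.
#'
#' @param trace a [fluorescence_trace()].
#' @param baseline_fraction proportion of samples defining the baseline
#'   (0 < fraction <= 0.5).
#' @return a `dff_trace` (fields `t_s`, `dff`, `F_min`, `dt_s`, `source_id`).
#' @export
compute_dff <- function(trace, baseline_fraction = 0.05) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (baseline_fraction <= 0 || baseline_fraction > 0.5)
    nm_stop("baseline_fraction must be in (0, 0.5]", "nm_config_error")
  n <- length(trace$f_corr)
  k <- max(1L, ceiling(baseline_fraction * n))
  f_min <- mean(sort(trace$f_corr)[seq_len(k)])
  if (f_min <= 0)
    nm_stop("F_min <= 0: background exceeds signal", "nm_baseline_error")
  structure(list(t_s = trace$t_s, dff = (trace$f_corr - f_min) / f_min,
                 F_min = f_min, dt_s = trace$dt_s,
                 source_id = trace$source_id),
            class = "dff_trace")
}

#' Detect calcium events in a dF/F trace
#'
#' Events are maximal intervals where the (optionally smoothed) dF/F stays
#' at or above `threshold = threshold_sd x robust noise SD`, last at least
#' `min_duration_s`, and are then extended outward to the half-threshold
#' crossings. The robust SD is MAD-based, so sparse events do not inflate
#' the threshold.
#'
#' @param dff a `dff_trace`.
#' @param threshold_sd threshold multiplier (default 3).
#' @param min_duration_s minimum core duration (default 3 frames).
#' @param smooth_s moving-average window in seconds applied before
#'   detection and peak measurement (default 0.3 s; 0 disables).
#' @return data.frame with one row per event: `t_start_s`, `t_end_s`,
#'   `peak_dff`, `peak_t_s`, `area_dff_s` (trapezoidal integral over the
#'   event), time-ordered and non-overlapping.
#' @export
detect_events <- function(dff, threshold_sd = 3, min_duration_s = NULL,
                          smooth_s = 0.3) {
  stopifnot(inherits(dff, "dff_trace"))
  dt <- dff$dt_s
  min_duration_s <- min_duration_s %||% (3 * dt)
  y <- moving_average(dff$dff, round(smooth_s / dt))
  # threshold relative to the trace's baseline level (median), so a small
  # systematic offset of F_min does not turn the whole trace into events
  center <- stats::median(y)
  sd_rob <- mad_sd(y)
  excess <- max(threshold_sd * sd_rob, 1e-9)
  thr <- center + excess
  empty <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      peak_dff = numeric(0), peak_t_s = numeric(0),
                      area_dff_s = numeric(0))
  above <- y >= thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  core <- which(r$values & r$lengths * dt >= min_duration_s)
  if (!length(core)) return(empty)
  half <- y >= center + excess / 2
  rows <- lapply(core, function(ci) {
    i0 <- starts[ci]; i1 <- ends[ci]
    while (i0 > 1L && half[i0 - 1L]) i0 <- i0 - 1L
    while (i1 < length(y) && half[i1 + 1L]) i1 <- i1 + 1L
    c(i0, i1)
  })
  # merge intervals that became overlapping after extension
  rows <- do.call(rbind, rows)
  merged <- list(); cur <- rows[1, ]
  for (i in seq_len(nrow(rows))[-1]) {
    if (rows[i, 1] <= cur[2] + 1L) cur[2] <- max(cur[2], rows[i, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- rows[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- lapply(merged, function(iv) {
    idx <- iv[1]:iv[2]
    pk <- idx[which.max(y[idx])]
    data.frame(t_start_s = dff$t_s[iv[1]], t_end_s = dff$t_s[iv[2]],
               peak_dff = y[pk], peak_t_s = dff$t_s[pk],
               area_dff_s = trapz(dff$t_s[idx], pmax(dff$dff[idx], 0)))
  })
  do.call(rbind, out)
}

#' Maximum event amplitude of a trace
#'
#' One value per trace (per mitochondrion/neuron): the largest event peak
#' dF/F, or 0 when no events were detected.
#' @param events data.frame from [detect_events()].
#' @export
max_event_amplitude <- function(events) {
  if (!nrow(events)) 0 else max(events$peak_dff)
}

#' Total calcium activity of a trace
#'
#' A combined measure of amplitude and duration: by default the summed
#' trapezoidal area (dF/F x s) over detected events; `mode = "whole_trace"`
#' integrates the positive part of the full trace instead.
#'
#' @param dff a `dff_trace`.
#' @param events data.frame from [detect_events()].
#' @param mode `"events"` (default) or `"whole_trace"`.
#' @export
total_activity <- function(dff, events, mode = c("events", "whole_trace")) {
  mode <- match.arg(mode)
  if (mode == "whole_trace") return(trapz(dff$t_s, pmax(dff$dff, 0)))
  if (!nrow(events)) 0 else sum(events$area_dff_s)
}

#' Score stimulus-aligned evoked responses
#'
#' For each protocol onset, the window `[onset, onset + period)` is scored
#' with its maximum dF/F and the events whose peaks fall inside it.
#' Windows truncated by the end of the trace are flagged.
#'
#' @param dff a `dff_trace`.
#' @param protocol a [stimulation_protocol()] whose onsets lie within the
#'   trace.
#' @param events optional events from [detect_events()].
#' @return data.frame: `stimulus_index`, `onset_s`, `window_max_dff`,
#'   `window_max_t_s`, `n_events`, `truncated`.
#' @export
align_to_stimuli <- function(dff, protocol, events = NULL) {
  stopifnot(inherits(dff, "dff_trace"), inherits(protocol, "stimulation_protocol"))
  onsets <- protocol$onset_times_s
  if (any(onsets < min(dff$t_s)) || any(onsets > max(dff$t_s)))
    nm_stop("protocol onsets must lie within the trace span", "nm_validation_error")
  period <- protocol$period_s %||% diff(range(dff$t_s))
  out <- lapply(seq_along(onsets), function(i) {
    hi <- onsets[i] + period
    win <- dff$t_s >= onsets[i] & dff$t_s < hi
    truncated <- hi > max(dff$t_s) + dff$dt_s / 2
    n_ev <- if (is.null(events)) NA_integer_
            else sum(events$peak_t_s >= onsets[i] & events$peak_t_s < hi)
    data.frame(stimulus_index = i, onset_s = onsets[i],
               window_max_dff = max(dff$dff[win]),
               window_max_t_s = dff$t_s[win][which.max(dff$dff[win])],
               n_events = n_ev, truncated = truncated)
  })
  do.call(rbind, out)
}

#' Normalize per-group activity values to a reference group's mean
#'
#' Every value is divided by the mean of the reference (control) group, so
#' the reference group maps to mean 1.
#'
#' @param groups named list of numeric vectors.
#' @param reference_group name of the reference group.
#' @return named list of normalized vectors.
#' @export
normalize_group_activity <- function(groups, reference_group) {
  if (!reference_group %in% names(groups))
    nm_stop("reference_group not found", "nm_validation_error")
  ref_mean <- mean(groups[[reference_group]])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    nm_stop("reference group mean must be > 0", "nm_normalization_error")
  lapply(groups, function(v) v / ref_mean)
}
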