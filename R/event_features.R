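#' Peak displacement of an event by a running mean window
#'
#' Slides a short running-mean window (5 ms, i.e. 25 samples at 5 kHz,
#' advanced one sample at a time) over the event and returns the largest
#' windowed mean as the peak displacement sustained for the window duration,
#' plus the 0-based start sample of that window. Ties break to the earliest
#' window. Events shorter than the window get the whole-event mean, flagged.
#'
#' @param trace a [trap_trace()].
#' @param start_sample,end_sample 0-based half-open event bounds.
#' @param window_ms running-mean window, ms.
#' @return list with `peak_displacement` (nm), `peak_start_sample`
#'   (0-based), `flagged_short` (logical).
#' @export
peak_window <- function(trace, start_sample, end_sample, window_ms = 5) {
  stopifnot(inherits(trace, "trap_trace"))
  n <- length(trace$positions)
  if (start_sample < 0 || end_sample > n || end_sample <= start_sample)
    stop("invalid event bounds")
  w <- max(1L, as.integer(round(window_ms / 1000 * trace$sample_rate_hz)))
  y <- trace$positions[(start_sample + 1L):end_sample]
  m <- length(y)
  if (m < w) {
    return(list(peak_displacement = mean(y),
                peak_start_sample = start_sample, flagged_short = TRUE))
  }
  cs <- c(0, cumsum(y))
  means <- (cs[(w + 1L):(m + 1L)] - cs[1:(m - w + 1L)]) / w
  i <- which.max(means)  # which.max returns the first maximum: earliest tie
  list(peak_displacement = means[i],
       peak_start_sample = start_sample + i - 1L,
       flagged_short = FALSE)
}

#' Time at peak force
#'
#' The time spent at peak force runs from the start of the maximal running
#' mean window to the (changepoint-refined) end of the binding event; its
#' reciprocal estimates the detachment rate under load.
#'
#' @param end_sample 0-based half-open event end.
#' @param peak_start_sample 0-based start of the peak window.
#' @param sample_rate_hz sampling rate, Hz.
#' @return time at peak force, s.
#' @export
time_at_peak_force <- function(end_sample, peak_start_sample,
                               sample_rate_hz) {
  if (peak_start_sample >= end_sample)
    stop("peak window must start before the event end")
  (end_sample - peak_start_sample) / sample_rate_hz
}

#' Per-event mechanics
#'
#' Computes, for each detected (or ground-truth) event: lifetime `t_on_s`,
#' peak displacement (5 ms running-mean maximum), peak force
#' (k_trap x peak displacement), time at peak force `T_PF_s` and detachment
#' rate `k_det_per_s = 1/T_PF`. Also derives the implied head count
#' (peak displacement / step size) and force per head.
#'
#' @param trace a [trap_trace()].
#' @param events data.frame with 0-based half-open `start_sample`,
#'   `end_sample`.
#' @param window_ms peak running-mean window, ms.
#' @param step_nm powerstroke size used for head counts, nm.
#' @param k_trap trap stiffness; defaults to the trace metadata (pass a
#'   calibrated estimate to override).
#' @return data.frame of class `event_metrics`, one row per event.
#' @export
event_metrics <- function(trace, events, window_ms = 5, step_nm = 7,
                          k_trap = trace$k_trap) {
  stopifnot(inherits(trace, "trap_trace"))
  n_ev <- nrow(events)
  out <- data.frame(event_id = if (n_ev) seq_len(n_ev) else integer(),
                    start_sample = events$start_sample,
                    end_sample = events$end_sample,
                    t_on_s = numeric(n_ev), peak_displacement_nm = numeric(n_ev),
                    peak_force_pN = numeric(n_ev), T_PF_s = numeric(n_ev),
                    k_det_per_s = numeric(n_ev), heads = numeric(n_ev),
                    force_per_head_pN = numeric(n_ev),
                    flagged_short = logical(n_ev))
  rate <- trace$sample_rate_hz
  for (i in seq_len(n_ev)) {
    s <- events$start_sample[i]; e <- events$end_sample[i]
    pk <- peak_window(trace, s, e, window_ms)
    tpf <- time_at_peak_force(e, pk$peak_start_sample, rate)
    out$t_on_s[i] <- (e - s) / rate
    out$peak_displacement_nm[i] <- pk$peak_displacement
    out$peak_force_pN[i] <- k_trap * pk$peak_displacement
    out$T_PF_s[i] <- tpf
    out$k_det_per_s[i] <- 1 / tpf
    out$heads[i] <- pk$peak_displacement / step_nm
    out$force_per_head_pN[i] <- if (pk$peak_displacement > 0)
      k_trap * step_nm else NA_real_
    out$flagged_short[i] <- pk$flagged_short
  }
  out$k_trap <- k_trap
  out$condition <- trace$condition
  class(out) <- c("event_metrics", "data.frame")
  out
}

#' Summarise event metrics by condition
#'
#' Groups per-event metrics (by default on condition label and trap
#' stiffness) and reports the number of events, mean and SEM of lifetime,
#' peak displacement, peak force and time at peak force, the mean force per
#' head, and two condition-level detachment-rate estimates: the default
#' `k_det = 1/mean(T_PF)` (rate of the mean duration, robust to short-T_PF
#' outliers in the per-event reciprocal) with its first-order-propagated
#' SEM, and `k_det_mean_of_rates = mean(1/T_PF)` for comparison. Groups
#' with a single event get SEM 0 and are flagged.
#'
#' @param metrics an `event_metrics` data.frame (conditions may be
#'   concatenated with `rbind`).
#' @param by grouping column names.
#' @return data.frame of class `condition_summary`, one row per group;
#'   attribute `"ecdf"` holds per-group ECDF functions for lifetimes,
#'   displacements and forces.
#' @export
summarize_conditions <- function(metrics, by = c("condition", "k_trap")) {
  stopifnot(all(by %in% names(metrics)))
  if (!nrow(metrics)) stop("no events to summarise")
  key <- interaction(metrics[by], drop = TRUE, sep = " | ")
  groups <- split(seq_len(nrow(metrics)), key)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  rows <- lapply(groups, function(idx) {
    g <- metrics[idx, , drop = FALSE]
    mT <- mean(g$T_PF_s)
    k_det <- 1 / mT
    # var(1/m) ~ var(m)/m^4 to first order
    sem_k <- sem(g$T_PF_s) / mT^2
    cbind(g[1, by, drop = FALSE],
          data.frame(n_events = nrow(g),
                     mean_t_on_s = mean(g$t_on_s), sem_t_on_s = sem(g$t_on_s),
                     mean_peak_displacement_nm = mean(g$peak_displacement_nm),
                     sem_peak_displacement_nm = sem(g$peak_displacement_nm),
                     mean_peak_force_pN = mean(g$peak_force_pN),
                     sem_peak_force_pN = sem(g$peak_force_pN),
                     mean_T_PF_s = mT, sem_T_PF_s = sem(g$T_PF_s),
                     k_det_per_s = k_det, sem_k_det_per_s = sem_k,
                     k_det_mean_of_rates_per_s = mean(g$k_det_per_s),
                     mean_force_per_head_pN =
                       mean(g$force_per_head_pN, na.rm = TRUE),
                     single_event = nrow(g) == 1L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ecdf") <- lapply(groups, function(idx) {
    g <- metrics[idx, , drop = FALSE]
    list(t_on = ecdf(g$t_on_s),
         displacement = ecdf(g$peak_displacement_nm),
         force = ecdf(g$peak_force_pN))
  })
  class(out) <- c("condition_summary", "data.frame")
  out
}
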