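#' Single changepoint by two-segment Gaussian likelihood
#'
#' Finds the split of a numeric segment that maximises the two-segment
#' Gaussian log-likelihood, each segment with its own mean and (MLE)
#' variance: ll(j) = -j/2 log v1 - (n-j)/2 log v2 up to constants. This is
#' the exact single-changepoint estimate for a simultaneous mean/variance
#' shift and is sensitive to both the displacement step and the variance
#' drop at a binding transition.
#'
#' @param y numeric vector.
#' @param min_seg minimum samples per segment.
#' @return 0-based split offset `j`: the changepoint lies between `y[j]`
#'   and `y[j+1]` (1-based), i.e. the right segment starts at offset `j`.
#' @export
changepoint_gaussian <- function(y, min_seg = 5L) {
  n <- length(y)
  min_seg <- max(2L, as.integer(min_seg))
  if (n < 2L * min_seg) stop("segment too short for changepoint scan")
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  j <- min_seg:(n - min_seg)
  l1 <- s1[j]; l2 <- s2[j]
  r1 <- s1[n] - l1; r2 <- s2[n] - l2
  v1 <- pmax((l2 - l1^2 / j) / j, 1e-12)
  v2 <- pmax((r2 - r1^2 / (n - j)) / (n - j), 1e-12)
  ll <- -j / 2 * log(v1) - (n - j) / 2 * log(v2)
  j[which.max(ll)]
}

# heuristic alternative mirroring a running 50-point mean/variance scan:
# score each candidate boundary by the likelihood-ratio between "one
# Gaussian over the two flanking windows" and "one Gaussian per window".
changepoint_window50 <- function(y, cp_window = 50L) {
  n <- length(y)
  w <- as.integer(cp_window)
  if (n < 2L * w) return(changepoint_gaussian(y))
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  b <- w:(n - w)  # candidate boundary offsets (right window starts here)
  lft1 <- s1[b] - c(0, s1)[b - w + 1L]
  lft2 <- s2[b] - c(0, s2)[b - w + 1L]
  rgt1 <- s1[b + w] - s1[b]
  rgt2 <- s2[b + w] - s2[b]
  vl <- pmax((lft2 - lft1^2 / w) / w, 1e-12)
  vr <- pmax((rgt2 - rgt1^2 / w) / w, 1e-12)
  tot1 <- lft1 + rgt1; tot2 <- lft2 + rgt2
  vp <- pmax((tot2 - tot1^2 / (2 * w)) / (2 * w), 1e-12)
  score <- w * log(vp) - w / 2 * log(vl) - w / 2 * log(vr)
  b[which.max(score)]
}

#' Refine coarse event boundaries by changepoint analysis
#'
#' For each coarse boundary from [decode_events()], re-estimates the
#' transition sample inside a neighbourhood of two window widths on either
#' side of the coarse bound (clipped to the trace and to the neighbouring
#' event). The default `method = "likelihood"` places the boundary at the
#' sample maximising the exact two-segment Gaussian log-likelihood;
#' `method = "window50"` scores candidate boundaries with flanking running
#' windows of `cp_window` samples advanced one sample at a time. If a
#' neighbourhood has fewer than 10 samples on either side of the coarse
#' bound, the coarse bound is kept with a warning.
#'
#' @param trace a [trap_trace()].
#' @param events coarse event data.frame from [decode_events()].
#' @param width HMM window width in samples (sets the neighbourhood size).
#' @param method boundary statistic, see above.
#' @param cp_window flanking window size for `method = "window50"`.
#' @return the events data.frame with refined `start_sample`, `end_sample`
#'   and recomputed `t_on_s`; original coarse bounds are kept in
#'   `coarse_start`/`coarse_end`.
#' @export
refine_changepoints <- function(trace, events, width = 100L,
                                method = c("likelihood", "window50"),
                                cp_window = 50L) {
  stopifnot(inherits(trace, "trap_trace"))
  method <- match.arg(method)
  n <- length(trace$positions)
  half <- 2L * as.integer(width)
  if (!nrow(events)) {
    events$t_on_s <- numeric(0)
    events$coarse_start <- integer(0)
    events$coarse_end <- integer(0)
    return(events)
  }
  events$coarse_start <- events$start_sample
  events$coarse_end <- events$end_sample

  refine_one <- function(b, lo_lim, hi_lim) {
    lo <- max(lo_lim, b - half)
    hi <- min(hi_lim, b + half)
    if (b - lo < 10L || hi - b < 10L) {
      warning("changepoint neighbourhood too small; keeping coarse bound at sample ", b)
      return(b)
    }
    y <- trace$positions[(lo + 1L):hi]  # samples lo .. hi-1 (0-based)
    j <- switch(method,
                likelihood = changepoint_gaussian(y),
                window50 = changepoint_window50(y, cp_window))
    lo + j
  }

  prev_end <- 0L
  for (i in seq_len(nrow(events))) {
    cs <- events$start_sample[i]; ce <- events$end_sample[i]
    next_start <- if (i < nrow(events)) events$start_sample[i + 1L] else n
    rs <- refine_one(cs, prev_end, min(ce, n))
    re <- refine_one(ce, max(rs + 1L, cs), min(next_start, n))
    if (re <= rs) { rs <- cs; re <- ce }  # never invert an event
    events$start_sample[i] <- rs
    events$end_sample[i] <- re
    prev_end <- re
  }
  events$t_on_s <- (events$end_sample - events$start_sample) /
    trace$sample_rate_hz
  events
}

#' Detect binding events in a displacement record
#'
#' End-to-end detector: running mean/variance window transform
#' ([window_transform()]), two-state HMM fit ([fit_hmm()]), Viterbi decoding
#' into coarse events ([decode_events()]) and changepoint boundary
#' refinement ([refine_changepoints()]).
#'
#' @param trace a [trap_trace()].
#' @param width window width, samples.
#' @param step window advance, samples.
#' @param min_event_windows minimum decoded run length, windows.
#' @param cp_method changepoint statistic, see [refine_changepoints()].
#' @param cp_window flanking window for `cp_method = "window50"`.
#' @return data.frame of detected events (0-based half-open sample bounds,
#'   lifetime `t_on_s`), with the fitted model in attribute `"model"`.
#' @examples
#' sim <- simulate_ensemble_trace(sim_config(duration_s = 20, seed = 4))
#' ev <- detect_events(sim$trace)
#' nrow(ev)
#' @export
detect_events <- function(trace, width = 100L, step = 25L,
                          min_event_windows = 1L,
                          cp_method = "likelihood", cp_window = 50L) {
  feats <- window_transform(trace, width = width, step = step)
  model <- fit_hmm(feats)
  coarse <- decode_events(feats, model, min_event_windows = min_event_windows)
  out <- refine_changepoints(trace, coarse, width = width,
                             method = cp_method, cp_window = cp_window)
  out$t_on_s <- (out$end_sample - out$start_sample) / trace$sample_rate_hz
  attr(out, "model") <- model
  out
}
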