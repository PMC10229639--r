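#' Construct a displacement trace object
#'
#' A `trap_trace` holds a uniformly sampled bead displacement record (nm,
#' relative to the trap center) together with the metadata needed by the
#' analysis: sampling rate, trap stiffness, temperature and a free-text
#' condition label.
#'
#' @param positions numeric vector of displacements, nm.
#' @param sample_rate_hz sampling rate, Hz.
#' @param k_trap trap stiffness, pN/nm.
#' @param temperature_K temperature, K.
#' @param condition free-text condition label.
#' @return an object of class `trap_trace`.
#' @export
trap_trace <- function(positions, sample_rate_hz, k_trap,
                       temperature_K = 298.15, condition = "") {
  if (length(positions) < 1) stop("trace must contain at least one sample")
  if (!all(is.finite(positions))) stop("trace positions must all be finite")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  if (!is.numeric(k_trap) || k_trap <= 0)
    stop("k_trap must be positive")
  structure(list(positions = as.numeric(positions),
                 sample_rate_hz = sample_rate_hz,
                 k_trap = k_trap,
                 temperature_K = temperature_K,
                 condition = as.character(condition)),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("trap_trace: %d samples at %.0f Hz (%.2f s), k_trap %.3f pN/nm, T %.2f K\n",
              length(x$positions), x$sample_rate_hz,
              length(x$positions) / x$sample_rate_hz, x$k_trap,
              x$temperature_K))
  if (nzchar(x$condition)) cat("  condition:", x$condition, "\n")
  invisible(x)
}

# equilibrium mean bead position with n heads attached: each attached head
# has delivered a step_nm powerstroke; the bead settles where the head
# springs (n * k_head) balance the trap, i.e. at the series-spring fraction
# of the unloaded displacement n * step_nm.
attached_mean <- function(n_attached, config) {
  if (n_attached == 0) return(0)
  ke <- config$k_trap + n_attached * config$k_head
  n_attached * config$step_nm * (n_attached * config$k_head) / ke
}

#' Simulate a bead-only (no motor) trap record
#'
#' Exact-discretization Ornstein-Uhlenbeck process for a bead in a harmonic
#' trap: stationary mean 0, stationary variance kT/k_trap, per-sample
#' autocorrelation exp(-k_trap * dt / gamma). The initial position is drawn
#' from the stationary distribution so the whole record is stationary.
#'
#' @param config a [sim_config()]; only the mechanical fields are used.
#' @return a [trap_trace()].
#' @examples
#' tr <- simulate_bead_only(sim_config(k_trap = 0.04, duration_s = 1, seed = 1))
#' var(tr$positions) # close to 4.116 / 0.04
#' @export
simulate_bead_only <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- max(1L, round(config$duration_s * config$sample_rate_hz))
  dt <- 1 / config$sample_rate_hz
  sd_stat <- sqrt(config$kT / config$k_trap)
  x0 <- rnorm(1, 0, sd_stat)
  z <- rnorm(n)
  pos <- ou_paint(rep(0, n), rep(config$k_trap, n), x0, config$kT, dt,
                  config$gamma, z)
  trap_trace(pos, config$sample_rate_hz, config$k_trap,
             config$temperature_K,
             sprintf("bead-only k=%.3f", config$k_trap))
}

#' Simulate motor attachment/detachment kinetics (Gillespie)
#'
#' Continuous-time Markov simulation of the number of attached heads.
#' Detached heads attach at `k_attach` each; attached heads detach with the
#' load-dependent hazard [detachment_hazard()] evaluated at the per-head
#' share F/N of the ensemble force F = k_trap * mu(N), where mu(N) is the
#' quasi-static mean displacement with N heads attached. A binding event is
#' a maximal interval with at least one head attached.
#'
#' @param config a [sim_config()].
#' @return a list of class `trap_truth` with elements `transitions`
#'   (data.frame: `time_s`, `n_attached`, `mu_nm`) and `events`
#'   (data.frame: `event_id`, `start_time_s`, `end_time_s`, `t_on_s`,
#'   `max_mu_nm`, `peak_time_s` — the first time the maximal mean
#'   displacement is reached, `n_at_peak`). Events still open at the end of
#'   the record are dropped.
#' @export
simulate_kinetics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_kinetics_impl(config)
}

# internal: no seed handling, so callers can compose RNG streams
simulate_kinetics_impl <- function(config) {
  dur <- config$duration_s
  mu_tab <- vapply(0:config$n_heads, attached_mean, numeric(1),
                   config = config)
  # precompute per-head hazard for each occupancy level
  haz_tab <- c(0, vapply(seq_len(config$n_heads), function(n) {
    f <- config$k_trap * mu_tab[n + 1] / n
    detachment_hazard(f, config)
  }, numeric(1)))

  cap <- 1024L
  t_v <- numeric(cap); n_v <- integer(cap)
  m <- 0L
  push <- function(tt, nn) {
    m <<- m + 1L
    if (m > cap) {
      cap <<- cap * 2L
      t_v <<- c(t_v, numeric(cap / 2L))
      n_v <<- c(n_v, integer(cap / 2L))
    }
    t_v[m] <<- tt; n_v[m] <<- nn
  }
  t <- 0; n_att <- 0L
  push(0, 0L)
  repeat {
    r_att <- (config$n_heads - n_att) * config$k_attach
    r_det <- n_att * haz_tab[n_att + 1L]
    rate <- r_att + r_det
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= dur) break
    if (runif(1) < r_att / rate) n_att <- n_att + 1L else n_att <- n_att - 1L
    push(t, n_att)
  }
  trans <- data.frame(time_s = t_v[seq_len(m)],
                      n_attached = n_v[seq_len(m)],
                      mu_nm = mu_tab[n_v[seq_len(m)] + 1L])
  events <- truth_events_from_transitions(trans, dur)
  structure(list(transitions = trans, events = events,
                 duration_s = dur), class = "trap_truth")
}

truth_events_from_transitions <- function(trans, duration_s) {
  att <- trans$n_attached > 0
  n <- nrow(trans)
  starts <- which(att & !c(FALSE, att[-n]))
  out <- list()
  eid <- 0L
  for (s in starts) {
    e <- s
    while (e < n && trans$n_attached[e + 1L] > 0) e <- e + 1L
    if (e == n) next  # event still open at end of record: drop
    end_t <- trans$time_s[e + 1L]
    seg <- trans[s:e, , drop = FALSE]
    imax <- which.max(seg$mu_nm)
    eid <- eid + 1L
    out[[eid]] <- data.frame(event_id = eid,
                             start_time_s = trans$time_s[s],
                             end_time_s = end_t,
                             t_on_s = end_t - trans$time_s[s],
                             max_mu_nm = seg$mu_nm[imax],
                             peak_time_s = seg$time_s[imax],
                             n_at_peak = seg$n_attached[imax])
  }
  if (eid == 0L)
    return(data.frame(event_id = integer(), start_time_s = numeric(),
                      end_time_s = numeric(), t_on_s = numeric(),
                      max_mu_nm = numeric(), peak_time_s = numeric(),
                      n_at_peak = integer()))
  do.call(rbind, out)
}

#' Simulate a mini-ensemble trap record with ground truth
#'
#' Runs the Gillespie kinetics of [simulate_kinetics()] and paints a
#' displacement record on top: between transitions the bead relaxes as an
#' Ornstein-Uhlenbeck process around the quasi-static mean mu(N) with
#' effective stiffness k_trap + N * k_head (the attached heads stiffen the
#' trap, which is what produces the variance drop used by the detector).
#' Transition times are rounded to the nearest sample when painting; truth
#' events whose rounded bounds coincide (sub-sample events) are dropped
#' from the returned event table.
#'
#' @param config a [sim_config()].
#' @return a list with elements `trace` (a [trap_trace()]) and `truth`
#'   (a `trap_truth`; its `events` gain 0-based `start_sample` /
#'   `end_sample` columns, half-open).
#' @export
simulate_ensemble_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- simulate_kinetics_impl(config)
  n <- max(1L, round(config$duration_s * config$sample_rate_hz))
  dt <- 1 / config$sample_rate_hz

  trans <- truth$transitions
  bnd <- pmin(pmax(round(trans$time_s / dt), 0), n)  # sample index of each transition
  seg_len <- diff(c(bnd, n))
  keep <- seg_len > 0
  mu_vec <- rep.int(trans$mu_nm[keep], seg_len[keep])
  keff_vec <- rep.int(config$k_trap + trans$n_attached[keep] * config$k_head,
                      seg_len[keep])

  sd_stat <- sqrt(config$kT / config$k_trap)
  x0 <- rnorm(1, 0, sd_stat)
  z <- rnorm(n)
  pos <- ou_paint(mu_vec, keff_vec, x0, config$kT, dt, config$gamma, z)

  ev <- truth$events
  if (nrow(ev)) {
    ev$start_sample <- pmin(pmax(round(ev$start_time_s / dt), 0), n)
    ev$end_sample <- pmin(pmax(round(ev$end_time_s / dt), 0), n)
    ev <- ev[ev$end_sample > ev$start_sample, , drop = FALSE]
    if (nrow(ev)) ev$event_id <- seq_len(nrow(ev))
    rownames(ev) <- NULL
    truth$events <- ev
  }
  cond <- sprintf("sim k=%.3f pi=%.1f", config$k_trap, config$pi_mM)
  list(trace = trap_trace(pos, config$sample_rate_hz, config$k_trap,
                          config$temperature_K, cond),
       truth = truth)
}
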