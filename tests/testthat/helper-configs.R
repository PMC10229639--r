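# shared fixture builders -------------------------------------------------

# single-head configuration in which the Bell law holds exactly:
# constant per-head load k_trap * mu(1), exponential lifetimes
single_head_cfg <- function(k_trap, seed, duration_s = 60, pi_mM = 30,
                            k_pi0_per_mM = 1 / 12, d_pi = 4.1,
                            k_adp0 = 0, d_adp = 0, k_attach = 5) {
  sim_config(n_heads = 1, k_trap = k_trap, k_attach = k_attach,
             k_adp0 = k_adp0, d_adp = d_adp, pi_mM = pi_mM,
             k_pi0_per_mM = k_pi0_per_mM, d_pi = d_pi,
             duration_s = duration_s, seed = seed)
}

# mini-ensemble configuration used for detector benchmarks: stiff trap,
# load-insensitive detachment, events frequently reach several heads
detector_cfg <- function(seed, duration_s = 120, k_trap = 0.10) {
  sim_config(n_heads = 4, k_trap = k_trap, k_attach = 1, k_adp0 = 2.5,
             d_adp = 0, pi_mM = 0, duration_s = duration_s, seed = seed)
}

# overlap-based matching of detected events to truth events
match_events <- function(truth, detected) {
  ov <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
  best <- vapply(seq_len(nrow(truth)), function(i) {
    o <- ov(truth$start_sample[i], truth$end_sample[i],
            detected$start_sample, detected$end_sample)
    if (length(o) && any(o > 0)) which.max(o) else NA_integer_
  }, integer(1))
  tp_det <- vapply(seq_len(nrow(detected)), function(j) {
    any(ov(detected$start_sample[j], detected$end_sample[j],
           truth$start_sample, truth$end_sample) > 0)
  }, logical(1))
  list(truth_match = best, detected_is_tp = tp_det)
}

# brute-force two-segment Gaussian log-likelihood scan (independent oracle
# for the changepoint estimator)
brute_changepoint <- function(y, min_seg = 5L) {
  n <- length(y)
  best <- -Inf; arg <- min_seg
  for (j in min_seg:(n - min_seg)) {
    a <- y[1:j]; b <- y[(j + 1):n]
    va <- max(mean((a - mean(a))^2), 1e-12)
    vb <- max(mean((b - mean(b))^2), 1e-12)
    ll <- -j / 2 * log(va) - (n - j) / 2 * log(vb)
    if (ll > best) { best <- ll; arg <- j }
  }
  arg
}
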