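test_that("peak window equals the brute-force maximum running mean", {
  set.seed(41)
  tr <- trap_trace(rnorm(3000, 10, 4), 5000, 0.06)
  pk <- peak_window(tr, 200, 1800)
  w <- 25
  y <- tr$positions[201:1800]
  brute <- vapply(1:(length(y) - w + 1),
                  function(i) mean(y[i:(i + w - 1)]), numeric(1))
  expect_equal(pk$peak_displacement, max(brute), tolerance = 1e-12)
  expect_equal(pk$peak_start_sample, 200 + which.max(brute) - 1)
})

test_that("peak window handles constants, spikes and short events", {
  tr <- trap_trace(rep(30, 1000), 5000, 0.04)
  pk <- peak_window(tr, 100, 600)
  expect_equal(pk$peak_displacement, 30)
  expect_equal(pk$peak_start_sample, 100)  # earliest tie

  # a single-sample spike is averaged down by the 25-sample window
  x <- rep(20, 500); x[250] <- 100
  pk2 <- peak_window(trap_trace(x, 5000, 0.04), 0, 500)
  expect_equal(pk2$peak_displacement, (24 * 20 + 100) / 25)

  # event shorter than the window: whole-event mean, flagged
  pk3 <- peak_window(trap_trace(x, 5000, 0.04), 0, 10)
  expect_true(pk3$flagged_short)
  expect_equal(pk3$peak_displacement, 20)

  # a rising ramp then plateau peaks in the plateau
  x4 <- c(seq(0, 40, length.out = 200), rep(40, 300))
  pk4 <- peak_window(trap_trace(x4, 5000, 0.04), 0, 500)
  expect_equal(pk4$peak_displacement, 40)
  expect_gte(pk4$peak_start_sample, 200)
})

test_that("time at peak force is the span from peak window to event end", {
  expect_equal(time_at_peak_force(5000, 3000, 5000), 0.4)
  expect_equal(1 / time_at_peak_force(5000, 3000, 5000), 2.5)
  # peak at event start: T_PF equals the lifetime
  expect_equal(time_at_peak_force(5000, 0, 5000), 1.0)
  expect_error(time_at_peak_force(100, 100, 5000), "before")
})

test_that("adding a constant shifts peak displacement and scales force", {
  set.seed(42)
  tr <- trap_trace(rnorm(2000, 5, 3), 5000, 0.06)
  ev <- data.frame(start_sample = 100L, end_sample = 1900L)
  m1 <- event_metrics(tr, ev)
  tr2 <- tr; tr2$positions <- tr$positions + 10
  m2 <- event_metrics(tr2, ev)
  expect_equal(m2$peak_displacement_nm, m1$peak_displacement_nm + 10,
               tolerance = 1e-9)
  expect_equal(m2$peak_force_pN, 0.06 * (m1$peak_displacement_nm + 10),
               tolerance = 1e-9)
  expect_equal(m2$T_PF_s, m1$T_PF_s)  # same argmax window
})

test_that("condition summaries compute means, SEMs and rate conversions", {
  m <- data.frame(event_id = 1:2, start_sample = c(0L, 6000L),
                  end_sample = c(5000L, 11000L),
                  t_on_s = c(1, 1), peak_displacement_nm = c(10, 20),
                  peak_force_pN = c(1, 2), T_PF_s = c(0.2, 0.6),
                  k_det_per_s = c(5, 5 / 3), heads = c(10, 20) / 7,
                  force_per_head_pN = c(0.7, 0.7),
                  flagged_short = FALSE, k_trap = 0.1, condition = "c1")
  class(m) <- c("event_metrics", "data.frame")
  s <- summarize_conditions(m)
  expect_equal(s$n_events, 2)
  expect_equal(s$k_det_per_s, 1 / 0.4)  # rate of the mean T_PF
  expect_equal(s$k_det_mean_of_rates_per_s, mean(c(5, 5 / 3)))
  expect_equal(s$sem_t_on_s, 0)
  expect_equal(s$mean_peak_force_pN, 1.5)
  ec <- attr(s, "ecdf")[[1]]
  expect_equal(ec$t_on(max(m$t_on_s)), 1)

  # single event: SEMs reported as 0 and flagged
  s1 <- summarize_conditions(m[1, ])
  expect_true(s1$single_event)
  expect_equal(s1$sem_k_det_per_s, 0)
})

test_that("detachment rates rise with stiffness when Pi loading dominates", {
  ks <- c(0.04, 0.06, 0.10)
  kdet <- vapply(seq_along(ks), function(i) {
    sim <- simulate_ensemble_trace(
      sim_config(n_heads = 4, k_trap = ks[i], k_attach = 1, k_adp0 = 0,
                 d_adp = 0, pi_mM = 30, k_pi0_per_mM = 1 / 12, d_pi = 4.1,
                 duration_s = 120, seed = 500 + i))
    ev <- suppressWarnings(detect_events(sim$trace))
    s <- summarize_conditions(event_metrics(sim$trace, ev))
    s$k_det_per_s
  }, numeric(1))
  expect_true(all(diff(kdet) > 0))
})
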