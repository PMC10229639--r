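test_that("window transform geometry and statistics are correct", {
  tr <- trap_trace(rep(4.2, 1000), 5000, 0.04)
  f <- window_transform(tr, 100, 25)
  expect_equal(nrow(f), 37)  # floor((1000-100)/25)+1
  expect_equal(f$start_sample, seq(0, 900, by = 25))
  expect_true(all(f$mean == 4.2))
  expect_true(all(f$variance == 0))

  set.seed(12)
  x <- rnorm(1e5, 0, 3)
  f2 <- window_transform(trap_trace(x, 5000, 0.04), 100, 25)
  expect_equal(mean(f2$variance), 9, tolerance = 0.03)
  expect_equal(mean(f2$mean), 0, tolerance = 0.01)

  # the wider "quarter overlap" reading (step = 3/4 width) also works
  f3 <- window_transform(trap_trace(x, 5000, 0.04), 100, 75)
  expect_equal(nrow(f3), floor((1e5 - 100) / 75) + 1)

  expect_error(window_transform(trap_trace(x[1:50], 5000, 0.04), 100, 25),
               "shorter")
  expect_error(window_transform(trap_trace(x, 5000, 0.04), 100, 0), "step")
})

test_that("the HMM recovers two well-separated regimes and labels unbound first", {
  set.seed(21)
  # alternate unbound stretches (mean 0, sd 10 nm) with bound stretches
  # (mean 20 nm, variance reduced 10x), painted at the sample level
  y <- unlist(lapply(1:10, function(i)
    c(rnorm(1500, 0, 10), rnorm(1000, 20, sqrt(10)))))
  obs <- trap_trace(y, 5000, 0.04)
  f <- window_transform(obs, 100, 25)
  m <- fit_hmm(f)
  expect_false(m$degenerate)
  expect_true(m$converged)
  # state 1 is the high-variance (unbound) regime
  expect_gt(m$emission_mean[1, 2], m$emission_mean[2, 2])
  expect_equal(unname(m$emission_mean[2, 1]), 20, tolerance = 0.10)
  expect_equal(unname(m$emission_mean[1, 1]), 0, tolerance = 2)
  expect_equal(unname(rowSums(m$trans)), c(1, 1), tolerance = 1e-9)
})

test_that("single-regime data is flagged degenerate and decodes all-unbound", {
  # a pure bead-only trace has no bound regime: EM splits the noise into
  # two near-identical regimes which the separation guard rejects
  tr <- simulate_bead_only(sim_config(duration_s = 4, seed = 14))
  f <- window_transform(tr)
  expect_warning(m <- fit_hmm(f), "degenerate")
  expect_true(m$degenerate)
  expect_equal(nrow(decode_events(f, m)), 0)
  # hence no false events on motor-free records
  ev <- suppressWarnings(detect_events(tr))
  expect_equal(nrow(ev), 0)
  # constant data is unambiguous too
  trc <- trap_trace(rep(1.5, 5000) + rep(c(0, 1e-9), 2500), 5000, 0.04)
  fc <- window_transform(trc)
  mc <- suppressWarnings(fit_hmm(fc))
  expect_true(mc$degenerate)
  expect_equal(nrow(decode_events(fc, mc)), 0)
})

test_that("decoding a simulated ensemble finds the truth events", {
  sim <- simulate_ensemble_trace(detector_cfg(seed = 61, duration_s = 120))
  ev <- suppressWarnings(detect_events(sim$trace))
  tru <- sim$truth$events
  big <- tru[tru$t_on_s >= 0.04 &
               tru$max_mu_nm >= 2 * sqrt(kt_pN_nm() / 0.10), ]
  mm <- match_events(big, ev)
  expect_gte(mean(!is.na(mm$truth_match)), 0.9)
  expect_gte(mean(match_events(tru, ev)$detected_is_tp), 0.9)
  expect_true(all(ev$t_on_s > 0))
  expect_true(all(ev$end_sample[-nrow(ev)] <= ev$start_sample[-1]))
})

test_that("events separated by less than one window may merge; wide gaps never do", {
  mk <- function(gap) {
    set.seed(55)
    y <- c(rnorm(3000, 0, 10), rnorm(1000, 20, sqrt(10)),
           rnorm(gap, 0, 10), rnorm(1000, 20, sqrt(10)), rnorm(3000, 0, 10))
    suppressWarnings(detect_events(trap_trace(y, 5000, 0.04)))
  }
  narrow <- mk(50)    # gap shorter than the 100-sample window
  wide <- mk(1000)
  expect_lte(nrow(narrow), 2)  # may merge into one decoded run
  expect_equal(nrow(wide), 2)
  # merged or not, the detected span covers both true events
  expect_lte(min(narrow$start_sample), 3100)
  expect_gte(max(narrow$end_sample), 3950)
})

test_that("detection is invariant to a global position offset", {
  sim <- simulate_ensemble_trace(detector_cfg(seed = 62, duration_s = 60))
  ev1 <- suppressWarnings(detect_events(sim$trace))
  shifted <- sim$trace
  shifted$positions <- shifted$positions + 500
  ev2 <- suppressWarnings(detect_events(shifted))
  expect_equal(ev1$start_sample, ev2$start_sample)
  expect_equal(ev1$end_sample, ev2$end_sample)
})

test_that("changepoint refinement locates constructed steps", {
  set.seed(31)
  # mean step 0 -> 20 nm, equal variance 16, change at sample 500 of 1000
  y <- c(rnorm(500, 0, 4), rnorm(500, 20, 4))
  j <- changepoint_gaussian(y)
  expect_lte(abs(j - 500), 5)
  expect_equal(j, brute_changepoint(y))

  # variance-only change 100 -> 10 nm^2
  set.seed(32)
  y2 <- c(rnorm(500, 0, 10), rnorm(500, 0, sqrt(10)))
  j2 <- changepoint_gaussian(y2)
  expect_lte(abs(j2 - 500), 10)
  expect_equal(j2, brute_changepoint(y2))

  # windowed variant stays close on the same data
  expect_lte(abs(minitrap:::changepoint_window50(y) - 500), 25)
})

test_that("refinement never inverts an event and tolerates pure noise", {
  set.seed(33)
  tr <- trap_trace(rnorm(2000, 0, 5), 5000, 0.04)
  coarse <- data.frame(event_id = 1L, start_sample = 800L,
                       end_sample = 1200L, n_windows = 13L)
  ref <- refine_changepoints(tr, coarse, width = 100)
  expect_lt(ref$start_sample, ref$end_sample)
  expect_gte(ref$start_sample, 800 - 200)
  expect_lte(ref$end_sample, 1200 + 200)
})

test_that("seeded detection is deterministic", {
  sim <- simulate_ensemble_trace(detector_cfg(seed = 63, duration_s = 40))
  ev1 <- suppressWarnings(detect_events(sim$trace))
  ev2 <- suppressWarnings(detect_events(sim$trace))
  expect_identical(ev1$start_sample, ev2$start_sample)
  expect_identical(ev1$end_sample, ev2$end_sample)
})
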