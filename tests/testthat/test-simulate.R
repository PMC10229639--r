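test_that("bead-only OU trace has the equipartition variance and autocorrelation", {
  cfg <- sim_config(k_trap = 0.04, duration_s = 200, seed = 101)
  tr <- simulate_bead_only(cfg)  # 1e6 samples
  v_target <- cfg$kT / cfg$k_trap  # 102.9 nm^2
  expect_equal(var(tr$positions), v_target, tolerance = 0.02)
  x <- tr$positions
  rho_hat <- cor(x[-length(x)], x[-1])
  rho_target <- exp(-cfg$k_trap / cfg$sample_rate_hz / cfg$gamma)
  expect_equal(rho_hat, rho_target, tolerance = 0.02)
})

test_that("stationary variance shrinks with trap stiffness", {
  v <- vapply(c(0.04, 0.10), function(k) {
    var(simulate_bead_only(sim_config(k_trap = k, duration_s = 10,
                                      seed = 7))$positions)
  }, numeric(1))
  expect_lt(v[2], v[1])
  expect_equal(v[1], kt_pN_nm() / 0.04, tolerance = 0.05)
  expect_equal(v[2], kt_pN_nm() / 0.10, tolerance = 0.05)
})

test_that("vanishing drag decorrelates successive samples", {
  cfg <- sim_config(k_trap = 0.04, gamma = 1e-12, duration_s = 10, seed = 5)
  x <- simulate_bead_only(cfg)$positions
  expect_lt(abs(cor(x[-length(x)], x[-1])), 0.02)
  expect_equal(var(x), cfg$kT / cfg$k_trap, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(k_trap = 0), "k_trap")
  expect_error(sim_config(k_trap = -1), "k_trap")
  expect_error(sim_config(sample_rate_hz = 0), "sample_rate_hz")
  expect_error(sim_config(duration_s = -2), "duration_s")
  expect_error(sim_config(n_heads = 0), "n_heads")
  expect_error(sim_config(k_attach = -1), "k_attach")
})

test_that("identical config and seed give identical traces", {
  cfg <- sim_config(duration_s = 5, seed = 42)
  a <- simulate_ensemble_trace(cfg)
  b <- simulate_ensemble_trace(cfg)
  expect_identical(a$trace$positions, b$trace$positions)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("zero attachment rate yields a bead-only record with empty truth", {
  cfg <- sim_config(k_attach = 0, duration_s = 5, seed = 3)
  sim <- simulate_ensemble_trace(cfg)
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(var(sim$trace$positions), cfg$kT / cfg$k_trap,
               tolerance = 0.1)
})

test_that("attached lifetimes at frozen load are exponential with the closed-form hazard", {
  # k_head -> tiny: mu ~ 0, so the per-head load is frozen at ~0 and the
  # detachment hazard is the unloaded rate; Gillespie lifetimes must be
  # exponential(h(0))
  cfg <- sim_config(n_heads = 1, k_head = 1e-9, k_attach = 50, k_adp0 = 8,
                    d_adp = 3, pi_mM = 30, k_pi0_per_mM = 1 / 12, d_pi = 4.1,
                    duration_s = 1400, seed = 202)
  tru <- simulate_kinetics(cfg)
  h0 <- detachment_hazard(0, cfg)
  t_on <- tru$events$t_on_s
  expect_gte(length(t_on), 1e4)
  ks <- suppressWarnings(stats::ks.test(t_on, "pexp", rate = h0))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth events are sorted, non-overlapping and inside the trace", {
  sim <- simulate_ensemble_trace(sim_config(duration_s = 30, seed = 9))
  ev <- sim$truth$events
  expect_true(all(diff(ev$start_sample) > 0))
  expect_true(all(ev$end_sample > ev$start_sample))
  expect_true(all(ev$end_sample[-nrow(ev)] <= ev$start_sample[-1]))
  expect_true(all(ev$end_sample <= length(sim$trace$positions)))
})

test_that("phosphate shortens and trap stiffening lengthens attached lifetimes", {
  # Pi pathway accelerated by load: lifetimes drop as stiffness rises
  mean_life <- function(k_trap, pi_mM, d_adp, k_adp0, seed) {
    cfg <- sim_config(n_heads = 4, k_trap = k_trap, k_attach = 1,
                      k_adp0 = k_adp0, d_adp = d_adp, pi_mM = pi_mM,
                      k_pi0_per_mM = 1 / 12, d_pi = 4.1,
                      duration_s = 400, seed = seed)
    ev <- simulate_kinetics(cfg)$events
    expect_gte(nrow(ev), 500)
    mean(ev$t_on_s)
  }
  # raising [Pi] at fixed stiffness never lengthens events
  l_soft_nopi <- mean_life(0.04, 0, 0, 5, 31)
  l_soft_pi <- mean_life(0.04, 30, 0, 5, 32)
  expect_lt(l_soft_pi, l_soft_nopi)
  # with Pi present, stiffer trap shortens events
  l_stiff_pi <- mean_life(0.10, 30, 0, 5, 33)
  expect_lt(l_stiff_pi, l_soft_pi)
  # without Pi and with a load-slowed ADP pathway, stiffer trap lengthens
  l_soft_adp <- mean_life(0.04, 0, 4, 15, 34)
  l_stiff_adp <- mean_life(0.10, 0, 4, 15, 35)
  expect_gt(l_stiff_adp, l_soft_adp)
})
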