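test_that("the Bell rate law evaluates correctly", {
  kT <- kt_pN_nm()
  expect_equal(bell_rate(13.7, 0.6, 0, kT), 13.7)
  # force chosen so F d / kT = ln 2 doubles the rate
  F_half <- log(2) * kT / 0.6
  expect_equal(bell_rate(13.7, 0.6, F_half, kT), 27.4, tolerance = 1e-9)
  expect_equal(F_half, 4.754, tolerance = 1e-3)
  # d = 0: no load dependence
  expect_equal(bell_rate(5, 0, c(0, 2, 10), kT), rep(5, 3))
  expect_error(bell_rate(5, 500, 1e4, kT), "overflow")
})

test_that("noiseless points are recovered exactly over the parameter range", {
  kT <- kt_pN_nm()
  forces <- list(c(1.65, 1.74, 2.34), c(0.2, 0.5, 0.9, 1.4), c(1, 2, 3, 4, 5, 6))
  for (k0 in c(0.5, 2.5, 13.7, 40)) {
    for (d in c(-2, -0.9, 0, 0.6, 4.1, 6)) {
      for (F in forces) {
        pts <- data.frame(F = F, k_det = bell_rate(k0, d, F, kT))
        fit <- fit_bell(pts)
        expect_equal(fit$k0, k0, tolerance = 1e-6)
        expect_equal(fit$d, d, tolerance = 1e-6)
      }
    }
  }
})

test_that("log and direct parameterizations agree on well-conditioned data", {
  set.seed(51)
  F <- c(0.5, 1.2, 2.1, 3.4)
  k <- bell_rate(3, 1.5, F) * exp(rnorm(4, 0, 0.05))
  pts <- data.frame(F = F, k_det = k)
  f1 <- fit_bell(pts, parameterization = "log")
  f2 <- fit_bell(pts, parameterization = "direct")
  expect_equal(f1$k0, f2$k0, tolerance = 1e-6)
  expect_equal(f1$d, f2$d, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  pts <- data.frame(F = c(1, 2), k_det = c(3, 4))
  expect_error(fit_bell(pts), "at least 3")
  pts2 <- data.frame(F = c(1, 1, 1), k_det = c(3, 3.2, 2.9))
  expect_error(fit_bell(pts2), "unidentifiable")
  pts3 <- data.frame(F = c(1, 2, 3), k_det = c(3, -1, 2))
  expect_error(fit_bell(pts3), "positive")
})

test_that("weighted confidence intervals reflect supplied SEMs", {
  kT <- kt_pN_nm()
  set.seed(52)
  F <- c(0.25, 0.35, 0.52)
  rel <- 0.045
  cover <- vapply(1:200, function(i) {
    k <- bell_rate(2.5, 4.1, F, kT) * exp(rnorm(3, 0, rel))
    fit <- fit_bell(data.frame(F = F, k_det = k, sem_k = rel * k))
    fit$ci95_d[1] <= 4.1 && 4.1 <= fit$ci95_d[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("fit comparison reports CI overlap and the load-sensitivity ratio", {
  kT <- kt_pN_nm()
  mk <- function(k0, d, se_d) {
    F <- c(1, 2, 3)
    fit <- fit_bell(data.frame(F = F, k_det = bell_rate(k0, d, F, kT)))
    fit$se_d <- se_d
    fit$ci95_d <- fit$d + c(-1, 1) * 1.96 * se_d
    fit
  }
  wt_pi <- mk(13.7, 0.6, 0.15)
  mut_pi <- mk(2.5, 4.1, 0.9)
  cmp <- compare_fits(wt_pi, mut_pi)
  expect_equal(cmp$d_ratio, 4.1 / 0.6, tolerance = 1e-6)  # about seven-fold
  expect_false(cmp$d_ci_overlap)
  same <- compare_fits(wt_pi, wt_pi)
  expect_true(same$d_ci_overlap && same$k0_ci_overlap)
})
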