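#' Bell-bond rate law
#'
#' Load-dependent reaction rate k(F) = k0 * exp(F * d / kT): an applied
#' force F tilts the energy landscape along the distance d to the
#' transition state, modulating the unloaded rate k0 exponentially.
#' Negative d means load slows the rate.
#'
#' @param k0 unloaded rate, 1/s (> 0).
#' @param d distance parameter, nm.
#' @param F force, pN (vectorised).
#' @param kT thermal energy, pN nm.
#' @return rate(s), 1/s.
#' @examples
#' bell_rate(13.7, 0.6, 0, kt_pN_nm()) # 13.7
#' @export
bell_rate <- function(k0, d, F, kT = kt_pN_nm()) {
  stopifnot(k0 > 0, kT > 0)
  expo <- F * d / kT
  if (any(abs(expo) > 700)) stop("Bell exponent overflow (|F d / kT| > 700)")
  k0 * exp(expo)
}

#' Fit the Bell-bond equation to condition-level rates
#'
#' Weighted nonlinear least squares fit of k_det = k0 * exp(F d / kT) to
#' condition-level (force, detachment rate) points, parameterised in
#' (log k0, d) for numerical stability. When per-point SEMs are supplied
#' (and `weighted = TRUE`) the weights are 1/SEM^2 and the parameter
#' covariance is reported unscaled, treating the SEMs as known measurement
#' errors, so the 95% intervals reflect the supplied uncertainties; without
#' SEMs the usual residual-variance-scaled covariance is used. 95%
#' confidence intervals are normal-theory (+- 1.96 SE).
#'
#' @param points data.frame with columns `F` (pN), `k_det` (1/s) and
#'   optionally `sem_k` (1/s) and `n_events`.
#' @param temperature_K temperature used for kT.
#' @param weighted use 1/SEM^2 weights when SEMs are present.
#' @param parameterization `"log"` fits (log k0, d); `"direct"` fits
#'   (k0, d) in the original space (provided for cross-checking; results
#'   agree on well-conditioned data).
#' @return object of class `bell_fit`: `k0`, `d`, `se_k0`, `se_d`,
#'   `ci95_k0`, `ci95_d`, `kT`, `n_points`, `rss`, `weighted`.
#' @examples
#' pts <- data.frame(F = c(1.65, 1.74, 2.34),
#'                   k_det = bell_rate(2.5, 4.1, c(1.65, 1.74, 2.34)))
#' fit_bell(pts)$d # 4.1
#' @export
fit_bell <- function(points, temperature_K = 298.15, weighted = TRUE,
                     parameterization = c("log", "direct")) {
  parameterization <- match.arg(parameterization)
  if (!all(c("F", "k_det") %in% names(points)))
    stop("points must have columns `F` and `k_det`")
  points <- points[complete.cases(points[c("F", "k_det")]), , drop = FALSE]
  if (nrow(points) < 3)
    stop("need at least 3 (F, k_det) points to fit the Bell equation")
  if (any(points$k_det <= 0)) stop("all rates must be positive")
  if (length(unique(points$F)) < 2)
    stop("all forces identical: Bell parameters unidentifiable")
  kT <- kt_pN_nm(temperature_K)

  use_sem <- weighted && "sem_k" %in% names(points) &&
    all(is.finite(points$sem_k)) && all(points$sem_k > 0)
  w <- if (use_sem) 1 / points$sem_k^2 else rep(1, nrow(points))

  # log-linear regression gives an excellent (often exact) start
  st <- coef(lm(log(k_det) ~ F, data = points))
  start <- list(lk0 = unname(st[1]), d = unname(st[2]) * kT)

  # zero-residual data (exactly log-linear): the NLS optimum coincides with
  # the log-space regression, and iterative optimizers misbehave at an
  # exact zero-residual start, so finish analytically
  log_resid <- log(points$k_det) - (start$lk0 + points$F * start$d / kT)
  if (max(abs(log_resid)) < 1e-10) {
    k0 <- exp(start$lk0); d <- start$d
    kh <- points$k_det
    J <- cbind(kh, kh * points$F / kT)  # gradient wrt (ln k0, d)
    v_unscaled <- solve(crossprod(sqrt(w) * J))
    vc <- if (use_sem) v_unscaled else 0 * v_unscaled  # sigma^2 = 0
    se_lk0 <- sqrt(vc[1, 1]); se_d <- sqrt(vc[2, 2])
    se_k0 <- k0 * se_lk0
    return(structure(list(k0 = k0, d = d, se_k0 = se_k0, se_d = se_d,
                          ci95_k0 = k0 + c(-1, 1) * 1.96 * se_k0,
                          ci95_d = d + c(-1, 1) * 1.96 * se_d,
                          kT = kT, n_points = nrow(points), rss = 0,
                          weighted = use_sem),
                     class = "bell_fit"))
  }

  dat <- data.frame(F = points$F, k_det = points$k_det, w = w)
  run_nls <- function(st) {
    if (parameterization == "log") {
      minpack.lm::nlsLM(k_det ~ exp(lk0 + F * d / kT), data = dat,
                        start = st, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 1000))
    } else {
      minpack.lm::nlsLM(k_det ~ k0 * exp(F * d / kT), data = dat,
                        start = list(k0 = exp(st$lk0), d = st$d),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 1000))
    }
  }
  # a start sitting exactly on a zero-residual solution can trip the
  # optimizer's rank check; nudge the start and let it converge back
  fit <- tryCatch(run_nls(start), error = function(e)
    run_nls(list(lk0 = start$lk0 + 0.05, d = start$d + 0.05)))
  if (!fit$convInfo$isConv && fit$convInfo$stopCode > 3)
    stop("Bell fit failed to converge after 1000 iterations; last RSS ",
         format(sum(w * fit$m$resid()^2)))

  cf <- coef(fit)
  grad <- fit$m$gradient()  # already sqrt(weight)-scaled by nls internals
  v_unscaled <- tryCatch(solve(crossprod(grad)), error = function(e)
    matrix(NA_real_, 2, 2))
  res <- fit$m$resid()  # already sqrt(w)-scaled residuals
  dof <- nrow(dat) - 2L
  sigma2 <- if (dof > 0) sum(res^2) / dof else 0
  vc <- if (use_sem) v_unscaled else v_unscaled * sigma2

  if (parameterization == "log") {
    k0 <- exp(unname(cf["lk0"])); d <- unname(cf["d"])
    se_lk0 <- sqrt(vc[1, 1]); se_d <- sqrt(vc[2, 2])
    se_k0 <- k0 * se_lk0  # delta method
  } else {
    k0 <- unname(cf["k0"]); d <- unname(cf["d"])
    se_k0 <- sqrt(vc[1, 1]); se_d <- sqrt(vc[2, 2])
  }
  rss <- sum(res^2)
  structure(list(k0 = k0, d = d, se_k0 = se_k0, se_d = se_d,
                 ci95_k0 = k0 + c(-1, 1) * 1.96 * se_k0,
                 ci95_d = d + c(-1, 1) * 1.96 * se_d,
                 kT = kT, n_points = nrow(dat), rss = rss,
                 weighted = use_sem),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("Bell-bond fit (kT = %.3f pN nm, %d points%s)\n", x$kT,
              x$n_points, if (x$weighted) ", 1/SEM^2 weights" else ""))
  cat(sprintf("  k0 = %.3g +- %.2g 1/s   95%% CI [%.3g, %.3g]\n",
              x$k0, x$se_k0, x$ci95_k0[1], x$ci95_k0[2]))
  cat(sprintf("  d  = %.3g +- %.2g nm    95%% CI [%.3g, %.3g]\n",
              x$d, x$se_d, x$ci95_d[1], x$ci95_d[2]))
  invisible(x)
}

#' Compare two Bell fits by confidence-interval overlap
#'
#' Reports whether the 95% confidence intervals of k0 and of d overlap
#' between two fits (non-overlap flags a significant difference, mirroring
#' CI-based comparison of fitted parameters) and the ratio of the d values
#' (second over first), a measure of relative load sensitivity.
#'
#' @param fit_a,fit_b `bell_fit` objects.
#' @return list with `k0_ci_overlap`, `d_ci_overlap`, `d_ratio`,
#'   `k0_ratio`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  list(k0_ci_overlap = overlap(fit_a$ci95_k0, fit_b$ci95_k0),
       d_ci_overlap = overlap(fit_a$ci95_d, fit_b$ci95_d),
       d_ratio = fit_b$d / fit_a$d,
       k0_ratio = fit_b$k0 / fit_a$k0)
}
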