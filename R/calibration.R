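#' Equipartition trap stiffness calibration
#'
#' Estimates trap stiffness from a bead-only record by the equipartition
#' theorem: one degree of freedom of a bead in a harmonic trap carries
#' kT/2 of thermal energy, so k_trap = kT / var(x). The sample mean is
#' subtracted first (tolerating trap-center offset or slow drift); the
#' unbiased (n-1) variance is used. The caller is responsible for supplying
#' a record free of binding events, which would inflate the variance and
#' bias the estimate low.
#'
#' @param trace a [trap_trace()] of bead-only data.
#' @return an object of class `stiffness_estimate`: list with `k_trap_hat`
#'   (pN/nm), `variance` (nm^2), `n_samples` and `temperature_K`.
#' @examples
#' tr <- simulate_bead_only(sim_config(k_trap = 0.06, duration_s = 5, seed = 2))
#' equipartition_stiffness(tr)$k_trap_hat
#' @export
equipartition_stiffness <- function(trace) {
  stopifnot(inherits(trace, "trap_trace"))
  n <- length(trace$positions)
  if (n < 2) stop("need at least 2 samples to estimate a variance")
  v <- var(trace$positions)
  if (v <= 0) stop("degenerate trace: zero positional variance")
  structure(list(k_trap_hat = kt_pN_nm(trace$temperature_K) / v,
                 variance = v, n_samples = n,
                 temperature_K = trace$temperature_K),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("equipartition stiffness: %.4f pN/nm (var %.2f nm^2, n = %d, T = %.2f K)\n",
              x$k_trap_hat, x$variance, x$n_samples, x$temperature_K))
  invisible(x)
}

#' Positional probability density of a trace
#'
#' Normalized histogram density of bead position. For a bead-only record
#' this approximates the Gaussian stationary density with variance
#' kT/k_trap; stiffer traps give a narrower, taller well.
#'
#' @param trace a [trap_trace()].
#' @param bin_width histogram bin width, nm.
#' @return data.frame with columns `mid` (bin centre, nm) and `density`
#'   (1/nm); `sum(density) * bin_width` is 1.
#' @export
positional_pdf <- function(trace, bin_width = 1) {
  stopifnot(inherits(trace, "trap_trace"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  x <- trace$positions
  if (!length(x)) stop("empty trace")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  data.frame(mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             density = counts / (length(x) * bin_width))
}

#' Gaussian fit to a positional density
#'
#' Least-squares Gaussian fit to the output of [positional_pdf()], used as
#' an internal-consistency check on the equipartition variance.
#'
#' @param pdf data.frame from [positional_pdf()].
#' @return list with `mean`, `sd` and `amplitude` of the fitted Gaussian.
#' @export
fit_positional_gaussian <- function(pdf) {
  m0 <- sum(pdf$mid * pdf$density) / sum(pdf$density)
  s0 <- sqrt(sum((pdf$mid - m0)^2 * pdf$density) / sum(pdf$density))
  fit <- minpack.lm::nlsLM(
    density ~ a * exp(-(mid - mu)^2 / (2 * sigma^2)),
    data = pdf,
    start = list(a = max(pdf$density), mu = m0, sigma = s0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       amplitude = unname(cf["a"]))
}
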