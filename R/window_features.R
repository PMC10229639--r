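#' Running mean/variance window transform
#'
#' Slides a fixed-width window over the displacement record and records each
#' window's mean and unbiased (n-1) variance. The default width of 100
#' samples (20 ms at 5 kHz) advanced in quarter-width steps of 25 samples
#' gives the feature sequence on which the two-state HMM operates: binding
#' events shift the window mean and shrink the window variance. The trailing
#' partial window is dropped.
#'
#' @param trace a [trap_trace()].
#' @param width window width, samples.
#' @param step window advance, samples (`width/4` by default; `step = width`
#'   gives non-overlapping windows).
#' @return data.frame of class `window_features` with columns
#'   `window_index` (0-based), `start_sample` (0-based), `mean`, `variance`;
#'   attributes `width`, `step`, `sample_rate_hz`, `n_samples` record the
#'   transform geometry.
#' @export
window_transform <- function(trace, width = 100L, step = 25L) {
  stopifnot(inherits(trace, "trap_trace"))
  width <- as.integer(width); step <- as.integer(step)
  n <- length(trace$positions)
  if (width < 2L) stop("width must be at least 2 samples")
  if (step < 1L || step > width) stop("step must be in [1, width]")
  if (n < width) stop("trace shorter than one window (", n, " < ", width, ")")
  starts <- seq.int(0L, n - width, by = step)  # 0-based
  x <- trace$positions
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  sum1 <- s1[starts + width + 1L] - s1[starts + 1L]
  sum2 <- s2[starts + width + 1L] - s2[starts + 1L]
  mu <- sum1 / width
  v <- pmax((sum2 - sum1^2 / width) / (width - 1L), 0)
  out <- data.frame(window_index = seq_along(starts) - 1L,
                    start_sample = starts, mean = mu, variance = v)
  attr(out, "width") <- width
  attr(out, "step") <- step
  attr(out, "sample_rate_hz") <- trace$sample_rate_hz
  attr(out, "n_samples") <- n
  class(out) <- c("window_features", "data.frame")
  out
}
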