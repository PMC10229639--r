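#' Fit a two-state Gaussian HMM to window features
#'
#' Baum-Welch EM fit of a two-state hidden Markov model over the window
#' mean and log-variance features of [window_transform()]. Emissions are
#' independent Gaussians over the window mean and over log(variance + eps);
#' the log transform makes the strongly right-skewed variance feature
#' near-Gaussian in each regime. States are relabelled after convergence so
#' that state 1 (unbound) always has the larger mean log-variance — the free
#' bead fluctuates more than a motor-stiffened one.
#'
#' Initialisation is deterministic: k-means (k = 2, Lloyd) on the
#' log-variance feature seeded with its 10% and 90% quantiles as centres.
#' If the two regimes are indistinguishable (single-regime data) the model
#' is flagged `degenerate` with a warning, and decoding downstream returns
#' no events.
#'
#' @param features a `window_features` data.frame.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param var_eps small variance offset (nm^2) inside the log.
#' @return an object of class `trap_hmm`: emission means/variances per
#'   state (rows: state 1 = unbound, state 2 = bound; columns: mean
#'   feature, log-variance feature), 2x2 transition matrix, initial
#'   probabilities, converged log-likelihood, iteration count and flags.
#' @export
fit_hmm <- function(features, max_iter = 500L, tol = 1e-6,
                    var_eps = 1e-6) {
  stopifnot(inherits(features, "window_features"))
  if (nrow(features) < 20)
    stop("need at least 20 windows to fit the HMM")
  obs <- cbind(mean = features$mean,
               logvar = log(features$variance + var_eps))
  T_ <- nrow(obs)

  lv <- obs[, "logvar"]
  q <- quantile(lv, c(0.1, 0.9), names = FALSE)
  degenerate <- FALSE
  if (diff(q) < 1e-8 || sd(lv) < 1e-10) {
    warning("window features look single-regime; flagging degenerate model")
    degenerate <- TRUE
    assign0 <- rep(1L, T_)
  } else {
    km <- kmeans(lv, centers = matrix(q, ncol = 1), algorithm = "Lloyd",
                 iter.max = 100)
    assign0 <- km$cluster
    if (min(table(factor(assign0, levels = 1:2))) < 2L) {
      warning("one regime nearly empty; flagging degenerate model")
      degenerate <- TRUE
    }
  }

  if (degenerate) {
    mu <- rbind(colMeans(obs), colMeans(obs))
    s2 <- rbind(apply(obs, 2, var), apply(obs, 2, var))
    s2[s2 < 1e-12] <- 1e-12
    model <- structure(list(emission_mean = mu, emission_var = s2,
                            trans = matrix(0.5, 2, 2),
                            init = c(1, 0), loglik = NA_real_,
                            n_iter = 0L, converged = FALSE,
                            degenerate = TRUE, var_eps = var_eps),
                       class = "trap_hmm")
    return(model)
  }

  mu <- rbind(colMeans(obs[assign0 == 1L, , drop = FALSE]),
              colMeans(obs[assign0 == 2L, , drop = FALSE]))
  s2 <- rbind(apply(obs[assign0 == 1L, , drop = FALSE], 2, var),
              apply(obs[assign0 == 2L, , drop = FALSE], 2, var))
  s2[!is.finite(s2) | s2 < 1e-12] <- 1e-12
  trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)

  ll_prev <- -Inf
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    ld <- emission_logdens(obs, mu, s2)
    fb <- hmm_forward_backward(ld, trans, init)
    ll <- fb$loglik
    if (!is.finite(ll))
      stop("EM failed: non-finite log-likelihood at iteration ", it)
    if (ll < ll_prev - 1e-6 * abs(ll_prev))
      stop("EM failed to improve (log-likelihood ", ll, " after ", ll_prev, ")")
    g <- fb$gamma
    w <- colSums(g)
    for (k in 1:2) {
      mu[k, ] <- colSums(g[, k] * obs) / w[k]
      s2[k, ] <- colSums(g[, k] * sweep(obs, 2, mu[k, ])^2) / w[k]
    }
    s2[s2 < 1e-12] <- 1e-12
    xs <- fb$xi
    trans <- xs / rowSums(xs)
    trans[!is.finite(trans)] <- 0.5
    init <- pmax(g[1, ], 1e-12)
    init <- init / sum(init)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  # relabel: state 1 = unbound = larger mean log-variance
  if (mu[1, "logvar"] < mu[2, "logvar"]) {
    mu <- mu[2:1, , drop = FALSE]
    s2 <- s2[2:1, , drop = FALSE]
    trans <- trans[2:1, 2:1]
    init <- init[2:1]
  }
  # single-regime guard: on bound-event-free records EM splits the noise
  # into two near-identical regimes; require the log-variance emissions to
  # separate by at least 3 pooled within-state SDs to call two states real
  separation <- abs(mu[1, "logvar"] - mu[2, "logvar"]) /
    sqrt(mean(s2[, "logvar"]))
  degenerate <- separation < 3
  if (degenerate)
    warning("emission regimes barely separated (d' = ",
            format(separation, digits = 3),
            "); flagging degenerate model, decoding all-unbound")
  structure(list(emission_mean = mu, emission_var = s2, trans = trans,
                 init = init, loglik = ll, n_iter = n_iter,
                 converged = converged, degenerate = degenerate,
                 separation = separation, var_eps = var_eps),
            class = "trap_hmm")
}

emission_logdens <- function(obs, mu, s2) {
  ld <- matrix(0, nrow(obs), 2)
  for (k in 1:2) {
    ld[, k] <- dnorm(obs[, 1], mu[k, 1], sqrt(s2[k, 1]), log = TRUE) +
      dnorm(obs[, 2], mu[k, 2], sqrt(s2[k, 2]), log = TRUE)
  }
  ld
}

#' @export
print.trap_hmm <- function(x, ...) {
  cat("two-state Gaussian HMM over (window mean, log window variance)\n")
  if (x$degenerate) {
    cat("  DEGENERATE: single-regime data, decodes all-unbound\n")
    return(invisible(x))
  }
  st <- c("unbound", "bound")
  for (k in 1:2)
    cat(sprintf("  state %d (%s): mean %.2f nm, logvar %.3f; trans stay %.4f\n",
                k, st[k], x$emission_mean[k, 1], x$emission_mean[k, 2],
                x$trans[k, k]))
  cat(sprintf("  loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Decode binding events from a fitted HMM
#'
#' Viterbi-decodes the window feature sequence and converts maximal runs of
#' the bound state into coarse events. Coarse sample bounds are the start
#' sample of the first bound window and the start sample of the last bound
#' window plus the window width (0-based, half-open). Runs shorter than
#' `min_event_windows` windows are discarded.
#'
#' @param features a `window_features` data.frame.
#' @param model a `trap_hmm` from [fit_hmm()].
#' @param min_event_windows minimum run length in windows.
#' @return data.frame with `event_id`, `start_sample`, `end_sample`,
#'   `n_windows` (coarse bounds; refine with [refine_changepoints()]).
#' @export
decode_events <- function(features, model, min_event_windows = 1L) {
  stopifnot(inherits(features, "window_features"),
            inherits(model, "trap_hmm"))
  empty <- data.frame(event_id = integer(), start_sample = integer(),
                      end_sample = integer(), n_windows = integer())
  if (model$degenerate) return(empty)
  obs <- cbind(features$mean, log(features$variance + model$var_eps))
  path <- hmm_viterbi(emission_logdens(obs, model$emission_mean,
                                       model$emission_var),
                      model$trans, pmax(model$init, 1e-12))
  width <- attr(features, "width")
  r <- rle(path == 2L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_event_windows
  if (!any(keep)) return(empty)
  i0 <- starts[keep]; i1 <- ends[keep]
  data.frame(event_id = seq_along(i0),
             start_sample = features$start_sample[i0],
             end_sample = features$start_sample[i1] + width,
             n_windows = i1 - i0 + 1L)
}
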