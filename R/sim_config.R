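#' Simulation configuration for synthetic trap records
#'
#' Bundles the mechanical and kinetic parameters of the synthetic-trace
#' generator. The mechanics describe a bead held in a harmonic optical trap
#' (stiffness `k_trap`) with viscous drag `gamma`; each attached motor head
#' adds a linear spring `k_head` in parallel with the trap and contributes a
#' `step_nm` powerstroke. Detachment of an attached head follows two
#' load-dependent pathways, an ADP-release-limited pathway slowed by
#' resistive load and a phosphate(Pi)-rebinding pathway accelerated by it:
#'
#'   h(f) = k_adp0 * exp(-f * d_adp / kT) +
#'          pi_mM * k_pi0_per_mM * exp(+f * d_pi / kT)
#'
#' where `f` is the per-head resistive load in pN.
#'
#' @param n_heads number of motor heads able to reach the filament.
#' @param step_nm powerstroke size per head, nm.
#' @param k_trap trap stiffness, pN/nm (two-trap total the motors work against).
#' @param k_head stiffness of one attached head, pN/nm.
#' @param gamma bead drag coefficient, pN s/nm (default approximates a
#'   1 micron bead in water).
#' @param temperature_K temperature, K.
#' @param sample_rate_hz sampling rate, Hz.
#' @param duration_s record duration, s.
#' @param k_attach attachment rate per detached head, 1/s.
#' @param k_adp0 unloaded ADP-release-limited detachment rate, 1/s.
#' @param d_adp load distance of the ADP pathway, nm (positive means load
#'   slows detachment).
#' @param pi_mM phosphate concentration, mM.
#' @param k_pi0_per_mM unloaded Pi-induced detachment rate per mM Pi,
#'   1/(s mM).
#' @param d_pi load distance of the Pi pathway, nm (positive means load
#'   accelerates detachment).
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @return an object of class `sim_config` (a validated list; element `kT`
#'   holds the thermal energy in pN nm).
#' @examples
#' cfg <- sim_config(k_trap = 0.04, duration_s = 1, seed = 1)
#' cfg$kT
#' @export
sim_config <- function(n_heads = 4L,
                       step_nm = 7,
                       k_trap = 0.04,
                       k_head = 0.3,
                       gamma = 1.9e-5,
                       temperature_K = 298.15,
                       sample_rate_hz = 5000,
                       duration_s = 10,
                       k_attach = 1,
                       k_adp0 = 15,
                       d_adp = 4,
                       pi_mM = 0,
                       k_pi0_per_mM = 1 / 12,
                       d_pi = 4.1,
                       seed = NULL) {
  cfg <- list(n_heads = as.integer(n_heads), step_nm = step_nm,
              k_trap = k_trap, k_head = k_head, gamma = gamma,
              temperature_K = temperature_K,
              sample_rate_hz = sample_rate_hz, duration_s = duration_s,
              k_attach = k_attach, k_adp0 = k_adp0, d_adp = d_adp,
              pi_mM = pi_mM, k_pi0_per_mM = k_pi0_per_mM, d_pi = d_pi,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  cfg$kT <- kt_pN_nm(temperature_K)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_pos <- function(x, name) {
    if (!is.numeric(cfg[[x]]) || length(cfg[[x]]) != 1 ||
        !is.finite(cfg[[x]]) || cfg[[x]] <= 0)
      stop("invalid sim_config: `", x, "` must be a positive number",
           call. = FALSE)
  }
  num_nonneg <- function(x) {
    if (!is.numeric(cfg[[x]]) || length(cfg[[x]]) != 1 ||
        !is.finite(cfg[[x]]) || cfg[[x]] < 0)
      stop("invalid sim_config: `", x, "` must be a non-negative number",
           call. = FALSE)
  }
  for (f in c("k_trap", "k_head", "gamma", "temperature_K",
              "sample_rate_hz", "duration_s", "step_nm"))
    num_pos(f)
  for (f in c("k_attach", "k_adp0", "pi_mM", "k_pi0_per_mM"))
    num_nonneg(f)
  for (f in c("d_adp", "d_pi"))
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]))
      stop("invalid sim_config: `", f, "` must be finite", call. = FALSE)
  if (cfg$n_heads < 1L)
    stop("invalid sim_config: `n_heads` must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trap record configuration\n")
  cat(sprintf("  %d head(s), step %.1f nm, k_trap %.3f pN/nm, k_head %.2f pN/nm\n",
              x$n_heads, x$step_nm, x$k_trap, x$k_head))
  cat(sprintf("  %.0f Hz, %.1f s, T = %.2f K (kT = %.3f pN nm)\n",
              x$sample_rate_hz, x$duration_s, x$temperature_K, x$kT))
  cat(sprintf("  k_attach %.3g /s, k_adp0 %.3g /s (d_adp %.2f nm), [Pi] %.1f mM, k_pi0 %.3g /s/mM (d_pi %.2f nm)\n",
              x$k_attach, x$k_adp0, x$d_adp, x$pi_mM, x$k_pi0_per_mM, x$d_pi))
  invisible(x)
}

#' Per-head detachment hazard under load
#'
#' Total detachment rate of one attached head experiencing a resistive load
#' `f_pN`, summing the ADP-release-limited pathway (slowed by load when
#' `d_adp > 0`) and the Pi-rebinding pathway (accelerated by load when
#' `d_pi > 0`). Exponents are clipped at 700 with a warning to avoid
#' overflow.
#'
#' @param f_pN per-head resistive load, pN.
#' @param config a [sim_config()].
#' @return hazard in 1/s.
#' @export
detachment_hazard <- function(f_pN, config) {
  e1 <- -f_pN * config$d_adp / config$kT
  e2 <- f_pN * config$d_pi / config$kT
  if (any(abs(c(e1, e2)) > 700)) {
    warning("detachment hazard exponent clipped at |700|")
    e1 <- pmin(pmax(e1, -700), 700)
    e2 <- pmin(pmax(e2, -700), 700)
  }
  config$k_adp0 * exp(e1) + config$pi_mM * config$k_pi0_per_mM * exp(e2)
}
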