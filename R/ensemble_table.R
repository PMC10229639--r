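#' Head count implied by an ensemble displacement
#'
#' Divides the ensemble displacement by the single-head powerstroke size
#' (7 nm by default) to estimate how many heads produced it. The raw
#' quotient is returned alongside a half-up rounding to one decimal for
#' display.
#'
#' @param displacement_nm ensemble displacement, nm (>= 0; vectorised).
#' @param step_nm powerstroke size, nm.
#' @return data.frame with `heads_raw` and `heads` (1-decimal display).
#' @examples
#' heads_from_displacement(29.1)$heads # 4.2
#' @export
heads_from_displacement <- function(displacement_nm, step_nm = 7) {
  if (any(displacement_nm < 0)) stop("displacement must be non-negative")
  if (step_nm <= 0) stop("step_nm must be positive")
  raw <- displacement_nm / step_nm
  data.frame(heads_raw = raw, heads = round_half_up(raw, 1))
}

#' Ensemble force from displacement
#'
#' F = k_trap x displacement from trap centre.
#'
#' @param displacement_nm displacement, nm (vectorised).
#' @param k_trap trap stiffness, pN/nm.
#' @return force in pN (full precision; display at 3 significant figures
#'   with [format_force()]).
#' @examples
#' force_from_displacement(40.2, 0.10) # 4.02
#' @export
force_from_displacement <- function(displacement_nm, k_trap) {
  if (any(k_trap <= 0)) stop("k_trap must be positive")
  k_trap * displacement_nm
}

#' @rdname force_from_displacement
#' @param force_pN force value(s) to format.
#' @export
format_force <- function(force_pN) signif(force_pN, 3)

# round half away from zero at `digits` decimals (base round() is
# round-half-even, which does not match the printed table convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble a per-condition ensemble summary table
#'
#' Builds one row per condition from mean displacements: ensemble force,
#' implied head count and force per head. The force column uses the mean of
#' per-event peak forces when present in the input (column
#' `mean_peak_force_pN`), else the product k_trap x mean displacement; the
#' choice is recorded per row in `force_source`. When force = k_trap x
#' displacement and heads = displacement/step, force per head reduces to
#' k_trap x step exactly.
#'
#' @param summaries data.frame with columns `condition` (or any label
#'   columns), `k_trap`, `mean_peak_displacement_nm` and optionally
#'   `mean_peak_force_pN`; a [summarize_conditions()] result works
#'   directly.
#' @param step_nm powerstroke size, nm.
#' @return data.frame of class `ensemble_table` with raw and display
#'   columns.
#' @export
build_table <- function(summaries, step_nm = 7) {
  req <- c("k_trap", "mean_peak_displacement_nm")
  if (!all(req %in% names(summaries)))
    stop("summaries must carry columns: ", paste(req, collapse = ", "))
  ok <- is.finite(summaries$k_trap) & summaries$k_trap > 0
  if (any(!ok))
    message("skipping ", sum(!ok), " row(s) without a valid k_trap")
  s <- summaries[ok, , drop = FALSE]
  disp <- s$mean_peak_displacement_nm
  have_event_force <- "mean_peak_force_pN" %in% names(s) &&
    all(is.finite(s$mean_peak_force_pN))
  force <- if (have_event_force) s$mean_peak_force_pN else
    force_from_displacement(disp, s$k_trap)
  h <- heads_from_displacement(disp, step_nm)
  out <- data.frame(s[setdiff(names(s), c("mean_peak_displacement_nm",
                                          "mean_peak_force_pN"))],
                    displacement_nm = disp,
                    force_pN = force,
                    force_display_pN = format_force(force),
                    heads_raw = h$heads_raw,
                    heads = h$heads,
                    force_per_head_pN = force / h$heads_raw,
                    force_per_head_display_pN =
                      round_half_up(force / h$heads_raw, 2),
                    force_source = rep(if (have_event_force)
                      "per_event_mean" else "k_trap_x_displacement",
                      length.out = nrow(s)),
                    check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ensemble_table", "data.frame")
  out
}

#' Write and read an ensemble summary table
#'
#' TSV round trip at full precision.
#'
#' @param table an `ensemble_table`.
#' @param path file path.
#' @return `write_ensemble_table()` returns `path` invisibly;
#'   `read_ensemble_table()` the table.
#' @export
write_ensemble_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_table
#' @export
read_ensemble_table <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  class(out) <- c("ensemble_table", "data.frame")
  out
}
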