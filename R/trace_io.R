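#' Write and read displacement trace files
#'
#' Traces are stored as plain-text CSV with metadata header lines of the
#' form `# key=value` (`k_trap_pN_per_nm`, `sample_rate_hz`,
#' `temperature_K`, `condition`) followed by a single `position_nm` column;
#' time is implicit in the uniform sampling. Positions are written with 17
#' significant digits so the round trip is bit-exact for doubles.
#'
#' @param trace a [trap_trace()].
#' @param path file path.
#' @param truth optional `trap_truth`; if given, the event table is written
#'   to `<path>_truth.tsv` and the transition table to
#'   `<path>_transitions.tsv` (see [write_truth()]).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a [trap_trace()].
#' @export
write_trace <- function(trace, path, truth = NULL) {
  stopifnot(inherits(trace, "trap_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# k_trap_pN_per_nm=%.17g", trace$k_trap),
    sprintf("# sample_rate_hz=%.17g", trace$sample_rate_hz),
    sprintf("# temperature_K=%.17g", trace$temperature_K),
    sprintf("# condition=%s", trace$condition),
    "position_nm",
    sprintf("%.17g", trace$positions)), con)
  if (!is.null(truth)) write_truth(truth, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(hdr_idx != seq_along(hdr_idx)))
    stop("malformed trace file: header lines must precede data (line ",
         hdr_idx[min(which(hdr_idx != seq_along(hdr_idx)))], ")")
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^#\\s*([^=]+)=(.*)$", hdr))
  bad <- which(lengths(kv) != 3)
  if (length(bad))
    stop("malformed trace header at line ", hdr_idx[bad[1]], ": ",
         hdr[bad[1]])
  meta <- setNames(vapply(kv, `[`, character(1), 3),
                   trimws(vapply(kv, `[`, character(1), 2)))
  need <- c("k_trap_pN_per_nm", "sample_rate_hz", "temperature_K")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("trace file missing required metadata: ",
         paste(missing_keys, collapse = ", "))
  body <- lines[-hdr_idx]
  if (length(body) < 2 || body[1] != "position_nm")
    stop("malformed trace file: expected `position_nm` column header at line ",
         length(hdr_idx) + 1)
  pos <- suppressWarnings(as.numeric(body[-1]))
  if (anyNA(pos)) {
    bad_line <- length(hdr_idx) + 1 + which(is.na(pos))[1]
    stop("malformed trace file: non-numeric position at line ", bad_line)
  }
  trap_trace(pos,
             sample_rate_hz = as.numeric(meta[["sample_rate_hz"]]),
             k_trap = as.numeric(meta[["k_trap_pN_per_nm"]]),
             temperature_K = as.numeric(meta[["temperature_K"]]),
             condition = if ("condition" %in% names(meta))
               meta[["condition"]] else "")
}

#' Write and read ground-truth annotation tables
#'
#' The event table is written as TSV (`event_id`, `start_sample`,
#' `end_sample` plus any additional truth columns); the transition table as
#' a second TSV. `read_truth()` restores both.
#'
#' @param truth a `trap_truth` from [simulate_ensemble_trace()].
#' @param path the trace path the annotations accompany; files are written
#'   as `<path>_truth.tsv` and `<path>_transitions.tsv`.
#' @return `write_truth()` returns the truth file path invisibly;
#'   `read_truth()` returns a `trap_truth`.
#' @export
write_truth <- function(truth, path) {
  ev_path <- paste0(path, "_truth.tsv")
  tr_path <- paste0(path, "_transitions.tsv")
  write.table(format(truth$events, digits = 17, scientific = FALSE,
                     trim = TRUE),
              ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format(truth$transitions, digits = 17, scientific = FALSE,
                     trim = TRUE),
              tr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev_path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  ev <- read.table(paste0(path, "_truth.tsv"), sep = "\t", header = TRUE)
  tr <- read.table(paste0(path, "_transitions.tsv"), sep = "\t",
                   header = TRUE)
  structure(list(transitions = tr, events = ev), class = "trap_truth")
}

#' Write and read detected event tables
#'
#' Events are stored as TSV with 0-based, half-open sample bounds.
#'
#' @param events data.frame with at least `event_id`, `start_sample`,
#'   `end_sample`, `t_on_s`.
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   data.frame.
#' @export
write_events <- function(events, path) {
  write.table(format(events, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.table(path, sep = "\t", header = TRUE)
}
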