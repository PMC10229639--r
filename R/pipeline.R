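#' Run the simulate-detect-features-table-fit pipeline
#'
#' Orchestrates the full analysis with reproducible seeding. The
#' configuration is a named list (or path to a YAML file) with the
#' structure:
#'
#' ```yaml
#' seed: 1
#' outdir: runs/demo
#' stages: [simulate, detect, features, table1, fit_bell]
#' simulate:
#'   conditions:            # one block per record; sim_config() fields
#'     - label: k0.04_pi30
#'       k_trap: 0.04
#'       pi_mM: 30
#'       duration_s: 60
#' detect: {width: 100, step: 25, min_event_windows: 1,
#'          cp_method: likelihood, cp_window: 50}
#' features: {window_ms: 5, step_nm: 7}
#' table1: {step_nm: 7}
#' fit_bell: {force: per_head, weighted: true}
#' ```
#'
#' Unknown keys anywhere in the configuration are rejected. Any suffix of
#' the stage sequence can be run on existing files in `outdir` (e.g. only
#' `fit_bell` on a hand-written `summary.tsv`). Every stage derives its own
#' RNG seed from the global seed as `seed + 7919 * stage_index +
#' condition_index`, so stages and conditions are individually
#' reproducible. A manifest of all written files with MD5 checksums and a
#' run log (versions, seed, parameters) are written to `outdir`.
#'
#' @param config named list or path to a YAML config file.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  cat("", file = logfile)  # truncate
  logline("minitrap ", as.character(utils::packageVersion("minitrap")),
          " | R ", R.version.string)
  logline("seed: ", cfg$seed)
  written <- character()
  note <- function(p) written <<- c(written, p)

  all_stages <- c("simulate", "detect", "features", "table1", "fit_bell")
  stage_seed <- function(stage, cond_idx = 0L) {
    as.integer((cfg$seed + 7919L * match(stage, all_stages) + cond_idx) %%
                 .Machine$integer.max)
  }
  cond_labels <- function() {
    if (!is.null(cfg$simulate))
      return(vapply(cfg$simulate$conditions, `[[`, character(1), "label"))
    # infer from files on disk
    f <- list.files(outdir, pattern = "^trace_.*\\.csv$")
    sub("^trace_(.*)\\.csv$", "\\1", f)
  }

  if ("simulate" %in% cfg$stages) {
    for (i in seq_along(cfg$simulate$conditions)) {
      block <- cfg$simulate$conditions[[i]]
      label <- block$label
      block$label <- NULL
      block$seed <- stage_seed("simulate", i)
      sc <- do.call(sim_config, block)
      sim <- simulate_ensemble_trace(sc)
      p <- file.path(outdir, paste0("trace_", label, ".csv"))
      write_trace(sim$trace, p, truth = sim$truth)
      note(p); note(paste0(p, "_truth.tsv")); note(paste0(p, "_transitions.tsv"))
      logline("simulate[", label, "]: ", nrow(sim$truth$events),
              " truth events, seed ", block$seed)
    }
  }

  if ("detect" %in% cfg$stages) {
    for (label in cond_labels()) {
      tp <- file.path(outdir, paste0("trace_", label, ".csv"))
      if (!file.exists(tp)) stop("detect: expected trace file ", tp)
      tr <- read_trace(tp)
      det <- cfg$detect %||% list()
      ev <- do.call(detect_events, c(list(trace = tr), det))
      p <- file.path(outdir, paste0("events_", label, ".tsv"))
      write_events(ev, p)
      note(p)
      logline("detect[", label, "]: ", nrow(ev), " events")
    }
  }

  if ("features" %in% cfg$stages) {
    metrics <- list()
    for (label in cond_labels()) {
      tp <- file.path(outdir, paste0("trace_", label, ".csv"))
      ep <- file.path(outdir, paste0("events_", label, ".tsv"))
      if (!file.exists(ep)) stop("features: expected events file ", ep)
      tr <- read_trace(tp)
      ev <- read_events(ep)
      fe <- cfg$features %||% list()
      m <- do.call(event_metrics, c(list(trace = tr, events = ev), fe))
      m$condition <- label
      metrics[[label]] <- m
    }
    metrics <- do.call(rbind, metrics)
    p <- file.path(outdir, "metrics.tsv")
    write_events(metrics, p); note(p)
    summ <- summarize_conditions(metrics)
    p2 <- file.path(outdir, "summary.tsv")
    write_events(as.data.frame(summ), p2); note(p2)
    logline("features: ", nrow(metrics), " events across ",
            nrow(summ), " condition(s)")
  }

  if ("table1" %in% cfg$stages) {
    sp <- file.path(outdir, "summary.tsv")
    if (!file.exists(sp)) stop("table1: expected summary file ", sp)
    summ <- read_events(sp)
    tb <- do.call(build_table, c(list(summaries = summ),
                                 cfg$table1 %||% list()))
    p <- file.path(outdir, "table1.tsv")
    write_ensemble_table(tb, p); note(p)
    logline("table1: ", nrow(tb), " row(s)")
  }

  if ("fit_bell" %in% cfg$stages) {
    sp <- file.path(outdir, "summary.tsv")
    if (!file.exists(sp)) stop("fit_bell: expected summary file ", sp)
    summ <- read_events(sp)
    fb <- cfg$fit_bell %||% list()
    force_col <- if (identical(fb$force, "ensemble"))
      "mean_peak_force_pN" else "mean_force_per_head_pN"
    pts <- data.frame(F = summ[[force_col]], k_det = summ$k_det_per_s,
                      sem_k = summ$sem_k_det_per_s,
                      n_events = summ$n_events)
    fit <- fit_bell(pts, weighted = !identical(fb$weighted, FALSE))
    p <- file.path(outdir, "bell_fit.json")
    jsonlite::write_json(
      list(k0 = fit$k0, d = fit$d, se_k0 = fit$se_k0, se_d = fit$se_d,
           ci95_k0 = fit$ci95_k0, ci95_d = fit$ci95_d, kT = fit$kT,
           n = fit$n_points, force = force_col, seed = cfg$seed),
      p, auto_unbox = TRUE, digits = NA)
    note(p)
    logline(sprintf("fit_bell: k0 = %.4g 1/s, d = %.4g nm (%s)",
                    fit$k0, fit$d, force_col))
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path")
  known_top <- c("seed", "outdir", "stages", "simulate", "detect",
                 "features", "table1", "fit_bell")
  bad <- setdiff(names(config), known_top)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config must set an integer `seed`")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outdir)) stop("config must set `outdir`")
  all_stages <- c("simulate", "detect", "features", "table1", "fit_bell")
  if (is.null(config$stages)) config$stages <- all_stages
  bad <- setdiff(unlist(config$stages), all_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$stages <- unlist(config$stages)

  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in `", where, "`: ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$simulate)) {
    check_keys(config$simulate, "conditions", "simulate")
    if (!length(config$simulate$conditions))
      stop("simulate stage needs at least one condition block")
    sim_fields <- c("label", names(formals(sim_config)))
    for (b in config$simulate$conditions) {
      check_keys(b, sim_fields, "simulate$conditions")
      if (is.null(b$label)) stop("each simulate condition needs a `label`")
    }
  }
  if (!is.null(config$detect))
    check_keys(config$detect,
               c("width", "step", "min_event_windows", "cp_method",
                 "cp_window"), "detect")
  if (!is.null(config$features))
    check_keys(config$features, c("window_ms", "step_nm"), "features")
  if (!is.null(config$table1))
    check_keys(config$table1, "step_nm", "table1")
  if (!is.null(config$fit_bell))
    check_keys(config$fit_bell, c("force", "weighted"), "fit_bell")
  config
}
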