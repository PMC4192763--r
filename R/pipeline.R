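#' Offline end-to-end analysis of a waveform capture
#'
#' Runs the full pipeline — parse, segment/quarantine, fit, stiffness,
#' rolling smoothing and (optionally) recruitment-manoeuvre titration — on a
#' capture file or text, and optionally writes the result files: the breath
#' table (CSV + JSON-lines), the long-format Edrs curves, and the RM ladder
#' CSV + JSON summary. Every quarantined breath keeps a row with its reason
#' code. Errors out (with diagnostic counts per reason) when no breath at
#' all survives quarantine.
#'
#' @param input Path to a capture file, or the capture text itself.
#' @param output_dir Optional directory for result files (created if
#'   needed).
#' @param meta A [stream_meta()].
#' @param filter A [filter_config()].
#' @param window Stiffness smoothing window, breathing cycles (default 60).
#' @param tail_fraction Expiratory tail fraction for PEEP detection.
#' @param calibration Optional [calibrate_peep()] result.
#' @param rm Run recruitment-manoeuvre analysis (`TRUE`/`FALSE`), or a
#'   numeric window `c(t_start, t_end)` in seconds marking the manoeuvre
#'   within the session (mirrors the start/stop manoeuvre marks).
#' @param rm_step RM protocol PEEP step, cmH2O (default 2).
#' @param min_breaths_per_level Minimum breaths per retained ladder level.
#' @param cond_cap,volume_floor_fraction Passed to [analyze_breaths()].
#' @return A list: `results` (the [analyze_breaths()] tibble), `rm` (an
#'   `rm_result` or `NULL`), `counts` (breaths per status/reason), `files`
#'   (paths written).
#' @export
run_offline <- function(input, output_dir = NULL,
                        meta = stream_meta(), filter = filter_config(),
                        window = 60, tail_fraction = 0.2, calibration = NULL,
                        rm = FALSE, rm_step = 2, min_breaths_per_level = 3,
                        cond_cap = 1e8, volume_floor_fraction = 0.05) {
  is_path <- length(input) == 1 && !grepl("\n", input, fixed = TRUE) &&
    file.exists(input)
  segments <- if (is_path) read_capture(input, meta) else parse_stream(input, meta)
  breaths <- segment_breaths(segments, filter, tail_fraction)
  results <- analyze_breaths(
    breaths, window = window, calibration = calibration,
    cond_cap = cond_cap, volume_floor_fraction = volume_floor_fraction
  )
  counts <- table(factor(results$reason, levels = quarantine_reasons))
  if (!any(results$status == "accepted")) {
    abort(paste0(
      "No breathing cycle survived quarantine. Counts per reason: ",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", ")
    ))
  }
  rm_result <- NULL
  if (!isFALSE(rm)) {
    rm_data <- results
    if (is.numeric(rm) && length(rm) == 2) {
      rm_data <- results[!is.na(results$t_start) &
                           results$t_start >= rm[1] & results$t_start <= rm[2], ]
    }
    ladder <- build_peep_ladder(
      rm_data, step = rm_step,
      min_breaths_per_level = min_breaths_per_level
    )
    rm_result <- recommend_peep(ladder, step = rm_step)
  }
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      breath_table = file.path(output_dir, "breaths.csv"),
      breath_jsonl = file.path(output_dir, "breaths.jsonl"),
      edrs = file.path(output_dir, "edrs_curves.csv")
    )
    write_breath_table(results, files[["breath_table"]])
    write_breath_jsonl(results, files[["breath_jsonl"]])
    write_edrs_curves(results, files[["edrs"]])
    if (!is.null(rm_result)) {
      files <- c(
        files,
        rm_ladder = file.path(output_dir, "rm_ladder.csv"),
        rm_summary = file.path(output_dir, "rm_summary.json")
      )
      write_rm_report(rm_result, files[["rm_ladder"]], files[["rm_summary"]])
    }
  }
  list(results = results, rm = rm_result, counts = counts, files = files)
}

#' Generate a simulated capture plus ground truth on disk
#'
#' Thin wrapper over [simulate_session()] / [simulate_rm_session()] that
#' writes the capture text and the ground-truth CSV. Seeded and reproducible:
#' the same seed and configuration produce byte-identical files.
#'
#' @param lung A [lung_config()].
#' @param vent A [vent_settings()].
#' @param output_dir Directory for `capture.txt` and `ground_truth.csv`.
#' @param n_breaths Number of breaths for a constant-PEEP session (mutually
#'   exclusive with `protocol`/`rm`).
#' @param rm Simulate a recruitment manoeuvre instead of a constant-PEEP
#'   session.
#' @param protocol Optional explicit PEEP protocol for the RM.
#' @param breaths_per_level Breaths per RM level.
#' @param dt Sample interval, s.
#' @param peep_start,step,max_peak_paw Protocol-builder settings.
#' @return The simulation list, invisibly, with `files` added.
#' @export
run_simulate <- function(lung, vent, output_dir, n_breaths = 100, rm = FALSE,
                         protocol = NULL, breaths_per_level = 10, dt = 0.02,
                         peep_start = 14, step = 2, max_peak_paw = 55) {
  sim <- if (isTRUE(rm) || !is.null(protocol)) {
    simulate_rm_session(
      lung, vent, protocol = protocol, breaths_per_level = breaths_per_level,
      dt = dt, peep_start = peep_start, step = step, max_peak_paw = max_peak_paw
    )
  } else {
    simulate_session(lung, vent, n_breaths = n_breaths, dt = dt)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    capture = file.path(output_dir, "capture.txt"),
    truth = file.path(output_dir, "ground_truth.csv")
  )
  writeLines(sim$text, files[["capture"]])
  write_ground_truth(sim$truth, files[["truth"]])
  sim$files <- files
  invisible(sim)
}
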