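#' Calibrate detected PEEP against the ventilator display
#'
#' The ventilator's displayed PEEP and the PEEP measured from the airway
#' pressure waveform can differ by a constant offset; PEEP-indexed analyses
#' should run on the display scale the clinician sets. The calibration offset
#' is `displayed - measured`, and every subsequently detected PEEP is
#' reported as `detected + offset`. An offset larger than 5 cmH2O in
#' magnitude is almost certainly a mis-entry, so it is applied but flagged
#' with a warning.
#'
#' @param displayed PEEP shown on the ventilator, cmH2O.
#' @param measured PEEP measured from the waveform (e.g. [detect_peep()]),
#'   cmH2O.
#' @return A `peep_calibration` object with fields `offset` and `suspect`.
#' @examples
#' cal <- calibrate_peep(displayed = 14, measured = 13.5)
#' apply_peep_calibration(13.5, cal) # 14
#' @export
calibrate_peep <- function(displayed, measured) {
  if (!is.finite(displayed) || !is.finite(measured)) {
    abort("`displayed` and `measured` must be finite pressures (cmH2O).")
  }
  offset <- displayed - measured
  suspect <- abs(offset) > 5
  if (suspect) {
    warn(sprintf(
      "PEEP calibration offset is %.3g cmH2O (>5): check the entered values. Calibration applied anyway.",
      offset
    ))
  }
  structure(list(offset = offset, suspect = suspect), class = "peep_calibration")
}

#' @rdname calibrate_peep
#' @param peep Detected PEEP value(s), cmH2O.
#' @param calibration A `peep_calibration` object (or `NULL` for identity).
#' @export
apply_peep_calibration <- function(peep, calibration) {
  if (is.null(calibration)) return(peep)
  stopifnot(inherits(calibration, "peep_calibration"))
  peep + calibration$offset
}

#' Build the stiffness-vs-PEEP ladder of a recruitment manoeuvre
#'
#' Assigns each accepted breath to a protocol PEEP level and manoeuvre arm,
#' then summarises stiffness per (level, arm). Detected (calibrated) PEEPs
#' are snapped to the nearest multiple of `step / 2` — half-step granularity
#' accommodates intermediate levels within a 2-cmH2O protocol — and grouped
#' into contiguous runs. Runs up to and including the maximum-PEEP run belong
#' to the ascending arm; later runs to the descending arm. The per-level
#' summary is the median stiffness (robust to residual artifacts), and levels
#' with fewer than `min_breaths_per_level` contributing breaths are dropped.
#'
#' @param results A [analyze_breaths()] tibble in time order.
#' @param step Protocol PEEP step, cmH2O (default 2).
#' @param min_breaths_per_level Minimum breaths for a level to be retained
#'   (default 3).
#' @param calibration Optional [calibrate_peep()] result applied to the
#'   breaths' PEEPs (skip if `results` was already calibrated).
#' @return A `peep_ladder` tibble: `peep`, `arm` (`"ascending"` /
#'   `"descending"`), `n_breaths`, `stiffness` (cmH2O/L).
#' @export
build_peep_ladder <- function(results, step = 2, min_breaths_per_level = 3,
                              calibration = NULL) {
  if (step <= 0) abort("`step` must be a positive PEEP increment (cmH2O).")
  d <- tibble::as_tibble(results)
  d <- d[d$status == "accepted" & !is.na(d$peep) & !is.na(d$stiffness), , drop = FALSE]
  peep_cal <- apply_peep_calibration(d$peep, calibration)
  grid <- step / 2
  level <- round(peep_cal / grid) * grid
  if (length(unique(level)) < 2) {
    abort("A PEEP ladder needs breaths at >= 2 distinct PEEP levels; run a full recruitment manoeuvre.")
  }
  run_id <- cumsum(c(TRUE, diff(level) != 0))
  run_level <- level[!duplicated(run_id)]
  max_run <- which(run_level == max(run_level))[1]
  arm <- ifelse(run_id <= max_run, "ascending", "descending")
  ladder <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(peep = level, arm = arm, stiffness = d$stiffness),
      .data$peep, .data$arm
    ),
    n_breaths = dplyr::n(),
    stiffness = median(.data$stiffness),
    .groups = "drop"
  )
  ladder <- ladder[ladder$n_breaths >= min_breaths_per_level, , drop = FALSE]
  if (nrow(ladder) == 0) {
    abort("No PEEP level has enough breaths (`min_breaths_per_level`) to build a ladder.")
  }
  ladder <- dplyr::arrange(ladder, .data$arm, .data$peep)
  class(ladder) <- c("peep_ladder", class(ladder))
  attr(ladder, "step") <- step
  ladder
}

#' Recommend a PEEP from a recruitment-manoeuvre ladder
#'
#' PEEP titration runs on the decremental (descending) limb, after the
#' manoeuvre has recruited the lung: the minimal-stiffness descending level
#' is located (ties resolve toward the higher, recruitment-preserving PEEP)
#' and the recommendation is the descending-arm level one protocol step above
#' it, to maintain time-dependent alveolar recruitment while balancing
#' recruitment against overdistension. When the minimum sits at the highest
#' descending level the recommendation falls back to that level with a
#' boundary warning. The hysteresis area — trapezoidal area between the
#' ascending and descending stiffness curves over their common PEEP range,
#' positive when ascending lies above descending — quantifies how much the
#' manoeuvre recruited.
#'
#' @param ladder A [build_peep_ladder()] result.
#' @param step Protocol PEEP step (defaults to the ladder's).
#' @return An `rm_result`: `ladder`, `recommended_peep`,
#'   `minimal_stiffness_peep`, `hysteresis_area` (cmH2O, signed) and
#'   `warnings`. See [tidy.rm_result()] / [glance.rm_result()] /
#'   [autoplot.rm_result()].
#' @export
recommend_peep <- function(ladder, step = attr(ladder, "step") %||% 2) {
  desc <- ladder[ladder$arm == "descending", , drop = FALSE]
  if (nrow(desc) < 2) {
    abort(paste(
      "The descending arm has fewer than 2 PEEP levels;",
      "run a full recruitment manoeuvre (step-wise up, then back down) before titrating."
    ))
  }
  warnings <- character(0)
  min_stiff <- min(desc$stiffness)
  cand <- desc$peep[desc$stiffness == min_stiff]
  minimal_peep <- max(cand) # ties resolve toward higher PEEP
  above <- sort(desc$peep[desc$peep > minimal_peep])
  if (length(above) == 0) {
    recommended <- minimal_peep
    warnings <- c(warnings, "minimal-stiffness PEEP is the highest descending level; recommending it directly (boundary)")
  } else {
    recommended <- above[1]
    if (abs(recommended - (minimal_peep + step)) > 1e-9) {
      warnings <- c(warnings, sprintf(
        "no descending level at exactly one step (%.3g cmH2O) above the minimum; using the next level up (%.3g cmH2O)",
        step, recommended
      ))
    }
  }
  structure(
    list(
      ladder = ladder,
      recommended_peep = recommended,
      minimal_stiffness_peep = minimal_peep,
      hysteresis_area = hysteresis_area(ladder),
      warnings = warnings
    ),
    class = "rm_result"
  )
}

# signed trapezoidal area between the arms over their common PEEP range
hysteresis_area <- function(ladder) {
  asc <- ladder[ladder$arm == "ascending", , drop = FALSE]
  desc <- ladder[ladder$arm == "descending", , drop = FALSE]
  if (nrow(asc) < 2 || nrow(desc) < 2) return(NA_real_)
  lo <- max(min(asc$peep), min(desc$peep))
  hi <- min(max(asc$peep), max(desc$peep))
  if (hi <= lo) return(NA_real_)
  grid <- sort(unique(c(asc$peep, desc$peep)))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) return(NA_real_)
  a <- approx(asc$peep, asc$stiffness, xout = grid)$y
  d <- approx(desc$peep, desc$stiffness, xout = grid)$y
  pracma::trapz(grid, a - d)
}

#' @export
print.rm_result <- function(x, ...) {
  cat("<rm_result> recruitment-manoeuvre PEEP titration\n")
  cat(sprintf("  minimal-stiffness PEEP (descending arm): %.3g cmH2O\n",
              x$minimal_stiffness_peep))
  cat(sprintf("  recommended PEEP:                        %.3g cmH2O\n",
              x$recommended_peep))
  cat(sprintf("  hysteresis area (ascending - descending): %.4g cmH2O\n",
              x$hysteresis_area))
  cat("  decision: pending clinician accept/override\n")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for recruitment-manoeuvre results
#'
#' `tidy()` returns the per-(level, arm) ladder; `glance()` a one-row summary
#' with the recommendation, the minimal-stiffness PEEP, the hysteresis area
#' and the warning count.
#'
#' @param x An `rm_result` from [recommend_peep()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rm_result <- function(x, ...) {
  out <- tibble::as_tibble(x$ladder)
  class(out) <- setdiff(class(out), "peep_ladder")
  out
}

#' @rdname tidy.rm_result
#' @export
glance.rm_result <- function(x, ...) {
  tibble::tibble(
    recommended_peep = x$recommended_peep,
    minimal_stiffness_peep = x$minimal_stiffness_peep,
    hysteresis_area = x$hysteresis_area,
    n_levels = nrow(x$ladder),
    n_levels_descending = sum(x$ladder$arm == "descending"),
    n_warnings = length(x$warnings)
  )
}

#' Write the recruitment-manoeuvre report
#'
#' CSV ladder (`peep, arm, n_breaths, stiffness`) plus a JSON summary with
#' the recommended PEEP, minimal-stiffness PEEP, hysteresis area, warnings,
#' and an explicit `decision` field (`"pending"`) for the clinician's
#' accept/override confirmation.
#'
#' @param rm An `rm_result`.
#' @param ladder_file,summary_file Destination paths (either may be `NULL`).
#' @export
write_rm_report <- function(rm, ladder_file = NULL, summary_file = NULL) {
  if (!is.null(ladder_file)) readr::write_csv(tidy(rm), ladder_file)
  if (!is.null(summary_file)) {
    jsonlite::write_json(
      list(
        recommended_peep = rm$recommended_peep,
        minimal_stiffness_peep = rm$minimal_stiffness_peep,
        hysteresis_area = rm$hysteresis_area,
        warnings = rm$warnings,
        decision = "pending"
      ),
      summary_file,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(rm)
}
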