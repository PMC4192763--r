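#' Breath quarantine filter settings
#'
#' Thresholds for the four quarantine rules applied to every raw breath
#' segment before model fitting: a missing `"BS"`/`"BE"` marker, a sudden
#' pressure step, a sudden flow step, and a too-short cycle. The flow-step
#' threshold is interpreted in the stream's *native* flow unit (default
#' L/min), mirroring how the acquisition-side check sees the raw numbers.
#'
#' @param max_pressure_step Largest allowed consecutive-sample pressure
#'   difference, cmH2O (default 10).
#' @param max_flow_step Largest allowed consecutive-sample flow difference in
#'   the stream's native flow unit (default 10).
#' @param min_points Minimum number of samples for a cycle to be processed
#'   (default 5).
#' @return A `filter_config` object.
#' @export
filter_config <- function(max_pressure_step = 10, max_flow_step = 10,
                          min_points = 5) {
  for (nm in c("max_pressure_step", "max_flow_step", "min_points")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  structure(
    list(
      max_pressure_step = max_pressure_step,
      max_flow_step = max_flow_step,
      min_points = as.integer(min_points)
    ),
    class = "filter_config"
  )
}

quarantine_reasons <- c(
  "none", "no_markers", "pressure_jump", "flow_jump", "too_short",
  "no_flow_reversal", "parse_corrupt"
)

# 1-based index of the last inspiratory sample: the sample before the first
# strictly negative flow that follows a positive flow. Zeros do not end
# inspiration. NA when no positive-to-negative transition exists.
find_insp_end <- function(flow) {
  n <- length(flow)
  if (n < 2) return(NA_integer_)
  seen_pos <- c(0, cumsum(flow > 0)[-n]) > 0
  j <- which(flow < 0 & seen_pos)
  if (length(j) == 0) return(NA_integer_)
  j[1] - 1L
}

classify_segment <- function(samples, has_bs, has_be, corrupt, cfg, flow_scale) {
  if (!(has_bs && has_be)) return("no_markers")
  n <- nrow(samples)
  if (n >= 2) {
    if (max(abs(diff(samples$pressure))) > cfg$max_pressure_step) {
      return("pressure_jump")
    }
    if (max(abs(diff(samples$flow))) * flow_scale > cfg$max_flow_step) {
      return("flow_jump")
    }
  }
  if (n < cfg$min_points) return("too_short")
  if (corrupt) return("parse_corrupt")
  "none"
}

#' Segment raw breaths into inspiration/expiration and quarantine bad cycles
#'
#' Applies the quarantine rules of [filter_config()] to every raw segment in
#' the order: missing markers, pressure jump, flow jump, too short, parse
#' corruption (the reported `reason` is the first rule that fires). Surviving
#' breaths are split at the end of inspiration — the last sample before the
#' first point where flow changes from positive to negative (zero-flow
#' samples still count as inspiration) — and the per-breath PEEP is read off
#' the expiratory pressure tail. A breath with no positive-to-negative flow
#' transition is quarantined with reason `no_flow_reversal`.
#'
#' @param segments Segment tibble from [parse_stream()].
#' @param filter A [filter_config()].
#' @param tail_fraction Fraction of the expiratory samples whose median
#'   pressure defines the detected PEEP (default 0.2); see [detect_peep()].
#' @return The input tibble with columns `status` (`"accepted"` /
#'   `"quarantined"`), `reason`, `insp_end` (1-based index of the last
#'   inspiratory sample, NA when quarantined) and `peep` (cmH2O, NA when the
#'   expiration is too short to estimate it).
#' @export
segment_breaths <- function(segments, filter = filter_config(),
                            tail_fraction = 0.2) {
  meta <- segments_meta(segments)
  scale <- flow_native_scale(meta)
  n <- nrow(segments)
  reason <- character(n)
  insp_end <- rep(NA_integer_, n)
  peep <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- segments$samples[[i]]
    r <- classify_segment(
      s, segments$has_bs[i], segments$has_be[i], segments$corrupt[i],
      filter, scale
    )
    if (r == "none") {
      ie <- find_insp_end(s$flow)
      if (is.na(ie)) {
        r <- "no_flow_reversal"
      } else {
        insp_end[i] <- ie
        peep[i] <- detect_peep(s, ie, tail_fraction)
      }
    }
    reason[i] <- r
  }
  out <- segments
  out$status <- ifelse(reason == "none", "accepted", "quarantined")
  out$reason <- reason
  out$insp_end <- insp_end
  out$peep <- peep
  attr(out, "stream_meta") <- meta
  out
}

#' Detect the per-breath PEEP from the expiratory pressure tail
#'
#' Returns the median airway pressure over the final `tail_fraction` of the
#' expiratory samples — a robust estimate of the end-expiratory pressure that
#' ignores the expiratory-flow transient. Requires at least 3 expiratory
#' samples; otherwise NA (the breath stays accepted but is excluded from
#' PEEP-indexed analyses).
#'
#' @param samples Tibble of one breath's samples (`t`, `flow`, `pressure`).
#' @param insp_end 1-based index of the last inspiratory sample.
#' @param tail_fraction Fraction of expiration to use (default 0.2).
#' @return PEEP in cmH2O, or NA.
#' @export
detect_peep <- function(samples, insp_end, tail_fraction = 0.2) {
  n <- nrow(samples)
  n_exp <- n - insp_end
  if (is.na(insp_end) || n_exp < 3) return(NA_real_)
  n_tail <- max(1L, ceiling(tail_fraction * n_exp))
  median(samples$pressure[(n - n_tail + 1L):n])
}
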