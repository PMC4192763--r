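#' Describe a waveform stream
#'
#' Captures the acquisition metadata needed to interpret a breath-delimited
#' waveform stream: the sampling interval, the unit in which flow values were
#' written, and the (informational) serial baud rate of the source device.
#' Flow is always converted to L/s internally; pressure is cmH2O throughout.
#'
#' The capture dialect is line-oriented text: a line equal to `"BS"` marks the
#' start of a breath and `"BE"` its end; every other non-blank line is a data
#' sample `"<flow><sep><pressure>"` with a comma or whitespace separator; lines
#' beginning `#` are comments. Sample times carry no clock in the stream and
#' are synthesised as cumulative multiples of `sample_interval`.
#'
#' @param sample_interval Seconds between successive samples (default 0.02,
#'   i.e. 50 Hz).
#' @param flow_units_in Unit of the flow field in the stream: `"L/min"`
#'   (common ventilator output, the default) or `"L/s"`.
#' @param pressure_units_in Pressure unit; only `"cmH2O"` is supported.
#' @param declared_baud Informational serial baud rate recorded with the
#'   capture; not used in parsing.
#' @return A `stream_meta` object (a named list).
#' @examples
#' stream_meta()
#' stream_meta(sample_interval = 0.01, flow_units_in = "L/s")
#' @export
stream_meta <- function(sample_interval = 0.02,
                        flow_units_in = c("L/min", "L/s"),
                        pressure_units_in = "cmH2O",
                        declared_baud = 38400L) {
  flow_units_in <- match.arg(flow_units_in)
  pressure_units_in <- match.arg(pressure_units_in)
  if (!is.numeric(sample_interval) || length(sample_interval) != 1 ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    abort("`sample_interval` must be a single positive number (seconds).")
  }
  structure(
    list(
      sample_interval = as.numeric(sample_interval),
      flow_units_in = flow_units_in,
      pressure_units_in = pressure_units_in,
      declared_baud = as.integer(declared_baud)
    ),
    class = "stream_meta"
  )
}

#' @export
print.stream_meta <- function(x, ...) {
  cat(sprintf(
    "<stream_meta> %.4g s/sample (%.6g Hz), flow in %s, pressure in %s, baud %d\n",
    x$sample_interval, 1 / x$sample_interval, x$flow_units_in,
    x$pressure_units_in, x$declared_baud
  ))
  invisible(x)
}

# multiplier taking internal L/s back to the stream's native flow unit
flow_native_scale <- function(meta) {
  if (meta$flow_units_in == "L/min") 60 else 1
}

segments_meta <- function(segments) {
  attr(segments, "stream_meta") %||% stream_meta()
}

new_segment_tibble <- function(has_bs, has_be, corrupt, samples, meta) {
  out <- tibble::tibble(
    breath_index = seq_along(samples),
    has_bs = as.logical(has_bs),
    has_be = as.logical(has_be),
    corrupt = as.logical(corrupt),
    n_samples = vapply(samples, nrow, integer(1)),
    samples = samples
  )
  attr(out, "stream_meta") <- meta
  out
}

#' Parse a breath-delimited waveform stream
#'
#' Splits a character stream in the capture dialect (see [stream_meta()]) into
#' raw breath segments. Every maximal span between a `"BS"` marker and the
#' next `"BE"` becomes one complete segment; samples before the first `"BS"`,
#' or after a trailing `"BS"` with no closing `"BE"`, become segments with the
#' corresponding marker flag `FALSE` so that truncated data are never silently
#' dropped. A malformed data line (non-numeric or non-finite field) marks the
#' enclosing segment `corrupt` and the offending sample is omitted.
#'
#' Flow values are converted to L/s according to `meta$flow_units_in`, and
#' sample times are cumulative multiples of `meta$sample_interval` counted
#' over all data lines in the stream (the first sample is at t = 0).
#'
#' @param x The stream: a single string (possibly containing newlines) or a
#'   character vector of lines.
#' @param meta A [stream_meta()] object.
#' @return A tibble with one row per segment: `breath_index`, `has_bs`,
#'   `has_be`, `corrupt`, `n_samples`, and a `samples` list-column of tibbles
#'   with columns `t` (s), `flow` (L/s) and `pressure` (cmH2O). The stream
#'   metadata ride along as the `"stream_meta"` attribute.
#' @seealso [stream_parser()] for incremental (chunk-fed) parsing,
#'   [read_capture()] to parse a file, [write_capture()] for the inverse.
#' @examples
#' txt <- c("BS", "30, 8.1", "20, 9.0", "-10, 6.2", "BE")
#' parse_stream(txt)
#' @export
parse_stream <- function(x, meta = stream_meta()) {
  lines <- split_stream_lines(x)
  ln <- trimws(lines)
  is_blank <- ln == ""
  is_comment <- startsWith(ln, "#")
  is_bs <- ln == "BS"
  is_be <- ln == "BE"
  is_data <- !(is_blank | is_comment | is_bs | is_be)

  data_pos <- which(is_data)
  n_data <- length(data_pos)
  flow <- pressure <- numeric(n_data)
  bad <- logical(n_data)
  if (n_data > 0) {
    fields <- strsplit(gsub(",", " ", ln[data_pos], fixed = TRUE), "[[:space:]]+")
    nf <- lengths(fields)
    two <- nf == 2L
    bad[!two] <- TRUE
    if (any(two)) {
      fm <- matrix(unlist(fields[two], use.names = FALSE), nrow = 2L)
      f <- suppressWarnings(as.numeric(fm[1L, ]))
      p <- suppressWarnings(as.numeric(fm[2L, ]))
      ok <- is.finite(f) & is.finite(p)
      bad[two][!ok] <- TRUE
      flow[two] <- f
      pressure[two] <- p
    }
  }
  flow <- flow / flow_native_scale(meta)
  t <- (seq_len(n_data) - 1) * meta$sample_interval

  # walk the markers to delimit segments
  marker_pos <- which(is_bs | is_be)
  segs <- list()
  seg_bs <- logical(0)
  seg_be <- logical(0)
  seg_bad <- logical(0)
  cur_start <- 1L
  cur_has_bs <- FALSE
  emit <- function(from, to, has_bs, has_be) {
    lo <- findInterval(from - 1L, data_pos) + 1L
    hi <- findInterval(to, data_pos)
    rows <- if (hi >= lo) lo:hi else integer(0)
    if (!has_bs && length(rows) == 0) return(invisible())
    keep <- rows[!bad[rows]]
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      t = t[keep], flow = flow[keep], pressure = pressure[keep]
    )
    seg_bs[length(segs)] <<- has_bs
    seg_be[length(segs)] <<- has_be
    seg_bad[length(segs)] <<- any(bad[rows])
  }
  for (m in marker_pos) {
    if (is_bs[m]) {
      emit(cur_start, m - 1L, cur_has_bs, FALSE)
      cur_has_bs <- TRUE
    } else {
      emit(cur_start, m - 1L, cur_has_bs, TRUE)
      cur_has_bs <- FALSE
    }
    cur_start <- m + 1L
  }
  emit(cur_start, length(ln), cur_has_bs, FALSE)

  new_segment_tibble(seg_bs, seg_be, seg_bad, segs, meta)
}

split_stream_lines <- function(x) {
  if (!is.character(x)) abort("The stream must be character data.")
  if (length(x) == 0) return(character(0))
  if (length(x) == 1 && grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
}

#' Incremental (online) stream parser
#'
#' Returns a parser object that can be fed a character stream in arbitrary
#' chunks — including chunks that split a line or a `"BS"`/`"BE"` marker —
#' and yields exactly the segments [parse_stream()] would produce on the
#' concatenated whole. This is the "online" acquisition path: feed whatever
#' the serial line (or a growing file) delivers, poll for completed breaths,
#' and call `$finish()` when the source disconnects.
#'
#' @param meta A [stream_meta()] object.
#' @return A list with functions:
#' \describe{
#'   \item{`feed(chars)`}{Append a chunk (character scalar) to the stream.}
#'   \item{`poll()`}{Tibble of segments completed so far (same shape as
#'     [parse_stream()]).}
#'   \item{`finish()`}{Flush the tail (an unterminated final line / open
#'     breath) and return all segments.}
#' }
#' @examples
#' p <- stream_parser()
#' p$feed("BS\n30, 8")
#' p$feed(".5\n-20, 6\nB")
#' p$feed("E\n")
#' p$finish()
#' @export
stream_parser <- function(meta = stream_meta()) {
  remainder <- ""
  tick <- 0L
  cur <- list(t = list(), flow = list(), pressure = list())
  cur_has_bs <- FALSE
  cur_corrupt <- FALSE
  cur_n_any <- 0L # samples incl. malformed ones
  segs <- list()
  seg_bs <- logical(0)
  seg_be <- logical(0)
  seg_bad <- logical(0)
  scale <- flow_native_scale(meta)
  dt <- meta$sample_interval

  reset_cur <- function(has_bs) {
    cur <<- list(t = list(), flow = list(), pressure = list())
    cur_has_bs <<- has_bs
    cur_corrupt <<- FALSE
    cur_n_any <<- 0L
  }
  close_cur <- function(has_be) {
    if (!cur_has_bs && cur_n_any == 0L) return(invisible())
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      t = unlist(cur$t) %||% numeric(0),
      flow = unlist(cur$flow) %||% numeric(0),
      pressure = unlist(cur$pressure) %||% numeric(0)
    )
    seg_bs[length(segs)] <<- cur_has_bs
    seg_be[length(segs)] <<- has_be
    seg_bad[length(segs)] <<- cur_corrupt
  }
  take_line <- function(line) {
    line <- trimws(line)
    if (line == "" || startsWith(line, "#")) return(invisible())
    if (line == "BS") {
      close_cur(FALSE)
      reset_cur(TRUE)
      return(invisible())
    }
    if (line == "BE") {
      close_cur(TRUE)
      reset_cur(FALSE)
      return(invisible())
    }
    fields <- strsplit(gsub(",", " ", line, fixed = TRUE), "[[:space:]]+")[[1]]
    cur_n_any <<- cur_n_any + 1L
    t_here <- tick * dt
    tick <<- tick + 1L
    if (length(fields) != 2L) {
      cur_corrupt <<- TRUE
      return(invisible())
    }
    f <- suppressWarnings(as.numeric(fields[1L]))
    p <- suppressWarnings(as.numeric(fields[2L]))
    if (!is.finite(f) || !is.finite(p)) {
      cur_corrupt <<- TRUE
      return(invisible())
    }
    k <- length(cur$t) + 1L
    cur$t[[k]] <<- t_here
    cur$flow[[k]] <<- f / scale
    cur$pressure[[k]] <<- p
  }
  feed <- function(chars) {
    stopifnot(is.character(chars), length(chars) == 1)
    buf <- paste0(remainder, chars)
    parts <- strsplit(buf, "\n", fixed = TRUE)[[1]]
    if (length(parts) == 0) parts <- ""
    ends_nl <- endsWith(buf, "\n")
    remainder <<- if (ends_nl) "" else parts[length(parts)]
    complete <- if (ends_nl) parts else parts[-length(parts)]
    for (line in complete) take_line(line)
    invisible(NULL)
  }
  poll <- function() {
    new_segment_tibble(seg_bs, seg_be, seg_bad, segs, meta)
  }
  finish <- function() {
    if (remainder != "") {
      line <- remainder
      remainder <<- ""
      take_line(line)
    }
    close_cur(FALSE)
    reset_cur(FALSE)
    poll()
  }
  list(feed = feed, poll = poll, finish = finish)
}

#' Read a waveform capture file
#'
#' @param file Path to a capture file in the dialect of [stream_meta()].
#' @param meta A [stream_meta()] object.
#' @return See [parse_stream()].
#' @export
read_capture <- function(file, meta = stream_meta()) {
  if (!file.exists(file)) abort(sprintf("Capture file not found: '%s'", file))
  parse_stream(readLines(file, warn = FALSE), meta)
}

#' Write segments back to the capture dialect
#'
#' The inverse of [parse_stream()]: emits `"BS"`/`"BE"` markers around each
#' segment's data lines, with flow converted back to the stream's native unit.
#' Values are written with 6 significant digits, so a parse -> write -> parse
#' round trip is lossless at that precision.
#'
#' @param segments A segment tibble from [parse_stream()] or the simulator.
#' @param file Optional path; when `NULL` the text is returned only.
#' @param meta Stream metadata; defaults to the metadata attached to
#'   `segments`.
#' @return The capture text, invisibly when `file` is given.
#' @export
write_capture <- function(segments, file = NULL, meta = segments_meta(segments)) {
  scale <- flow_native_scale(meta)
  blocks <- purrr::pmap(
    list(segments$samples, segments$has_bs, segments$has_be),
    function(s, bs, be) {
      c(
        if (bs) "BS",
        sprintf("%.6g,%.6g", s$flow * scale, s$pressure),
        if (be) "BE"
      )
    }
  )
  text <- paste(unlist(blocks), collapse = "\n")
  if (!is.null(file)) {
    con <- tryCatch(file(file, open = "wt"),
      error = function(e) abort(sprintf("Cannot open '%s' for writing: %s", file, conditionMessage(e)))
    )
    on.exit(close(con))
    writeLines(text, con)
    return(invisible(text))
  }
  text
}

breath_table_columns <- c(
  "breath_index", "t_start_s", "status", "reason",
  "Ers_cmH2O_per_L", "Rrs_cmH2Os_per_L", "P0_cmH2O",
  "stiffness_cmH2O_per_L", "peep_cmH2O"
)

#' Write / read the per-breath result table
#'
#' One row per breath cycle (accepted and quarantined alike) with the fixed
#' header `breath_index, t_start_s, status, reason, Ers_cmH2O_per_L,
#' Rrs_cmH2Os_per_L, P0_cmH2O, stiffness_cmH2O_per_L, peep_cmH2O`.
#' Quarantined breaths keep their row, with empty mechanics fields and the
#' reason code, so nothing is silently dropped. Numeric fields are written
#' with 6 significant digits and round-trip losslessly at that precision.
#'
#' @param results A mechanics tibble from [analyze_breaths()].
#' @param file Destination path (CSV). [write_breath_jsonl()] writes the
#'   JSON-lines twin with identical fields.
#' @return `file`, invisibly.
#' @export
write_breath_table <- function(results, file) {
  tab <- as_breath_table(results)
  tryCatch(
    readr::write_csv(tab, file, na = ""),
    error = function(e) abort(sprintf("Cannot write breath table to '%s': %s", file, conditionMessage(e)))
  )
  invisible(file)
}

as_breath_table <- function(results) {
  tab <- tibble::tibble(
    breath_index = results$breath_index,
    t_start_s = signif(results$t_start, 6),
    status = results$status,
    reason = results$reason,
    Ers_cmH2O_per_L = signif(results$ers, 6),
    Rrs_cmH2Os_per_L = signif(results$rrs, 6),
    P0_cmH2O = signif(results$p0, 6),
    stiffness_cmH2O_per_L = signif(results$stiffness, 6),
    peep_cmH2O = signif(results$peep, 6)
  )
  tab
}

#' @rdname write_breath_table
#' @export
read_breath_table <- function(file) {
  readr::read_csv(
    file,
    col_types = readr::cols(
      breath_index = readr::col_integer(),
      t_start_s = readr::col_double(),
      status = readr::col_character(),
      reason = readr::col_character(),
      Ers_cmH2O_per_L = readr::col_double(),
      Rrs_cmH2Os_per_L = readr::col_double(),
      P0_cmH2O = readr::col_double(),
      stiffness_cmH2O_per_L = readr::col_double(),
      peep_cmH2O = readr::col_double()
    ),
    na = c("", "NA")
  )
}

#' @rdname write_breath_table
#' @export
write_breath_jsonl <- function(results, file) {
  tab <- as_breath_table(results)
  lines <- vapply(
    seq_len(nrow(tab)),
    function(i) jsonlite::toJSON(as.list(tab[i, ]), auto_unbox = TRUE, na = "null", digits = NA),
    character(1)
  )
  writeLines(lines, file)
  invisible(file)
}

#' Export per-breath time-varying elastance curves
#'
#' Long-format CSV (`breath_index, tau, Edrs_cmH2O_per_L`) of the retained
#' Edrs samples of every accepted breath, for external plotting.
#'
#' @param results A mechanics tibble from [analyze_breaths()].
#' @param file Destination path.
#' @export
write_edrs_curves <- function(results, file) {
  curves <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(results), "breath_index", "edrs"),
    "edrs"
  )
  curves <- dplyr::rename(curves, Edrs_cmH2O_per_L = "edrs")
  curves <- dplyr::mutate(curves, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_csv(curves, file, na = "")
  invisible(file)
}
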