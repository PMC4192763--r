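#' Synthetic lung ground truth
#'
#' Parameters of the single-compartment test lung used to generate waveform
#' streams. Elastance follows a U-shaped law in PEEP,
#' `Ers(PEEP) = ers_base + curvature * (PEEP - peep_opt)^2`, optionally scaled
#' by `recruit_factor` on the descending arm of a recruitment manoeuvre
#' (values < 1 emulate recruitment: a softer lung on the way back down, which
#' is what produces stiffness-PEEP hysteresis). Spontaneous effort is a
#' half-sine pressure dip of amplitude `effort_amp` subtracted from the
#' inspiratory airway pressure with per-breath probability `effort_prob`
#' (under volume control the flow trajectory stays ventilator-imposed).
#' Gaussian noise of SD `noise_sd` is added to every pressure sample.
#'
#' Defaults describe a passive, moderately stiff ARDS-like adult lung:
#' Ers 25 cmH2O/L, Rrs 8 cmH2O.s/L, optimum PEEP 16 cmH2O, curvature
#' 0.15 cmH2O/L per (cmH2O)^2, pressure noise 0.2 cmH2O.
#'
#' @param ers_base Baseline elastance at the optimum PEEP, cmH2O/L.
#' @param rrs Airway resistance, cmH2O.s/L.
#' @param peep_opt PEEP of minimal elastance, cmH2O.
#' @param curvature Quadratic coefficient of the Ers(PEEP) law.
#' @param recruit_factor Descending-arm elastance multiplier in (0, 1].
#' @param noise_sd Pressure noise SD, cmH2O.
#' @param effort_prob Per-breath probability of a spontaneous effort.
#' @param effort_amp Effort dip amplitude, cmH2O.
#' @param seed Integer RNG seed used by the simulation entry points; `NULL`
#'   to use the current RNG state.
#' @return A `lung_config` object.
#' @export
lung_config <- function(ers_base = 25, rrs = 8, peep_opt = 16, curvature = 0.15,
                        recruit_factor = 1, noise_sd = 0.2,
                        effort_prob = 0, effort_amp = 5, seed = NULL) {
  if (ers_base <= 0 || rrs <= 0) abort("`ers_base` and `rrs` must be positive.")
  if (recruit_factor <= 0 || recruit_factor > 1) {
    abort("`recruit_factor` must be in (0, 1].")
  }
  if (effort_prob < 0 || effort_prob > 1) abort("`effort_prob` must be in [0, 1].")
  if (noise_sd < 0 || curvature < 0) abort("`noise_sd` and `curvature` must be non-negative.")
  structure(
    list(
      ers_base = ers_base, rrs = rrs, peep_opt = peep_opt,
      curvature = curvature, recruit_factor = recruit_factor,
      noise_sd = noise_sd, effort_prob = effort_prob, effort_amp = effort_amp,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "lung_config"
  )
}

#' Ventilator settings for the simulator
#'
#' Volume-control settings. Defaults: tidal volume 0.5 L (6-8 mL/kg for a
#' ~70 kg adult), inspiratory time 1 s, 15 breaths/min, descending-ramp
#' inspiratory flow (the profile of the volume-control mode modelled here).
#'
#' @param tidal_volume Delivered volume per breath, litres.
#' @param t_insp Inspiratory time, seconds; must be shorter than the breath
#'   period `60 / resp_rate`.
#' @param resp_rate Respiratory rate, breaths/min.
#' @param peep_set Set PEEP, cmH2O.
#' @param flow_shape `"ramp_descending"` (peak flow `2 VT / t_insp` decaying
#'   linearly to zero) or `"square"` (constant `VT / t_insp`).
#' @return A `vent_settings` object.
#' @export
vent_settings <- function(tidal_volume = 0.5, t_insp = 1, resp_rate = 15,
                          peep_set = 10,
                          flow_shape = c("ramp_descending", "square")) {
  flow_shape <- match.arg(flow_shape)
  if (tidal_volume <= 0) abort("`tidal_volume` must be positive (litres).")
  if (resp_rate <= 0) abort("`resp_rate` must be positive (breaths/min).")
  if (t_insp <= 0 || t_insp >= 60 / resp_rate) {
    abort("`t_insp` must be positive and shorter than the breath period 60/resp_rate.")
  }
  structure(
    list(
      tidal_volume = tidal_volume, t_insp = t_insp, resp_rate = resp_rate,
      peep_set = peep_set, flow_shape = flow_shape
    ),
    class = "vent_settings"
  )
}

effective_elastance <- function(lung, peep, arm = "ascending") {
  ers <- lung$ers_base + lung$curvature * (peep - lung$peep_opt)^2
  if (identical(arm, "descending")) ers <- ers * lung$recruit_factor
  ers
}

# exhalation-valve opening transient: the passive decay (time constant
# Rrs/Ers) is modulated by a rise factor (1 - exp(-t/tau_open)) so pressure
# and flow leave end-inspiration smoothly instead of stepping, as a real
# valve does. Closed form below is the exact solution of
# dV/dt = -(V / tau) * (1 - exp(-t / tau_open)).
VALVE_OPEN_TC <- 0.4

sim_breath_core <- function(lung, vent, arm, dt, t0, effort) {
  ers <- effective_elastance(lung, vent$peep_set, arm)
  vt <- vent$tidal_volume
  ti_dur <- vent$t_insp
  n_i <- max(2L, round(ti_dur / dt))
  ti <- (0:n_i) * dt
  if (vent$flow_shape == "ramp_descending") {
    q_peak <- 2 * vt / ti_dur
    qi <- q_peak * (1 - ti / ti_dur)
    vi <- q_peak * (ti - ti^2 / (2 * ti_dur))
  } else {
    qi <- rep(vt / ti_dur, n_i + 1L)
    vi <- qi * ti
  }
  tau <- lung$rrs / ers
  # expiratory samples fill the rest of the breath period, ending one tick
  # before the next breath starts so consecutive breaths tile the timeline
  te_dur <- 60 / vent$resp_rate - ti_dur
  n_e <- max(3L, round(te_dur / dt) - 1L)
  te <- (1:n_e) * dt
  s_int <- te - VALVE_OPEN_TC * (1 - exp(-te / VALVE_OPEN_TC))
  ve <- vt * exp(-s_int / tau)
  qe <- -(ve / tau) * (1 - exp(-te / VALVE_OPEN_TC))
  q <- c(qi, qe)
  v <- c(vi, ve)
  p <- ers * v + lung$rrs * q + vent$peep_set
  has_effort <- if (is.null(effort)) runif(1) < lung$effort_prob else isTRUE(effort)
  if (has_effort) {
    w0 <- 0.2 * ti_dur
    w <- 0.6 * ti_dur
    in_dip <- ti >= w0 & ti <= w0 + w
    pmus <- numeric(n_i + 1L)
    pmus[in_dip] <- lung$effort_amp * sin(pi * (ti[in_dip] - w0) / w)
    p[seq_len(n_i + 1L)] <- p[seq_len(n_i + 1L)] - pmus
  }
  if (lung$noise_sd > 0) p <- p + rnorm(length(p), 0, lung$noise_sd)
  list(
    samples = tibble::new_tibble(
      list(t = t0 + c(ti, ti_dur + te), flow = q, pressure = p),
      nrow = length(q)
    ),
    truth = tibble::new_tibble(
      list(peep_set = vent$peep_set, arm = arm, ers_true = ers,
           rrs_true = lung$rrs, effort = has_effort),
      nrow = 1L
    )
  )
}

#' Simulate a single ventilator breath
#'
#' Forward-simulates one volume-control breath of the single-compartment
#' lung: the inspiratory flow profile of [vent_settings()], analytic inspired
#' volume, airway pressure `Ers_eff V + Rrs Q + PEEP - Pmus + noise`, and a
#' passive expiration (decay time constant `Rrs/Ers`) with a short
#' exhalation-valve opening transient so pressure and flow stay
#' sample-to-sample continuous.
#'
#' @param lung A [lung_config()].
#' @param vent A [vent_settings()].
#' @param arm `"ascending"` or `"descending"` (selects the recruit-factor).
#' @param dt Sample interval, s (default 0.02).
#' @param t0 Time of the first sample, s.
#' @param effort Force the spontaneous-effort artifact on (`TRUE`) or off
#'   (`FALSE`); `NULL` draws it with probability `lung$effort_prob`.
#' @param seed RNG seed (defaults to `lung$seed`); `NULL` leaves the RNG
#'   state alone.
#' @return A list with `samples` (tibble `t`, `flow` L/s, `pressure` cmH2O)
#'   and `truth` (one-row tibble: `peep_set`, `arm`, `ers_true`, `rrs_true`,
#'   `effort`).
#' @export
simulate_breath <- function(lung, vent, arm = "ascending", dt = 0.02, t0 = 0,
                            effort = NULL, seed = lung$seed) {
  if (!is.null(seed)) set.seed(seed)
  sim_breath_core(lung, vent, arm, dt, t0, effort)
}

sim_to_segments <- function(sample_list, meta) {
  new_segment_tibble(
    has_bs = rep(TRUE, length(sample_list)),
    has_be = rep(TRUE, length(sample_list)),
    corrupt = rep(FALSE, length(sample_list)),
    samples = sample_list,
    meta = meta
  )
}

#' Simulate a constant-PEEP ventilation session
#'
#' Generates `n_breaths` consecutive breaths at fixed settings and renders
#' them as dialect-conformant capture text. Identical seed and configuration
#' give byte-identical text.
#'
#' @inheritParams simulate_breath
#' @param n_breaths Number of breaths.
#' @return A list: `text` (capture stream), `truth` (per-breath ground-truth
#'   tibble with `breath_index`), `segments` (the parsed-equivalent segment
#'   tibble), `meta`.
#' @export
simulate_session <- function(lung, vent, n_breaths, dt = 0.02,
                             seed = lung$seed) {
  if (n_breaths < 1) abort("`n_breaths` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  meta <- stream_meta(sample_interval = dt)
  period <- 60 / vent$resp_rate
  sims <- purrr::map(seq_len(n_breaths), function(i) {
    sim_breath_core(lung, vent, "ascending", dt, (i - 1) * period, NULL)
  })
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  truth <- dplyr::mutate(truth, breath_index = dplyr::row_number(), .before = 1)
  segments <- sim_to_segments(purrr::map(sims, "samples"), meta)
  list(
    text = write_capture(segments, meta = meta),
    truth = truth, segments = segments, meta = meta
  )
}

#' Peak inspiratory airway pressure predicted for given settings
#'
#' Noiseless, effort-free forward evaluation of the peak airway pressure of
#' one breath — used by the protocol builder to stop the ascending limb.
#'
#' @inheritParams simulate_breath
#' @param peep PEEP level to evaluate at, cmH2O.
#' @return Peak pressure, cmH2O.
#' @export
peak_airway_pressure <- function(lung, vent, peep, arm = "ascending",
                                 dt = 0.02) {
  v2 <- vent
  v2$peep_set <- peep
  quiet <- lung
  quiet$noise_sd <- 0
  sim <- sim_breath_core(quiet, v2, arm, dt, 0, FALSE)
  max(sim$samples$pressure)
}

#' Build a step-wise recruitment-manoeuvre PEEP protocol
#'
#' Ascends from `peep_start` in `step` increments for as long as the
#' predicted peak airway pressure stays at or below `max_peak_paw`
#' (default 55 cmH2O), then mirrors back down to the starting PEEP.
#'
#' @inheritParams peak_airway_pressure
#' @param peep_start Starting (and final) PEEP, cmH2O.
#' @param step PEEP increment, cmH2O (default 2).
#' @param max_peak_paw Peak-pressure ceiling ending the ascent, cmH2O.
#' @return Numeric vector of PEEP levels, ascending then descending.
#' @export
rm_protocol <- function(lung, vent, peep_start = 14, step = 2,
                        max_peak_paw = 55, dt = 0.02) {
  asc <- numeric(0)
  p <- peep_start
  while (peak_airway_pressure(lung, vent, p, "ascending", dt) <= max_peak_paw) {
    asc <- c(asc, p)
    p <- p + step
    if (length(asc) > 50) abort("Protocol builder exceeded 50 ascending levels; check the configuration.")
  }
  if (length(asc) < 2) {
    abort("Peak airway pressure exceeds the ceiling already at the starting PEEP; no protocol possible.")
  }
  c(asc, rev(asc)[-1])
}

#' Simulate a full recruitment-manoeuvre session
#'
#' Runs the lung through a step-wise PEEP protocol (ascending to the maximum
#' level, then descending; the maximum level belongs to the ascending arm)
#' with `breaths_per_level` breaths at each level, and emits the capture
#' stream plus the per-breath ground-truth table.
#'
#' @inheritParams simulate_session
#' @param protocol Numeric vector of PEEP levels in manoeuvre order; `NULL`
#'   builds the default protocol with [rm_protocol()].
#' @param breaths_per_level Breaths to hold at each level (default 10).
#' @param peep_start,step,max_peak_paw Passed to [rm_protocol()] when
#'   `protocol` is `NULL`.
#' @return As [simulate_session()]; `truth` additionally carries `arm` per
#'   breath and the attribute `"protocol"`.
#' @export
simulate_rm_session <- function(lung, vent, protocol = NULL,
                                breaths_per_level = 10, dt = 0.02,
                                peep_start = 14, step = 2, max_peak_paw = 55,
                                seed = lung$seed) {
  if (is.null(protocol)) {
    protocol <- rm_protocol(lung, vent, peep_start, step, max_peak_paw, dt)
  }
  if (length(protocol) == 0 || breaths_per_level < 1) {
    abort("Empty protocol: need >= 1 PEEP level and `breaths_per_level` >= 1.")
  }
  i_max <- which(protocol == max(protocol))[1]
  arms <- ifelse(seq_along(protocol) <= i_max, "ascending", "descending")
  peaks <- vapply(
    seq_along(protocol),
    function(i) peak_airway_pressure(lung, vent, protocol[i], arms[i], dt),
    numeric(1)
  )
  if (any(peaks > 80)) {
    abort(sprintf(
      "Refusing to simulate: predicted peak airway pressure %.3g cmH2O exceeds 80 cmH2O (non-physiological protocol).",
      max(peaks)
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  meta <- stream_meta(sample_interval = dt)
  period <- 60 / vent$resp_rate
  sims <- vector("list", length(protocol) * breaths_per_level)
  k <- 0L
  for (i in seq_along(protocol)) {
    v2 <- vent
    v2$peep_set <- protocol[i]
    for (b in seq_len(breaths_per_level)) {
      k <- k + 1L
      sims[[k]] <- sim_breath_core(lung, v2, arms[i], dt, (k - 1L) * period, NULL)
    }
  }
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  truth <- dplyr::mutate(truth, breath_index = dplyr::row_number(), .before = 1)
  attr(truth, "protocol") <- protocol
  segments <- sim_to_segments(purrr::map(sims, "samples"), meta)
  list(
    text = write_capture(segments, meta = meta),
    truth = truth, segments = segments, meta = meta
  )
}

#' Write the simulator's ground-truth table
#'
#' CSV with columns `breath_index, peep_set, arm, Ers_true, Rrs_true,
#' effort_flag`.
#'
#' @param truth Ground-truth tibble from a simulate function.
#' @param file Destination path.
#' @export
write_ground_truth <- function(truth, file) {
  out <- tibble::tibble(
    breath_index = truth$breath_index,
    peep_set = truth$peep_set,
    arm = truth$arm,
    Ers_true = truth$ers_true,
    Rrs_true = truth$rrs_true,
    effort_flag = truth$effort
  )
  readr::write_csv(out, file)
  invisible(file)
}

corruption_kinds <- c("drop_be", "pressure_spike", "flow_spike", "truncate_short")

#' Inject stream corruptions targeting the quarantine filters
#'
#' Corrupts chosen breaths of a capture stream so that exactly one quarantine
#' rule fires per corrupted breath, and returns the injection log mapping
#' each breath to its expected reason code:
#' \describe{
#'   \item{`drop_be`}{delete the breath's `"BE"` marker -> `no_markers`}
#'   \item{`pressure_spike`}{add `spike` cmH2O to one mid-breath pressure
#'     sample -> `pressure_jump`}
#'   \item{`flow_spike`}{add `spike` native flow units to one mid-breath flow
#'     sample -> `flow_jump`}
#'   \item{`truncate_short`}{keep only the first 4 data lines ->
#'     `too_short`}
#' }
#'
#' @param text Capture text (as produced by the simulate functions).
#' @param spec Data frame with columns `breath_index` and `corruption`.
#' @param spike Spike amplitude (default 12: just beyond the +/-10 default
#'   thresholds).
#' @return List: `text` (corrupted stream) and `log` (tibble `breath_index`,
#'   `corruption`, `expected_reason`).
#' @export
corrupt_stream <- function(text, spec, spike = 12) {
  stopifnot(all(c("breath_index", "corruption") %in% names(spec)))
  bad_kind <- setdiff(unique(spec$corruption), corruption_kinds)
  if (length(bad_kind) > 0) {
    abort(sprintf("Unknown corruption kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  lines <- split_stream_lines(text)
  ln <- trimws(lines)
  spec <- spec[order(-spec$breath_index), , drop = FALSE]
  n_breaths <- sum(ln == "BS")
  if (any(spec$breath_index < 1 | spec$breath_index > n_breaths)) {
    abort("`breath_index` out of range for this stream.")
  }
  # process in decreasing breath order so deletions never shift the
  # positions of breaths still to be corrupted
  for (i in seq_len(nrow(spec))) {
    k <- spec$breath_index[i]
    kind <- spec$corruption[i]
    bs_pos <- which(ln == "BS")
    be_pos <- which(ln == "BE")
    start <- bs_pos[k]
    end <- be_pos[be_pos > start][1]
    block <- (start + 1L):(end - 1L)
    data_idx <- block[!(ln[block] == "" | startsWith(ln[block], "#"))]
    if (kind == "drop_be") {
      lines <- lines[-end]
      ln <- ln[-end]
    } else if (kind == "truncate_short") {
      drop <- data_idx[-seq_len(4L)]
      if (length(drop) > 0) {
        lines <- lines[-drop]
        ln <- ln[-drop]
      }
    } else {
      j <- data_idx[ceiling(length(data_idx) / 2)]
      f <- as.numeric(strsplit(gsub(",", " ", ln[j], fixed = TRUE), "[[:space:]]+")[[1]])
      if (kind == "pressure_spike") f[2] <- f[2] + spike else f[1] <- f[1] + spike
      lines[j] <- sprintf("%.6g,%.6g", f[1], f[2])
      ln[j] <- lines[j]
    }
  }
  reasons <- c(
    drop_be = "no_markers", pressure_spike = "pressure_jump",
    flow_spike = "flow_jump", truncate_short = "too_short"
  )
  log <- tibble::tibble(
    breath_index = rev(spec$breath_index),
    corruption = rev(spec$corruption),
    expected_reason = unname(reasons[rev(spec$corruption)])
  )
  list(text = paste(lines, collapse = "\n"), log = log)
}
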