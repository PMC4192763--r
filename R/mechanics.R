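#' Inspired volume by trapezoidal integration of flow
#'
#' V(t) is the cumulative trapezoidal integral of flow with V = 0 at the
#' first sample. Exact for piecewise-linear flow, hence exact for the ramp
#' profiles of volume-control ventilation.
#'
#' @param samples Tibble with columns `t` (s) and `flow` (L/s); at least two
#'   samples with increasing `t`.
#' @return The input tibble with a `volume` column (litres).
#' @examples
#' s <- tibble::tibble(t = seq(0, 1, 0.02), flow = 0.5)
#' tail(integrate_volume(s)$volume, 1) # 0.5 L
#' @export
integrate_volume <- function(samples) {
  if (nrow(samples) < 2) abort("Need at least 2 samples to integrate flow.")
  if (any(diff(samples$t) <= 0)) abort("Sample times must be strictly increasing.")
  samples$volume <- as.numeric(pracma::cumtrapz(samples$t, samples$flow))
  samples
}

#' Fit the single-compartment lung model to one inspiration
#'
#' Ordinary least squares of airway pressure on inspired volume, flow and an
#' intercept: `Paw(t) = Ers V(t) + Rrs Q(t) + P0`. The intercept P0 is a
#' fitted offset pressure, not pinned to the detected PEEP. When the
#' regressor matrix is ill-conditioned (condition number above `cond_cap`,
#' e.g. constant flow collinear with the intercept) the estimates are still
#' reported but flagged so downstream summaries can exclude them.
#'
#' @param samples Inspiratory samples (`t`, `flow`, `pressure`), at least 5.
#' @param volume Optional precomputed volume series (litres); computed with
#'   [integrate_volume()] when missing.
#' @param cond_cap Condition-number cap above which the fit is flagged
#'   `ill_conditioned` (default 1e8).
#' @return A `vm_fit` object; see [tidy.vm_fit()], [glance.vm_fit()],
#'   [augment.vm_fit()].
#' @export
fit_single_compartment <- function(samples, volume = NULL, cond_cap = 1e8) {
  if (nrow(samples) < 5) abort("Need at least 5 inspiratory samples to fit the model.")
  if (is.null(volume)) volume <- integrate_volume(samples)$volume
  y <- samples$pressure
  X <- cbind(V = volume, Q = samples$flow, `(Intercept)` = 1)
  sv <- svd(X, nu = 0, nv = 0)$d
  condition <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  qr_x <- qr(X)
  coef <- qr.coef(qr_x, y)
  coef[is.na(coef)] <- 0
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  n <- length(y)
  df_res <- n - qr_x$rank
  sigma2 <- if (df_res > 0) sum(resid^2) / df_res else NA_real_
  xtx_inv <- tryCatch(chol2inv(qr.R(qr_x)), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tss <- sum((y - mean(y))^2)
  flag <- if (!is.finite(condition) || condition > cond_cap) "ill_conditioned" else "ok"
  structure(
    list(
      coefficients = c(Ers = unname(coef[1]), Rrs = unname(coef[2]), P0 = unname(coef[3])),
      std_error = c(Ers = se[1], Rrs = se[2], P0 = se[3]),
      sigma = sqrt(sigma2),
      r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
      df_residual = df_res,
      nobs = n,
      condition = condition,
      flag = flag,
      data = tibble::new_tibble(
        list(t = samples$t, flow = samples$flow, pressure = samples$pressure,
             volume = volume, .fitted = fitted, .resid = resid),
        nrow = n
      )
    ),
    class = "vm_fit"
  )
}

#' @export
print.vm_fit <- function(x, ...) {
  cat("<vm_fit> single-compartment model, ", x$nobs, " samples\n", sep = "")
  cat(sprintf(
    "  Ers = %.4g cmH2O/L, Rrs = %.4g cmH2O.s/L, P0 = %.4g cmH2O\n",
    x$coefficients["Ers"], x$coefficients["Rrs"], x$coefficients["P0"]
  ))
  cat(sprintf("  sigma = %.3g, R^2 = %.4f, condition = %.3g [%s]\n",
              x$sigma, x$r_squared, x$condition, x$flag))
  invisible(x)
}

#' Broom-style accessors for single-compartment fits
#'
#' `tidy()` returns one row per model term (`Ers`, `Rrs`, `P0`) with estimate
#' and standard error; `glance()` returns a one-row model summary including
#' the regressor condition number and quality flag; `augment()` returns the
#' sample-level data with fitted pressures and residuals.
#'
#' @param x,model A `vm_fit` from [fit_single_compartment()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vm_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_error
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pt(abs(stat), df = x$df_residual, lower.tail = FALSE))
  )
}

#' @rdname tidy.vm_fit
#' @export
glance.vm_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    nobs = x$nobs,
    df.residual = x$df_residual,
    condition = x$condition,
    flag = x$flag
  )
}

#' @rdname tidy.vm_fit
#' @export
augment.vm_fit <- function(x, ...) {
  x$data
}

#' Time-varying elastance curve of one inspiration
#'
#' Point-wise elastance after removing the resistive and offset pressure
#' components: `Edrs(t) = (Paw - Rrs Q - P0) / V`, evaluated on normalised
#' inspiration time `tau = t / T_insp` in (0, 1]. Samples whose volume is
#' below `volume_floor_fraction` of the end-inspiratory volume are dropped to
#' avoid the V -> 0 singularity at the start of the breath.
#'
#' @param samples Inspiratory samples (`t`, `flow`, `pressure`).
#' @param rrs,p0 Resistance and offset pressure from the per-breath fit.
#' @param volume Optional precomputed volume series.
#' @param volume_floor_fraction Fraction of end-inspiratory volume below
#'   which samples are excluded (default 0.05).
#' @return Tibble `(tau, edrs)` with `tau` strictly increasing in (0, 1];
#'   zero rows (with attribute `flag = "low_volume"`) when the
#'   end-inspiratory volume is not positive.
#' @export
compute_edrs <- function(samples, rrs, p0, volume = NULL,
                         volume_floor_fraction = 0.05) {
  if (is.null(volume)) volume <- integrate_volume(samples)$volume
  n <- nrow(samples)
  v_end <- volume[n]
  if (!is.finite(v_end) || v_end <= 0) {
    out <- tibble::tibble(tau = numeric(0), edrs = numeric(0))
    attr(out, "flag") <- "low_volume"
    return(out)
  }
  t0 <- samples$t[1]
  t_insp <- samples$t[n] - t0
  keep <- volume > volume_floor_fraction * v_end
  tibble::new_tibble(
    list(
      tau = (samples$t[keep] - t0) / t_insp,
      edrs = (samples$pressure[keep] - rrs * samples$flow[keep] - p0) / volume[keep]
    ),
    nrow = sum(keep)
  )
}

#' Stiffness: normalised area under the Edrs curve
#'
#' Trapezoidal area of the time-varying elastance over normalised inspiration
#' time, divided by the tau-span the curve actually covers — so a constant
#' curve returns that constant regardless of the volume-floor cutoff, and the
#' metric is comparable across respiratory rates. Negative values are
#' reported as-is: strong spontaneous effort genuinely drives the apparent
#' elastance below zero, and that signature is diagnostic.
#'
#' @param edrs_curve Tibble `(tau, edrs)` from [compute_edrs()].
#' @return Stiffness in cmH2O/L, or NA when the curve has fewer than 2 points.
#' @examples
#' compute_stiffness(tibble::tibble(tau = c(0, 1), edrs = c(10, 30))) # 20
#' @export
compute_stiffness <- function(edrs_curve) {
  if (is.null(edrs_curve) || nrow(edrs_curve) < 2) return(NA_real_)
  span <- max(edrs_curve$tau) - min(edrs_curve$tau)
  if (span <= 0) return(NA_real_)
  pracma::trapz(edrs_curve$tau, edrs_curve$edrs) / span
}

#' Rolling mean over the defined stiffness history
#'
#' Smooths a per-breath stiffness series with the mean of the most recent
#' `window` *defined* values (quarantined or otherwise undefined breaths are
#' skipped, not zero-filled): the value at breath i is the mean of the last
#' `min(window, number defined so far)` defined values up to and including i.
#'
#' @param x Numeric series with NAs for undefined breaths.
#' @param window Number of breathing cycles to average over (default 60).
#' @return Numeric series of the same length; NA until the first defined value.
#' @export
rolling_stiffness <- function(x, window = 60) {
  if (window < 1) abort("`window` must be >= 1.")
  def <- which(!is.na(x))
  out <- rep(NA_real_, length(x))
  if (length(def) == 0) return(out)
  cs <- c(0, cumsum(x[def]))
  k <- findInterval(seq_along(x), def)
  lo <- pmax(k - window + 1L, 1L)
  has <- k > 0
  out[has] <- (cs[k[has] + 1L] - cs[lo[has]]) / (k[has] - lo[has] + 1L)
  out
}

#' Per-breath respiratory mechanics for a segmented session
#'
#' Runs the full per-breath identification over a segmented breath tibble:
#' volume integration, single-compartment least squares, the time-varying
#' elastance curve, its normalised area (stiffness), and the rolling smoothed
#' stiffness series. Quarantined breaths keep their rows with NA mechanics.
#' Ill-conditioned fits report their estimates but their stiffness is left
#' undefined so they drop out of downstream summaries, as do breaths whose
#' end-inspiratory volume is not positive (`condition = "low_volume"`).
#'
#' @param breaths Output of [segment_breaths()].
#' @param window Smoothing window in breathing cycles (default 60).
#' @param calibration Optional [calibrate_peep()] result; detected PEEPs are
#'   reported on the ventilator-display scale `detected + offset`.
#' @param cond_cap Condition-number cap for [fit_single_compartment()].
#' @param volume_floor_fraction Volume floor for [compute_edrs()].
#' @return A `vm_mechanics` tibble, one row per breath: `breath_index`,
#'   `t_start`, `status`, `reason`, `ers`, `rrs`, `p0`, `condition`,
#'   `stiffness`, `stiffness_smooth`, `peep`, `n_samples` and the `edrs`
#'   list-column of `(tau, edrs)` curves.
#' @export
analyze_breaths <- function(breaths, window = 60, calibration = NULL,
                            cond_cap = 1e8, volume_floor_fraction = 0.05) {
  n <- nrow(breaths)
  ers <- rrs <- p0 <- stiff <- t_start <- rep(NA_real_, n)
  cond <- rep(NA_character_, n)
  curves <- vector("list", n)
  empty_curve <- tibble::tibble(tau = numeric(0), edrs = numeric(0))
  for (i in seq_len(n)) {
    s <- breaths$samples[[i]]
    t_start[i] <- if (nrow(s) > 0) s$t[1] else NA_real_
    curves[[i]] <- empty_curve
    if (breaths$status[i] != "accepted") next
    insp <- s[seq_len(breaths$insp_end[i]), , drop = FALSE]
    v <- as.numeric(pracma::cumtrapz(insp$t, insp$flow))
    fit <- fit_single_compartment(insp, volume = v, cond_cap = cond_cap)
    ers[i] <- fit$coefficients["Ers"]
    rrs[i] <- fit$coefficients["Rrs"]
    p0[i] <- fit$coefficients["P0"]
    curve <- compute_edrs(insp, rrs[i], p0[i], volume = v,
                          volume_floor_fraction = volume_floor_fraction)
    low_vol <- identical(attr(curve, "flag"), "low_volume")
    cond[i] <- if (low_vol) "low_volume" else fit$flag
    curves[[i]] <- curve
    if (cond[i] == "ok") stiff[i] <- compute_stiffness(curve)
  }
  peep <- breaths$peep
  if (!is.null(calibration)) peep <- apply_peep_calibration(peep, calibration)
  out <- tibble::tibble(
    breath_index = breaths$breath_index,
    t_start = t_start,
    status = breaths$status,
    reason = breaths$reason,
    ers = ers, rrs = rrs, p0 = p0,
    condition = cond,
    stiffness = stiff,
    stiffness_smooth = rolling_stiffness(stiff, window),
    peep = peep,
    n_samples = breaths$n_samples,
    edrs = curves
  )
  class(out) <- c("vm_mechanics", class(out))
  attr(out, "window") <- window
  attr(out, "stream_meta") <- segments_meta(breaths)
  out
}
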