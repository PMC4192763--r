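test_that("volume integration is exact for constant and linear flow", {
  s <- tibble::tibble(t = seq(0, 1, 0.02), flow = 0.5)
  expect_equal(tail(integrate_volume(s)$volume, 1), 0.5)
  # linear (ramp) flow: V(t) = q0 t - (q0/2) t^2 exactly under the trapezoid rule
  tt <- seq(0, 1, 0.02)
  s2 <- tibble::tibble(t = tt, flow = 1 - tt)
  expect_equal(integrate_volume(s2)$volume, tt - tt^2 / 2, tolerance = 1e-14)
  expect_error(integrate_volume(s2[1, ]), "at least 2")
})

test_that("the fit recovers noiseless single-compartment parameters exactly", {
  sim <- simulate_breath(quiet_lung(ers_base = 30, rrs = 10),
                         vent_settings(peep_set = 12), seed = NULL)
  ie <- ventmech:::find_insp_end(sim$samples$flow)
  fit <- fit_single_compartment(sim$samples[seq_len(ie), ])
  expect_equal(unname(fit$coefficients["Ers"]), 30, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["Rrs"]), 10, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["P0"]), 12, tolerance = 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-12)
  expect_equal(fit$flag, "ok")
})

test_that("coefficients and standard errors agree with lm()", {
  set.seed(51)
  tt <- seq(0.02, 1, 0.02)
  flow <- 1 - 0.8 * tt
  vol <- as.numeric(pracma::cumtrapz(tt, flow))
  pressure <- 25 * vol + 8 * flow + 10 + rnorm(length(tt), sd = 0.5)
  s <- tibble::tibble(t = tt, flow = flow, pressure = pressure)
  fit <- fit_single_compartment(s, volume = vol)
  ref <- lm(pressure ~ vol + flow)
  rs <- summary(ref)$coefficients
  expect_equal(unname(fit$coefficients), unname(coef(ref)[c(2, 3, 1)]), tolerance = 1e-10)
  expect_equal(unname(fit$std_error), unname(rs[c(2, 3, 1), "Std. Error"]), tolerance = 1e-8)
  expect_equal(fit$sigma, summary(ref)$sigma, tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  # broom-style accessors carry the same numbers
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "Ers"], unname(coef(ref)["vol"]), tolerance = 1e-10)
  expect_equal(glance(fit)$nobs, length(tt))
  expect_equal(augment(fit)$.resid, unname(residuals(ref)), tolerance = 1e-10)
})

test_that("constant flow is flagged ill-conditioned and excluded from stiffness", {
  tt <- seq(0.02, 1, 0.02)
  s <- tibble::tibble(t = tt, flow = rep(0.5, length(tt)),
                      pressure = 25 * 0.5 * tt + 8 * 0.5 + 10)
  fit <- fit_single_compartment(s)
  expect_equal(fit$flag, "ill_conditioned")
  # through the pipeline the breath keeps its estimates but not a stiffness
  txt <- breath_text(c(rep(30, 50), rep(-12, 25)), c(seq(14, 27, length.out = 50),
                                                     rep(10, 25)))
  loose <- filter_config(max_pressure_step = 100, max_flow_step = 100)
  res <- analyze_breaths(segment_breaths(parse_stream(txt), loose))
  expect_equal(res$status, "accepted")
  expect_equal(res$condition, "ill_conditioned")
  expect_false(is.na(res$ers))
  expect_true(is.na(res$stiffness))
})

test_that("the elastance curve is flat at Ers for a passive linear lung", {
  sim <- simulate_breath(quiet_lung(ers_base = 28, rrs = 6),
                         vent_settings(peep_set = 10), seed = NULL)
  ie <- ventmech:::find_insp_end(sim$samples$flow)
  insp <- sim$samples[seq_len(ie), ]
  fit <- fit_single_compartment(insp)
  curve <- compute_edrs(insp, fit$coefficients["Rrs"], fit$coefficients["P0"])
  expect_true(all(curve$tau > 0 & curve$tau <= 1))
  expect_true(all(diff(curve$tau) > 0))
  expect_equal(curve$edrs, rep(28, nrow(curve)), tolerance = 1e-6)
  expect_equal(compute_stiffness(curve), 28, tolerance = 1e-6)
})

test_that("the volume floor drops early samples and low volume flags the curve", {
  tt <- seq(0.02, 1, 0.02)
  vol <- tt # linear volume ramp, v_end = 1
  s <- tibble::tibble(t = tt, flow = 1, pressure = 20 * vol + 8 + 5)
  curve <- compute_edrs(s, rrs = 8, p0 = 5, volume = vol, volume_floor_fraction = 0.10)
  expect_true(all(vol[tt %in% (curve$tau * (1 - 0.02) + 0.02)] > 0.10) ||
                min(curve$tau) > 0.10 - 1e-9)
  expect_lt(nrow(curve), length(tt))
  # non-positive end volume -> empty curve with the low_volume flag
  s0 <- tibble::tibble(t = tt, flow = 0, pressure = 10)
  c0 <- compute_edrs(s0, rrs = 8, p0 = 5, volume = rep(0, length(tt)))
  expect_equal(nrow(c0), 0)
  expect_equal(attr(c0, "flag"), "low_volume")
  expect_true(is.na(compute_stiffness(c0)))
})

test_that("stiffness is the tau-normalised area and passes through constants", {
  expect_equal(compute_stiffness(tibble::tibble(tau = c(0, 1), edrs = c(10, 30))), 20)
  # constant curve over a partial tau span still returns the constant
  expect_equal(compute_stiffness(tibble::tibble(tau = seq(0.3, 1, 0.1),
                                                edrs = rep(17, 8))), 17)
  expect_true(is.na(compute_stiffness(tibble::tibble(tau = 0.5, edrs = 10))))
})

test_that("spontaneous effort depresses the elastance curve mid-breath", {
  vent <- vent_settings(peep_set = 10)
  passive <- simulate_breath(quiet_lung(), vent, seed = NULL)
  effort <- simulate_breath(quiet_lung(effort_prob = 1, effort_amp = 8), vent,
                            seed = 61)
  analyze_one <- function(sim) {
    seg <- segment_breaths(parse_stream(write_capture(
      ventmech:::new_segment_tibble(TRUE, TRUE, FALSE, list(sim$samples), stream_meta())
    )))
    analyze_breaths(seg)
  }
  rp <- analyze_one(passive)
  re <- analyze_one(effort)
  # effort pulls the apparent stiffness below the passive value
  expect_lt(re$stiffness, rp$stiffness - 1)
  # and makes the curve non-flat: mid-breath dip relative to its own ends
  ce <- re$edrs[[1]]
  expect_gt(diff(range(ce$edrs)), 5 * diff(range(rp$edrs[[1]]$edrs)))
})

test_that("rolling stiffness averages only the defined history", {
  x <- c(NA, 10, 12, NA, 14, 16)
  out <- rolling_stiffness(x, window = 2)
  expect_true(is.na(out[1]))
  expect_equal(out[2], 10)
  expect_equal(out[3], 11)
  expect_equal(out[4], 11) # NA breath carries the last window forward
  expect_equal(out[5], 13)
  expect_equal(out[6], 15)
  expect_equal(rolling_stiffness(rep(NA_real_, 4), 3), rep(NA_real_, 4))
  expect_error(rolling_stiffness(x, window = 0), ">= 1")
})

test_that("session analysis keeps one aligned row per breath", {
  sim <- simulate_session(lung_config(noise_sd = 0.2, seed = 71),
                          vent_settings(peep_set = 12), n_breaths = 40)
  bad <- corrupt_stream(sim$text, data.frame(breath_index = c(7, 30),
                                             corruption = c("drop_be", "flow_spike")))
  res <- analyze_text(bad$text, window = 10)
  expect_s3_class(res, "vm_mechanics")
  expect_equal(nrow(res), 40)
  expect_equal(res$breath_index, 1:40)
  q <- res$status == "quarantined"
  expect_equal(which(q), c(7, 30))
  expect_true(all(is.na(res$ers[q])))
  expect_true(all(is.na(res$stiffness[q])))
  ok <- !q
  # estimates centred on the truth for a quiet lung with modest noise
  expect_equal(mean(res$ers[ok]), mean(sim$truth$ers_true[ok]), tolerance = 0.05)
  expect_equal(mean(res$rrs[ok]), 8, tolerance = 0.05)
  expect_true(all(abs(res$stiffness_smooth[40] - res$ers[40]) <
                    abs(res$stiffness[40] - res$ers[40]) + 2))
  # breath start times are equally spaced by the cycle length
  expect_equal(diff(res$t_start), rep(res$t_start[2], 39), tolerance = 1e-9)
})
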