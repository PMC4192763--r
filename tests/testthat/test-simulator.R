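test_that("configuration objects validate their physiology", {
  expect_error(lung_config(ers_base = -1), "positive")
  expect_error(lung_config(recruit_factor = 0), "\\(0, 1\\]")
  expect_error(lung_config(effort_prob = 1.5), "\\[0, 1\\]")
  expect_error(lung_config(noise_sd = -0.1), "non-negative")
  expect_error(vent_settings(tidal_volume = 0), "positive")
  expect_error(vent_settings(t_insp = 4, resp_rate = 15), "breath period")
  expect_error(vent_settings(flow_shape = "sine"))
})

test_that("a noiseless breath satisfies the model equation sample by sample", {
  lung <- quiet_lung(ers_base = 25, rrs = 8)
  vent <- vent_settings(tidal_volume = 0.5, t_insp = 1, peep_set = 12)
  sim <- simulate_breath(lung, vent, seed = NULL)
  s <- sim$samples
  v <- as.numeric(pracma::cumtrapz(s$t, s$flow))
  # on the inspiratory limb the trapezoid is exact for the ramp profile
  ie <- ventmech:::find_insp_end(s$flow)
  resid <- s$pressure[1:ie] - (25 * v[1:ie] + 8 * s$flow[1:ie] + 12)
  expect_lt(max(abs(resid)), 1e-9)
  # peak ramp flow is 2 VT / t_insp at the first sample, decaying linearly
  expect_equal(s$flow[1], 2 * 0.5 / 1)
  expect_equal(diff(s$flow[1:ie]), rep(s$flow[2] - s$flow[1], ie - 1),
               tolerance = 1e-12)
  # delivered volume equals the set tidal volume
  expect_equal(v[ie], 0.5, tolerance = 1e-3)
  # expiration decays: volume falls monotonically back towards FRC
  expect_lt(v[length(v)], 0.02)
  expect_true(all(s$flow[(ie + 1):length(v)] <= 0))
  # pressure returns to PEEP at end-expiration
  expect_equal(tail(s$pressure, 1), 12, tolerance = 0.1)
})

test_that("square flow delivers the same volume at constant flow", {
  sim <- simulate_breath(quiet_lung(), vent_settings(flow_shape = "square"),
                         seed = NULL)
  ie <- ventmech:::find_insp_end(sim$samples$flow)
  expect_equal(unique(sim$samples$flow[1:ie]), 0.5)
  v <- as.numeric(pracma::cumtrapz(sim$samples$t, sim$samples$flow))
  expect_equal(v[ie], 0.5, tolerance = 1e-3)
})

test_that("identical seeds reproduce the stream byte for byte", {
  lung <- lung_config(noise_sd = 0.3, effort_prob = 0.3, seed = 99)
  a <- simulate_session(lung, vent_settings(), n_breaths = 5)
  b <- simulate_session(lung, vent_settings(), n_breaths = 5)
  expect_identical(a$text, b$text)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_session(lung, vent_settings(), n_breaths = 5, seed = 100)
  expect_false(identical(a$text, c_$text))
})

test_that("elastance follows the U-shaped PEEP law with descending recruitment", {
  lung <- lung_config(ers_base = 20, curvature = 0.3, peep_opt = 16,
                      recruit_factor = 0.8)
  expect_equal(effective_elastance(lung, 16), 20)
  expect_equal(effective_elastance(lung, 10), 20 + 0.3 * 36)
  expect_equal(effective_elastance(lung, 22), 20 + 0.3 * 36)
  expect_equal(effective_elastance(lung, 16, "descending"), 16)
  # the generated breaths carry the effective elastance in their truth rows
  sim <- simulate_breath(lung, vent_settings(peep_set = 10), arm = "descending",
                         seed = 1)
  expect_equal(sim$truth$ers_true, (20 + 0.3 * 36) * 0.8)
})

test_that("clean simulated breaths survive the default quarantine filters", {
  lung <- lung_config(noise_sd = 0.4, seed = 17)
  sim <- simulate_session(lung, vent_settings(peep_set = 14), n_breaths = 30)
  seg <- segment_breaths(parse_stream(sim$text))
  expect_true(all(seg$status == "accepted"))
  # pure square flow genuinely steps ~30 native units at end-inspiration, so
  # at the default thresholds it is (correctly) caught by the flow-jump rule
  sq <- simulate_session(lung, vent_settings(flow_shape = "square"), n_breaths = 3)
  sq_seg <- segment_breaths(parse_stream(sq$text))
  expect_true(all(sq_seg$reason == "flow_jump"))
  expect_true(all(segment_breaths(parse_stream(sq$text),
                                  filter_config(max_flow_step = 40))$status ==
                    "accepted"))
})

test_that("the protocol builder ascends only while peak pressure permits", {
  lung <- quiet_lung(ers_base = 30, rrs = 8)
  vent <- vent_settings()
  proto <- rm_protocol(lung, vent, peep_start = 14, step = 2, max_peak_paw = 55)
  top <- max(proto)
  expect_lte(peak_airway_pressure(lung, vent, top), 55)
  expect_gt(peak_airway_pressure(lung, vent, top + 2), 55)
  # symmetric descent back to the start, top level appearing once
  expect_equal(proto, c(seq(14, top, 2), seq(top - 2, 14, -2)))
  expect_error(rm_protocol(quiet_lung(ers_base = 120), vent, peep_start = 30),
               "ceiling")
})

test_that("non-physiological manoeuvres are refused above 80 cmH2O peak pressure", {
  lung <- quiet_lung(ers_base = 140, rrs = 8)
  expect_error(
    simulate_rm_session(lung, vent_settings(), protocol = c(14, 16, 14),
                        breaths_per_level = 2),
    "exceeds 80"
  )
})

test_that("manoeuvre truth labels arms and levels in protocol order", {
  lung <- lung_config(seed = 23, recruit_factor = 0.9)
  proto <- c(14, 16, 18, 16, 14)
  sim <- simulate_rm_session(lung, vent_settings(), protocol = proto,
                             breaths_per_level = 3)
  expect_equal(nrow(sim$truth), 15)
  expect_equal(sim$truth$peep_set, rep(proto, each = 3))
  expect_equal(sim$truth$arm, rep(c(rep("ascending", 3), rep("descending", 2)),
                                  each = 3))
  expect_equal(attr(sim$truth, "protocol"), proto)
  # descending levels are softer than their ascending twins
  ers_at <- function(p, a) unique(sim$truth$ers_true[sim$truth$peep_set == p &
                                                       sim$truth$arm == a])
  expect_lt(ers_at(16, "descending"), ers_at(16, "ascending"))
  # text and segment representations agree
  expect_equal(parse_stream(sim$text)$samples, sim$segments$samples,
               tolerance = 1e-5)
  # ground-truth file round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("breath_index", "peep_set", "arm", "Ers_true",
                              "Rrs_true", "effort_flag"))
  expect_equal(back$Ers_true, sim$truth$ers_true)
})

test_that("effort breaths carry the artifact only where the truth says so", {
  lung <- lung_config(noise_sd = 0, effort_prob = 0.5, effort_amp = 6, seed = 29)
  sim <- simulate_session(lung, vent_settings(peep_set = 10), n_breaths = 40)
  expect_gt(sum(sim$truth$effort), 5)
  expect_gt(sum(!sim$truth$effort), 5)
  res <- analyze_breaths(segment_breaths(sim$segments), window = 1)
  # effort depresses stiffness well below the passive breaths
  expect_lt(max(res$stiffness[sim$truth$effort]),
            min(res$stiffness[!sim$truth$effort]))
})
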