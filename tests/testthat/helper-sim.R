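# Shared simulation scaffolding for the test suite. All fixtures are
# generated in code; nothing is read from disk.

quiet_lung <- function(ers_base = 25, rrs = 8, ...) {
  lung_config(ers_base = ers_base, rrs = rrs, curvature = 0, noise_sd = 0,
              seed = NULL, ...)
}

# parse -> segment -> analyze in one call
analyze_text <- function(text, meta = stream_meta(), filter = filter_config(),
                         window = 60, ...) {
  analyze_breaths(segment_breaths(parse_stream(text, meta), filter), window = window, ...)
}

# build a one-breath capture text from flow (native units) and pressure vectors
breath_text <- function(flow_native, pressure, bs = TRUE, be = TRUE) {
  paste(c(
    if (bs) "BS",
    sprintf("%g,%g", flow_native, pressure),
    if (be) "BE"
  ), collapse = "\n")
}

# the step-wise manoeuvre protocol used throughout: 14 -> 26 -> 14 in 2-cmH2O
# steps (ascending arm includes the 26 top level)
std_rm_protocol <- function() c(seq(14, 26, 2), seq(24, 14, -2))

# Lung for the recommendation-recovery study: a quadratic U in PEEP with its
# minimum at `opt`, made as sharp as the protocol can safely ventilate — the
# elastance at the farthest protocol level is capped at 88 cmH2O/L (predicted
# peak pressure ~70 cmH2O, inside the simulator's 80-cmH2O refusal), with the
# curvature never above 1.5.
rm_recovery_curvature <- function(opt, base = 10, peep_lo = 14, peep_hi = 26,
                                  ers_cap = 88) {
  dist <- max(abs(peep_hi - opt), abs(peep_lo - opt))
  min((ers_cap - base) / dist^2, 1.5)
}

rm_recovery_lung <- function(opt, seed, noise_sd = 0.5, recruit_factor = 1) {
  lung_config(
    ers_base = 10, rrs = 8, peep_opt = opt,
    curvature = rm_recovery_curvature(opt),
    recruit_factor = recruit_factor, noise_sd = noise_sd, seed = seed
  )
}

# run one seeded RM replicate and return the recommended PEEP (segment path)
rm_recovery_recommendation <- function(opt, seed, breaths_per_level = 5) {
  lung <- rm_recovery_lung(opt, seed)
  sim <- simulate_rm_session(
    lung, vent_settings(peep_set = 14),
    protocol = std_rm_protocol(), breaths_per_level = breaths_per_level
  )
  res <- analyze_breaths(segment_breaths(sim$segments), window = 1)
  recommend_peep(build_peep_ladder(res, step = 2))$recommended_peep
}

# construct a peep_ladder tibble directly (for recommendation-rule tests)
make_ladder <- function(peep, arm, stiffness, n_breaths = 5, step = 2) {
  out <- tibble::tibble(
    peep = peep, arm = arm, n_breaths = n_breaths, stiffness = stiffness
  )
  class(out) <- c("peep_ladder", class(out))
  attr(out, "step") <- step
  out
}

# minimal mechanics-results tibble for ladder-construction tests
make_results <- function(peep, stiffness) {
  tibble::tibble(
    breath_index = seq_along(peep),
    t_start = (seq_along(peep) - 1) * 4,
    status = "accepted", reason = "none",
    ers = stiffness, rrs = 8, p0 = peep, condition = "ok",
    stiffness = stiffness, peep = peep
  )
}
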