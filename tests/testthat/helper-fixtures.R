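# memoized fixtures shared across test files (all generated in code)
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small session for io/sync tests (short blocks; scoring not meaningful)
small_session <- function() fixture("small", function()
  simulate_session(sim_config(n_units = 12, baseline_s = 60, event_s = 60,
                              post_s = 60, contact_delay_range = c(3, 8),
                              seed = 42)))

# mixed-category session at the generator's default gains
mixed_session <- function() fixture("mixed", function()
  simulate_session(sim_config(n_units = 60, seed = 7)))

mixed_scoring <- function() fixture("mixed_scoring", function()
  score_session(mixed_session()$session))

# decoding fixture: gain 5, 4 presentations/class
decode_session <- function() fixture("decode", function()
  simulate_session(sim_config(n_units = 60, event_gain_range = c(5, 5),
                              n_presentations = 4, seed = 7)))

decode_scoring <- function() fixture("decode_scoring", function()
  score_session(decode_session()$session))

# all-event-specific cohort with aftereffects in 30% of units
aftereffect_session <- function() fixture("aftereffect", function()
  simulate_session(sim_config(
    n_units = 100,
    class_mix = c(male_specific = 0.25, female_specific = 0.25,
                  toy_specific = 0.25, food_specific = 0.25,
                  panresponsive = 0, decreased = 0, nonresponsive = 0),
    aftereffect = list(prob = 0.3, tau_s = 120), seed = 5)))

aftereffect_scoring <- function() fixture("aftereffect_scoring", function()
  score_session(aftereffect_session()$session))

# scripted-behavior tracking
tracking_sim <- function() fixture("tracking", function()
  simulate_tracking(sim_config(seed = 9)))

tracking_features <- function() fixture("tracking_features", function() {
  trk <- tracking_sim()
  compute_features(clean_tracking(trk$tracking), 30)
})

# brute-force Mann-Whitney pair-count oracle for the auROC response score
oracle_score <- function(baseline, event) {
  wins <- 0; ties <- 0
  for (b in baseline) {
    wins <- wins + sum(event > b)
    ties <- ties + sum(event == b)
  }
  u <- wins + ties / 2
  (u / (length(baseline) * length(event)) - 0.5) * 2
}

# hand-built ethospike_psth for timewarp tests
make_psth <- function(bin_centers, z, tp, tc, te = max(bin_centers)) {
  structure(list(unit_id = "syn", bin_centers = bin_centers, z = z,
                 rate = z, baseline_mean = 0, baseline_sd = 1, bin_s =
                   diff(bin_centers[1:2]),
                 anchors = c(presentation = tp, contact = tc,
                             event_end = te)),
            class = "ethospike_psth")
}
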