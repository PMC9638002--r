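test_that("invalid configurations are rejected", {
  expect_error(sim_config(event_gain_range = c(-1, 2)), "event_gain")
  expect_error(sim_config(class_mix = c(male_specific = 0.5,
                                        female_specific = 0.2,
                                        toy_specific = 0, food_specific = 0,
                                        panresponsive = 0, decreased = 0,
                                        nonresponsive = 0)), "sum to 1")
  expect_error(sim_config(connections = data.frame(proj = 1, targ = 2,
                                                   delay_ms = 8,
                                                   transfer_prob = 0.1)),
               "delay_ms")
  expect_error(sim_config(connections = data.frame(proj = 1, targ = 2,
                                                   delay_ms = 2,
                                                   transfer_prob = 1.2)),
               "transfer_prob")
})

test_that("all-nonresponsive sessions show no event/baseline rate change", {
  cfg <- sim_config(n_units = 20,
                    class_mix = c(male_specific = 0, female_specific = 0,
                                  toy_specific = 0, food_specific = 0,
                                  panresponsive = 0, decreased = 0,
                                  nonresponsive = 1),
                    baseline_rate = list(meanlog = log(1), sdlog = 0,
                                         pan_meanlog = log(1)),
                    seed = 13)
  sim <- simulate_session(cfg)
  base_n <- 0; base_t <- 0; ev_n <- 0; ev_t <- 0
  for (u in sim$session$units) for (e in sim$session$events) {
    ep <- event_epochs(e)
    base_n <- base_n + length(spikes_in(u$spike_times, ep$baseline))
    base_t <- base_t + diff(ep$baseline)
    ev_n <- ev_n + length(spikes_in(u$spike_times, ep$event))
    ev_t <- ev_t + diff(ep$event)
  }
  ratio <- (ev_n / ev_t) / (base_n / base_t)
  se <- ratio * sqrt(1 / ev_n + 1 / base_n)
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("an event-specific unit carries its configured gain", {
  cfg <- sim_config(n_units = 1,
                    class_mix = c(male_specific = 0, female_specific = 1,
                                  toy_specific = 0, food_specific = 0,
                                  panresponsive = 0, decreased = 0,
                                  nonresponsive = 0),
                    baseline_rate = list(meanlog = log(2), sdlog = 0,
                                         pan_meanlog = log(2)),
                    event_gain_range = c(5, 5),
                    n_presentations = 4, seed = 17)
  sim <- simulate_session(cfg)
  st <- sim$session$units[[1]]$spike_times
  base_n <- 0; base_t <- 0; ev_n <- 0; ev_t <- 0
  for (e in sim$session$events) {
    if (e$stimulus_class != "female") next
    ep <- event_epochs(e)
    base_n <- base_n + length(spikes_in(st, ep$baseline))
    base_t <- base_t + diff(ep$baseline)
    # measure after first contact so the pre-onset span does not dilute it
    ev_n <- ev_n + length(spikes_in(st, c(e$t_contact, e$t_event_end)))
    ev_t <- ev_t + (e$t_event_end - e$t_contact)
  }
  ratio <- (ev_n / ev_t) / (base_n / base_t)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 6.5)
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- sim_config(n_units = 6, seed = 23)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(lapply(s1$session$units, `[[`, "spike_times"),
                   lapply(s2$session$units, `[[`, "spike_times"))
  expect_identical(s1$truth$units, s2$truth$units)
  expect_identical(s1$session$sync$received_times,
                   s2$session$sync$received_times)
})

test_that("spike counts are Poisson-dispersed at the configured rate", {
  set.seed(29)
  st <- simulate_poisson_train(4, 900)
  counts <- binned_rates(st, c(0, 900), 1)
  disp <- stats::var(counts) / mean(counts)
  # variance/mean ~ 1 +/- sqrt(2/(n-1)) under Poisson
  expect_lt(abs(disp - 1), 3 * sqrt(2 / 899))
})

test_that("inject_connection follows its transmission model", {
  set.seed(31)
  proj <- simulate_poisson_train(10, 100)
  expect_length(inject_connection(proj, 1.5, 0), 0)
  shifted <- inject_connection(proj, 1.5, 1, jitter_ms = 0)
  expect_equal(shifted, proj + 0.0015, tolerance = 1e-12)
  big <- sort(runif(10000, 0, 1000))
  ind <- inject_connection(big, 2, 0.1)
  expect_lt(abs(length(ind) - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_error(inject_connection(proj, 1.5, 1.5), "transfer_prob")
})

test_that("merge_spike_trains drops near-coincident duplicates", {
  out <- merge_spike_trains(c(1, 2), c(1 + 2e-8, 3))
  expect_equal(out, c(1, 2, 3))
  out2 <- merge_spike_trains(c(1, 2), c(1.001, 3))
  expect_length(out2, 4)
})

test_that("scripted head-to-head bouts put snouts in contact", {
  trk <- tracking_sim()
  cl <- clean_tracking(trk$tracking)
  hh <- which(trk$labels == "head-head")
  ih <- cl[cl$agent == "implanted" & cl$bodypart == "head", ]
  cn <- cl[cl$agent == "conspecific" & cl$bodypart == "nose", ]
  d <- sqrt((ih$x[hh] - cn$x[hh])^2 + (ih$y[hh] - cn$y[hh])^2)
  expect_lt(stats::quantile(d, 0.99), 4)
  expect_lt(stats::median(d), 2.5)
})

test_that("non-social frame fraction and dropout rate match the config", {
  trk <- tracking_sim()
  cfg <- sim_config(seed = 9)
  expect_lt(abs(mean(trk$labels == "non-social") -
                  cfg$behavior$nonsocial_frac), 0.02)
  expect_lt(abs(mean(trk$tracking$likelihood < 0.9) -
                  cfg$behavior$dropout_rate), 0.01)
})
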