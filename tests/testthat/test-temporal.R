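test_that("zscore_psth matches hand-computed z values", {
  # baseline bins [1,3,1,3,2] (mean 2, sd 1), event bins [4,2,6]
  mk <- function(counts, t0) unlist(lapply(seq_along(counts), function(i)
    if (counts[i] > 0) t0 + i - 1 + (seq_len(counts[i]) - 0.5) / counts[i]))
  st <- sort(c(mk(c(1, 3, 1, 3, 2), 0), mk(c(4, 2, 6), 5)))
  ev <- new_event_block("toy", 1, 0, 5, 5.5, 8, 9)
  p <- zscore_psth(st, ev, bin_s = 1)
  expect_equal(p$baseline_mean, 2)
  expect_equal(p$baseline_sd, 1)
  expect_equal(p$z[6:8], c(2, 0, 4))
})

test_that("silent baselines use the SD floor instead of infinities", {
  ev <- new_event_block("toy", 1, 0, 5, 5.5, 8, 9)
  st <- c(6.1, 6.2, 6.3)  # active only during the event
  p <- zscore_psth(st, ev, bin_s = 1, sd_floor = 0.1)
  expect_true(all(is.finite(p$z)))
  expect_true(any(p$z > 0))
  expect_equal(p$z[1:5], rep(0, 5))
})

test_that("z is an affine function of rate with baseline statistics", {
  set.seed(59)
  ev <- new_event_block("male", 1, 0, 60, 65, 120, 150)
  st <- simulate_poisson_train(4, 150)
  p <- zscore_psth(st, ev, bin_s = 1)
  k <- 3
  z_shifted <- ((p$rate + k) - p$baseline_mean) / p$baseline_sd
  expect_equal(z_shifted, p$z + k / p$baseline_sd, tolerance = 1e-12)
})

test_that("timewarp is the identity on traces already in the common frame", {
  x <- seq(0.05, by = 0.1, length.out = 198)
  z <- sin(seq_along(x) / 20)
  tp <- x[50]; tc <- x[149]
  w <- timewarp(make_psth(x, z, tp, tc), lengths = c(50, 100, 50))
  expect_equal(w$values, z, tolerance = 1e-9)
})

test_that("timewarp preserves anchors and per-segment linearity", {
  x <- seq(0.5, by = 1, length.out = 40)
  z <- c(seq(0, 1, length.out = 10), seq(1, 5, length.out = 15)[-1],
         seq(5, 2, length.out = 17)[-1])
  tp <- x[10]; tc <- x[24]
  w <- timewarp(make_psth(x, z, tp, tc), lengths = c(20, 30, 25))
  expect_equal(w$values[w$anchor_index[["presentation"]]], z[10],
               tolerance = 1e-12)
  expect_equal(w$values[w$anchor_index[["contact"]]], z[24],
               tolerance = 1e-12)
  seg2 <- w$values[w$anchor_index[["presentation"]]:
                     w$anchor_index[["contact"]]]
  expect_lt(max(abs(diff(diff(seg2)))), 1e-9)     # still linear
  expect_true(all(diff(seg2) > -1e-9))            # still monotone
  expect_error(timewarp(make_psth(x, z, -5, tc)), "anchors")
})

test_that("onset latency distances match hand-placed bursts", {
  burst <- function(t0) t0 + seq(0, 0.4, by = 0.02)
  mk_unit <- function(id, lat, ev_list) {
    st <- sort(unlist(c(
      lapply(ev_list, function(e) burst(e$t_presentation + lat)),
      lapply(ev_list, function(e)
        seq(e$t_presentation + 6, e$t_event_end - 1, by = 0.4)))))
    new_unit(id, st, 1, 0)
  }
  evs <- list(new_event_block("male", 1, 0, 60, 66, 120, 180),
              new_event_block("male", 2, 180, 240, 246, 300, 360))
  units <- list(mk_unit("a", 1.0, evs), mk_unit("b", 3.5, evs))
  session <- new_session(units, evs)
  scoring <- list(profiles = data.frame(unit_id = c("a", "b"),
                                        category = "male_specific",
                                        responsive = TRUE),
                  events = data.frame(index = 1:2,
                                      stimulus_class = "male",
                                      presentation_index = 1:2))
  os <- onset_synchrony(session, scoring, smooth_bins = 1)
  expect_equal(length(os$within), 2)
  expect_true(all(abs(os$within - 2.5) <= 0.15))
})

test_that("units sharing a common onset are tighter within than across events", {
  sim <- fixture("onset_sim", function()
    simulate_session(sim_config(
      n_units = 24,
      class_mix = c(male_specific = 0.25, female_specific = 0.25,
                    toy_specific = 0.25, food_specific = 0.25,
                    panresponsive = 0, decreased = 0, nonresponsive = 0),
      event_gain_range = c(5, 6), aftereffect = list(prob = 0, tau_s = 120),
      seed = 21)))
  sc <- score_session(sim$session)
  os <- onset_synchrony(sim$session, sc)
  expect_gte(length(os$within), 100)
  expect_lt(mean(os$within), mean(os$across))
  expect_lt(os$test$p.value, 0.05)
})

test_that("aftereffect flags follow the injected decay", {
  sim <- aftereffect_session()
  sc <- aftereffect_scoring()
  af <- detect_aftereffects(sim$session, sc)
  merged <- merge(af$per_unit, sim$truth$units[, c("unit_id", "aftereffect")],
                  by = "unit_id")
  expect_gt(mean(merged$flagged[merged$aftereffect]), 0.9)   # tau = 120 s
  expect_lt(mean(merged$flagged[!merged$aftereffect]), 0.1)  # instant return
  expect_length(af$bin_curve, 18)
})

test_that("decoding timecourse rises after contact and stays up post-event", {
  sim <- fixture("tc_sim", function()
    simulate_session(sim_config(
      n_units = 40, event_gain_range = c(5, 5),
      aftereffect = list(prob = 1, tau_s = 120), seed = 33)))
  sc <- score_session(sim$session)
  tc <- event_period_decode_timecourse(sim$session, sc, bin_s = 10,
                                       pre_s = 40, post_s = 60)
  pre <- tc$accuracy[tc$segment == "pre"]
  post <- tc$accuracy[tc$segment == "post"]
  late_event <- tc$accuracy[tc$segment == "event" & tc$offset_s >= 100]
  expect_lt(mean(pre), 0.6)          # before presentation: near chance
  expect_gt(mean(late_event), 0.65)  # during the event: decodable
  expect_gt(mean(post), 0.5)         # aftereffects keep identity decodable
  expect_gt(mean(post), mean(pre))
})
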