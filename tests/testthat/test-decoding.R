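# deterministic separable score matrix: each class drives its own units
separable_scores <- function(n_per_class = 4, n_units_per_class = 3,
                             noise = 0.02, seed = 97) {
  set.seed(seed)
  classes <- rep(stimulus_classes(), each = n_per_class)
  n_units <- 4 * n_units_per_class
  f <- matrix(rnorm(length(classes) * n_units, 0, noise),
              length(classes), n_units)
  for (k in 1:4) {
    cols <- (k - 1) * n_units_per_class + seq_len(n_units_per_class)
    f[classes == stimulus_classes()[k], cols] <-
      f[classes == stimulus_classes()[k], cols] + 0.8
  }
  list(features = f, labels = classes)
}

test_that("the leave-one-out decoder is perfect on separable scores", {
  s <- separable_scores()
  rep_ <- loo_stimulus_decoder(s$features, s$labels, n_shuffle = 50,
                               seed = 3)
  expect_equal(rep_$accuracy, 1)
  expect_gt(mean(rep_$shuffle_accuracies), 0.1)
  expect_lt(mean(rep_$shuffle_accuracies), 0.4)
})

test_that("a single-event class triggers a training warning", {
  s <- separable_scores()
  f <- s$features[c(1, 5:16), ]
  l <- s$labels[c(1, 5:16)]
  expect_warning(loo_stimulus_decoder(f, l, n_shuffle = 0), "lacks class")
})

test_that("the dropping curve at full size equals the full decoder", {
  s <- separable_scores()
  full <- loo_stimulus_decoder(s$features, s$labels, n_shuffle = 0)
  curve <- neuron_dropping_curve(s$features, s$labels,
                                 n_grid = ncol(s$features), n_repeat = 3,
                                 seed = 5)
  expect_equal(curve$mean_accuracy, full$accuracy)
  expect_equal(curve$sd_accuracy, 0)
})

test_that("accuracy does not drop as units are added to separable scores", {
  s <- separable_scores(noise = 0.3)
  curve <- neuron_dropping_curve(s$features, s$labels,
                                 n_grid = c(2, 4, 8, 12), n_repeat = 40,
                                 seed = 7)
  expect_true(all(diff(curve$mean_accuracy) > -0.05))
})

test_that("omitting informative units costs more than omitting noise units", {
  s <- separable_scores(n_units_per_class = 2)
  f <- cbind(s$features, matrix(rnorm(16 * 8, 0, 0.3), 16, 8))
  cats <- c(rep("male_specific", 8), rep("nonresponsive", 8))
  om_es <- category_omission(f, s$labels, cats, "male_specific",
                             n_repeat = 40, seed = 9)
  om_nr <- category_omission(f, s$labels, cats, "nonresponsive",
                             n_repeat = 40, seed = 9)
  expect_lt(om_es$accuracy_omitted, om_nr$accuracy_omitted)
  expect_lt(om_es$delta, om_nr$delta)
  expect_error(category_omission(f, s$labels, cats, "panresponsive"),
               "absent")
})

test_that("window decoding is at chance before presentation and high after contact", {
  sim <- decode_session()
  sc <- decode_scoring()
  wd <- window_decoder(sim$session, sc, range_s = c(-30, 30), step_s = 10)
  first <- wd$trace$accuracy[wd$trace$offset_s == -30]
  after <- wd$trace$accuracy[wd$trace$offset_s >= 0]
  expect_lt(first, 0.7)
  expect_gt(mean(after), 0.8)
  expect_equal(nrow(wd$epochs), 3)
})

test_that("window decoding stays at chance on a flat-rate session", {
  cfg <- sim_config(n_units = 12,
                    class_mix = c(male_specific = 0, female_specific = 0,
                                  toy_specific = 0, food_specific = 0,
                                  panresponsive = 0, decreased = 0,
                                  nonresponsive = 1),
                    baseline_rate = list(meanlog = log(3), sdlog = 0.3,
                                         pan_meanlog = log(3)),
                    seed = 101)
  sim <- simulate_session(cfg)
  sc <- score_session(sim$session)
  prof <- sc$profiles; prof$responsive <- TRUE  # force units into the pool
  wd <- window_decoder(sim$session, list(profiles = prof,
                                         events = sc$events,
                                         scores = sc$scores),
                       range_s = c(-10, 20), step_s = 10)
  expect_lt(mean(wd$trace$accuracy), 0.55)
})

test_that("binary-state decoding separates gated populations", {
  set.seed(103)
  lab <- rep(c(TRUE, FALSE), 60)
  f <- matrix(rnorm(120 * 8), 120, 8) + outer(as.numeric(lab), rep(2, 8))
  rep_ <- interaction_decoder(f, lab, n_shuffle = 30, seed = 11)
  expect_gt(rep_$accuracy, 0.9)
  expect_lt(abs(mean(rep_$shuffle_accuracies, na.rm = TRUE) - 0.5), 0.1)
  expect_error(interaction_decoder(f, rep(TRUE, 120)), "single-label")
  # movement decoding is the same protocol under a different label set
  expect_gt(movement_decoder(f, lab, n_shuffle = 0, seed = 11)$accuracy,
            0.9)
})

test_that("population z-rate features are baseline-referenced", {
  sim <- decode_session()
  pz <- population_zrates(sim$session, 1, bin_s = 1)
  expect_equal(nrow(pz$features), 300)
  expect_equal(ncol(pz$features), 60)
  expect_true(all(is.finite(pz$features)))
})

test_that("the depth filter is transparent when every unit passes", {
  s <- separable_scores()
  depths <- runif(ncol(s$features), 1000, 1400)
  full <- loo_stimulus_decoder(s$features, s$labels, n_shuffle = 0)
  filt <- depth_restricted_decoder(s$features, s$labels, depths,
                                   center_um = 1000, window_um = 500,
                                   min_units = 10)
  expect_equal(filt$accuracy, full$accuracy)
  expect_error(depth_restricted_decoder(s$features, s$labels, depths,
                                        center_um = 0, window_um = 500),
               "need at least")
})
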