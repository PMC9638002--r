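test_that("cross-correlograms mirror under train exchange", {
  set.seed(87)
  a <- simulate_poisson_train(6, 120)
  b <- simulate_poisson_train(6, 120)
  ab <- cross_correlogram(a, b)
  ba <- cross_correlogram(b, a)
  expect_equal(ab$counts, rev(ba$counts))
  auto <- cross_correlogram(a, a)
  expect_equal(auto$counts, rev(auto$counts))
  # self-lags at exactly zero are excluded from the autocorrelogram
  expect_lt(max(auto$counts), length(a))
})

test_that("a single lag lands in the right 0.25-ms bin", {
  ccg <- cross_correlogram(c(0.1), c(0.1015))
  expect_equal(sum(ccg$counts), 1)
  hit <- ccg$centers[ccg$counts == 1]
  expect_gte(hit, 1.5); expect_lt(hit, 1.75)
})

test_that("independent Poisson trains give the product-rate bin count", {
  set.seed(89)
  a <- simulate_poisson_train(8, 600)
  b <- simulate_poisson_train(8, 600)
  ccg <- cross_correlogram(a, b)
  expected <- 8 * 8 * 600 * 0.00025
  tol <- 3 * sqrt(expected / length(ccg$counts))
  expect_lt(abs(mean(ccg$counts) - expected), tol)
})

test_that("detection requires a wide directional supra-threshold peak", {
  set.seed(91)
  a <- simulate_poisson_train(8, 600)
  b <- simulate_poisson_train(8, 600)
  expect_false(detect_connection(cross_correlogram(a, b))$significant)
  proj <- simulate_poisson_train(10, 600)
  targ <- merge_spike_trains(simulate_poisson_train(4, 600),
                             inject_connection(proj, 1.5, 0.15))
  fwd <- detect_connection(cross_correlogram(proj, targ))
  expect_true(fwd$significant)
  expect_gte(fwd$peak_lag_ms, 1.0)
  expect_lte(fwd$peak_lag_ms, 2.0)
  expect_gte(fwd$peak_left_ms, 0)
  expect_gte(fwd$peak_width_ms, 0.75)
  rev <- detect_connection(cross_correlogram(targ, proj))
  expect_false(rev$significant)
  # spike-count exclusions
  few <- detect_connection(cross_correlogram(proj[1:50], targ))
  expect_false(few$significant)
})

test_that("connection strength matches its limit cases and grows with p", {
  set.seed(93)
  proj <- simulate_poisson_train(10, 600)
  only_induced <- inject_connection(proj, 1.5, 1)
  cs <- connection_strength(proj, only_induced)
  expect_gt(cs$strength, 0.8)
  expect_null(connection_strength(proj, simulate_poisson_train(4, 600)))
  ms <- vapply(c(0.05, 0.1, 0.2), function(p) {
    s <- vapply(1:5, function(r) {
      pr <- simulate_poisson_train(10, 600)
      tg <- merge_spike_trains(simulate_poisson_train(5, 600),
                               inject_connection(pr, 1.5, p))
      out <- connection_strength(pr, tg)
      if (is.null(out)) NA_real_ else out$strength
    }, 0)
    mean(s, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(ms) > 0))
})

test_that("scan_connections recovers an injected pair and its direction", {
  set.seed(95)
  trains <- lapply(1:4, function(i) simulate_poisson_train(7, 600))
  trains[[2]] <- merge_spike_trains(trains[[2]],
                                    inject_connection(trains[[1]], 2, 0.2))
  found <- scan_connections(trains, depths = c(0, 100, 200, 300))
  expect_equal(nrow(found), 1)
  expect_equal(found$proj, "1")
  expect_equal(found$targ, "2")
  expect_equal(found$depth_dist_um, 100)
})

test_that("enrichment is 1 for a single category and seeded-stable", {
  pairs1 <- data.frame(proj = c("a", "b"), targ = c("c", "d"))
  cats1 <- c(a = "panresponsive", b = "panresponsive",
             c = "panresponsive", d = "panresponsive")
  en1 <- connection_type_enrichment(pairs1, cats1, n_resample = 100)
  expect_equal(en1$ratio["panresponsive", "panresponsive"], 1)
  # exclusive event-specific -> panresponsive wiring is enriched
  proj_nodes <- sprintf("p%d", 1:12); targ_nodes <- sprintf("t%d", 1:12)
  cats <- c(stats::setNames(rep(c("male_specific", "nonresponsive"),
                                c(8, 4)), proj_nodes),
            stats::setNames(rep(c("panresponsive", "nonresponsive"),
                                c(8, 4)), targ_nodes))
  pairs <- data.frame(proj = proj_nodes[1:8], targ = targ_nodes[1:8])
  pairs <- rbind(pairs, data.frame(proj = proj_nodes[9:12],
                                   targ = targ_nodes[9:12]))
  en <- connection_type_enrichment(pairs, cats, n_resample = 500, seed = 2)
  expect_gt(en$ratio["male_specific", "panresponsive"], 1)
  expect_lt(en$ratio["male_specific", "nonresponsive"], 1)
  en_same <- connection_type_enrichment(pairs, cats, n_resample = 500,
                                        seed = 2)
  expect_identical(en$ratio, en_same$ratio)
  en_other <- connection_type_enrichment(pairs, cats, n_resample = 500,
                                         seed = 3)
  expect_lt(abs(en$ratio["male_specific", "panresponsive"] -
                  en_other$ratio["male_specific", "panresponsive"]) /
              en$ratio["male_specific", "panresponsive"], 0.05)
})

test_that("paired epoch changes are zero on identical epochs and antisymmetric", {
  a <- data.frame(proj = c("x", "y", "z"), targ = c("u", "v", "w"),
                  strength = c(0.1, 0.2, 0.3))
  ch0 <- paired_epoch_strength_change(a, a)
  expect_equal(ch0$pairs$delta, c(0, 0, 0))
  b <- a; b$strength <- c(0.15, 0.3, 0.32)
  fwd <- paired_epoch_strength_change(a, b)
  bwd <- paired_epoch_strength_change(b, a)
  expect_equal(fwd$pairs$delta, -bwd$pairs$delta)
  expect_equal(fwd$mean_delta, -bwd$mean_delta)
})
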