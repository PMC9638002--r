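# minimal two-agent tracking table built from explicit part positions
mk_tracking <- function(n_frames, imp, con, likelihood = 1) {
  rows <- list()
  for (f in seq_len(n_frames)) {
    for (ag in c("implanted", "conspecific")) {
      parts <- if (ag == "implanted") imp else con
      for (nm in names(parts)) {
        p <- parts[[nm]]
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, agent = ag, bodypart = nm, x = p[1], y = p[2],
          likelihood = likelihood, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

imp_parts <- function(head = c(0, 0), tail = c(-7, 0)) {
  mid <- (head + tail) / 2
  list(head = head, headstage_left = head + c(-1, 1),
       headstage_right = head + c(-1, -1), nape_left = mid + c(1, 1),
       nape_center = mid + c(1, 0), nape_right = mid + c(1, -1),
       back_left = mid + c(0, 1), back_center = mid,
       back_right = mid + c(0, -1), tailbase = tail)
}

con_parts <- function(head = c(20, 0), tail = c(27, 0)) {
  mid <- (head + tail) / 2
  list(nose = head, ear_left = head + c(1, 1), ear_right = head + c(1, -1),
       nape_left = mid + c(-1, 1), nape_center = mid + c(-1, 0),
       nape_right = mid + c(-1, -1), back_left = mid + c(0, 1),
       back_center = mid, back_right = mid + c(0, -1), tailbase = tail)
}

test_that("clean_tracking is the identity on confident plausible data", {
  tr <- mk_tracking(4, imp_parts(), con_parts())
  out <- clean_tracking(tr)
  expect_equal(out$x, tr[order(tr$frame, tr$agent, tr$bodypart), ]$x)
  expect_false(any(out$interpolated))
})

test_that("clean_tracking interpolates dropped points linearly", {
  tr <- mk_tracking(3, imp_parts(), con_parts())
  i <- which(tr$frame == 2 & tr$agent == "implanted" &
               tr$bodypart == "head")
  tr$x[tr$agent == "implanted" & tr$bodypart == "head"] <- c(0, 99, 2)
  tr$y[tr$agent == "implanted" & tr$bodypart == "head"] <- c(0, 99, 2)
  tr$likelihood[i] <- 0.5
  out <- clean_tracking(tr)
  h <- out[out$agent == "implanted" & out$bodypart == "head", ]
  expect_equal(h$x, c(0, 1, 2))
  expect_equal(h$y, c(0, 1, 2))
  expect_equal(h$interpolated, c(FALSE, TRUE, FALSE))
})

test_that("simulated dropouts are fully repaired at the configured rate", {
  trk <- tracking_sim()
  cl <- clean_tracking(trk$tracking)
  expect_false(anyNA(cl$x))
  expect_lt(abs(mean(cl$interpolated) - 0.03), 0.015)
})

test_that("features match hand geometry", {
  # both rats stationary, heads at (0,0) and (3,4): 3-4-5 distance
  tr <- mk_tracking(5, imp_parts(head = c(0, 0), tail = c(-7, 0)),
                    con_parts(head = c(3, 4), tail = c(10, 4)))
  f <- compute_features(clean_tracking(tr), frame_rate = 30)
  expect_equal(ncol(f) - 1, 30)
  expect_true(all(f$imp_head_speed == 0))
  expect_true(all(f$con_tail_speed == 0))
  expect_equal(f$dist_head_head, rep(5, 5))
  # implanted at origin facing +x, conspecific head at (1,1): pi/4
  tr2 <- mk_tracking(3, imp_parts(head = c(0, 0), tail = c(-7, 0)),
                     con_parts(head = c(1, 1), tail = c(8, 1)))
  f2 <- compute_features(clean_tracking(tr2), frame_rate = 30)
  expect_equal(f2$imp_hd_to_con_head, rep(pi / 4, 3), tolerance = 1e-9)
})

test_that("relative features are invariant to arena rotation/translation", {
  trk <- tracking_sim()
  cl <- clean_tracking(trk$tracking)
  f0 <- compute_features(cl, 30)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- cl
  xy <- as.matrix(cl[, c("x", "y")]) %*% t(R)
  rot$x <- xy[, 1] + 12; rot$y <- xy[, 2] - 5
  f1 <- compute_features(rot, 30)
  invariant <- c("imp_head_speed", "con_head_speed", "imp_spine_len",
                 "imp_head_angvel", "dist_head_head", "dist_tail_tail",
                 "dist_imp_head_con_tail", "head_angle_diff",
                 "imp_hd_to_con_head", "con_hd_to_imp_tail",
                 "dd_headhead_minus_headtail",
                 "hd_diff_headhead_minus_headtail", "dist_centroid")
  for (col in invariant)
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-6)
})

test_that("the classifier memorizes separable training data", {
  set.seed(61)
  labs <- rep(behavior_labels(), each = 60)
  f <- matrix(rnorm(length(labs) * 30, sd = 0.1), length(labs), 30)
  for (k in seq_along(behavior_labels()))
    f[labs == behavior_labels()[k], k] <-
      f[labs == behavior_labels()[k], k] + 5
  colnames(f) <- sprintf("f%02d", 1:30)
  f <- as.data.frame(f)
  m <- train_behavior_classifier(f, labs)
  expect_equal(mean(classify_behavior(f, m) == labs), 1)
  expect_error(train_behavior_classifier(f, rep("non-social", nrow(f))),
               "head-head")
})

test_that("bout post-processing merges gaps then deletes short runs", {
  fr <- 30
  # 4-frame isolated run is deleted
  lab <- c(rep("non-social", 20), rep("approach", 4), rep("non-social", 20))
  out <- postprocess_bouts(lab, fr)
  expect_false("approach" %in% out$bouts$label)
  # two 10-frame runs separated by 3 frames (0.1 s < 0.25 s) merge to 23
  lab2 <- c(rep("non-social", 10), rep("head-head", 10),
            rep("non-social", 3), rep("head-head", 10),
            rep("non-social", 10))
  out2 <- postprocess_bouts(lab2, fr)
  hh <- out2$bouts[out2$bouts$label == "head-head", ]
  expect_equal(nrow(hh), 1)
  expect_equal(hh$n_frames, 23)
  # clean alternation with long gaps is unchanged
  lab3 <- rep(c(rep("head-head", 10), rep("non-social", 10)), 4)
  out3 <- postprocess_bouts(lab3, fr)
  expect_equal(out3$labels, lab3)
})

test_that("bout post-processing is idempotent", {
  set.seed(67)
  for (k in 1:10) {
    lab <- sample(behavior_labels(), 300, replace = TRUE,
                  prob = c(0.6, rep(0.4 / 6, 6)))
    once <- postprocess_bouts(lab, 30)
    twice <- postprocess_bouts(once$labels, 30)
    expect_identical(twice$labels, once$labels)
    expect_true(all(once$bouts$n_frames[once$bouts$label != "non-social"] >= 5))
  }
})

test_that("contact threshold recovers the class boundary", {
  set.seed(71)
  d_contact <- runif(200, 0, 4); d_far <- runif(200, 8, 12)
  fit <- fit_contact_threshold(c(d_contact, d_far),
                               c(rep(TRUE, 200), rep(FALSE, 200)))
  expect_equal(fit$balanced_accuracy, 1)
  expect_gt(fit$threshold, 4); expect_lt(fit$threshold, 8)
  g1 <- rnorm(3000, 5, 2); g2 <- rnorm(3000, 15, 2)
  fit2 <- fit_contact_threshold(c(g1, g2),
                                c(rep(TRUE, 3000), rep(FALSE, 3000)))
  expect_lt(abs(fit2$threshold - 10), 1)
  expect_error(fit_contact_threshold(d_contact, rep(TRUE, 200)),
               "degenerate")
  expect_equal(toy_interaction(c(3, 9), fit$threshold), c(TRUE, FALSE))
})

test_that("food interaction tests head position against the ROI", {
  roi <- list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  heads <- rbind(c(5, 5), c(15, 5))
  expect_equal(as.logical(food_interaction(heads, roi)), c(TRUE, FALSE))
})

test_that("interaction scores track mask-gated firing", {
  ev <- new_event_block("male", 1, 0, 300, 305, 600, 900)
  iv <- cbind(seq(305, 580, by = 40), seq(325, 600, by = 40))
  set.seed(73)
  # constant-rate unit: no interaction modulation
  st <- simulate_poisson_train(3, 900)
  r0 <- interaction_response_score(st, list(ev), list(iv))
  expect_equal(r0$class, "none")
  # 3x gain inside the mask
  lam <- function(t) {
    g <- rep(1, length(t))
    for (r in seq_len(nrow(iv))) g[t >= iv[r, 1] & t < iv[r, 2]] <- 3
    g
  }
  cand <- sort(runif(rpois(1, 3 * 3 * 900), 0, 900))
  st3 <- cand[runif(length(cand)) < lam(cand) / 3]
  r3 <- interaction_response_score(st3, list(ev), list(iv))
  expect_equal(r3$class, "increase")
  # antisymmetry under mask inversion
  inv <- cbind(c(300, iv[, 2]), c(iv[, 1], 600))
  inv <- inv[inv[, 2] > inv[, 1], , drop = FALSE]
  r_inv <- interaction_response_score(st3, list(ev), list(inv))
  expect_equal(r_inv$score, -r3$score, tolerance = 0.12)
})

test_that("peri-bout histograms flag injected onset responses", {
  set.seed(79)
  bouts <- sort(runif(50, 10, 580))
  bouts <- bouts[c(TRUE, diff(bouts) > 12)]
  base <- simulate_poisson_train(2, 600)
  extra <- unlist(lapply(bouts, function(b) b + sort(runif(6, 0, 1))))
  gated <- sort(c(base, extra))
  p1 <- behavior_peth(base, bouts)
  expect_false(p1$responsive)
  p2 <- behavior_peth(gated, bouts)
  expect_true(p2$responsive)
  # invariant to bout ordering
  p3 <- behavior_peth(gated, sample(bouts))
  expect_identical(p3$z, p2$z)
  expect_warning(p4 <- behavior_peth(base, bouts[1:3]), "bouts")
  expect_null(p4)
})

test_that("speed correlation classifies gated and independent units", {
  set.seed(83)
  tt <- seq(0, 600, by = 1 / 30)
  sp <- abs(stats::filter(rnorm(length(tt)), rep(1, 90) / 90,
                          sides = 2, circular = TRUE)) * 40
  lam_max <- 2 + max(sp)
  cand <- sort(runif(rpois(1, lam_max * 600), 0, 600))
  spc <- approx(tt, sp, xout = cand, rule = 2)$y
  pos <- cand[runif(length(cand)) < (1 + spc) / lam_max]
  neg <- cand[runif(length(cand)) < (1 + max(sp) - spc) / lam_max]
  ind <- simulate_poisson_train(4, 600)
  epochs <- list(c(0, 200), c(200, 400), c(400, 600))
  expect_equal(speed_correlation(pos, sp, tt, epochs)$class, "positive")
  expect_equal(speed_correlation(neg, sp, tt, epochs)$class, "negative")
  expect_equal(speed_correlation(ind, sp, tt, epochs)$class, "none")
  expect_error(speed_correlation(pos, rep(1, length(tt)), tt, epochs),
               "constant")
})
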