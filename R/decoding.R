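# -- internal regularized LDA ------------------------------------------------
# Features are standardized with training-fold statistics and projected onto
# at most (n_train - n_classes) principal components before MASS::lda, which
# keeps the within-class covariance nonsingular when units outnumber events.
# Uniform priors keep shuffle controls centred on analytic chance.

lda_fit <- function(X, y) {
  X <- as.matrix(X)
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) < nlevels(y))
    warning("training fold lacks class(es): ",
            paste(setdiff(levels(y), levels(droplevels(y))), collapse = ", "))
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes to fit a decoder")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, ctr, scl)
  pc <- stats::prcomp(Xs, center = FALSE)
  d <- max(1, min(nrow(X) - nlevels(y), sum(pc$sdev > 1e-8)))
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  fit <- suppressWarnings(
    MASS::lda(Xs %*% rot, grouping = y,
              prior = rep(1 / nlevels(y), nlevels(y))))
  list(center = ctr, scale = scl, rot = rot, lda = fit, levels = levels(y))
}

lda_predict <- function(fit, X, posterior = FALSE) {
  Xs <- scale(as.matrix(X), fit$center, fit$scale) %*% fit$rot
  pr <- stats::predict(fit$lda, Xs)
  if (posterior) pr$posterior else as.character(pr$class)
}

loo_accuracy <- function(features, labels) {
  n <- nrow(features)
  labels <- factor(labels)  # keep full level set inside each fold
  pred <- character(n)
  for (e in seq_len(n)) {
    fit <- lda_fit(features[-e, , drop = FALSE], labels[-e])
    pred[e] <- lda_predict(fit, features[e, , drop = FALSE])
  }
  list(pred = pred, accuracy = mean(pred == as.character(labels)))
}

#' Leave-one-out stimulus-identity decoder
#'
#' Linear-discriminant classification of stimulus class from per-event
#' population response-score vectors: the decoder is trained on all events
#' but one and tested on the held-out event, cycling through every event.
#' The chance level is estimated by repeating the whole procedure with
#' shuffled labels.
#'
#' @param features Events x units matrix of response scores.
#' @param labels Stimulus class per event.
#' @param n_shuffle Number of label shuffles for the control (default 500).
#' @param seed RNG seed for the shuffles.
#' @return Object of class `decode_report`: `protocol`, `predicted`,
#'   `truth`, `accuracy`, `shuffle_accuracies` (full distribution),
#'   `n_units`.
#' @export
loo_stimulus_decoder <- function(features, labels, n_shuffle = 500,
                                 seed = 1) {
  features <- as.matrix(features)
  res <- loo_accuracy(features, labels)
  shuf <- numeric(n_shuffle)
  if (n_shuffle > 0) {
    set.seed(seed)
    for (s in seq_len(n_shuffle))
      shuf[s] <- suppressWarnings(
        loo_accuracy(features, sample(labels))$accuracy)
  }
  structure(list(protocol = "stimulus_loo", predicted = res$pred,
                 truth = labels, accuracy = res$accuracy,
                 shuffle_accuracies = shuf, n_units = ncol(features)),
            class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat("<decode_report> ", x$protocol, ": accuracy ",
      sprintf("%.3f", x$accuracy), " (", x$n_units, " units",
      if (length(x$shuffle_accuracies))
        sprintf("; shuffle mean %.3f", mean(x$shuffle_accuracies)),
      ")\n", sep = "")
  invisible(x)
}

#' Decoding accuracy as a function of population size
#'
#' Leave-one-out accuracy for random unit subsets of increasing size.
#'
#' @param features Events x units score matrix.
#' @param labels Stimulus class per event.
#' @param n_grid Unit counts to evaluate (default: 2 up to all units on a
#'   doubling grid).
#' @param n_repeat Random subsets per count (default 500).
#' @param seed RNG seed.
#' @return data.frame `n_units`, `mean_accuracy`, `sd_accuracy`.
#' @export
neuron_dropping_curve <- function(features, labels, n_grid = NULL,
                                  n_repeat = 500, seed = 1) {
  features <- as.matrix(features)
  n_max <- ncol(features)
  if (is.null(n_grid)) {
    n_grid <- 2
    while (utils::tail(n_grid, 1) * 2 < n_max)
      n_grid <- c(n_grid, utils::tail(n_grid, 1) * 2)
    n_grid <- unique(c(n_grid, n_max))
  }
  if (any(n_grid > n_max)) stop("n_grid exceeds available units")
  set.seed(seed)
  out <- lapply(n_grid, function(n) {
    acc <- vapply(seq_len(n_repeat), function(r) {
      sel <- sample(n_max, n)
      suppressWarnings(
        loo_accuracy(features[, sel, drop = FALSE], labels)$accuracy)
    }, 0)
    data.frame(n_units = n, mean_accuracy = mean(acc),
               sd_accuracy = stats::sd(acc))
  })
  do.call(rbind, out)
}

#' Accuracy cost of omitting a unit category
#'
#' Compares leave-one-out accuracy without the omitted category against the
#' mean accuracy of random unit subsets of the same size (controlling for
#' neuron count).
#'
#' @param features Events x units score matrix.
#' @param labels Stimulus class per event.
#' @param categories Category label per unit (column).
#' @param omit Category to omit.
#' @param n_repeat Random matched subsets (default 500).
#' @param seed RNG seed.
#' @return List `accuracy_omitted`, `accuracy_matched` (mean over matched
#'   random subsets), `delta` (omitted minus matched), `n_omitted`.
#' @export
category_omission <- function(features, labels, categories, omit,
                              n_repeat = 500, seed = 1) {
  features <- as.matrix(features)
  if (!omit %in% categories)
    stop("category to omit is absent: ", omit)
  keep <- which(categories != omit)
  if (length(keep) < 2) stop("too few units left after omission")
  acc_omit <- suppressWarnings(
    loo_accuracy(features[, keep, drop = FALSE], labels)$accuracy)
  set.seed(seed)
  acc_match <- vapply(seq_len(n_repeat), function(r) {
    sel <- sample(ncol(features), length(keep))
    suppressWarnings(
      loo_accuracy(features[, sel, drop = FALSE], labels)$accuracy)
  }, 0)
  list(accuracy_omitted = acc_omit, accuracy_matched = mean(acc_match),
       delta = acc_omit - mean(acc_match),
       n_omitted = ncol(features) - length(keep))
}

#' Sliding-window decoding around first contact
#'
#' Leave-one-out stimulus decoding from response scores computed in a
#' sliding window of firing around each event's first-contact anchor, plus
#' a 5-s-epoch summary from 10 s before to 5 s after contact.
#'
#' @param session An `ethospike_session`.
#' @param scoring Result of [score_session()].
#' @param window_s Window width (s, default 10).
#' @param range_s Window-start offsets from contact (default `c(-30, 30)`;
#'   windows extending outside the block are truncated and flagged).
#' @param step_s Step between window starts (default 5).
#' @param min_spikes Passed to [response_score()].
#' @return List `trace` (offset_s, accuracy, truncated) and `epochs`
#'   (5-s epochs, accuracy).
#' @export
window_decoder <- function(session, scoring, window_s = 10,
                           range_s = c(-30, 30), step_s = 5,
                           min_spikes = 10) {
  prof <- scoring$profiles
  keep <- which(prof$responsive)
  if (length(keep) < 2) stop("need at least 2 responsive units")
  labels <- scoring$events$stimulus_class
  ev <- session$events

  decode_at <- function(offsets, win) {
    out <- list()
    for (off in offsets) {
      feats <- matrix(NA_real_, length(ev), length(keep))
      truncated <- FALSE
      for (e in seq_along(ev)) {
        blk <- ev[[e]]
        t0 <- blk$t_contact + off
        t1 <- t0 + win
        t0c <- max(t0, blk$t_baseline_start)
        t1c <- min(t1, blk$t_post_end)
        if (t0c > t0 || t1c < t1) truncated <- TRUE
        base <- c(blk$t_baseline_start, blk$t_presentation)
        for (u in seq_along(keep)) {
          st <- session$units[[keep[u]]]$spike_times
          feats[e, u] <- response_score(binned_rates(st, base, 1),
                                        binned_rates(st, c(t0c, t1c), 1),
                                        min_spikes, 1)
        }
      }
      acc <- suppressWarnings(loo_accuracy(feats, labels)$accuracy)
      out[[length(out) + 1]] <- data.frame(offset_s = off, accuracy = acc,
                                           truncated = truncated)
    }
    do.call(rbind, out)
  }
  trace <- decode_at(seq(range_s[1], range_s[2] - window_s, by = step_s),
                     window_s)
  epochs <- decode_at(c(-10, -5, 0), 5)
  names(epochs)[1] <- "epoch_start_s"
  list(trace = trace, epochs = epochs)
}

#' Population z-rate features for one event
#'
#' Bins x units matrix of firing rates in `bin_s` bins over the event
#' period, z-scored per unit against the event's baseline bins.
#'
#' @param session An `ethospike_session`.
#' @param event_index Index into `session$events`.
#' @param bin_s Bin width (s, default 1).
#' @param units Optional integer subset of units.
#' @return List `features` (bins x units), `bin_centers` (s).
#' @export
population_zrates <- function(session, event_index, bin_s = 1,
                              units = NULL) {
  blk <- session$events[[event_index]]
  if (is.null(units)) units <- seq_along(session$units)
  feats <- NULL
  for (i in units) {
    st <- session$units[[i]]$spike_times
    base <- binned_rates(st, c(blk$t_baseline_start, blk$t_presentation),
                         bin_s)
    evr <- binned_rates(st, c(blk$t_presentation, blk$t_event_end), bin_s)
    sdv <- max(stats::sd(base), (1 / bin_s) / sqrt(length(base)))
    feats <- cbind(feats, (evr - mean(base)) / sdv)
  }
  colnames(feats) <- unit_ids(session)[units]
  list(features = feats,
       bin_centers = blk$t_presentation +
         (seq_len(nrow(feats)) - 0.5) * bin_s)
}

#' Cross-validated binary-state decoding (interaction, movement)
#'
#' k-fold linear-discriminant decoding of a binary per-bin state (e.g.
#' interacting vs not, moving vs resting) from population z-rate features,
#' summarized as the ROC area of the held-out decision scores, with a
#' shuffle control.
#'
#' @param features Bins x units z-rate matrix (e.g. from
#'   [population_zrates()]).
#' @param labels Logical (or 2-level) state per bin; both values must occur.
#' @param k_folds Cross-validation folds (default 5).
#' @param n_shuffle Label shuffles for the control (default 100).
#' @param seed RNG seed (fold assignment and shuffles).
#' @return Object of class `decode_report` with `accuracy` holding the ROC
#'   area.
#' @export
interaction_decoder <- function(features, labels, k_folds = 5,
                                n_shuffle = 100, seed = 1) {
  features <- as.matrix(features)
  lab <- as.logical(labels)
  if (length(unique(lab)) < 2) stop("single-label event: decoding skipped")
  set.seed(seed)
  roc_area <- function(lab_use) {
    fold <- sample(rep_len(seq_len(k_folds), nrow(features)))
    score <- numeric(nrow(features))
    for (k in seq_len(k_folds)) {
      te <- fold == k
      if (length(unique(lab_use[!te])) < 2) return(NA_real_)
      fit <- lda_fit(features[!te, , drop = FALSE], lab_use[!te])
      post <- lda_predict(fit, features[te, , drop = FALSE],
                          posterior = TRUE)
      score[te] <- post[, "TRUE"]
    }
    auroc(score[!lab_use], score[lab_use])
  }
  auc <- roc_area(lab)
  shuf <- vapply(seq_len(n_shuffle), function(s) roc_area(sample(lab)), 0)
  structure(list(protocol = "binary_state", predicted = NULL, truth = lab,
                 accuracy = auc, shuffle_accuracies = shuf,
                 n_units = ncol(features)),
            class = "decode_report")
}

#' @rdname interaction_decoder
#' @export
movement_decoder <- interaction_decoder

#' Depth-restricted stimulus decoding
#'
#' Leave-one-out stimulus decoding using only units within a `window_um`
#' depth span; equals [loo_stimulus_decoder()] when every unit passes the
#' filter.
#'
#' @param features Events x units score matrix.
#' @param labels Stimulus class per event.
#' @param depths Unit depths (um), one per column.
#' @param center_um Window start depth; default slides the window to
#'   maximize the number of included units.
#' @param window_um Depth span (default 500).
#' @param min_units Minimum units required (default 10).
#' @param n_shuffle,seed Passed to [loo_stimulus_decoder()].
#' @return A `decode_report` with an extra `units_used` field.
#' @export
depth_restricted_decoder <- function(features, labels, depths,
                                     center_um = NULL, window_um = 500,
                                     min_units = 10, n_shuffle = 0,
                                     seed = 1) {
  features <- as.matrix(features)
  if (is.null(center_um)) {
    cand <- sort(unique(depths))
    counts <- vapply(cand, function(c0)
      sum(depths >= c0 & depths <= c0 + window_um), 0L)
    center_um <- cand[which.max(counts)]
  }
  sel <- which(depths >= center_um & depths <= center_um + window_um)
  if (length(sel) < min_units)
    stop("only ", length(sel), " units within ", window_um,
         " um; need at least ", min_units)
  rep_ <- loo_stimulus_decoder(features[, sel, drop = FALSE], labels,
                               n_shuffle = n_shuffle, seed = seed)
  rep_$units_used <- sel
  rep_
}
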