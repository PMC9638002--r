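#' Binned firing rates over an interval
#'
#' @param spike_times Sorted spike times (s).
#' @param interval `c(start, end)` in seconds, half-open.
#' @param bin_s Bin width (s), default 1. A trailing partial bin is dropped.
#' @return Numeric vector of rates (spikes/s), one per full bin.
#' @export
binned_rates <- function(spike_times, interval, bin_s = 1) {
  len <- interval[2] - interval[1]
  if (!is.finite(len) || len < bin_s)
    stop("interval shorter than one bin")
  n_bins <- floor(len / bin_s + 1e-9)
  st <- spikes_in(spike_times, c(interval[1], interval[1] + n_bins * bin_s))
  idx <- floor((st - interval[1]) / bin_s) + 1L
  idx[idx > n_bins] <- n_bins  # guard against edge rounding
  tabulate(idx, nbins = n_bins) / bin_s
}

# auROC of event vs baseline via the rank-sum identity with midrank ties
auroc <- function(baseline, event) {
  ne <- length(event); nb <- length(baseline)
  r <- rank(c(event, baseline))
  (sum(r[seq_len(ne)]) - ne * (ne + 1) / 2) / (ne * nb)
}

#' auROC response score of event vs baseline firing
#'
#' The score is `(auROC - 0.5) * 2` where the auROC compares the event-period
#' firing-rate distribution (positive class) against the baseline
#' distribution, with midrank handling of ties. Units with fewer than
#' `min_spikes` spikes pooled over both periods are assigned a score of 0
#' (too little data to estimate tuning).
#'
#' @param baseline_rates,event_rates Firing-rate sequences (spikes/s) from
#'   equal-width bins.
#' @param min_spikes Minimum pooled spike count (default 50).
#' @param bin_s Bin width (s) used to convert rates back to counts.
#' @return Score in `[-1, 1]`.
#' @export
response_score <- function(baseline_rates, event_rates, min_spikes = 50,
                           bin_s = 1) {
  if (!length(baseline_rates) || !length(event_rates))
    stop("baseline and event rate sequences must be non-empty")
  pooled <- (sum(baseline_rates) + sum(event_rates)) * bin_s
  if (pooled < min_spikes) return(0)
  (auroc(baseline_rates, event_rates) - 0.5) * 2
}

#' Categorize a unit from its per-class average scores
#'
#' Counts classes whose average score exceeds `theta`: exactly one gives the
#' event-specific category; two or more spanning the social (male/female)
#' and non-social (toy/food) sides gives `panresponsive`; two or more on one
#' side only gives `multimodal_social` / `multimodal_nonsocial`. With none
#' above `theta`, a class below `-theta` gives `decreased`, otherwise
#' `nonresponsive`.
#'
#' @param class_scores Named numeric of length 4 with names
#'   `male`, `female`, `toy`, `food`.
#' @param theta Responsiveness threshold (default 0.2).
#' @return Category string.
#' @export
classify_unit <- function(class_scores, theta = 0.2) {
  if (any(!is.finite(class_scores)))
    stop("non-finite class score")
  cs <- class_scores[stimulus_classes()]
  if (any(is.na(cs)))
    stop("class_scores must be named male/female/toy/food")
  up <- names(cs)[cs > theta]
  if (length(up) == 1)
    return(paste0(up, "_specific"))
  if (length(up) >= 2) {
    social <- any(up %in% c("male", "female"))
    nonsocial <- any(up %in% c("toy", "food"))
    if (social && nonsocial) return("panresponsive")
    return(if (social) "multimodal_social" else "multimodal_nonsocial")
  }
  if (any(cs < -theta)) return("decreased")
  "nonresponsive"
}

#' Categories counted as responsive
#' @return Character vector of category labels whose units enter population
#'   vectors and decoders.
#' @export
responsive_categories <- function() {
  c("male_specific", "female_specific", "toy_specific", "food_specific",
    "panresponsive", "multimodal_social", "multimodal_nonsocial")
}

#' Score and categorize every unit in a session
#'
#' Computes the per-event auROC response score (1-s bins, event period vs
#' the immediately preceding baseline), per-class averages over all
#' presentations of each class, and the category label.
#'
#' @param session An `ethospike_session`.
#' @param bin_s Rate bin width (s).
#' @param theta Responsiveness threshold.
#' @param min_spikes Pooled minimum spike count for a non-zero score.
#' @return List with `scores` (units x events matrix), `class_scores`
#'   (units x 4 matrix), `profiles` (data.frame unit_id, category,
#'   responsive) and `events` (event descriptors).
#' @export
score_session <- function(session, bin_s = 1, theta = 0.2, min_spikes = 50) {
  ev <- session$events
  ids <- unit_ids(session)
  classes <- vapply(ev, `[[`, "", "stimulus_class")
  scores <- matrix(NA_real_, length(ids), length(ev),
                   dimnames = list(ids, paste0(classes, "_",
                                               vapply(ev, `[[`, 0L,
                                                      "presentation_index"))))
  for (i in seq_along(session$units)) {
    st <- session$units[[i]]$spike_times
    for (e in seq_along(ev)) {
      ep <- event_epochs(ev[[e]])
      scores[i, e] <- response_score(binned_rates(st, ep$baseline, bin_s),
                                     binned_rates(st, ep$event, bin_s),
                                     min_spikes, bin_s)
    }
  }
  class_scores <- vapply(stimulus_classes(), function(cl)
    rowMeans(scores[, classes == cl, drop = FALSE]), numeric(length(ids)))
  if (is.null(dim(class_scores)))
    class_scores <- matrix(class_scores, nrow = 1,
                           dimnames = list(ids, stimulus_classes()))
  category <- apply(class_scores, 1, classify_unit, theta = theta)
  profiles <- data.frame(unit_id = ids, category = category,
                         responsive = category %in% responsive_categories(),
                         stringsAsFactors = FALSE)
  list(scores = scores, class_scores = class_scores, profiles = profiles,
       events = data.frame(index = seq_along(ev), stimulus_class = classes,
                           presentation_index = vapply(ev, `[[`, 0L,
                                                       "presentation_index"),
                           stringsAsFactors = FALSE))
}

#' Correlation matrix of population response vectors
#'
#' Pearson correlations between per-event population vectors (ordered unit
#' scores over the responsive units).
#'
#' @param score_matrix Units x events score matrix restricted to a common
#'   unit ordering (e.g. `score_session()$scores` subset to responsive
#'   units).
#' @return Symmetric events x events correlation matrix with unit diagonal.
#'   Zero-variance vectors give `NA` entries with a warning, never a silent
#'   0.
#' @export
population_correlation <- function(score_matrix) {
  if (ncol(score_matrix) < 2) stop("need at least 2 population vectors")
  sds <- apply(score_matrix, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance population vector(s): ",
            paste(colnames(score_matrix)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  cc <- suppressWarnings(stats::cor(score_matrix))
  cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  diag(cc) <- 1
  cc
}

#' Anatomical clustering of a unit category along the probe
#'
#' Mean pairwise absolute depth distance within a category, compared with
#' the all-units pairwise-distance distribution by a rank-based test.
#'
#' @param category_depths Depths (um) of the units in the category (>= 2).
#' @param all_depths Depths (um) of all units.
#' @return List `mean_category`, `mean_all`, `test`
#'   (a `wilcox.test` result on the two pairwise-distance sets).
#' @export
pairwise_depth_stat <- function(category_depths, all_depths) {
  if (length(category_depths) < 2)
    stop("pairwise depth statistic undefined for a singleton category")
  pd <- function(d) {
    m <- abs(outer(d, d, "-"))
    m[upper.tri(m)]
  }
  d_cat <- pd(category_depths)
  d_all <- pd(all_depths)
  list(mean_category = mean(d_cat), mean_all = mean(d_all),
       test = suppressWarnings(stats::wilcox.test(d_cat, d_all)))
}
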