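#' Serial-position regions of the 15-item list
#'
#' Serial-position process scores split the list into primacy, midlist and
#' recency regions.  The default cut points (primacy 1--4, midlist 5--11,
#' recency 12--15) follow the common convention for 15-item list-learning
#' instruments; they are configurable because different labs use different
#' cuts.
#'
#' @param primacy,midlist,recency Integer vectors of list positions.  Must be
#'   disjoint and jointly cover 1--15.
#' @return A `vlt_regions` object (named list of position vectors).
#' @export
serial_regions <- function(primacy = 1:4, midlist = 5:11, recency = 12:15) {
  all_pos <- sort(c(primacy, midlist, recency))
  if (!identical(as.integer(all_pos), 1:15)) {
    stop("regions must be disjoint and cover positions 1..15 exactly")
  }
  structure(list(primacy = as.integer(primacy),
                 midlist = as.integer(midlist),
                 recency = as.integer(recency)),
            class = "vlt_regions")
}

REGION_NAMES <- c("primacy", "midlist", "recency")

#' Count-level features of a scored session
#'
#' Per-trial correct counts, total immediate recall (sum of trials 1--5,
#' range 0--75), delayed recall (0--15), recognition true/false positives,
#' per-trial repetitions and intrusions, and the count of first-correct
#' recalls with onset within the first 10 seconds of each recall phase.
#' Missing subtests yield missing features, never zeros.
#'
#' @param scored A `vlt_scored_session` from [score_session()].
#' @return Named numeric vector.
#' @export
compute_count_features <- function(scored) {
  counts <- scored$counts
  out <- c(stats::setNames(as.numeric(counts[IMMEDIATE_LABELS]),
                           paste0("immediate_count_trial_", 1:5)),
           total_immediate_recall =
             if (anyNA(counts[IMMEDIATE_LABELS])) NA_real_
             else sum(counts[IMMEDIATE_LABELS]),
           delayed_recall = as.numeric(counts[["DELAYED"]]),
           recognition_true_positives =
             as.numeric(scored$recognition[["true_positives"]]),
           recognition_false_positives =
             as.numeric(scored$recognition[["false_positives"]]))
  per_trial <- function(field, prefix) {
    v <- stats::setNames(rep(NA_real_, 6L), TRIAL_LABELS)
    if (!is.null(scored$trials)) {
      for (s in scored$trials) v[s$trial_label] <- as.numeric(s[[field]])
    }
    tot <- if (anyNA(v[IMMEDIATE_LABELS])) NA_real_
           else sum(v[IMMEDIATE_LABELS])
    c(stats::setNames(v[IMMEDIATE_LABELS], paste0(prefix, "_trial_", 1:5)),
      stats::setNames(v[["DELAYED"]], paste0(prefix, "_delayed")),
      stats::setNames(tot, paste0("total_", prefix)))
  }
  c(out,
    per_trial("repetitions", "repetitions"),
    per_trial("intrusions", "intrusions"),
    per_trial("within_10s_count", "within_10s_count")[
      c(paste0("within_10s_count_trial_", 1:5), "total_within_10s_count")])
}

#' Serial-position features of a scored session
#'
#' Per trial and region: the number of recalled items whose list position
#' falls in the region, plus per-region totals over the five immediate
#' trials, the delayed-recall region counts, and region proportions
#' (count / region size).  Region counts per trial always sum to the trial's
#' correct count.
#'
#' @param scored A `vlt_scored_session` (token-level; count-only variants
#'   yield all-missing region features).
#' @param regions A [serial_regions()] object.
#' @return Named numeric vector.
#' @export
compute_serial_position_features <- function(scored,
                                             regions = serial_regions()) {
  out <- numeric(0)
  region_count <- function(correct_set, region) {
    length(intersect(correct_set, region))
  }
  for (r in REGION_NAMES) {
    per_trial <- rep(NA_real_, 5L)
    for (t in 1:5) {
      s <- scored$trials[[IMMEDIATE_LABELS[t]]]
      if (!is.null(s)) per_trial[t] <- region_count(s$correct_set, regions[[r]])
    }
    tot <- if (anyNA(per_trial)) NA_real_ else sum(per_trial)
    sd_ <- scored$trials[["DELAYED"]]
    del <- if (is.null(sd_)) NA_real_
           else region_count(sd_$correct_set, regions[[r]])
    rs <- length(regions[[r]])
    out <- c(out,
             stats::setNames(per_trial,
                             paste0("immediate_", r, "_items_trial_", 1:5)),
             stats::setNames(per_trial / rs,
                             paste0("immediate_", r, "_proportion_trial_", 1:5)),
             stats::setNames(tot, paste0("immediate_total_", r, "_items")),
             stats::setNames(tot / (5 * rs),
                             paste0("immediate_total_", r, "_proportion")),
             stats::setNames(del, paste0("delayed_recall_", r, "_items")),
             stats::setNames(del / rs,
                             paste0("delayed_recall_", r, "_proportion")))
  }
  out
}

ls_slope <- function(y, x) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Learning-slope features from per-trial correct counts
#'
#' Overall slope is the least-squares slope of correct count on trial index
#' (1--5); early restricts to trials 1--3 and late to trials 3--5 (three-point
#' regressions).  Peak slope is the largest single-trial gain
#' max(count[t+1] - count[t]); simple gain is count[5] - count[1].  All five
#' features are missing if any immediate count is missing.
#'
#' @param counts Numeric vector of the five immediate correct counts
#'   (trials 1--5, in order).
#' @return Named numeric vector of `overall_learning_slope`,
#'   `early_learning_slope`, `late_learning_slope`, `peak_learning_slope`,
#'   `simple_gain`.
#' @export
compute_slope_features <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 5L) stop("need exactly five immediate counts")
  if (anyNA(counts)) {
    return(c(overall_learning_slope = NA_real_,
             early_learning_slope = NA_real_,
             late_learning_slope = NA_real_,
             peak_learning_slope = NA_real_, simple_gain = NA_real_))
  }
  c(overall_learning_slope = ls_slope(counts, 1:5),
    early_learning_slope = ls_slope(counts[1:3], 1:3),
    late_learning_slope = ls_slope(counts[3:5], 3:5),
    peak_learning_slope = max(diff(counts)),
    simple_gain = counts[5] - counts[1])
}

#' Item-consistency features across trials
#'
#' The constancy learning index is the consecutive-trial recall overlap
#' ratio: sum over t = 1..4 of |C_t intersect C_(t+1)| divided by the sum of
#' |C_t|, where C_t is the set of list positions recalled at trial t
#' (missing when the denominator is zero).  Gained/lost counts track items
#' entering and leaving the recalled set between consecutive trials.
#' Savings is delayed recall divided by trial-5 recall, a consolidation
#' measure (missing when trial-5 recall is zero).
#'
#' @param scored A token-level `vlt_scored_session`.
#' @return Named numeric vector.
#' @export
compute_consistency_features <- function(scored) {
  sets <- lapply(IMMEDIATE_LABELS, function(l) {
    s <- scored$trials[[l]]
    if (is.null(s)) NULL else s$correct_set
  })
  gained <- lost <- rep(NA_real_, 4L)
  overlap_num <- overlap_den <- NA_real_
  if (!any(vapply(sets, is.null, logical(1)))) {
    ov <- vapply(1:4, function(t) length(intersect(sets[[t]], sets[[t + 1]])),
                 numeric(1))
    gained <- vapply(1:4, function(t) length(setdiff(sets[[t + 1]], sets[[t]])),
                     numeric(1))
    lost <- vapply(1:4, function(t) length(setdiff(sets[[t]], sets[[t + 1]])),
                   numeric(1))
    overlap_num <- sum(ov)
    overlap_den <- sum(lengths(sets[1:4]))
  }
  cli <- if (is.na(overlap_den) || overlap_den == 0) NA_real_
         else overlap_num / overlap_den
  c5 <- scored$counts[["T5"]]
  del <- scored$counts[["DELAYED"]]
  savings <- if (is.na(c5) || is.na(del) || c5 == 0) NA_real_ else del / c5
  c(constancy_learning_index = cli,
    stats::setNames(gained, paste0("words_gained_trial_", 2:5)),
    stats::setNames(lost, paste0("words_lost_trial_", 2:5)),
    total_words_gained = if (anyNA(gained)) NA_real_ else sum(gained),
    total_words_lost = if (anyNA(lost)) NA_real_ else sum(lost),
    savings = savings)
}

serial_cluster_count <- function(order, bidirectional = FALSE) {
  if (length(order) < 2L) return(0)
  d <- diff(order)
  if (bidirectional) sum(abs(d) == 1) else sum(d == 1)
}

#' Pair-frequency subjective organization between two output orders
#'
#' O is the number of unordered item pairs recalled adjacently (in either
#' order) in both trials; the chance-expected value 2c(c-1)/(h k) is
#' subtracted, where h and k are the two trials' correct counts and c the
#' number of shared items.  Under random output order within fixed recall
#' sets the measure has expectation zero.
#'
#' @param order1,order2 Integer vectors of list positions in first-recall
#'   order for two consecutive trials.
#' @return The PF score, or `NA` when h*k = 0.
#' @export
pair_frequency <- function(order1, order2) {
  h <- length(order1)
  k <- length(order2)
  if (h * k == 0) return(NA_real_)
  adj_pairs <- function(ord) {
    if (length(ord) < 2L) return(character(0))
    a <- ord[-length(ord)]
    b <- ord[-1]
    unique(paste(pmin(a, b), pmax(a, b)))
  }
  O <- length(intersect(adj_pairs(order1), adj_pairs(order2)))
  c <- length(intersect(order1, order2))
  O - 2 * c * (c - 1) / (h * k)
}

#' Output-organization features of a scored session
#'
#' Serial clustering counts adjacent output pairs whose list positions are
#' consecutive in presentation order (forward chaining by default;
#' `bidirectional = TRUE` also counts backward steps).  Subjective
#' organization is the chance-corrected pair-frequency measure
#' [pair_frequency()] between consecutive immediate trials.
#'
#' @param scored A token-level `vlt_scored_session`.
#' @param bidirectional Count backward-adjacent list pairs as clusters too?
#' @return Named numeric vector.
#' @export
compute_organization_features <- function(scored, bidirectional = FALSE) {
  orders <- lapply(TRIAL_LABELS, function(l) {
    s <- scored$trials[[l]]
    if (is.null(s)) NULL else s$first_recall_order
  })
  names(orders) <- TRIAL_LABELS
  sc <- vapply(TRIAL_LABELS, function(l) {
    if (is.null(orders[[l]])) NA_real_
    else serial_cluster_count(orders[[l]], bidirectional)
  }, numeric(1))
  pf <- vapply(1:4, function(t) {
    o1 <- orders[[IMMEDIATE_LABELS[t]]]
    o2 <- orders[[IMMEDIATE_LABELS[t + 1]]]
    if (is.null(o1) || is.null(o2)) NA_real_ else pair_frequency(o1, o2)
  }, numeric(1))
  c(stats::setNames(sc[IMMEDIATE_LABELS], paste0("serial_clusters_trial_", 1:5)),
    serial_clusters_delayed = as.numeric(sc[["DELAYED"]]),
    total_serial_clusters = if (anyNA(sc[IMMEDIATE_LABELS])) NA_real_
                            else sum(sc[IMMEDIATE_LABELS]),
    stats::setNames(pf, paste0("subjective_organization_t", 1:4, "_t", 2:5)),
    total_subjective_organization = if (anyNA(pf)) NA_real_ else sum(pf))
}

#' All process-score features for one session variant
#'
#' Assembles the full feature catalog: counts, serial-position regions,
#' learning slopes, item consistency, output organization, and recall
#' timing.  Features whose inputs are unavailable (count-only variants,
#' missing onsets, missing trials) are `NA`, never zero-filled; imputation
#' is an explicit later step.
#'
#' @param session A [vlt_session].
#' @param rater Which variant to use.
#' @param word_list Word list; defaults to the built-in list matching
#'   `session$list_id`.
#' @param regions A [serial_regions()] object.
#' @return Named numeric vector in stable catalog order.
#' @export
vlt_features <- function(session, rater = "asr", word_list = NULL,
                         regions = serial_regions()) {
  scored <- score_session(session, rater = rater, word_list = word_list)
  counts5 <- scored$counts[IMMEDIATE_LABELS]
  c(compute_count_features(scored),
    compute_serial_position_features(scored, regions),
    compute_slope_features(counts5),
    compute_consistency_features(scored),
    compute_organization_features(scored))
}

#' Feature table for a cohort of sessions
#'
#' @param sessions List of [vlt_session] objects (unique participant ids).
#' @param rater Which variant to extract features from.
#' @param word_lists Named list of word lists keyed by `list_id`; defaults to
#'   the built-in synthetic lists.
#' @param regions A [serial_regions()] object.
#' @param metadata Optional data frame with a `participant_id` column to
#'   left-join onto the table.
#' @return Data frame: `participant_id`, `rater`, metadata columns, then the
#'   feature catalog in stable order.
#' @export
vlt_feature_table <- function(sessions, rater = "asr", word_lists = NULL,
                              regions = serial_regions(), metadata = NULL) {
  if (length(sessions) < 1L) stop("need at least one session")
  ids <- vapply(sessions, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id: ", ids[duplicated(ids)][1])
  }
  rows <- lapply(sessions, function(s) {
    wl <- if (is.null(word_lists)) NULL else word_lists[[s$list_id]]
    vlt_features(s, rater = rater, word_list = wl, regions = regions)
  })
  feat <- do.call(rbind, rows)
  out <- data.frame(participant_id = ids, rater = rater,
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    stopifnot("participant_id" %in% names(metadata))
    out <- merge(out, metadata, by = "participant_id", all.x = TRUE,
                 sort = FALSE)
    out <- out[match(ids, out$participant_id), , drop = FALSE]
  }
  out <- cbind(out, as.data.frame(feat))
  rownames(out) <- NULL
  out
}

#' Names of all features in the catalog
#'
#' @param regions A [serial_regions()] object (region names are fixed; the
#'   argument exists for forward compatibility).
#' @return Character vector in stable catalog order.
#' @export
vlt_feature_names <- function(regions = serial_regions()) {
  wl <- vlt_word_lists()[[1]]
  s <- vlt_session("template", wl$list_id, list(
    vlt_variant("asr",
                trials = lapply(TRIAL_LABELS, vlt_trial, tokens = character()),
                recognition = vlt_recognition(
                  c(wl$targets, wl$foils), rep(c(TRUE, FALSE), each = 15),
                  rep(FALSE, 30)))))
  names(vlt_features(s, "asr", word_list = wl, regions = regions))
}

#' Data dictionary for the feature catalog
#'
#' @param regions A [serial_regions()] object.
#' @return Data frame with columns `feature`, `family`, `range`.
#' @export
vlt_feature_dictionary <- function(regions = serial_regions()) {
  nm <- vlt_feature_names(regions)
  fam <- rep("count", length(nm))
  fam[grepl("_(primacy|midlist|recency)_", nm)] <- "serial_position"
  fam[grepl("slope|simple_gain", nm)] <- "slope"
  fam[grepl("constancy|gained|lost|savings", nm)] <- "consistency"
  fam[grepl("serial_clusters|subjective_organization", nm)] <- "organization"
  fam[grepl("within_10s", nm)] <- "timing"
  rng <- rep("[0, Inf)", length(nm))
  rng[grepl("proportion|savings", nm)] <- "[0, 1]"
  rng[grepl("slope|simple_gain|subjective_organization", nm)] <-
    "(-Inf, Inf)"
  rng[nm == "total_immediate_recall"] <- "[0, 75]"
  rng[nm %in% c("delayed_recall", "recognition_true_positives",
                "recognition_false_positives")] <- "[0, 15]"
  rng[nm == "constancy_learning_index"] <- "[0, 1]"
  data.frame(feature = nm, family = fam, range = rng,
             stringsAsFactors = FALSE)
}
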