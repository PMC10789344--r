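make_orders <- function(c1, c2, c3, c4, c5, del) {
  list(T1 = c1, T2 = c2, T3 = c3, T4 = c4, T5 = c5, DELAYED = del)
}

test_that("count features sum per-trial counts into totals", {
  s <- toy_session(make_orders(1:5, 1:7, 1:8, 1:9, 1:10, 1:8),
                   recognition = toy_recognition(12, 2))
  f <- vlt_features(s, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(f[paste0("immediate_count_trial_", 1:5)]),
               c(5, 7, 8, 9, 10))
  expect_equal(unname(f["total_immediate_recall"]), 39)
  expect_equal(unname(f["delayed_recall"]), 8)
  expect_equal(unname(f["recognition_true_positives"]), 12)
  expect_equal(unname(f["recognition_false_positives"]), 2)

  empty <- toy_session(make_orders(integer(), integer(), integer(),
                                   integer(), integer(), integer()))
  fe <- vlt_features(empty, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(fe["total_immediate_recall"]), 0)
})

test_that("serial-position region counts follow set intersections", {
  orders <- make_orders(c(1, 2, 8, 15), 1:15, integer(), c(5), c(12),
                        integer())
  s <- toy_session(orders)
  f <- vlt_features(s, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(f["immediate_primacy_items_trial_1"]), 2)
  expect_equal(unname(f["immediate_midlist_items_trial_1"]), 1)
  expect_equal(unname(f["immediate_recency_items_trial_1"]), 1)
  expect_equal(unname(f["immediate_midlist_items_trial_2"]), 7)  # saturation
  expect_equal(unname(f["immediate_primacy_items_trial_3"]), 0)
  expect_equal(unname(f["immediate_midlist_proportion_trial_2"]), 1)
})

test_that("count-only clinical variants degrade to count-level features", {
  v <- vlt_variant("clinical",
                   counts = c(T1 = 4, T2 = 6, T3 = 7, T4 = 8, T5 = 9,
                              DELAYED = 6, recognition_tp = 13,
                              recognition_fp = 1))
  s <- vlt_session("p1", "toy", list(v))
  f <- vlt_features(s, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(f["total_immediate_recall"]), 34)
  expect_equal(unname(f["overall_learning_slope"]), slope_oracle(c(4, 6, 7, 8, 9)))
  expect_true(is.na(f["immediate_midlist_items_trial_3"]))
  expect_true(is.na(f["constancy_learning_index"]))
  expect_true(is.na(f["total_serial_clusters"]))
  expect_equal(unname(f["recognition_true_positives"]), 13)
})

test_that("learning slopes match the closed-form least-squares oracle", {
  f <- compute_slope_features(c(3, 5, 7, 9, 11))
  expect_equal(unname(f["overall_learning_slope"]), 2)
  expect_equal(unname(f["peak_learning_slope"]), 2)
  expect_equal(unname(f["simple_gain"]), 8)
  expect_equal(unname(compute_slope_features(rep(5, 5))),
               c(0, 0, 0, 0, 0), ignore_attr = TRUE)

  g <- compute_slope_features(c(2, 6, 7, 7, 10))
  expect_equal(unname(g["overall_learning_slope"]), slope_oracle(c(2, 6, 7, 7, 10)))
  expect_equal(unname(g["early_learning_slope"]),
               unname(stats::coef(stats::lm(c(2, 6, 7) ~ I(1:3)))[2]))
  expect_equal(unname(g["late_learning_slope"]),
               unname(stats::coef(stats::lm(c(7, 7, 10) ~ I(3:5)))[2]))
  set.seed(21)
  for (i in 1:20) {
    counts <- sample(0:15, 5, replace = TRUE)
    expect_identical(unname(compute_slope_features(counts)["overall_learning_slope"]),
                     slope_oracle(counts))
  }
  expect_true(all(is.na(compute_slope_features(c(3, NA, 5, 6, 7)))))
})

test_that("constancy index and gained/lost follow consecutive-trial set overlap", {
  same <- toy_session(make_orders(1:6, 1:6, 1:6, 1:6, 1:6, 1:6))
  f <- vlt_features(same, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(f["constancy_learning_index"]), 1)
  expect_equal(unname(f["total_words_gained"]), 0)
  expect_equal(unname(f["total_words_lost"]), 0)
  expect_equal(unname(f["savings"]), 1)

  disjoint <- toy_session(make_orders(1:3, 4:6, 7:9, 10:12, 13:15, integer()))
  fd <- vlt_features(disjoint, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(fd["constancy_learning_index"]), 0)

  hand <- toy_session(make_orders(c(1, 2), c(2, 3, 4), c(2, 3, 4),
                                  c(2, 3, 4), c(2, 3, 4), integer()))
  fh <- vlt_features(hand, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(fh["constancy_learning_index"]), 10 / 11)
  expect_equal(unname(fh["words_gained_trial_2"]), 2)
  expect_equal(unname(fh["words_lost_trial_2"]), 1)
  expect_equal(unname(fh["savings"]), 0)  # delayed 0, trial-5 count 3

  none5 <- toy_session(make_orders(1:2, 1:2, 1:2, 1:2, integer(), integer()))
  fn <- vlt_features(none5, rater = "clinical", word_list = toy_word_list())
  expect_true(is.na(fn["savings"]))
})

test_that("serial clusters count forward list-adjacent output pairs", {
  inorder <- toy_session(make_orders(1:15, integer(), integer(), integer(),
                                     integer(), integer()))
  f <- vlt_features(inorder, rater = "clinical", word_list = toy_word_list())
  expect_equal(unname(f["serial_clusters_trial_1"]), 14)

  sc <- score_trial(toy_trial("T1", c(3, 4, 2, 1, 10, 11, 12)),
                    toy_word_list())
  expect_equal(vltkit:::serial_cluster_count(sc$first_recall_order), 3)
  expect_equal(vltkit:::serial_cluster_count(sc$first_recall_order,
                                             bidirectional = TRUE), 4)
})

test_that("pair-frequency subjective organization is chance-corrected", {
  expect_equal(pair_frequency(c(4, 2, 3, 10), c(3, 2, 11, 4)), 0.25)
  expect_true(is.na(pair_frequency(integer(), integer())))
  expect_true(is.na(pair_frequency(c(1, 2), integer())))

  # under random output order within fixed recall sets, E[PF] = 0
  set.seed(31)
  s1 <- c(1, 3, 5, 7, 9, 11, 13)
  s2 <- c(1, 2, 3, 5, 7, 8, 11, 14)
  pf <- replicate(3000, pair_frequency(sample(s1), sample(s2)))
  se <- stats::sd(pf) / sqrt(length(pf))
  expect_lt(abs(mean(pf)), 3 * se)
})

test_that("region counts sum to trial counts on simulated sessions", {
  set.seed(41)
  params <- default_group_params("scd")
  for (i in 1:200) {
    s <- simulate_session(params, u = stats::rnorm(1, 0, params$sigma_u),
                          word_list = vlt_word_lists()[[1]])
    f <- vlt_features(s, rater = "clinical")
    for (t in 1:5) {
      regsum <- sum(f[paste0("immediate_", c("primacy", "midlist", "recency"),
                             "_items_trial_", t)])
      expect_identical(regsum, unname(f[paste0("immediate_count_trial_", t)]))
    }
    expect_identical(unname(f["total_immediate_recall"]),
                     sum(f[paste0("immediate_count_trial_", 1:5)]))
  }
})

test_that("the feature catalog is complete and stably named", {
  nm <- vlt_feature_names()
  expect_gte(length(nm), 60)
  expect_false(anyDuplicated(nm) > 0)
  top10 <- c("delayed_recall", "immediate_midlist_items_trial_3",
             "delayed_recall_midlist_items", "late_learning_slope",
             "immediate_total_midlist_items", "immediate_count_trial_5",
             "total_immediate_recall", "immediate_count_trial_4",
             "delayed_recall_recency_items", "immediate_count_trial_3")
  expect_true(all(top10 %in% nm))
  dict <- vlt_feature_dictionary()
  expect_identical(dict$feature, nm)
})

test_that("feature tables are rectangular with unique participants", {
  set.seed(51)
  cfg <- cohort_config(n_scd = 3, n_mci = 3, n_dementia = 0, seed = 7)
  co <- simulate_cohort(cfg)
  tab <- vlt_feature_table(co$sessions, rater = "asr",
                           metadata = co$metadata)
  expect_equal(nrow(tab), 6)
  expect_true(all(vlt_feature_names() %in% names(tab)))
  expect_identical(tab$participant_id, co$metadata$participant_id)
  expect_error(vlt_feature_table(co$sessions[c(1, 1)]), "duplicate")
  # ASR variant carries no intrusions by construction
  expect_true(all(tab$total_intrusions == 0, na.rm = TRUE))
})

test_that("serial regions must partition the list", {
  expect_error(serial_regions(1:4, 5:10, 12:15), "cover")
  expect_error(serial_regions(1:5, 5:11, 12:15), "cover")
  r <- serial_regions(1:3, 4:12, 13:15)
  expect_equal(length(r$midlist), 9)
})
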