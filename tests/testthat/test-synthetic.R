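test_that("limit cases of the recall model behave as expected", {
  wl <- vlt_word_lists()[[1]]
  set.seed(181)
  # floor: no learning at all; delayed recall is pure reminiscence
  p_floor <- group_params(alpha = -50, beta = 0, primacy_boost = 0,
                          recency_boost = 0, sigma_u = 0, eps = 0.2,
                          intrusion_rate = 0, repetition_rate = 0)
  dels <- replicate(400, {
    s <- simulate_session(p_floor, u = 0, word_list = wl)
    sc <- score_session(s, "clinical", wl)
    expect_equal(sum(sc$counts[paste0("T", 1:5)]), 0)
    sc$counts[["DELAYED"]]
  })
  se <- sqrt(15 * 0.2 * 0.8 / 400)
  expect_lt(abs(mean(dels) - 15 * 0.2), 3 * se)
})

test_that("per-trial counts match the binomial expectation oracle", {
  wl <- vlt_word_lists()[[1]]
  set.seed(191)
  p <- group_params(alpha = -0.4, beta = 0, primacy_boost = 0,
                    recency_boost = 0, sigma_u = 0, intrusion_rate = 0,
                    repetition_rate = 0)
  prob <- 1 / (1 + exp(0.4))
  counts <- replicate(2000, {
    s <- simulate_session(p, u = 0, word_list = wl)
    score_session(s, "clinical", wl)$counts[["T3"]]
  })
  se <- sqrt(15 * prob * (1 - prob) / 2000)
  expect_lt(abs(mean(counts) - 15 * prob), 3 * se)
})

test_that("output order interpolates between list order and previous output", {
  wl <- vlt_word_lists()[[1]]
  set.seed(201)
  # order_mix = 0, no jitter: output is exactly in presentation order
  p0 <- group_params(alpha = 0.5, order_mix = 0, order_noise = 0,
                     intrusion_rate = 0, repetition_rate = 0)
  for (i in 1:5) {
    s <- simulate_session(p0, u = 0, word_list = wl)
    sc <- score_session(s, "clinical", wl)
    for (t in paste0("T", 1:5)) {
      ord <- sc$trials[[t]]$first_recall_order
      expect_identical(ord, sort(ord))
      # clusters = consecutive-position adjacencies of the recalled set
      expect_equal(vltkit:::serial_cluster_count(ord),
                   sum(diff(sort(ord)) == 1))
    }
  }
  # order_mix = 1, no jitter: words recalled in consecutive trials keep
  # their previous relative output order
  p1 <- group_params(alpha = 0.5, order_mix = 1, order_noise = 0,
                     intrusion_rate = 0, repetition_rate = 0)
  for (i in 1:5) {
    s <- simulate_session(p1, u = 0, word_list = wl)
    sc <- score_session(s, "clinical", wl)
    for (t in 1:4) {
      prev <- sc$trials[[paste0("T", t)]]$first_recall_order
      cur <- sc$trials[[paste0("T", t + 1)]]$first_recall_order
      shared <- intersect(prev, cur)
      expect_identical(cur[cur %in% shared], prev[prev %in% shared])
    }
  }
  # for a contiguous recalled set in list order, clusters = count - 1
  expect_equal(vltkit:::serial_cluster_count(4:11), 7)
})

test_that("the ASR miss process degrades transcripts as configured", {
  wl <- vlt_word_lists()[[1]]
  set.seed(211)
  s <- simulate_session(default_group_params("scd"), u = 0.5, word_list = wl)

  clean <- apply_asr_noise(s, asr_noise_params(0, 1, 0), word_list = wl)
  fc <- vlt_features(clean, "clinical", wl)
  fa <- vlt_features(clean, "asr", wl)
  expect_equal(fa["total_immediate_recall"], fc["total_immediate_recall"],
               ignore_attr = TRUE)
  expect_equal(unname(fa["total_intrusions"]), 0)

  dead <- apply_asr_noise(s, asr_noise_params(1, 1, 1), word_list = wl)
  fd <- vlt_features(dead, "asr", wl)
  expect_equal(unname(fd["total_immediate_recall"]), 0)
  expect_equal(unname(fd["delayed_recall"]), 0)
})

test_that("fast unpaused speech concentrates misses in high scorers", {
  wl <- vlt_word_lists()[[1]]
  set.seed(221)
  p <- default_group_params("scd")
  noise <- asr_noise_params(base_miss = 0.02, fast_gap_s = 1.5,
                            fast_miss = 0.6)
  res <- t(replicate(500, {
    u <- stats::rnorm(1, 0, p$sigma_u)
    s <- apply_asr_noise(simulate_session(p, u, wl), noise, word_list = wl)
    c(clin = sum(score_session(s, "clinical", wl)$counts[paste0("T", 1:5)]),
      asr = sum(score_session(s, "asr", wl)$counts[paste0("T", 1:5)]))
  }))
  diff <- res[, "clin"] - res[, "asr"]
  expect_gt(stats::cor(res[, "clin"], diff), 0.3)
})

test_that("mean counts, savings and separation respond monotonically to parameters", {
  wl <- vlt_word_lists()[[1]]
  mean_total <- function(beta) {
    set.seed(231)
    mean(replicate(150, {
      s <- simulate_session(group_params(beta = beta, sigma_u = 0), 0, wl)
      sum(score_session(s, "clinical", wl)$counts[paste0("T", 1:5)])
    }))
  }
  expect_true(all(diff(vapply(c(0.1, 0.4, 0.8), mean_total,
                              numeric(1))) > 0))

  mean_savings <- function(theta) {
    set.seed(241)
    mean(replicate(150, {
      s <- simulate_session(group_params(theta = theta, theta_u = 0,
                                         eps = 0), 0, wl)
      f <- vlt_features(s, "clinical", wl)
      f[["savings"]]
    }), na.rm = TRUE)
  }
  expect_true(all(diff(vapply(c(0.3, 0.6, 0.9), mean_savings,
                              numeric(1))) > 0))

  sep_auc <- function(delta) {
    set.seed(251)
    base <- default_group_params("scd")
    imp <- base
    imp$alpha <- base$alpha - delta
    imp$theta <- base$theta - delta / 4
    tot <- function(par) replicate(60, {
      u <- stats::rnorm(1, 0, par$sigma_u)
      s <- simulate_session(par, u, wl)
      sum(score_session(s, "clinical", wl)$counts[paste0("T", 1:5)])
    })
    mann_whitney_z(tot(base), tot(imp))$auc
  }
  aucs <- vapply(c(0.2, 0.8, 1.6), sep_auc, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("mean savings recovers the retention probability when reminiscence is off", {
  wl <- vlt_word_lists()[[1]]
  set.seed(261)
  p <- group_params(theta = 0.65, theta_u = 0, eps = 0)
  sav <- replicate(500, {
    s <- simulate_session(p, u = stats::rnorm(1, 0, p$sigma_u), wl)
    vlt_features(s, "clinical", wl)[["savings"]]
  })
  expect_lt(abs(mean(sav, na.rm = TRUE) - 0.65), 0.05)
})

test_that("cohort simulation is seed-deterministic and carries metadata", {
  cfg <- cohort_config(n_scd = 5, n_mci = 4, n_dementia = 2, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$metadata, b$metadata)
  expect_equal(nrow(a$metadata), 11)
  expect_setequal(unique(a$metadata$label), c("SCD", "MCI/dementia"))
  expect_true(all(c("age", "mmse", "cdr_sob", "z_svf", "z_rbmt_delayed",
                    "gds15", "education") %in% names(a$metadata)))
  expect_true(all(a$metadata$mmse >= 20 & a$metadata$mmse <= 30))
  expect_error(cohort_config(n_scd = 5), "seed")
})

test_that("group parameter validation rejects invalid probabilities", {
  expect_error(group_params(theta = 1.2), "theta")
  expect_error(group_params(order_mix = -0.1), "order_mix")
  expect_error(group_params(sigma_u = -1), "sigma_u")
  expect_error(asr_noise_params(0.5, 1, 0.2), "base_miss")
})
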