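#' Generative parameters for one diagnostic group
#'
#' The session generator draws, for word w and learning trial t, a recall
#' indicator from Bernoulli(logistic(alpha + beta (t-1) + primacy_boost
#' [w in primacy] + recency_boost [w in recency] + u)), with u a
#' participant-level random effect (SD `sigma_u`).  Delayed recall keeps a
#' trial-5-recalled word with probability `theta` (consolidation) and
#' resurrects a non-recalled word with probability `eps` (reminiscence).
#' Recognition responding thresholds a Gaussian familiarity signal (mean
#' `dprime` for targets, 0 for foils) at criterion `crit`.  Output order
#' blends presentation order with the previous trial's output order
#' (`order_mix`, plus Gaussian jitter `order_noise`); onsets accumulate
#' log-normal inter-word gaps (`gap_mu`, `gap_sigma`, log-seconds scale).
#' Intrusions are injected at rate `intrusion_rate` (expected count per
#' trial) and each recalled word is re-emitted with probability
#' `repetition_rate`.
#'
#' @param alpha Baseline recall log-odds at trial 1 for a midlist word.
#' @param beta Per-trial learning increment (log-odds).
#' @param primacy_boost,recency_boost Serial-position log-odds boosts.
#' @param sigma_u SD of the participant random effect.
#' @param theta Delayed retention probability for trial-5-recalled words
#'   (for a participant of average ability).
#' @param theta_u Log-odds loading of the participant effect u on delayed
#'   retention: the retention probability is
#'   logistic(logit(theta) + theta_u * u).  At 0 retention is the fixed
#'   probability `theta` for everyone; a positive loading ties
#'   consolidation to ability, which is what spreads delayed recall more
#'   widely than a fixed binomial would.
#' @param eps Delayed reminiscence probability for other words.
#' @param dprime Recognition discriminability.
#' @param crit Recognition response criterion.
#' @param order_mix Weight in [0,1]: 0 = pure list order, 1 = pure
#'   previous-trial output order.
#' @param order_noise SD of the order jitter (rank units).
#' @param gap_mu,gap_sigma Log-scale mean and SD of inter-word onset gaps.
#' @param gap_mu_sd SD of a participant-level shift on `gap_mu`: some
#'   people habitually recall in quick unpaused bursts, others slowly.
#'   This trait is what concentrates transcription misses in a minority of
#'   fast speakers rather than spreading them evenly.
#' @param intrusion_rate Expected intrusions per trial (Poisson).
#' @param repetition_rate Per-recalled-word probability of a within-trial
#'   repetition.
#' @return A `vlt_group_params` list.
#' @export
group_params <- function(alpha = -0.65, beta = 0.5, primacy_boost = 0.6,
                         recency_boost = 0.9, sigma_u = 0.85, theta = 0.74,
                         theta_u = 0.9, eps = 0.04, dprime = 2.8, crit = 1.0,
                         order_mix = 0.35, order_noise = 3.0,
                         gap_mu = log(1.6), gap_sigma = 0.8,
                         gap_mu_sd = 0.8,
                         intrusion_rate = 0.2, repetition_rate = 0.06) {
  p <- list(alpha = alpha, beta = beta, primacy_boost = primacy_boost,
            recency_boost = recency_boost, sigma_u = sigma_u, theta = theta,
            theta_u = theta_u, eps = eps, dprime = dprime, crit = crit, order_mix = order_mix,
            order_noise = order_noise, gap_mu = gap_mu,
            gap_sigma = gap_sigma, gap_mu_sd = gap_mu_sd,
            intrusion_rate = intrusion_rate,
            repetition_rate = repetition_rate)
  for (f in c("theta", "eps", "order_mix", "repetition_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (sigma_u < 0) stop("sigma_u must be non-negative")
  if (intrusion_rate < 0) stop("intrusion_rate must be non-negative")
  structure(p, class = "vlt_group_params")
}

#' ASR word-miss process parameters
#'
#' The automatic transcriber misses words predominantly when they are
#' spoken quickly, without pauses: a recalled word whose preceding gap is
#' shorter than `fast_gap_s` seconds is dropped with probability
#' `fast_miss`, otherwise with `base_miss`.
#'
#' @param base_miss Baseline per-word miss probability.
#' @param fast_gap_s Gap threshold (seconds) below which misses rise.
#' @param fast_miss Elevated miss probability for fast speech.
#' @return A `vlt_asr_noise` list.
#' @export
asr_noise_params <- function(base_miss = 0.05, fast_gap_s = 1.0,
                             fast_miss = 0.5) {
  if (!(base_miss >= 0 && base_miss <= fast_miss && fast_miss <= 1)) {
    stop("need 0 <= base_miss <= fast_miss <= 1")
  }
  structure(list(base_miss = base_miss, fast_gap_s = fast_gap_s,
                 fast_miss = fast_miss),
            class = "vlt_asr_noise")
}

#' Default generative parameters per diagnostic group
#'
#' Shipped defaults are calibrated so that the default cohort reproduces
#' the reference group means and SDs of ASR-scored total immediate recall
#' (37.6 (12.9) for SCD vs 24.1 (10.7) for the impaired group) and delayed
#' recall (8.1 (3.5) vs 3.6 (3.2)).  The dementia group reuses the MCI
#' parameters with a severity shift, since a separate calibration is not
#' supportable for a small group.
#'
#' @param group `"scd"`, `"mci"` or `"dementia"`.
#' @return A [group_params()] object.
#' @export
default_group_params <- function(group = c("scd", "mci", "dementia")) {
  group <- match.arg(group)
  switch(group,
    scd = group_params(alpha = -0.72, sigma_u = 1.0, theta = 0.86,
                       theta_u = 1.2),
    mci = group_params(alpha = -1.60, beta = 0.33, sigma_u = 0.75,
                       theta = 0.45, theta_u = 1.8, eps = 0.02,
                       dprime = 2.3, crit = 0.9,
                       gap_mu = log(2.2), intrusion_rate = 0.3,
                       repetition_rate = 0.08),
    dementia = {
      p <- default_group_params("mci")
      p$alpha <- p$alpha - 0.6
      p$beta <- p$beta * 0.8
      p$theta <- p$theta * 0.75
      p$dprime <- p$dprime - 0.5
      p$gap_mu <- p$gap_mu + 0.2
      p
    })
}

#' Cohort configuration
#'
#' @param n_scd,n_mci,n_dementia Group sizes (default: the reference cohort
#'   composition 69 / 56 / 13).
#' @param params Named list of [group_params()] for `scd`, `mci`,
#'   `dementia`.
#' @param asr_noise An [asr_noise_params()] object.
#' @param age Named list of `c(mean, sd)` per group; defaults 62.4 (10.8)
#'   for SCD and 71.9 (9.5) for MCI and dementia.
#' @param seed Mandatory integer seed.
#' @return A `vlt_cohort_config` list.
#' @export
cohort_config <- function(n_scd = 69, n_mci = 56, n_dementia = 13,
                          params = list(scd = default_group_params("scd"),
                                        mci = default_group_params("mci"),
                                        dementia =
                                          default_group_params("dementia")),
                          asr_noise = asr_noise_params(),
                          age = list(scd = c(62.4, 10.8),
                                     mci = c(71.9, 9.5),
                                     dementia = c(71.9, 9.5)),
                          seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_scd >= 0, n_mci >= 0, n_dementia >= 0)
  structure(list(n_scd = n_scd, n_mci = n_mci, n_dementia = n_dementia,
                 params = params, asr_noise = asr_noise, age = age,
                 seed = as.integer(seed)),
            class = "vlt_cohort_config")
}

# Intrusion tokens come from a fixed dummy vocabulary (multisyllabic, so
# they never collide with the monosyllabic list words); semantic content of
# intrusions is out of scope.
INTRUSION_VOCAB <- c("window", "doctor", "music", "river", "paper",
                     "flower", "candle", "mirror", "garden", "butter",
                     "pillow", "rocket", "summer", "table", "letter")

logistic <- function(x) 1 / (1 + exp(-x))

# Output order: blend of list order and the previous trial's output order,
# with Gaussian jitter.  prev_rank maps list position -> rank in previous
# output (list position itself when the word was not previously recalled).
order_recall <- function(positions, prev_rank, order_mix, order_noise) {
  if (length(positions) < 2L) return(positions)
  score <- (1 - order_mix) * positions + order_mix * prev_rank[positions] +
    order_noise * stats::rnorm(length(positions))
  positions[order(score)]
}

build_trial <- function(label, order_pos, params, word_list, intrusion_pool) {
  tokens <- word_list$targets[order_pos]
  n_rep <- stats::rbinom(1, length(order_pos), params$repetition_rate)
  if (n_rep > 0 && length(order_pos) > 0) {
    rep_words <- sample(tokens, n_rep, replace = FALSE)
    for (w in rep_words) {
      at <- match(w, tokens)  # re-emit somewhere after the first occurrence
      ins <- sample(at:length(tokens), 1)
      tokens <- append(tokens, w, after = ins)
    }
  }
  n_int <- stats::rpois(1, params$intrusion_rate)
  if (n_int > 0) {
    for (w in sample(intrusion_pool, n_int, replace = TRUE)) {
      tokens <- append(tokens, w, after = sample(0:length(tokens), 1))
    }
  }
  gaps <- stats::rlnorm(length(tokens), params$gap_mu, params$gap_sigma)
  vlt_trial(label, tokens, onset_s = cumsum(gaps))
}

#' Simulate one session (clinical variant = ground truth)
#'
#' @param params A [group_params()] object.
#' @param u Participant random effect (log-odds scale).
#' @param word_list A [vlt_word_list]; default the first built-in list.
#' @param participant_id Identifier.
#' @param regions Serial regions defining the primacy/recency boosts.
#' @return A [vlt_session] with a `"clinical"` variant carrying tokens,
#'   onsets and the recognition sheet.  Uses the current RNG state; seed
#'   upstream for reproducibility.
#' @export
simulate_session <- function(params, u = 0, word_list = NULL,
                             participant_id = "p1",
                             regions = serial_regions()) {
  stopifnot(inherits(params, "vlt_group_params"))
  if (is.null(word_list)) word_list <- vlt_word_lists()[[1]]
  pool <- setdiff(INTRUSION_VOCAB, c(word_list$targets, word_list$foils))
  pos_eff <- numeric(15)
  pos_eff[regions$primacy] <- params$primacy_boost
  pos_eff[regions$recency] <- params$recency_boost
  # participant-level speech-rate trait shifts all inter-word gaps
  params$gap_mu <- params$gap_mu + stats::rnorm(1, 0, params$gap_mu_sd)

  trials <- vector("list", 6L)
  prev_rank <- 1:15
  recalled5 <- integer(0)
  for (t in 1:5) {
    p <- logistic(params$alpha + params$beta * (t - 1) + pos_eff + u)
    rec <- which(stats::runif(15) < p)
    ord <- order_recall(rec, prev_rank, params$order_mix, params$order_noise)
    trials[[t]] <- build_trial(IMMEDIATE_LABELS[t], ord, params, word_list,
                               pool)
    if (length(ord) > 0) {
      # full permutation: previous output first, unseen words after in
      # list order, so ranks never collide
      perm <- c(ord, setdiff(1:15, ord))
      prev_rank <- match(1:15, perm)
    }
    if (t == 5L) recalled5 <- rec
  }
  p_ret <- if (params$theta <= 0 || params$theta >= 1) params$theta
           else logistic(stats::qlogis(params$theta) + params$theta_u * u)
  keep <- stats::runif(15) < ifelse(seq_len(15) %in% recalled5,
                                    p_ret, params$eps)
  del <- which(keep)
  ord <- order_recall(del, prev_rank, params$order_mix, params$order_noise)
  trials[[6L]] <- build_trial("DELAYED", ord, params, word_list, pool)

  fam_t <- stats::rnorm(15, params$dprime, 1)
  fam_f <- stats::rnorm(15, 0, 1)
  rec_sheet <- vlt_recognition(
    word = c(word_list$targets, word_list$foils),
    is_target = rep(c(TRUE, FALSE), each = 15),
    response = c(fam_t, fam_f) > params$crit)

  vlt_session(participant_id, word_list$list_id,
              list(vlt_variant("clinical", trials = trials,
                               recognition = rec_sheet)))
}

#' Add an ASR variant by applying the word-miss process
#'
#' Each target event in the clinical transcript is independently dropped
#' with probability `fast_miss` when its preceding inter-word gap is below
#' `fast_gap_s` seconds, else `base_miss`.  Intrusion tokens are removed
#' entirely: the transcriber cannot identify out-of-list words.  The
#' recognition sheet is carried over unchanged (recognition responses are
#' entered manually, not transcribed).
#'
#' @param session A [vlt_session] with a clinical variant carrying onsets.
#' @param noise An [asr_noise_params()] object.
#' @param word_list Word list; default the built-in list matching the
#'   session.
#' @return The session with an added `"asr"` variant.
#' @export
apply_asr_noise <- function(session, noise = asr_noise_params(),
                            word_list = NULL) {
  stopifnot(inherits(session, "vlt_session"),
            inherits(noise, "vlt_asr_noise"))
  clin <- session$variants[["clinical"]]
  if (is.null(clin) || is.null(clin$trials)) {
    stop("session ", session$participant_id,
         " needs a token-level clinical variant")
  }
  if (is.null(word_list)) word_list <- vlt_word_lists()[[session$list_id]]
  asr_trials <- lapply(clin$trials, function(tr) {
    ev <- tr$events
    if (nrow(ev) == 0L) return(vlt_trial(tr$trial_label))
    if (anyNA(ev$onset_s)) {
      stop("trial ", tr$trial_label, ": ASR noise needs onsets")
    }
    gaps <- diff(c(0, ev$onset_s))
    is_target <- normalize_tokens(ev$token) %in% word_list$targets
    p_miss <- ifelse(gaps < noise$fast_gap_s, noise$fast_miss,
                     noise$base_miss)
    keep <- is_target & stats::runif(nrow(ev)) >= p_miss
    vlt_trial(tr$trial_label, ev$token[keep], ev$onset_s[keep])
  })
  session$variants[["asr"]] <- vlt_variant("asr", trials = asr_trials,
                                           recognition = clin$recognition)
  session
}

aux_score <- function(m, sd_target, corr_u, u, sigma_u, n) {
  b <- corr_u * sd_target / sigma_u
  m + b * u + stats::rnorm(n, 0, sd_target * sqrt(max(0, 1 - corr_u^2)))
}

#' Simulate a full cohort
#'
#' Generates sessions (clinical truth + ASR variant) for the configured
#' group sizes, together with a metadata table carrying diagnosis group,
#' the SCD-vs-impaired label, age, sex, education, auxiliary cognitive
#' z-scores (generated as linear functions of the latent ability plus
#' noise, mirroring the low-to-moderate correlation structure of real
#' cognitive batteries without claiming to model those tests), and
#' severity/functioning scales.  Reproducible given the seed.
#'
#' @param config A [cohort_config()].
#' @return List: `sessions` (list of [vlt_session]), `metadata` (data
#'   frame, one row per participant), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "vlt_cohort_config"))
  set.seed(config$seed)
  lists <- vlt_word_lists()
  groups <- rep(c("scd", "mci", "dementia"),
                c(config$n_scd, config$n_mci, config$n_dementia))
  n <- length(groups)
  if (n == 0L) stop("empty cohort")
  sessions <- vector("list", n)
  meta <- vector("list", n)
  p_male <- c(scd = 0.657, mci = 0.588, dementia = 0.588)
  edu_probs <- list(scd = c(0.271, 0.371, 0.357),
                    mci = c(0.397, 0.309, 0.294),
                    dementia = c(0.397, 0.309, 0.294))
  for (i in seq_len(n)) {
    g <- groups[i]
    par <- config$params[[g]]
    u <- stats::rnorm(1, 0, par$sigma_u)
    pid <- sprintf("%s-%03d", g, i)
    wl <- lists[[(i - 1L) %% length(lists) + 1L]]
    s <- simulate_session(par, u, wl, participant_id = pid)
    sessions[[i]] <- apply_asr_noise(s, config$asr_noise, word_list = wl)
    ag <- config$age[[g]]
    meta[[i]] <- data.frame(
      participant_id = pid,
      group = c(scd = "SCD", mci = "MCI", dementia = "dementia")[[g]],
      label = if (g == "scd") "SCD" else "MCI/dementia",
      age = stats::rnorm(1, ag[1], ag[2]),
      sex = if (stats::runif(1) < p_male[[g]]) "m" else "f",
      education = sample(c("low", "mid", "high"), 1, prob = edu_probs[[g]]),
      latent_ability = u,
      z_svf = aux_score(if (g == "scd") -0.8 else -1.2, 0.9, 0.35, u,
                        par$sigma_u, 1),
      z_stroop = aux_score(if (g == "scd") 0.0 else -1.7,
                           if (g == "scd") 1.1 else 3.8, 0.15, u,
                           par$sigma_u, 1),
      z_tmt = aux_score(if (g == "scd") 0.1 else -1.2,
                        if (g == "scd") 1.1 else 2.1, 0.15, u,
                        par$sigma_u, 1),
      z_rbmt_immediate = aux_score(if (g == "scd") -0.3 else -1.1,
                                   if (g == "scd") 1.0 else 0.9, 0.45, u,
                                   par$sigma_u, 1),
      z_rbmt_delayed = aux_score(if (g == "scd") -0.2 else -1.2, 1.0, 0.5,
                                 u, par$sigma_u, 1),
      cdr_sob = round(2 * pmax(0, aux_score(if (g == "scd") 0.8 else 2.0,
                                            if (g == "scd") 0.9 else 1.7,
                                            -0.4, u, par$sigma_u, 1))) / 2,
      dad = pmin(100, aux_score(if (g == "scd") 94.7 else 83.6,
                                if (g == "scd") 7.9 else 15.9, 0.3, u,
                                par$sigma_u, 1)),
      mmse = pmin(30, pmax(20, round(aux_score(
        if (g == "scd") 28.7 else 26.1,
        if (g == "scd") 1.2 else 2.6, 0.4, u, par$sigma_u, 1)))),
      gds15 = pmin(15, pmax(0, round(stats::rnorm(
        1, if (g == "scd") 3.1 else 3.2, if (g == "scd") 2.3 else 2.9)))),
      stringsAsFactors = FALSE)
  }
  list(sessions = sessions, metadata = do.call(rbind, meta),
       config = config)
}

#' Shipped default cohort configuration
#'
#' The calibrated defaults: the reference cohort composition (69 SCD, 56
#' MCI, 13 dementia), group parameters from [default_group_params()], and
#' the default ASR miss process.
#'
#' @param seed Integer seed (mandatory).
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()] object.
#' @export
default_cohort_config <- function(seed, ...) {
  cohort_config(seed = seed, ...)
}
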