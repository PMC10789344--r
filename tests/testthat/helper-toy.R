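# Toy fixtures built in code: a 15-item word list with alphabetic tokens
# and convenience builders for sessions specified by recall orders.

toy_word_list <- function() {
  vlt_word_list(
    "toy",
    targets = c("alpha", "bravo", "charlie", "delta", "echo", "foxtrot",
                "golf", "hotel", "india", "juliett", "kilo", "lima",
                "mike", "november", "oscar"),
    foils = c("papa", "quebec", "romeo", "sierra", "tango", "uniform",
              "victor", "whiskey", "xray", "yankee", "zulu", "apple",
              "berry", "cedar", "maple"))
}

# Build a trial from list positions (in output order); onsets optional.
toy_trial <- function(label, positions, wl = toy_word_list(),
                      onset_s = NULL) {
  vlt_trial(label, wl$targets[positions], onset_s = onset_s)
}

# A full session from a named list of position vectors (T1..T5, DELAYED).
toy_session <- function(orders, wl = toy_word_list(), rater = "clinical",
                        pid = "toy-1", recognition = NULL) {
  trials <- lapply(names(orders), function(l) toy_trial(l, orders[[l]], wl))
  vlt_session(pid, wl$list_id,
              list(vlt_variant(rater, trials = trials,
                               recognition = recognition)))
}

toy_recognition <- function(target_yes = 15, foil_yes = 0,
                            wl = toy_word_list()) {
  vlt_recognition(c(wl$targets, wl$foils),
                  rep(c(TRUE, FALSE), each = 15),
                  c(rep(c(TRUE, FALSE), c(target_yes, 15 - target_yes)),
                    rep(c(TRUE, FALSE), c(foil_yes, 15 - foil_yes))))
}

# Independent brute-force Mann-Whitney U: wins + half-ties over all pairs.
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Independent two-way ANOVA oracle for ICC(A,k): explicit sums of squares.
icc_anova_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# Closed-form least-squares slope over trials 1..5.
slope_oracle <- function(c5) {
  t <- 1:5
  sum((t - 3) * (c5 - mean(c5))) / sum((t - 3)^2)
}
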