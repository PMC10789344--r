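#' Intraclass correlation ICC(A,k): two-way model, absolute agreement, mean
#' of k ratings
#'
#' Agreement between the clinician's score and the automatically derived
#' score is quantified with the mean-rating (k = 2), absolute-agreement,
#' two-way mixed-effects ICC.  From the two-way ANOVA mean squares (rows =
#' subjects, columns = raters),
#' \deqn{ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n).}
#' The confidence interval uses the McGraw-Wong F-based interval for the
#' single-rater ICC(A,1) with Satterthwaite degrees of freedom, transformed
#' to the mean-rating form by the Spearman-Brown step.
#'
#' @param clinical,asr Numeric vectors of paired ratings (same participants,
#'   same order).  Pairs with a missing side are excluded listwise and
#'   counted.
#' @param alpha Significance level for the (1 - alpha) confidence interval.
#' @return A `vlt_icc` object: `icc`, `ci_low`, `ci_high`, `n_subjects`,
#'   `k_raters`, `ms_rows`, `ms_cols`, `ms_error`, `n_excluded`, `alpha`.
#' @export
icc_a_k <- function(clinical, asr, alpha = 0.05) {
  stopifnot(length(clinical) == length(asr))
  ok <- !is.na(clinical) & !is.na(asr)
  n_excluded <- sum(!ok)
  x <- cbind(clinical[ok], asr[ok])
  n <- nrow(x)
  k <- 2L
  if (n < 3L) stop("ICC needs at least 3 complete pairs, got ", n)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ss_rows <= .Machine$double.eps * max(1, ss_tot)) {
    warning("zero between-subject variance; ICC degenerate, reported as 0")
    icc <- 0
    ci <- c(NA_real_, NA_real_)
  } else {
    icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
    ci <- icc_ak_ci(ms_r, ms_c, ms_e, n, k, alpha)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, k_raters = k,
                 ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
                 n_excluded = n_excluded, alpha = alpha),
            class = "vlt_icc")
}

# McGraw & Wong (1996) interval: F-based bounds for ICC(A,1) with
# Satterthwaite df, then Spearman-Brown to the mean-rating form.
icc_ak_ci <- function(ms_r, ms_c, ms_e, n, k, alpha) {
  rho1 <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  if (ms_e <= 0 && ms_c <= 0) return(c(1, 1))  # exact agreement
  if (rho1 >= 1 - 1e-12) return(c(1, 1))
  a <- k * rho1 / (n * (1 - rho1))
  b <- 1 + k * rho1 * (n - 1) / (n * (1 - rho1))
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  denom <- k * ms_c + (k * n - k - n) * ms_e
  l1 <- n * (ms_r - f_u * ms_e) / (f_u * denom + n * ms_r)
  u1 <- n * (f_l * ms_r - ms_e) / (denom + n * f_l * ms_r)
  sb <- function(r) r * k / (1 + r * (k - 1))
  c(max(-1, sb(l1)), min(1, sb(u1)))
}

#' @export
print.vlt_icc <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(A,%d) = %.*f  [%.*f, %.*f]  (n = %d", x$k_raters,
              digits, x$icc, digits, x$ci_low, digits, x$ci_high,
              x$n_subjects))
  if (x$n_excluded > 0) cat(sprintf(", %d pairs excluded", x$n_excluded))
  cat(")\n")
  invisible(x)
}

#' Clinical-minus-ASR difference summary
#'
#' Differences are defined as clinical minus ASR, so a positive difference
#' means the ASR missed words.  The exceedance threshold is configurable
#' (e.g. 14 words for total immediate recall, 4 for delayed recall).
#'
#' @param clinical,asr Paired numeric vectors.
#' @param threshold Count pairs whose difference exceeds (strictly) this
#'   value.
#' @return List: `mean_diff`, `min_diff`, `max_diff`, `n`, `threshold`,
#'   `count_exceeding`, `fraction_exceeding`.
#' @export
difference_summary <- function(clinical, asr, threshold = 14) {
  ok <- !is.na(clinical) & !is.na(asr)
  d <- clinical[ok] - asr[ok]
  if (length(d) < 1L) stop("need at least one complete pair")
  list(mean_diff = mean(d), min_diff = min(d), max_diff = max(d),
       n = length(d), threshold = threshold,
       count_exceeding = sum(d > threshold),
       fraction_exceeding = mean(d > threshold))
}

#' Subgroup ICC sensitivity analysis
#'
#' ICC(A,k) per diagnostic subgroup (or any grouping, e.g. per trial).
#' Groups with fewer than 3 complete pairs are skipped with a message.
#'
#' @param clinical,asr Paired numeric vectors.
#' @param groups Vector of group labels, same length.
#' @param alpha Significance level.
#' @return Named list of `vlt_icc` objects (skipped groups absent).
#' @export
subgroup_icc <- function(clinical, asr, groups, alpha = 0.05) {
  stopifnot(length(groups) == length(clinical))
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- groups == g & !is.na(clinical) & !is.na(asr)
    if (sum(sel, na.rm = TRUE) < 3L) {
      message("subgroup '", g, "' has < 3 complete pairs; skipped")
      next
    }
    out[[g]] <- icc_a_k(clinical[sel], asr[sel], alpha = alpha)
  }
  out
}

#' Clinical-vs-ASR agreement scatterplot
#'
#' Scatter of ASR against clinical scores with the identity line; points on
#' the line are pairs the ASR scored exactly.
#'
#' @param clinical,asr Paired numeric vectors.
#' @param measure Label for titles/axes.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_agreement <- function(clinical, asr, measure = "score", ...) {
  ok <- !is.na(clinical) & !is.na(asr)
  graphics::plot(clinical[ok], asr[ok],
                 xlab = paste("clinical", measure),
                 ylab = paste("ASR", measure),
                 main = paste("Agreement:", measure), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
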