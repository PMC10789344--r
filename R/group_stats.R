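#' Mann-Whitney U test with standardized Z and rank effect size
#'
#' U is computed with midranks; Z uses the normal approximation with
#' tie-corrected variance and no continuity correction, matching common
#' statistical-package output for large samples.  The effect size is
#' r = |Z| / sqrt(N) with N the combined sample size, and the univariate
#' AUC is U / (n_a * n_b) (the probability that a random value from group A
#' exceeds a random value from group B, ties counted half).
#'
#' @param group_a,group_b Numeric vectors (missing values dropped; at least
#'   2 non-missing per group).  The sign of Z follows group A: Z < 0 when
#'   group A ranks lower than expected.
#' @return A `vlt_effect` list: `U`, `Z`, `p` (two-sided), `r`, `N`, `n_a`,
#'   `n_b`, `auc`.
#' @export
mann_whitney_z <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 non-missing values")
  nn <- n1 + n2
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  z <- if (v <= 0) 0 else (u - n1 * n2 / 2) / sqrt(v)
  structure(list(U = u, Z = z, p = 2 * stats::pnorm(-abs(z)),
                 r = abs(z) / sqrt(nn), N = nn, n_a = n1, n_b = n2,
                 auc = u / (n1 * n2)),
            class = "vlt_effect")
}

#' @export
print.vlt_effect <- function(x, digits = 3, ...) {
  cat(sprintf("Mann-Whitney: U = %.1f, Z = %.*f, p = %.3g, r = %.*f, AUC = %.*f (N = %d)\n",
              x$U, digits, x$Z, x$p, digits, x$r, digits, x$auc, x$N))
  invisible(x)
}

#' Rank effect size from a standardized Z statistic
#'
#' The conversion r = |Z| / sqrt(N) used to report Mann-Whitney group
#' differences as effect sizes.
#'
#' @param z Standardized statistic.
#' @param n Combined sample size.
#' @return r in [0, 1] (values above 1 are impossible for genuine Z).
#' @export
effect_size_r <- function(z, n) abs(z) / sqrt(n)

#' Rank features by Mann-Whitney effect size
#'
#' For each feature, compares the two groups with [mann_whitney_z()] and
#' ranks descending by r = |Z|/sqrt(N).  Per-feature N is reported
#' explicitly because missing values make it feature-specific.
#'
#' @param feature_table Data frame from [vlt_feature_table()] (or any data
#'   frame of numeric feature columns).
#' @param labels Two-level factor (or coercible) aligned with the rows.
#' @param group_a Label level treated as group A (sign convention of Z);
#'   default the second level, so with levels `c("SCD", "impaired")` the
#'   impaired group drives the sign, giving negative Z for features on which
#'   impaired participants rank lower.
#' @param features Feature columns to test; default all numeric columns
#'   except `participant_id`-like metadata.
#' @return A `vlt_effect_sizes` data frame: `feature`, `Z`, `p`, `r`, `auc`,
#'   `U`, `N`, `n_a`, `n_b`, sorted by descending `r`.
#' @export
effect_size_ranking <- function(feature_table, labels, group_a = NULL,
                                features = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (is.null(group_a)) group_a <- levels(labels)[2]
  if (is.null(features)) {
    num <- vapply(feature_table, is.numeric, logical(1))
    features <- names(feature_table)[num]
  }
  rows <- lapply(features, function(f) {
    v <- feature_table[[f]]
    ia <- labels == group_a & !is.na(v)
    ib <- labels != group_a & !is.na(v)
    if (sum(ia) < 2L || sum(ib) < 2L) return(NULL)
    e <- mann_whitney_z(v[ia], v[ib])
    data.frame(feature = f, Z = e$Z, p = e$p, r = e$r, auc = e$auc,
               U = e$U, N = e$N, n_a = e$n_a, n_b = e$n_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vlt_effect_sizes", "data.frame")
  out
}

#' @export
print.vlt_effect_sizes <- function(x, n = 10, ...) {
  cat("Feature effect sizes (Mann-Whitney r = |Z|/sqrt(N)), top", n, "\n")
  y <- utils::head(as.data.frame(x), n)
  y$Z <- round(y$Z, 3); y$r <- round(y$r, 3); y$auc <- round(y$auc, 3)
  y$p <- signif(y$p, 3)
  print(y[, c("feature", "Z", "p", "r", "auc", "N")], row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix with case-wise deletion
#'
#' Rows with any missing value across the selected variables are dropped
#' (case-wise deletion), then pairwise Pearson correlations and two-sided
#' p-values are computed on the common complete subset.
#'
#' @param data Data frame of numeric variables.
#' @param min_n Minimum number of complete cases; below it the matrix is
#'   all-missing.
#' @return A `vlt_corr` list: `r` (correlation matrix), `p`, `n_complete`,
#'   `variables`.
#' @export
correlation_matrix <- function(data, min_n = 3) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  data <- data[num]
  cc <- stats::complete.cases(data)
  n <- sum(cc)
  v <- ncol(data)
  if (n < min_n) {
    r <- p <- matrix(NA_real_, v, v, dimnames = list(names(data), names(data)))
  } else {
    x <- data[cc, , drop = FALSE]
    r <- stats::cor(x)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- 0
  }
  structure(list(r = r, p = p, n_complete = n, variables = names(data)),
            class = "vlt_corr")
}

#' @export
print.vlt_corr <- function(x, digits = 2, ...) {
  cat("Pearson correlations on", x$n_complete,
      "complete cases (case-wise deletion)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Correlation heatmap (base graphics)
#'
#' Sign-coded colors: blue positive, red negative, darker = stronger.
#'
#' @param x A `vlt_corr` object.
#' @param ... Unused.
#' @export
plot.vlt_corr <- function(x, ...) {
  r <- x$r
  v <- ncol(r)
  pal <- grDevices::colorRampPalette(c("#B2182B", "white", "#2166AC"))(201)
  op <- graphics::par(mar = c(1, 8, 8, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(v), seq_len(v), t(r[v:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "",
                  ylab = "")
  graphics::axis(3, at = seq_len(v), labels = colnames(r), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(v), labels = rev(rownames(r)), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  invisible(x)
}

#' Demographic group comparison (convenience)
#'
#' Standard univariate comparisons for cohort-characteristics tables:
#' Welch t-test for continuous variables, chi-square for categorical ones,
#' and the Mann-Whitney test for skewed continuous variables.
#'
#' @param values Vector (numeric or categorical).
#' @param labels Two-level grouping.
#' @param type `"t"`, `"chisq"` or `"mannwhitney"`.
#' @return List with group summaries and the p-value.
#' @export
group_comparison <- function(values, labels,
                             type = c("t", "chisq", "mannwhitney")) {
  type <- match.arg(type)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  split_v <- split(values, labels)
  if (type == "t") {
    ht <- stats::t.test(split_v[[1]], split_v[[2]])
    list(mean_sd = lapply(split_v, function(v)
           c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))),
         p = ht$p.value)
  } else if (type == "chisq") {
    tab <- table(values, labels)
    list(table = tab, p = stats::chisq.test(tab)$p.value)
  } else {
    e <- mann_whitney_z(split_v[[1]], split_v[[2]])
    list(median = lapply(split_v, stats::median, na.rm = TRUE), p = e$p)
  }
}
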