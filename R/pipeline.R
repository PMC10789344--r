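#' Run the full analysis pipeline
#'
#' End-to-end run on a cohort: feature extraction for both raters,
#' clinical-vs-ASR reliability (ICCs with subgroup and per-trial
#' sensitivity analyses, difference summaries, agreement scatterplots),
#' effect-size ranking of the ASR feature catalog, the diagnostic model
#' family under LOOCV, and the feature-vs-cognition correlation matrix.
#' All tabular outputs are UTF-8 CSV; figures (PDF) are optional and
#' headless-safe.  Every stage logs row counts.
#'
#' @param cohort A list with `sessions` and `metadata`, as produced by
#'   [simulate_cohort()] (or assembled from [read_sessions()] plus a
#'   metadata table with `participant_id`, `label`, `group`, `age`).
#' @param out_dir Output directory (created if needed).
#' @param rater Rater whose features feed the classifier and effect sizes.
#' @param regions A [serial_regions()] object.
#' @param config A [classifier_config()].
#' @param run_classification Fit the 4x3 model family (the slow stage)?
#' @param figures Write PDF figures?
#' @return Invisibly, a list with the in-memory results (`features_asr`,
#'   `features_clinical`, `reliability`, `effect_sizes`, `models`,
#'   `correlations`).
#' @export
run_pipeline <- function(cohort, out_dir, rater = "asr",
                         regions = serial_regions(),
                         config = classifier_config(),
                         run_classification = TRUE, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- cohort$sessions
  metadata <- cohort$metadata
  message("pipeline: ", length(sessions), " sessions in")

  tab_asr <- vlt_feature_table(sessions, rater = "asr", regions = regions,
                               metadata = metadata)
  tab_cli <- vlt_feature_table(sessions, rater = "clinical",
                               regions = regions, metadata = metadata)
  utils::write.csv(tab_asr, file.path(out_dir, "features_asr.csv"),
                   row.names = FALSE)
  utils::write.csv(tab_cli, file.path(out_dir, "features_clinical.csv"),
                   row.names = FALSE)
  dict <- vlt_feature_dictionary(regions)
  jsonlite::write_json(dict, file.path(out_dir, "feature_dictionary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("features: ", nrow(tab_asr), " participants x ", nrow(dict),
          " features")

  # reliability: headline measures, diagnostic subgroups, per-trial post hoc
  rel_measures <- c("total_immediate_recall", "delayed_recall",
                    paste0("immediate_count_trial_", 1:5))
  rel_rows <- list()
  for (m in rel_measures) {
    clin <- tab_cli[[m]]
    asr <- tab_asr[[m]]
    rel_rows[[m]] <- data.frame(measure = m, subgroup = "all",
                                icc_row(clin, asr))
    if (!is.null(metadata$label)) {
      for (g in names(sub <- subgroup_icc(clin, asr, metadata$label))) {
        rel_rows[[paste(m, g)]] <- data.frame(measure = m, subgroup = g,
                                              icc_df(sub[[g]], clin, asr,
                                                     metadata$label == g))
      }
    }
  }
  reliability <- do.call(rbind, rel_rows)
  rownames(reliability) <- NULL
  utils::write.csv(reliability, file.path(out_dir, "reliability.csv"),
                   row.names = FALSE)
  message("reliability: ", nrow(reliability), " measure x subgroup rows")

  if (figures) {
    grDevices::pdf(file.path(out_dir, "agreement_scatterplots.pdf"),
                   width = 9, height = 4.5)
    graphics::par(mfrow = c(1, 2))
    plot_agreement(tab_cli$total_immediate_recall,
                   tab_asr$total_immediate_recall, "total immediate recall")
    plot_agreement(tab_cli$delayed_recall, tab_asr$delayed_recall,
                   "delayed recall")
    grDevices::dev.off()
  }

  labels <- factor(metadata$label, levels = c("SCD", "MCI/dementia"))
  feat_tab <- if (rater == "asr") tab_asr else tab_cli
  es <- effect_size_ranking(feat_tab, labels,
                            features = intersect(vlt_feature_names(regions),
                                                 names(feat_tab)))
  utils::write.csv(as.data.frame(es), file.path(out_dir, "effect_sizes.csv"),
                   row.names = FALSE)
  message("effect sizes: ", nrow(es), " features ranked")

  top10 <- utils::head(es$feature, 10)
  corr_vars <- c("mmse", "z_svf", "z_stroop", "z_tmt", "z_rbmt_immediate",
                 "z_rbmt_delayed", "cdr_sob", "dad")
  corr_df <- cbind(feat_tab[intersect(top10, names(feat_tab))],
                   metadata[intersect(corr_vars, names(metadata))])
  correlations <- correlation_matrix(corr_df)
  utils::write.csv(correlations$r, file.path(out_dir, "correlations.csv"))
  if (figures) {
    grDevices::pdf(file.path(out_dir, "correlation_heatmap.pdf"),
                   width = 7, height = 7)
    plot(correlations)
    grDevices::dev.off()
  }
  message("correlations: ", correlations$n_complete, " complete cases")

  models <- NULL
  if (run_classification) {
    models <- run_model_family(feat_tab, labels, config = config,
                               sensitivity_exclude =
                                 metadata$group == "dementia")
    utils::write.csv(models$results, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
    utils::write.csv(models$pairwise,
                     file.path(out_dir, "model_comparisons.csv"),
                     row.names = FALSE)
    if (!is.null(models$sensitivity)) {
      utils::write.csv(models$sensitivity$results,
                       file.path(out_dir, "models_excl_dementia.csv"),
                       row.names = FALSE)
    }
    if (figures) {
      grDevices::pdf(file.path(out_dir, "roc_curves.pdf"), width = 8,
                     height = 8)
      graphics::par(mfrow = c(2, 2))
      for (subtest in MODEL_SUBTESTS) {
        graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3,
                       xlab = "false positive rate",
                       ylab = "true positive rate", main = subtest)
        for (tier in 1:3) {
          rp <- roc_points(models$scores[[paste0(subtest, "_model", tier)]],
                           labels)
          graphics::lines(rp$fpr, rp$tpr, col = tier + 1)
        }
        graphics::legend("bottomright", legend = paste("model", 1:3),
                         col = 2:4, lty = 1, cex = 0.8)
      }
      grDevices::dev.off()
    }
    message("classification: ", nrow(models$results), " models fitted")
  }

  run_meta <- list(
    package_version = as.character(utils::packageVersion("vltkit")),
    r_version = R.version.string,
    n_sessions = length(sessions),
    rater = rater,
    classifier = unclass(config),
    seed = cohort$config$seed %||% NA)
  jsonlite::write_json(run_meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")

  invisible(list(features_asr = tab_asr, features_clinical = tab_cli,
                 reliability = reliability, effect_sizes = es,
                 models = models, correlations = correlations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

icc_row <- function(clin, asr) {
  icc_df(icc_a_k(clin, asr), clin, asr, TRUE)
}

icc_df <- function(icc, clin, asr, sel) {
  ds <- difference_summary(clin[sel], asr[sel], threshold = 14)
  data.frame(icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
             n = icc$n_subjects, mean_diff = ds$mean_diff,
             min_diff = ds$min_diff, max_diff = ds$max_diff,
             stringsAsFactors = FALSE)
}
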