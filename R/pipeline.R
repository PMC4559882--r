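#' Default pipeline configuration
#'
#' @param reference_assay reference (normalizer) assay name.
#' @param base_assay the class-discriminating assay; its normalized
#'   measure `dx_<base_assay>` is the classifier input.
#' @param helper_assay correlated helper assay for noise reduction,
#'   or `NA` to skip the improvement stage.
#' @param class_map file-label to internal-label mapping.
#' @param alpha variability-QC significance level.
#' @param bias_level bias-outlier flagging level.
#' @param prior_target prior probability of the target class.
#' @param seed seed for the accuracy Monte-Carlo propagation.
#' @return Named list of validated settings.
#' @export
pipeline_config <- function(reference_assay = "U6",
                            base_assay = "miR-205",
                            helper_assay = "miR-21",
                            class_map = c(ADC = "target", SQC = "versus"),
                            alpha = 0.05,
                            bias_level = 0.01,
                            prior_target = 0.5,
                            seed = 1234L) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (bias_level <= 0 || bias_level >= 1) {
    stop_validation("bias_level must be in (0, 1)")
  }
  if (prior_target <= 0 || prior_target >= 1) {
    stop_validation("prior_target must be in (0, 1)")
  }
  list(reference_assay = reference_assay, base_assay = base_assay,
       helper_assay = helper_assay, class_map = class_map,
       alpha = alpha, bias_level = bias_level,
       prior_target = prior_target, seed = as.integer(seed))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the complete chain: variance QC with outlier rejection,
#' reference normalization, per-class statistics, Bayes-classifier
#' fit on the normalized base measure, optional noise-reduction
#' improvement with the helper measure, and odds-banded evaluation of
#' both classifiers. The configuration is echoed into the returned
#' bundle documenting how each number was produced; with identical inputs, configuration and
#' seed the bundle is identical.
#'
#' @param cohort a [qpcr_cohort()] or a path to a cohort TSV.
#' @param config a [pipeline_config()].
#' @param out optional directory: when given, report sections are
#'   written there as JSON documents and a summary TSV.
#' @return Object of class `pipeline_result`: list with `config`,
#'   `qc`, `measures`, `stats`, `correlations`, `coefficient`,
#'   `model_base`, `model_improved`, `evaluation` (per model:
#'   confusion, predicted accuracy, AUC, thresholds, bias-outlier
#'   p-values).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out = NULL) {
  if (is.character(cohort)) {
    cohort <- read_cohort(cohort, class_map = config$class_map,
                          priors = c(target = config$prior_target,
                                     versus = 1 - config$prior_target))
  }
  prior_ratio <- config$prior_target / (1 - config$prior_target)

  qc <- apply_qc(cohort, alpha = config$alpha)
  measures <- normalize_cohort(qc$cohort, config$reference_assay)

  base_m <- paste0("dx_", config$base_assay)
  helper_m <- if (is.na(config$helper_assay)) NA_character_ else
    paste0("dx_", config$helper_assay)
  stat_names <- c(base_m, if (!is.na(helper_m)) helper_m,
                  paste0("x_", config$reference_assay))
  stats_tab <- class_stats_table(measures, stat_names)

  fit_on <- function(values, name) {
    keep <- is.finite(values) & measures$class_label %in%
      c("target", "versus")
    fit_bayes_classifier(values[keep & measures$class_label == "target"],
                         values[keep & measures$class_label == "versus"],
                         prior_ratio = prior_ratio, measure = name)
  }
  evaluate_on <- function(model, values) {
    keep <- is.finite(values)
    conf <- banded_confusion(model, values[keep],
                             measures$class_label[keep])
    list(confusion = conf,
         predicted = predicted_accuracy(model, seed = config$seed),
         auc = roc_auc(values[keep], measures$class_label[keep]),
         thresholds = odds_thresholds(model),
         bias_p = bias_outlier_p(model$orientation * values,
                                 model$target))
  }

  y_base <- measures[[base_m]]
  model_base <- fit_on(y_base, base_m)
  evaluation <- list(base = evaluate_on(model_base, y_base))

  correlations <- NULL
  coefficient <- NULL
  model_improved <- NULL
  if (!is.na(helper_m)) {
    correlations <- correlation_table(measures, base_m, helper_m)
    coefficient <- optimize_coefficient(measures[[base_m]],
                                        measures[[helper_m]],
                                        measures$class_label)
    y_imp <- combine_measures(measures[[base_m]], measures[[helper_m]],
                              coefficient$c_opt)
    model_improved <- fit_on(y_imp, sprintf("%s %+.2f*%s", base_m,
                                            coefficient$c_opt, helper_m))
    evaluation$improved <- evaluate_on(model_improved, y_imp)
  }

  result <- structure(list(config = config, qc = qc,
                           measures = measures, stats = stats_tab,
                           correlations = correlations,
                           coefficient = coefficient,
                           model_base = model_base,
                           model_improved = model_improved,
                           evaluation = evaluation),
                      class = "pipeline_result")
  if (!is.null(out)) write_pipeline_reports(result, out)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== QC ==\n"); print(x$qc)
  cat("\n== Class statistics ==\n"); print(x$stats, row.names = FALSE)
  cat("\n== Base classifier ==\n"); print(x$model_base)
  print(x$evaluation$base$confusion)
  if (!is.null(x$model_improved)) {
    cat("\n== Improvement ==\n"); print(x$coefficient)
    print(x$model_improved)
    print(x$evaluation$improved$confusion)
    cat(sprintf("AUC: base %.4f -> improved %.4f\n",
                x$evaluation$base$auc, x$evaluation$improved$auc))
  }
  invisible(x)
}

#' @export
as_report.pipeline_result <- function(x, ...) {
  eval_rep <- function(ev) {
    list(confusion = as_report(ev$confusion),
         predicted_accuracy = as.list(ev$predicted),
         auc = ev$auc,
         thresholds = stats::setNames(as.list(ev$thresholds$chi),
                                      rownames(ev$thresholds)))
  }
  rep <- list(config = x$config[setdiff(names(x$config), "class_map")],
              qc = as_report(x$qc),
              model = as_report(x$model_base),
              evaluation = eval_rep(x$evaluation$base))
  if (!is.null(x$model_improved)) {
    rep$coefficient <- list(c_opt = x$coefficient$c_opt,
                            c_closed_form = x$coefficient$c_closed_form,
                            r_overall = x$coefficient$r_overall)
    rep$model_improved <- as_report(x$model_improved)
    rep$evaluation_improved <- eval_rep(x$evaluation$improved)
  }
  rep
}

#' @noRd
write_pipeline_reports <- function(result, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_report(result, file.path(out, "report.json"))
  utils::write.table(result$stats, file.path(out, "class_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Map a pipeline failure to the documented exit status
#'
#' Runs `expr`; returns 0 on success, 2 on validation failure, 3 on
#' degenerate statistics, 1 on any other error. Used by the
#' command-line driver.
#'
#' @param expr expression to evaluate.
#' @return list with `status` (integer) and `value` (result or
#'   condition message).
#' @export
with_exit_status <- function(expr) {
  tryCatch(
    list(status = 0L, value = force(expr)),
    qpcr_validation_error = function(e)
      list(status = 2L, value = conditionMessage(e)),
    qpcr_degenerate_error = function(e)
      list(status = 3L, value = conditionMessage(e)),
    error = function(e) list(status = 1L, value = conditionMessage(e)))
}
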