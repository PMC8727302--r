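#' Fit the single-cell relapse-risk classifier to a cohort
#'
#' Runs the full estimation path on a UMI count matrix: QC filtering
#' (mitochondrial-gene removal, transcript threshold), gene blacklisting,
#' depth normalization, optional healthy-cell exclusion, per-cell
#' sensitivity/resistance module scores and PC score, median-quadrant
#' categorization, per-patient quantification and relapse-risk calls. The
#' fitted parameters are the dataset-wide score medians; [predict()] applies
#' them to new cells.
#'
#' @param counts A [cell_counts()] object (cells x genes UMI counts with
#'   annotations).
#' @param modules Named list with `sensitivity` and `resistance`
#'   [gene_module()]s, e.g. from [read_modules()].
#' @param patient_meta Optional data.frame with `patient` and `outcome`
#'   (`relapse` / `no-relapse` / `unknown`) used to evaluate the risk calls.
#' @param marker_module Optional [gene_module()] of healthy-cell markers;
#'   when given, marker-high cells are excluded before scoring.
#' @param min_transcripts,target_sum,threshold_sd Preprocessing parameters;
#'   see [qc_filter()], [normalize_counts()], [exclude_healthy_cells()].
#' @param n_bins,n_ctrl Scoring parameters; see [module_score()].
#' @param rule,threshold Risk-call rule; see [risk_call()].
#' @param seed Master seed for the control-gene draws.
#' @return An object of class `relapse_fit`: list with `scores`
#'   (per-cell `module_score_table` with `category` column), `medians`,
#'   `patients` (per-patient summary with fractions, PC mean/SEM, risk call
#'   and outcome), `evaluation` (or `NULL` without outcomes), `excluded`,
#'   `norm` (the preprocessed matrix, for downstream DE), `params`, `call`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 3, cells_per_patient = 60,
#'                                      n_genes = 600, n_sens_genes = 60,
#'                                      n_res_genes = 30, seed = 7))
#' fit <- relapse_fit(cohort$counts, cohort$modules,
#'                    patient_meta = cohort$patients)
#' summary(fit)
#' @export
relapse_fit <- function(counts, modules, patient_meta = NULL,
                        marker_module = NULL,
                        min_transcripts = 500, target_sum = 3500,
                        threshold_sd = 2, n_bins = 24, n_ctrl = 100,
                        rule = "resistant-majority", threshold = 0.3,
                        seed = 1L) {
  cl <- match.call()
  norm <- preprocess(counts, min_transcripts = min_transcripts,
                     target_sum = target_sum,
                     marker_module = marker_module,
                     threshold_sd = threshold_sd,
                     n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, "preprocess"))
  scores <- score_cells(norm, modules, n_bins = n_bins, n_ctrl = n_ctrl,
                        seed = seed)
  cats <- categorize_cells(scores)
  scores$category <- cats$category
  pmap <- stats::setNames(norm$cells$patient, norm$cells$cell)

  patients <- patient_fractions(cats, pmap)
  pc_sum <- patient_pc_summary(scores, pmap)
  patients <- merge(patients, pc_sum[, c("patient", "mean_pc", "sem_pc")],
                    by = "patient", sort = TRUE)
  patients <- risk_call(patients, rule = rule, threshold = threshold)
  rl <- attr(patients, "rule")

  evaluation <- NULL
  if (!is.null(patient_meta) && "outcome" %in% names(patient_meta)) {
    patients$outcome <- patient_meta$outcome[
      match(patients$patient, patient_meta$patient)]
    known <- !is.na(patients$outcome) & patients$outcome != "unknown"
    if (any(known)) {
      evaluation <- evaluate_predictions(patients$risk_call[known],
                                         patients$outcome[known])
    }
  } else {
    patients$outcome <- NA_character_
  }
  attr(patients, "rule") <- rl

  structure(list(scores = scores, medians = attr(cats, "medians"),
                 patients = patients, evaluation = evaluation,
                 excluded = attr(norm, "excluded"), norm = norm,
                 params = list(min_transcripts = min_transcripts,
                               target_sum = target_sum,
                               threshold_sd = threshold_sd,
                               n_bins = n_bins, n_ctrl = n_ctrl,
                               rule = rule, threshold = threshold,
                               seed = seed),
                 call = cl),
            class = "relapse_fit")
}

#' @export
print.relapse_fit <- function(x, ...) {
  cat("Single-cell relapse-risk classification\n")
  cat(sprintf("  %d cells scored across %d patients (%d excluded as healthy)\n",
              nrow(x$scores), nrow(x$patients), length(x$excluded)))
  cat(sprintf("  score medians: sensitivity %.4f, resistance %.4f\n",
              x$medians[["sensitivity"]], x$medians[["resistance"]]))
  tab <- table(x$scores$category)
  cat(sprintf("  cells: %d sensitive, %d resistant, %d unclassified\n",
              tab[["sensitive"]], tab[["resistant"]], tab[["unclassified"]]))
  cat(sprintf("  risk rule: %s; %d predicted-relapse / %d predicted-no-relapse\n",
              x$params$rule,
              sum(x$patients$risk_call == "predicted-relapse"),
              sum(x$patients$risk_call == "predicted-no-relapse")))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  outcome agreement: %d/%d correct (accuracy %.3f)\n",
                x$evaluation$correct, x$evaluation$n, x$evaluation$accuracy))
  }
  invisible(x)
}

#' @export
summary.relapse_fit <- function(object, digits = 3, ...) {
  print(object)
  cat("\nPer-patient summary:\n")
  tab <- object$patients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(object$evaluation)) {
    cat("\nConfusion (outcome x call):\n")
    print(object$evaluation$confusion)
  }
  invisible(object)
}

#' Fitted score medians
#'
#' The median-quadrant rule's only estimated parameters: the dataset-wide
#' medians of the sensitivity and resistance scores.
#'
#' @param object A `relapse_fit`.
#' @param ... Ignored.
#' @return Named numeric vector `c(sensitivity, resistance)`.
#' @export
coef.relapse_fit <- function(object, ...) object$medians

#' Classify new scored cells with a fitted model's medians
#'
#' Applies the fitted dataset's score medians to new per-cell scores — the
#' quadrant rule's analogue of out-of-sample prediction. With
#' `type = "patient"`, the cell categories are further aggregated into
#' per-patient fractions and risk calls under the fitted rule.
#'
#' @param object A `relapse_fit`.
#' @param newdata A `module_score_table` (or data.frame with
#'   `sensitivity_score`, `resistance_score`, and for patient-level output
#'   `patient`). Defaults to the training scores.
#' @param type `"cell"` for per-cell categories, `"patient"` for per-patient
#'   fractions plus risk calls.
#' @param ... Ignored.
#' @return See `type`.
#' @export
predict.relapse_fit <- function(object, newdata = NULL,
                                type = c("cell", "patient"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$scores
  cats <- categorize_cells(newdata, medians = object$medians)
  if (type == "cell") return(cats)
  pmap <- stats::setNames(newdata$patient, newdata$cell)
  out <- patient_fractions(cats, pmap)
  risk_call(out, rule = object$params$rule,
            threshold = object$params$threshold)
}

#' Module-score scatter of a fitted classification
#'
#' Sensitivity vs resistance score per cell, colored by category, with the
#' fitted medians drawn as quadrant boundaries.
#'
#' @param x A `relapse_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.relapse_fit <- function(x, ...) {
  s <- x$scores
  cols <- c(sensitive = "#1b7837", resistant = "#762a83",
            unclassified = "grey70")
  graphics::plot(s$resistance_score, s$sensitivity_score,
                 col = cols[as.character(s$category)], pch = 16, cex = 0.5,
                 xlab = "resistance score", ylab = "sensitivity score", ...)
  graphics::abline(v = x$medians[["resistance"]],
                   h = x$medians[["sensitivity"]], lty = 2, col = "grey40")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}
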