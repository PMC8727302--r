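# Median-quadrant categorization of cells, per-patient summaries,
# relapse-risk calls and their evaluation against outcomes.

#' Categorize cells as sensitive or resistant (median-quadrant rule)
#'
#' Medians of the sensitivity and resistance scores are taken over the
#' complete set of cells passed in (cross-patient). A cell is *sensitive*
#' when its sensitivity score is strictly above the median sensitivity score
#' and its resistance score strictly below the median resistance score;
#' *resistant* for the converse; everything else — including ties at either
#' median — is *unclassified*.
#'
#' @param scores A `module_score_table` (or any data.frame with columns
#'   `cell`, `sensitivity_score`, `resistance_score`).
#' @param medians Optional `c(sensitivity, resistance)` median pair to apply
#'   instead of recomputing (used when projecting new cells onto a fitted
#'   dataset's medians).
#' @return Data.frame with columns `cell`, `category` (factor
#'   sensitive/resistant/unclassified); the medians used are in attribute
#'   `"medians"`.
#' @export
categorize_cells <- function(scores, medians = NULL) {
  if (nrow(scores) == 0) stop("no scored cells to categorize")
  s <- scores$sensitivity_score
  r <- scores$resistance_score
  if (is.null(medians)) {
    if (nrow(scores) < 2) stop("medians need at least 2 scored cells")
    medians <- c(sensitivity = stats::median(s), resistance = stats::median(r))
  } else {
    medians <- c(sensitivity = unname(medians[[1]]),
                 resistance = unname(medians[[2]]))
  }
  category <- rep("unclassified", nrow(scores))
  category[s > medians[["sensitivity"]] & r < medians[["resistance"]]] <- "sensitive"
  category[r > medians[["resistance"]] & s < medians[["sensitivity"]]] <- "resistant"
  out <- data.frame(cell = scores$cell,
                    category = factor(category,
                                      levels = c("sensitive", "resistant",
                                                 "unclassified")))
  attr(out, "medians") <- medians
  out
}

#' Per-patient sensitive/resistant fractions
#'
#' @param categories Output of [categorize_cells()].
#' @param patient_map Named character vector or data.frame (`cell`,
#'   `patient`) mapping every categorized cell to a patient.
#' @return Data.frame with one row per patient: `patient`, `n_cells`,
#'   `n_sensitive`, `n_resistant`, `frac_sensitive`, `frac_resistant`.
#' @export
patient_fractions <- function(categories, patient_map) {
  pat <- lookup_patients(categories$cell, patient_map)
  tab <- table(patient = pat, category = categories$category)
  n <- rowSums(tab)
  data.frame(patient = rownames(tab),
             n_cells = as.integer(n),
             n_sensitive = as.integer(tab[, "sensitive"]),
             n_resistant = as.integer(tab[, "resistant"]),
             frac_sensitive = as.numeric(tab[, "sensitive"] / n),
             frac_resistant = as.numeric(tab[, "resistant"] / n),
             row.names = NULL)
}

lookup_patients <- function(cells, patient_map) {
  if (is.data.frame(patient_map)) {
    patient_map <- stats::setNames(as.character(patient_map$patient),
                                   patient_map$cell)
  }
  pat <- patient_map[cells]
  if (any(is.na(pat))) {
    stop("unknown patient id for cell(s): ",
         paste(utils::head(cells[is.na(pat)], 5), collapse = ", "))
  }
  unname(pat)
}

#' Per-patient mean and standard error of the PC score
#'
#' @param pc Named numeric vector of per-cell PC scores (names = cell ids),
#'   or a `module_score_table`.
#' @param patient_map As in [patient_fractions()].
#' @return Data.frame `patient`, `n_cells`, `mean_pc`, `sem_pc`. SEM uses
#'   the sample SD (n - 1); for single-cell patients it is `NA`.
#' @export
patient_pc_summary <- function(pc, patient_map) {
  if (is.data.frame(pc)) {
    pc <- stats::setNames(pc$pc_score, pc$cell)
  }
  pat <- lookup_patients(names(pc), patient_map)
  sp <- split(unname(pc), pat)
  data.frame(patient = names(sp),
             n_cells = lengths(sp),
             mean_pc = vapply(sp, mean, numeric(1)),
             sem_pc = vapply(sp, function(x) {
               if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
             }, numeric(1)),
             row.names = NULL)
}

#' Call relapse risk per patient
#'
#' Default rule `"resistant-majority"`: a patient is predicted to relapse
#' when the fraction of resistant cells exceeds the fraction of sensitive
#' cells. An exact tie is called predicted-no-relapse (conservative toward
#' the unclassified mass). Rule `"resistant-threshold"` instead compares
#' `frac_resistant` to a fixed `threshold`. The rule used is recorded in
#' attribute `"rule"`.
#'
#' @param summary Data.frame from [patient_fractions()].
#' @param rule `"resistant-majority"` or `"resistant-threshold"`.
#' @param threshold Resistant-fraction cutoff for the threshold rule.
#' @return The input with a `risk_call` column added
#'   (predicted-relapse / predicted-no-relapse).
#' @export
risk_call <- function(summary, rule = c("resistant-majority",
                                        "resistant-threshold"),
                      threshold = 0.3) {
  rule <- match.arg(rule)
  hit <- switch(rule,
                "resistant-majority" =
                  summary$frac_resistant > summary$frac_sensitive,
                "resistant-threshold" =
                  summary$frac_resistant > threshold)
  summary$risk_call <- ifelse(hit, "predicted-relapse", "predicted-no-relapse")
  attr(summary, "rule") <- rule
  summary
}

#' Evaluate risk calls against known outcomes
#'
#' @param calls Character vector of risk calls (`predicted-relapse` /
#'   `predicted-no-relapse`), or a data.frame with `risk_call`.
#' @param outcomes Character vector of true outcomes (`relapse` /
#'   `no-relapse`; `unknown`/`NA` entries are dropped), aligned with
#'   `calls`.
#' @return List with `n`, `correct`, `accuracy`, `confusion` (2x2 table) and
#'   `by_class` (per-outcome correct counts and fractions).
#' @export
evaluate_predictions <- function(calls, outcomes) {
  if (is.data.frame(calls)) calls <- calls$risk_call
  stopifnot(length(calls) == length(outcomes))
  keep <- !is.na(outcomes) & outcomes != "unknown"
  if (!any(keep)) stop("no patients with known outcomes to evaluate")
  calls <- calls[keep]
  outcomes <- outcomes[keep]
  pred_relapse <- calls == "predicted-relapse"
  true_relapse <- outcomes == "relapse"
  correct <- pred_relapse == true_relapse
  confusion <- table(outcome = factor(outcomes, c("relapse", "no-relapse")),
                     call = factor(calls, c("predicted-relapse",
                                            "predicted-no-relapse")))
  by_class <- data.frame(
    outcome = c("relapse", "no-relapse"),
    n = c(sum(true_relapse), sum(!true_relapse)),
    correct = c(sum(correct & true_relapse), sum(correct & !true_relapse)))
  by_class$frac_correct <- ifelse(by_class$n > 0,
                                  by_class$correct / by_class$n, NA_real_)
  list(n = length(calls), correct = sum(correct),
       accuracy = mean(correct), confusion = confusion, by_class = by_class)
}
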