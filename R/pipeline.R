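# One-call orchestration: simulate (or load) -> preprocess -> score ->
# classify -> DE / bulkify, with every artifact serialized plus a manifest
# and a human-readable report.

default_run_config <- function() {
  list(seed = 1L,
       out = NULL,
       simulate = list(enabled = TRUE),
       counts = NULL,
       modules = NULL,
       patient_meta = NULL,
       preprocess = list(min_transcripts = 500, target_sum = 3500,
                         exclude_healthy = TRUE, threshold_sd = 2),
       score = list(n_bins = 24, n_ctrl = 100),
       classify = list(rule = "resistant-majority", threshold = 0.3),
       de = list(enabled = TRUE, min_pct = 0.1),
       bulkify = list(enabled = FALSE, mode = "equal", d = "auto"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline from a config
#'
#' Executes simulate (or load) -> preprocess -> score -> classify and,
#' when enabled, differential expression and pseudobulk construction, as one
#' reproducible run. All stage outputs, the verbatim config, and a manifest
#' (package version, seeds, parameters, cell/gene counts surviving each
#' stage) are written under `config$out`; outputs are fully determined by
#' (config, seed).
#'
#' @param config A YAML file path or a nested list. Top-level keys: `seed`,
#'   `out` (output directory), `simulate` (`enabled` plus any [sim_config()]
#'   argument), `counts` (directory of an MTX triplet, used when simulation
#'   is disabled), `modules` (module CSV path; defaults to the simulated
#'   modules), `patient_meta` (CSV with `patient`, `outcome`), `preprocess`,
#'   `score`, `classify`, `de`, `bulkify` (stage parameter lists).
#' @return Invisibly, a list with the `relapse_fit` object, the DE and
#'   pseudobulk results (when run), the manifest, and the report text.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  if (is.null(cfg$out)) stop("config must set an output directory `out`")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "relapsescore",
                   version = as.character(utils::packageVersion("relapsescore")),
                   seed = seed, stages = list())

  # --- inputs: simulate or load -------------------------------------------
  truth <- NULL
  patient_meta <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate
    sim_args$enabled <- NULL
    sim_args$seed <- derive_seed(seed, "simulate")
    cohort <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(cohort)
    counts <- cohort$counts
    modules <- cohort$modules
    truth <- cohort$truth
    patient_meta <- cohort$patients
    write_counts(counts, file.path(cfg$out, "counts"))
    write_modules(data.frame(
      gene = c(modules$resistance$genes, modules$sensitivity$genes),
      direction = c(rep("up", length(modules$resistance$genes)),
                    rep("down", length(modules$sensitivity$genes)))),
      file.path(cfg$out, "modules.csv"))
    write_precise_csv(truth, file.path(cfg$out, "cell_truth.csv"))
    write_precise_csv(patient_meta, file.path(cfg$out, "patient_meta.csv"))
    manifest$stages$simulate <- list(n_cells = nrow(counts$counts),
                                     n_genes = ncol(counts$counts),
                                     n_patients = nrow(patient_meta))
  } else {
    if (is.null(cfg$counts) || !dir.exists(cfg$counts)) {
      stop("simulation disabled and counts directory missing: ",
           cfg$counts %||% "<unset>")
    }
    counts <- read_counts(cfg$counts, format = "mtx")
    if (is.null(cfg$modules)) stop("simulation disabled: `modules` CSV required")
    modules <- read_modules(cfg$modules)
    if (!is.null(cfg$patient_meta)) {
      patient_meta <- utils::read.csv(cfg$patient_meta)
    }
    manifest$stages$load <- list(n_cells = nrow(counts$counts),
                                 n_genes = ncol(counts$counts))
  }

  # --- fit (preprocess + score + classify) --------------------------------
  marker <- NULL
  if (isTRUE(cfg$preprocess$exclude_healthy) &&
      any(counts$genes$tcell_marker)) {
    marker <- tcell_marker_module(counts)
  }
  fit <- relapse_fit(counts, modules, patient_meta = patient_meta,
                     marker_module = marker,
                     min_transcripts = cfg$preprocess$min_transcripts,
                     target_sum = cfg$preprocess$target_sum,
                     threshold_sd = cfg$preprocess$threshold_sd,
                     n_bins = cfg$score$n_bins, n_ctrl = cfg$score$n_ctrl,
                     rule = cfg$classify$rule,
                     threshold = cfg$classify$threshold,
                     seed = derive_seed(seed, "score"))
  write_results(fit$scores, fit$patients, cfg$out)
  manifest$stages$preprocess <- list(
    cells_retained = nrow(fit$norm$values),
    genes_retained = ncol(fit$norm$values),
    cells_excluded_healthy = length(fit$excluded),
    provenance = fit$norm$provenance)
  manifest$stages$classify <- list(
    medians = as.list(fit$medians),
    rule = cfg$classify$rule,
    categories = as.list(table(fit$scores$category)))

  # --- DE ------------------------------------------------------------------
  de <- NULL
  if (isTRUE(cfg$de$enabled)) {
    grp <- as.character(fit$scores$category)
    grp[grp == "unclassified"] <- NA
    if (length(unique(stats::na.omit(grp))) == 2) {
      de <- differential_expression(fit$norm, grp,
                                    min_pct = cfg$de$min_pct,
                                    seed = derive_seed(seed, "de"))
      write_precise_csv(de, file.path(cfg$out, "de.csv"))
      manifest$stages$de <- list(n_tested = attr(de, "n_tested"),
                                 n_significant = sum(de$significant))
    }
  }

  # --- pseudobulk ----------------------------------------------------------
  bulk <- NULL
  if (isTRUE(cfg$bulkify$enabled)) {
    pool <- pool_bulk(counts, mode = cfg$bulkify$mode, d = cfg$bulkify$d,
                      seed = derive_seed(seed, "bulkify"))
    bulk <- bulk_module_score(pool, modules,
                              target_sum = cfg$preprocess$target_sum,
                              n_bins = cfg$score$n_bins,
                              n_ctrl = cfg$score$n_ctrl,
                              seed = derive_seed(seed, "bulkify", 3))
    write_precise_csv(bulk, file.path(cfg$out, "bulk_scores.csv"))
    manifest$stages$bulkify <- list(mode = pool$mode, d = pool$d,
                                    cells_dropped = pool$cells_dropped)
  }

  report <- make_report(fit$patients, fit$evaluation)
  writeLines(report, file.path(cfg$out, "report.md"))
  jsonlite::write_json(cfg, file.path(cfg$out, "config.json"),
                       auto_unbox = TRUE, null = "null")
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fit = fit, de = de, bulk = bulk, truth = truth,
                 manifest = manifest, report = report, out = cfg$out))
}

#' Render a per-patient text report
#'
#' Markdown table of per-patient fractions, risk calls and outcomes, with an
#' accuracy line when outcomes are known. Misclassified patients are marked,
#' never dropped.
#'
#' @param summaries Per-patient summary (from a `relapse_fit` or
#'   [risk_call()]).
#' @param evaluation Optional result of [evaluate_predictions()].
#' @return Character vector of report lines.
#' @export
make_report <- function(summaries, evaluation = NULL) {
  lines <- c("# Relapse-risk classification report", "")
  if (is.null(summaries) || nrow(summaries) == 0) {
    return(c(lines, "No patients in this run."))
  }
  has_outcome <- "outcome" %in% names(summaries) &&
    any(!is.na(summaries$outcome))
  header <- "| patient | cells | frac sensitive | frac resistant | call |"
  sep <- "|---|---|---|---|---|"
  if (has_outcome) {
    header <- paste0(header, " outcome | agree |")
    sep <- paste0(sep, "---|---|")
  }
  lines <- c(lines, header, sep)
  for (i in seq_len(nrow(summaries))) {
    row <- sprintf("| %s | %d | %.3f | %.3f | %s |",
                   summaries$patient[i], summaries$n_cells[i],
                   summaries$frac_sensitive[i], summaries$frac_resistant[i],
                   summaries$risk_call[i])
    if (has_outcome) {
      oc <- summaries$outcome[i]
      agree <- if (is.na(oc) || oc == "unknown") {
        "?"
      } else if ((summaries$risk_call[i] == "predicted-relapse") ==
                 (oc == "relapse")) {
        "yes"
      } else {
        "NO"
      }
      row <- sprintf("%s %s | %s |", row,
                     if (is.na(oc)) "unknown" else oc, agree)
    }
    lines <- c(lines, row)
  }
  lines <- c(lines, "")
  if (!is.null(evaluation)) {
    lines <- c(lines,
               sprintf("Accuracy: %d/%d correct (%.3f).",
                       evaluation$correct, evaluation$n,
                       evaluation$accuracy),
               sprintf("Relapse patients: %d/%d correct; no-relapse: %d/%d correct.",
                       evaluation$by_class$correct[1],
                       evaluation$by_class$n[1],
                       evaluation$by_class$correct[2],
                       evaluation$by_class$n[2]))
  } else {
    lines <- c(lines, "Accuracy: unavailable (no known outcomes).")
  }
  lines
}
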