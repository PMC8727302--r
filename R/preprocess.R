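# QC filtering, gene blacklisting, healthy-cell exclusion, depth
# normalization and per-gene scaling.

#' Quality-control filter: drop mitochondrial genes, then shallow cells
#'
#' Mitochondrial genes are removed first (their expression is too variable to
#' be informative); cells whose *remaining* total falls below
#' `min_transcripts` are then removed. The threshold is inclusive: a cell
#' with exactly `min_transcripts` non-mitochondrial transcripts is kept.
#' Survivor order is preserved.
#'
#' @param counts A [cell_counts()] object with mitochondrial genes flagged.
#' @param min_transcripts Minimum retained transcripts per cell (default
#'   500).
#' @return A filtered `cell_counts`. Signals a `relapsescore_empty`
#'   condition if no cell survives.
#' @export
qc_filter <- function(counts, min_transcripts = 500) {
  stopifnot(inherits(counts, "cell_counts"), min_transcripts >= 0)
  keep_genes <- which(!counts$genes$mito)
  x <- counts[, keep_genes]
  totals <- cell_totals(x)
  keep_cells <- which(totals >= min_transcripts)
  if (length(keep_cells) == 0) {
    stop_empty(sprintf("no cell has >= %d non-mitochondrial transcripts",
                       min_transcripts))
  }
  out <- x[keep_cells, ]
  out$provenance <- c(counts$provenance,
                      sprintf("qc_filter(min_transcripts=%d)",
                              as.integer(min_transcripts)))
  out
}

#' Remove blacklisted genes
#'
#' Drops XIST/TSIX, all Y-chromosome genes and hemoglobin genes (flagged in
#' the gene annotation), which track donor sex and erythrocyte contamination
#' rather than leukemic cell state. Cells are untouched; with no flagged
#' genes this is the identity.
#'
#' @param counts A [cell_counts()] object.
#' @return A `cell_counts` without the blacklisted genes.
#' @export
remove_blacklist_genes <- function(counts) {
  stopifnot(inherits(counts, "cell_counts"))
  drop <- counts$genes$hemoglobin | counts$genes$y_linked |
    counts$genes$xist_tsix
  if (!any(drop)) {
    out <- counts
  } else {
    out <- counts[, which(!drop)]
  }
  out$provenance <- c(counts$provenance,
                      sprintf("remove_blacklist_genes(removed=%d)", sum(drop)))
  out
}

#' Depth-normalize and log-transform
#'
#' Each cell's counts are rescaled to a common total of `target_sum`
#' transcripts and log-transformed:
#' `value(c, g) = log(1 + count(c, g) * target_sum / total(c))`.
#' Cells with proportional count vectors therefore map to identical rows.
#'
#' @param counts A [cell_counts()] object; every cell total must be > 0.
#' @param target_sum Common per-cell total after rescaling (default 3500).
#' @return An object of class `norm_matrix`: list with `values` (dense
#'   cells x genes matrix of log-normalized expression), `target_sum`,
#'   `genes`, `cells`, `provenance`.
#' @export
normalize_counts <- function(counts, target_sum = 3500) {
  stopifnot(inherits(counts, "cell_counts"), target_sum > 0)
  totals <- cell_totals(counts)
  if (any(totals == 0)) {
    stop(sprintf("%d cell(s) have zero total counts; run qc_filter() first",
                 sum(totals == 0)))
  }
  m <- as.matrix(counts$counts)
  vals <- log1p(m * (target_sum / totals))
  structure(list(values = vals, target_sum = target_sum,
                 genes = counts$genes, cells = counts$cells,
                 provenance = c(counts$provenance,
                                sprintf("normalize(target_sum=%g)",
                                        target_sum))),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d cells x %d genes (target_sum=%g)\n",
              nrow(x$values), ncol(x$values), x$target_sum))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

subset_norm <- function(norm, i) {
  structure(list(values = norm$values[i, , drop = FALSE],
                 target_sum = norm$target_sum,
                 genes = norm$genes,
                 cells = norm$cells[i, , drop = FALSE],
                 provenance = norm$provenance),
            class = "norm_matrix")
}

#' Exclude healthy (T-like) cells by marker-module score
#'
#' Scores every cell for a T-cell marker module (via [module_score()]) and
#' removes cells scoring above `mean + threshold_sd * SD` of the per-cell
#' marker scores. This replaces cluster-level inspection with an explicit,
#' auditable filter; the excluded cell ids are returned.
#'
#' @param norm A `norm_matrix`.
#' @param marker_module A [gene_module()] of healthy-cell markers.
#' @param threshold_sd Exclusion threshold in SD units above the mean
#'   (default 2).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return List with `norm` (filtered), `excluded` (cell ids) and
#'   `marker_scores` (named vector over all input cells). Signals a
#'   `relapsescore_empty` condition if every cell is excluded.
#' @export
exclude_healthy_cells <- function(norm, marker_module, threshold_sd = 2,
                                  n_bins = 24, n_ctrl = 100, seed = NULL) {
  stopifnot(inherits(norm, "norm_matrix"), inherits(marker_module, "gene_module"))
  sc <- module_score(norm, marker_module, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed)
  cut <- mean(sc) + threshold_sd * stats::sd(sc)
  drop <- is.finite(cut) & sc > cut
  if (all(drop)) stop_empty("all cells excluded as healthy contaminants")
  out <- subset_norm(norm, which(!drop))
  out$provenance <- c(norm$provenance,
                      sprintf("exclude_healthy_cells(threshold_sd=%g, excluded=%d)",
                              threshold_sd, sum(drop)))
  list(norm = out, excluded = names(sc)[drop], marker_scores = sc)
}

#' Scale genes to zero mean and unit variance
#'
#' Centers and scales each gene column using the sample SD (n - 1
#' denominator). Zero-variance genes are kept as all-zero columns and
#' flagged, so gene indices stay aligned across stages. Scaling an already
#' scaled matrix is a no-op (up to floating point).
#'
#' @param norm A `norm_matrix` (or any object with a `values` matrix).
#' @return An object of class `scaled_matrix`: `values`, `zero_variance`
#'   (logical per gene), plus the annotation tables carried through.
#' @export
scale_genes <- function(norm) {
  v <- norm$values
  if (nrow(v) < 2) stop("scaling needs at least 2 cells")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  zero_var <- sdv == 0 | !is.finite(sdv)
  sdv[zero_var] <- 1
  scaled <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  scaled[, zero_var] <- 0
  structure(list(values = scaled, zero_variance = zero_var,
                 genes = norm$genes, cells = norm$cells,
                 provenance = c(norm$provenance, "scale_genes")),
            class = "scaled_matrix")
}

#' Standard preprocessing pipeline
#'
#' Composes the filters in their fixed order — mitochondrial-gene removal
#' and transcript threshold ([qc_filter()]), gene blacklist
#' ([remove_blacklist_genes()]), depth normalization
#' ([normalize_counts()]) — and, if a marker module is supplied, excludes
#' healthy cells after normalization.
#'
#' @param counts A [cell_counts()] object.
#' @param min_transcripts,target_sum See the stage functions.
#' @param marker_module Optional [gene_module()] for healthy-cell exclusion
#'   (set `NULL` to skip).
#' @param threshold_sd,n_bins,n_ctrl See [exclude_healthy_cells()].
#' @param seed Seed for the marker-score control draw.
#' @return A `norm_matrix`; excluded cell ids (if any) in attribute
#'   `"excluded"`.
#' @export
preprocess <- function(counts, min_transcripts = 500, target_sum = 3500,
                       marker_module = NULL, threshold_sd = 2,
                       n_bins = 24, n_ctrl = 100, seed = NULL) {
  x <- qc_filter(counts, min_transcripts = min_transcripts)
  x <- remove_blacklist_genes(x)
  norm <- normalize_counts(x, target_sum = target_sum)
  excluded <- character()
  if (!is.null(marker_module)) {
    keep <- intersect(marker_module$genes, norm$genes$gene)
    if (length(keep) > 0) {
      ex <- exclude_healthy_cells(norm, marker_module,
                                  threshold_sd = threshold_sd,
                                  n_bins = n_bins, n_ctrl = n_ctrl,
                                  seed = seed)
      norm <- ex$norm
      excluded <- ex$excluded
    }
  }
  attr(norm, "excluded") <- excluded
  norm
}
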