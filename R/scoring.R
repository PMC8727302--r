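# Per-cell gene-module scores with expression-binned control genes, and the
# first-PC continuum score over the union of module genes.

#' Assign genes to expression bins
#'
#' Genes are partitioned into `n_bins` near-equal-size groups by the rank of
#' their average expression across all cells. Genes with exactly equal
#' averages share a rank (and hence a bin), so the binning is independent of
#' input gene order; when fewer than `n_bins` distinct averages exist, bins
#' merge and a warning is emitted.
#'
#' @param norm A `norm_matrix`.
#' @param n_bins Number of expression bins (default 24).
#' @return Integer vector of bin ids in `1..n_bins`, named by gene, with
#'   attribute `"n_bins_effective"`.
#' @export
bin_genes_by_expression <- function(norm, n_bins = 24) {
  v <- norm$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty matrix: nothing to bin")
  stopifnot(n_bins >= 1)
  means <- colMeans(v)
  n_distinct <- length(unique(means))
  if (n_distinct < n_bins) {
    warning(sprintf("only %d distinct average-expression values for %d bins; bins merge",
                    n_distinct, n_bins))
  }
  r <- rank(means, ties.method = "min")
  bins <- floor((r - 1) * n_bins / length(means)) + 1L
  names(bins) <- colnames(v)
  attr(bins, "n_bins_effective") <- length(unique(bins))
  bins
}

#' Per-cell gene-module score against binned control genes
#'
#' For each module gene, one control set is drawn from the gene's expression
#' bin (module genes are never admissible as controls) and shared across all
#' cells. A cell's score is the average, over module genes, of the gene's
#' expression minus the mean expression of its control set. Because the
#' control term is a within-cell average, adding a constant to all of a
#' cell's genes cancels exactly.
#'
#' When a bin holds more than `n_ctrl` admissible controls, `n_ctrl` are
#' sampled without replacement; with `n_ctrl` or fewer, all admissible genes
#' in the bin are used (deterministically), which keeps the estimator
#' defined on small fixtures.
#'
#' @param norm A `norm_matrix` of log-normalized expression.
#' @param module A [gene_module()].
#' @param bins Optional precomputed output of [bin_genes_by_expression()];
#'   computed at `n_bins` if omitted.
#' @param n_ctrl Control genes per module gene (default 100).
#' @param n_bins Bins used when `bins` is not supplied (default 24).
#' @param seed Optional seed fixing the control draw.
#' @return Named numeric vector of per-cell scores, with attribute
#'   `"genes_used"` (module genes found in the matrix).
#' @export
module_score <- function(norm, module, bins = NULL, n_ctrl = 100,
                         n_bins = 24, seed = NULL) {
  stopifnot(inherits(module, "gene_module"), n_ctrl >= 1)
  v <- norm$values
  gene_ids <- colnames(v)
  present <- intersect(module$genes, gene_ids)
  if (length(present) == 0) {
    stop(sprintf("none of the %d genes of module '%s' are in the matrix (missing e.g. %s)",
                 length(module$genes), module$name,
                 paste(utils::head(module$genes, 5), collapse = ", ")))
  }
  if (is.null(bins)) bins <- bin_genes_by_expression(norm, n_bins = n_bins)
  stopifnot(identical(names(bins), gene_ids))

  ctrl_sets <- with_seed(seed, {
    lapply(present, function(g) {
      cand <- gene_ids[bins == bins[[g]]]
      cand <- setdiff(cand, module$genes)
      if (length(cand) == 0) {
        stop(sprintf("no admissible control genes in the expression bin of '%s'", g))
      }
      if (length(cand) > n_ctrl) sample(cand, n_ctrl) else cand
    })
  })

  # score = mean over module genes of (expr - mean(ctrl set)); the control
  # part collapses to one weighted column sum per cell.
  w <- numeric(ncol(v))
  names(w) <- gene_ids
  for (cs in ctrl_sets) w[cs] <- w[cs] + 1 / length(cs)
  ctrl_term <- as.vector(v %*% w) / length(present)
  score <- rowMeans(v[, present, drop = FALSE]) - ctrl_term
  names(score) <- rownames(v)
  attr(score, "genes_used") <- length(present)
  score
}

#' First-principal-component continuum score
#'
#' Projects cells onto the leading principal component of the scaled
#' expression matrix restricted to the union of the sensitivity and
#' resistance module genes. The single coordinate summarizes a cell's
#' position along the sensitivity–resistance continuum. The sign of a PC is
#' arbitrary, so the axis is oriented data-drivenly: if the projection
#' correlates negatively with `orient_by` (conventionally the sensitivity
#' score), it is flipped, making high PC scores mean predicted-sensitive.
#'
#' @param scaled A `scaled_matrix` from [scale_genes()].
#' @param union_genes Gene ids to restrict to (typically
#'   `union(sensitivity, resistance)` module genes).
#' @param orient_by Optional numeric vector (one value per cell) used to
#'   orient the axis.
#' @return Named numeric vector of per-cell PC scores.
#' @export
pc_score <- function(scaled, union_genes, orient_by = NULL) {
  v <- scaled$values
  if (nrow(v) < 2) stop("PC score needs at least 2 cells")
  keep <- intersect(union_genes, colnames(v))
  if (length(keep) == 0) stop("none of the union genes are in the matrix")
  x <- v[, keep, drop = FALSE]
  x <- sweep(x, 2, colMeans(x), "-")
  if (all(x == 0)) stop("rank-0 submatrix: no variance over the union genes")
  sv <- svd(x, nu = 1, nv = 1)
  proj <- sv$u[, 1] * sv$d[1]
  if (!is.null(orient_by)) {
    stopifnot(length(orient_by) == nrow(v))
    r <- suppressWarnings(stats::cor(proj, orient_by))
    if (is.finite(r) && r < 0) proj <- -proj
  }
  names(proj) <- rownames(v)
  proj
}

#' Score all cells: sensitivity, resistance and PC score
#'
#' Convenience wrapper producing the per-cell score table the classification
#' consumes. Module scores are computed on log-normalized values; the PC
#' score on gene-scaled values, oriented by the sensitivity score.
#'
#' @param norm A `norm_matrix`.
#' @param modules Named list with `sensitivity` and `resistance`
#'   [gene_module()]s (as from [read_modules()]).
#' @param n_bins,n_ctrl Scoring parameters (defaults 24 and 100).
#' @param seed Seed for the control draws (sensitivity and resistance
#'   modules use derived sub-seeds).
#' @return A data.frame of class `module_score_table` with columns `cell`,
#'   `patient`, `sensitivity_score`, `resistance_score`, `pc_score`;
#'   parameters and per-module `genes_used` in attributes.
#' @export
score_cells <- function(norm, modules, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(all(c("sensitivity", "resistance") %in% names(modules)))
  if (length(intersect(modules$sensitivity$genes,
                       modules$resistance$genes)) > 0) {
    stop("sensitivity and resistance modules must be disjoint")
  }
  bins <- bin_genes_by_expression(norm, n_bins = n_bins)
  sens <- module_score(norm, modules$sensitivity, bins = bins,
                       n_ctrl = n_ctrl,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, "score", 1))
  res <- module_score(norm, modules$resistance, bins = bins,
                      n_ctrl = n_ctrl,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, "score", 2))
  union_genes <- union(modules$sensitivity$genes, modules$resistance$genes)
  scaled <- scale_genes(norm)
  pc <- pc_score(scaled, union_genes, orient_by = sens)
  out <- data.frame(cell = rownames(norm$values),
                    patient = norm$cells$patient,
                    sensitivity_score = unname(sens),
                    resistance_score = unname(res),
                    pc_score = unname(pc))
  class(out) <- c("module_score_table", "data.frame")
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  attr(out, "genes_used") <- c(sensitivity = attr(sens, "genes_used"),
                               resistance = attr(res, "genes_used"))
  out
}
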