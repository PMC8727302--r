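# Differential expression between the two cell states, gene-to-score
# correlation, and pseudobulk construction with bulk-level module scoring.

# Two-sided Wilcoxon rank-sum p-value. For small groups (both sizes <= 10)
# the exact permutation distribution of the rank sum is enumerated, which
# remains correct under ties; otherwise the normal approximation with tie
# correction is used. Two-sided tail: P(|W - E[W]| >= |w - E[W]|).
wilcox_rank_sum_p <- function(x, y, exact_max = 10) {
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    splits <- utils::combn(n, nx)
    ws <- colSums(matrix(r[splits], nrow = nx))
    return(mean(abs(ws - mu) >= abs(w - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Differential expression between sensitive and resistant cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized expression
#' between two cell groups, with a detection prefilter (a gene is tested
#' only if expressed, value > 0, in at least `min_pct` of the cells of one
#' group) and Bonferroni correction over the genes actually tested. The
#' natural-log fold change is
#' `ln(mean(expm1(x_A)) + 1) - ln(mean(expm1(x_B)) + 1)`, i.e. computed on
#' depth-normalized counts, where group A is the first level of `groups`.
#' A gene is flagged significant when its Bonferroni-adjusted p-value is
#' below 0.05 and `|lnFC|` exceeds 0.20.
#'
#' For small groups (both sizes at most 10) the exact permutation
#' distribution of the rank sum is enumerated; larger groups use the
#' tie-corrected normal approximation.
#'
#' @param norm A `norm_matrix`.
#' @param groups Character/factor vector aligned with the cells (rows);
#'   exactly two levels after dropping `NA`s. Cells with `NA` group are
#'   ignored.
#' @param min_pct Detection threshold (default 0.1).
#' @param balance If `TRUE`, subsample the larger group (without
#'   replacement, seeded) to the smaller group's size before testing.
#' @param seed Seed for the balancing subsample.
#' @return Data.frame: `gene`, `ln_fold_change`, `p_value`, `p_bonferroni`,
#'   `pct_1`, `pct_2`, `significant`, ordered by p-value. Untested genes are
#'   absent; the number tested is in attribute `"n_tested"`.
#' @export
differential_expression <- function(norm, groups, min_pct = 0.1,
                                    balance = FALSE, seed = NULL) {
  v <- norm$values
  stopifnot(length(groups) == nrow(v))
  groups <- as.character(groups)
  keep <- !is.na(groups)
  v <- v[keep, , drop = FALSE]
  groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required, got: ",
                             paste(lev, collapse = ", "))
  ia <- which(groups == lev[1])
  ib <- which(groups == lev[2])
  if (length(ia) == 0 || length(ib) == 0) stop("one group is empty")
  if (balance) {
    m <- min(length(ia), length(ib))
    idx <- with_seed(seed, list(sort(sample(ia, m)), sort(sample(ib, m))))
    ia <- idx[[1]]
    ib <- idx[[2]]
  }
  va <- v[ia, , drop = FALSE]
  vb <- v[ib, , drop = FALSE]
  pct1 <- colMeans(va > 0)
  pct2 <- colMeans(vb > 0)
  tested <- which(pmax(pct1, pct2) >= min_pct)
  if (length(tested) == 0) stop("no gene passes the detection prefilter")
  p <- vapply(tested, function(j) wilcox_rank_sum_p(va[, j], vb[, j]),
              numeric(1))
  lnfc <- log(colMeans(expm1(va[, tested, drop = FALSE])) + 1) -
    log(colMeans(expm1(vb[, tested, drop = FALSE])) + 1)
  p_bonf <- pmin(1, p * length(tested))
  out <- data.frame(gene = colnames(v)[tested],
                    ln_fold_change = unname(lnfc),
                    p_value = p,
                    p_bonferroni = p_bonf,
                    pct_1 = unname(pct1[tested]),
                    pct_2 = unname(pct2[tested]),
                    significant = p_bonf < 0.05 & abs(lnfc) > 0.20)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(tested)
  attr(out, "groups") <- stats::setNames(c(length(ia), length(ib)), lev)
  out
}

#' Spearman correlation of every gene with the module scores
#'
#' @param norm A `norm_matrix` (at least 3 cells).
#' @param scores A `module_score_table` aligned with the cells.
#' @return Data.frame: `gene`, `rho_sensitivity`, `rho_resistance`,
#'   `constant` (flag; constant genes have `NA` correlations).
#' @export
correlate_genes_with_scores <- function(norm, scores) {
  v <- norm$values
  if (nrow(v) < 3) stop("gene-score correlation needs at least 3 cells")
  stopifnot(nrow(scores) == nrow(v))
  constant <- apply(v, 2, function(x) length(unique(x)) == 1)
  rho_s <- suppressWarnings(
    as.vector(stats::cor(v, scores$sensitivity_score, method = "spearman")))
  rho_r <- suppressWarnings(
    as.vector(stats::cor(v, scores$resistance_score, method = "spearman")))
  rho_s[constant] <- NA_real_
  rho_r[constant] <- NA_real_
  data.frame(gene = colnames(v), rho_sensitivity = rho_s,
             rho_resistance = rho_r, constant = constant)
}

#' Pool single cells into pseudobulk profiles
#'
#' `mode = "complete"` sums every transcript of every cell per sample.
#' `mode = "equal"` first downsamples each cell without replacement
#' (multivariate hypergeometric) to exactly `d` transcripts so that every
#' contributing cell carries equal weight — the correction needed when
#' resistant cells have systematically fewer transcripts and would otherwise
#' be under-represented. Cells with fewer than `d` transcripts are dropped
#' and counted.
#'
#' @param counts A [cell_counts()] object.
#' @param sample_map Named vector or data.frame (`cell`, `sample`) mapping
#'   cells to pseudobulk samples; defaults to the patient annotation.
#' @param mode `"complete"` or `"equal"`.
#' @param d Per-cell contribution depth for equal mode; `"auto"` uses the
#'   minimum cell total across the dataset.
#' @param seed Seed for the downsampling draws.
#' @return Object of class `pseudobulk`: list with `profiles` (samples x
#'   genes integer matrix), `mode`, `d`, `cells_used`, `cells_dropped`.
#' @export
pool_bulk <- function(counts, sample_map = NULL,
                      mode = c("complete", "equal"), d = "auto",
                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "cell_counts"))
  if (is.null(sample_map)) {
    sample_map <- stats::setNames(counts$cells$patient, counts$cells$cell)
  } else if (is.data.frame(sample_map)) {
    sample_map <- stats::setNames(as.character(sample_map$sample),
                                  sample_map$cell)
  }
  samp <- sample_map[counts$cells$cell]
  if (any(is.na(samp))) stop("cells missing from sample_map")
  m <- as.matrix(counts$counts)
  totals <- rowSums(m)

  if (mode == "complete") {
    prof <- rowsum(m, group = samp)
    used <- as.vector(table(samp)[rownames(prof)])
    return(structure(list(profiles = prof, mode = mode, d = NA_integer_,
                          cells_used = stats::setNames(used, rownames(prof)),
                          cells_dropped = 0L),
                     class = "pseudobulk"))
  }

  if (identical(d, "auto")) d <- min(totals)
  d <- as.integer(d)
  if (d <= 0) stop("d must be a positive count")
  if (all(totals < d)) stop("no cell reaches depth d = ", d)
  keep <- totals >= d
  down <- with_seed(seed, {
    t(vapply(which(keep), function(i) {
      row <- m[i, ]
      if (totals[i] == d) return(as.integer(row))
      picked <- sample.int(totals[i], d)
      tabulate(findInterval(picked - 1, cumsum(row)) + 1L,
               nbins = ncol(m))
    }, integer(ncol(m))))
  })
  colnames(down) <- colnames(m)
  prof <- rowsum(down, group = samp[keep])
  used <- as.vector(table(samp[keep])[rownames(prof)])
  structure(list(profiles = prof, mode = mode, d = d,
                 cells_used = stats::setNames(used, rownames(prof)),
                 cells_dropped = sum(!keep)),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk (%s): %d samples x %d genes\n", x$mode,
              nrow(x$profiles), ncol(x$profiles)))
  if (x$mode == "equal") {
    cat(sprintf("  d = %d transcripts/cell; %d cell(s) below d dropped\n",
                x$d, x$cells_dropped))
  }
  invisible(x)
}

#' Module scores on pseudobulk profiles
#'
#' Normalizes the per-sample profiles exactly like cells (common total,
#' log1p) and applies [module_score()] with samples in the role of cells.
#' Expression binning then uses cross-sample average expression, so at least
#' two samples are required.
#'
#' @param profiles A `pseudobulk` object or a samples x genes count matrix.
#' @param modules Named list with `sensitivity` and `resistance` modules.
#' @param target_sum,n_bins,n_ctrl,seed As in the cell-level pipeline.
#' @return Data.frame: `sample`, `sensitivity_score`, `resistance_score`.
#' @export
bulk_module_score <- function(profiles, modules, target_sum = 3500,
                              n_bins = 24, n_ctrl = 100, seed = 1L) {
  m <- if (inherits(profiles, "pseudobulk")) profiles$profiles else profiles
  if (nrow(m) < 2) {
    stop("bulk scoring needs at least 2 samples; supply a reference panel")
  }
  cc <- cell_counts(m)
  norm <- normalize_counts(cc, target_sum = target_sum)
  bins <- bin_genes_by_expression(norm, n_bins = n_bins)
  sens <- module_score(norm, modules$sensitivity, bins = bins,
                       n_ctrl = n_ctrl,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, "bulkify", 1))
  res <- module_score(norm, modules$resistance, bins = bins,
                      n_ctrl = n_ctrl,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, "bulkify", 2))
  data.frame(sample = rownames(m), sensitivity_score = unname(sens),
             resistance_score = unname(res))
}
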