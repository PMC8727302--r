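#' Cell-by-gene UMI count matrix with annotations
#'
#' The raw substrate of every stage of the pipeline: a cells x genes matrix of
#' non-negative integer UMI counts plus aligned per-gene and per-cell
#' annotation tables. Gene annotations carry the flags the preprocessing
#' filters act on (mitochondrial, hemoglobin, Y-linked, XIST/TSIX, T-cell
#' marker) and a chromosome label; cell annotations carry patient id and
#' sample source.
#'
#' @param counts A cells x genes matrix or `Matrix::sparseMatrix` of
#'   non-negative integers. Row names are cell ids, column names gene ids
#'   (generated if absent).
#' @param genes Optional data.frame of per-gene annotations with columns
#'   `gene`, `chromosome`, and logical flags `mito`, `hemoglobin`, `y_linked`,
#'   `xist_tsix`, `tcell_marker`. Missing columns are filled with defaults.
#' @param cells Optional data.frame of per-cell annotations with columns
#'   `cell`, `patient`, `source`.
#' @param provenance Character vector of operations already applied.
#' @return An object of class `cell_counts`.
#' @export
cell_counts <- function(counts, genes = NULL, cells = NULL,
                        provenance = character()) {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix"))) {
    stop("`counts` must be a matrix of UMI counts (cells x genes)")
  }
  vals <- if (methods::is(counts, "Matrix")) counts@x else as.vector(counts)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    stop("counts must be finite non-negative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene_%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")

  genes <- complete_gene_annotation(genes, colnames(counts))
  cells <- complete_cell_annotation(cells, rownames(counts))
  if (nrow(genes) != ncol(counts) || !identical(genes$gene, colnames(counts))) {
    stop("gene annotation does not align with matrix columns")
  }
  if (nrow(cells) != nrow(counts) || !identical(cells$cell, rownames(counts))) {
    stop("cell annotation does not align with matrix rows")
  }
  structure(list(counts = counts, genes = genes, cells = cells,
                 provenance = provenance),
            class = "cell_counts")
}

gene_flag_columns <- c("mito", "hemoglobin", "y_linked", "xist_tsix",
                       "tcell_marker")

complete_gene_annotation <- function(genes, gene_ids) {
  if (is.null(genes)) genes <- data.frame(gene = gene_ids)
  genes <- as.data.frame(genes)
  if (!"gene" %in% names(genes)) stop("gene annotation needs a `gene` column")
  genes$gene <- as.character(genes$gene)
  if (!"chromosome" %in% names(genes)) genes$chromosome <- NA_character_
  for (fl in gene_flag_columns) {
    if (!fl %in% names(genes)) genes[[fl]] <- FALSE
    genes[[fl]] <- as.logical(genes[[fl]])
  }
  rownames(genes) <- NULL
  genes[, c("gene", "chromosome", gene_flag_columns)]
}

complete_cell_annotation <- function(cells, cell_ids) {
  if (is.null(cells)) cells <- data.frame(cell = cell_ids)
  cells <- as.data.frame(cells)
  if (!"cell" %in% names(cells)) stop("cell annotation needs a `cell` column")
  cells$cell <- as.character(cells$cell)
  if (!"patient" %in% names(cells)) cells$patient <- NA_character_
  if (!"source" %in% names(cells)) cells$source <- NA_character_
  rownames(cells) <- NULL
  cells[, c("cell", "patient", "source",
            setdiff(names(cells), c("cell", "patient", "source")))]
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param x A `cell_counts` object.
#' @param i Cell index (integer, logical, or cell ids).
#' @param j Gene index (integer, logical, or gene ids).
#' @param ... Ignored.
#' @return A `cell_counts` with annotations subset in step.
#' @export
`[.cell_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  cell_counts(x$counts[i, j, drop = FALSE],
              genes = x$genes[j, , drop = FALSE],
              cells = x$cells[i, , drop = FALSE],
              provenance = x$provenance)
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  np <- length(unique(stats::na.omit(x$cells$patient)))
  if (np > 0) cat(sprintf("  patients: %d\n", np))
  flagged <- vapply(x$genes[gene_flag_columns], sum, numeric(1))
  flagged <- flagged[flagged > 0]
  if (length(flagged)) {
    cat("  flagged genes:",
        paste(sprintf("%s=%d", names(flagged), flagged), collapse = ", "), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Per-cell total transcript counts.
cell_totals <- function(x) {
  if (methods::is(x$counts, "Matrix")) {
    Matrix::rowSums(x$counts)
  } else {
    rowSums(x$counts)
  }
}

#' A gene module (directional gene set)
#'
#' A named, directional list of gene symbols: the resistance module ("up",
#' genes apparently upregulated after in vivo prednisone, read as markers of
#' cells surviving treatment) or the sensitivity module ("down", markers of
#' cells eliminated by treatment).
#'
#' @param name Module name.
#' @param direction `"up"` (resistance) or `"down"` (sensitivity).
#' @param genes Character vector of unique gene ids; order preserved.
#' @return An object of class `gene_module`.
#' @export
gene_module <- function(name, direction = c("up", "down"), genes) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (length(genes) == 0) stop("a gene module cannot be empty")
  if (anyDuplicated(genes)) stop("duplicate genes in module '", name, "'")
  structure(list(name = name, direction = direction, genes = genes),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module '%s' (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  invisible(x)
}

#' Build the T-cell marker module from gene annotations
#'
#' Collects the genes flagged `tcell_marker` in a count matrix's annotation
#' into a module usable by [exclude_healthy_cells()].
#'
#' @param counts A `cell_counts` object.
#' @return A `gene_module`, or an error if no genes are flagged.
#' @export
tcell_marker_module <- function(counts) {
  g <- counts$genes$gene[counts$genes$tcell_marker]
  if (length(g) == 0) stop("no genes flagged as T-cell markers")
  gene_module("tcell_marker", "up", g)
}
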