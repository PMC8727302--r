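# On-disk formats: Matrix Market triplets with TSV annotations (10x-style,
# genes as rows on disk, cells x genes in memory), dense TSV matrices, and
# CSV module/result tables.

#' Write a count matrix to a directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate integer, genes as rows per
#' the 10x convention), `genes.tsv` and `barcodes.tsv` (tab-separated, no
#' header). `genes.tsv` columns: gene, chromosome, then the five flag columns
#' (0/1). `barcodes.tsv` columns: cell, patient, source.
#'
#' @param x A [cell_counts()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(t(x$counts), sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  g <- x$genes
  for (fl in gene_flag_columns) g[[fl]] <- as.integer(g[[fl]])
  utils::write.table(g, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     na = "")
  utils::write.table(x$cells[, c("cell", "patient", "source")],
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(dir)
}

#' Read a count matrix
#'
#' `format = "mtx"` expects the layout written by [write_counts()]:
#' `matrix.mtx` (genes x cells on disk), `genes.tsv`, `barcodes.tsv`.
#' `format = "tsv"` expects a dense tab-separated table, cells as rows, with
#' a header of gene ids and first column of cell ids; gene annotations then
#' default to unflagged.
#'
#' @param path Directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return A [cell_counts()] object.
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
    return(cell_counts(as.matrix(tab)))
  }
  mtx_file <- file.path(path, "matrix.mtx")
  genes_file <- file.path(path, "genes.tsv")
  cells_file <- file.path(path, "barcodes.tsv")
  for (f in c(mtx_file, genes_file, cells_file)) {
    if (!file.exists(f)) stop("missing file: ", f)
  }
  m <- Matrix::readMM(mtx_file)
  if (any(m@x < 0)) stop("negative entries in ", mtx_file)
  if (any(m@x != floor(m@x))) stop("non-integer entries in ", mtx_file)
  genes <- utils::read.table(genes_file, sep = "\t", header = FALSE,
                             colClasses = c("character", "character",
                                            rep("integer", 5)),
                             na.strings = "")
  names(genes) <- c("gene", "chromosome", gene_flag_columns)
  cells <- utils::read.table(cells_file, sep = "\t", header = FALSE,
                             colClasses = "character", na.strings = "")
  names(cells) <- c("cell", "patient", "source")[seq_len(ncol(cells))]
  if (nrow(genes) != nrow(m)) {
    stop(sprintf("dimension mismatch: %s has %d rows but %s declares %d genes",
                 genes_file, nrow(genes), mtx_file, nrow(m)))
  }
  if (nrow(cells) != ncol(m)) {
    stop(sprintf("dimension mismatch: %s has %d rows but %s declares %d cells",
                 cells_file, nrow(cells), mtx_file, ncol(m)))
  }
  counts <- t(as.matrix(m))
  rownames(counts) <- cells$cell
  colnames(counts) <- genes$gene
  cell_counts(counts, genes = genes, cells = cells)
}

#' Read a gene-module table
#'
#' Parses a CSV with columns `gene` and `direction` (`up` = resistance,
#' `down` = sensitivity) into the two modules driving the classification.
#' Genes absent from any particular count matrix are *not* dropped here;
#' scoring intersects with the measured genes itself.
#'
#' @param path CSV file path.
#' @return Named list of [gene_module()]s: `resistance` and `sensitivity`.
#' @export
read_modules <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (nrow(tab) == 0) stop("empty module table: ", path)
  if (!all(c("gene", "direction") %in% names(tab))) {
    stop("module table needs columns `gene` and `direction`")
  }
  bad <- setdiff(unique(tab$direction), c("up", "down"))
  if (length(bad)) {
    stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  }
  up <- tab$gene[tab$direction == "up"]
  down <- tab$gene[tab$direction == "down"]
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop("duplicate gene within a direction")
  }
  if (length(intersect(up, down)) > 0) {
    stop("gene(s) listed under both directions: ",
         paste(intersect(up, down), collapse = ", "))
  }
  if (length(up) == 0 || length(down) == 0) {
    stop("module table must contain both an up and a down module")
  }
  list(resistance = gene_module("resistance", "up", up),
       sensitivity = gene_module("sensitivity", "down", down))
}

#' Write the gene-module table
#'
#' @param table Data.frame with columns `gene`, `direction` (as produced by
#'   [generate_module_table()]).
#' @param path Output CSV path.
#' @export
write_modules <- function(table, path) {
  utils::write.csv(table[, c("gene", "direction")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write per-cell and per-patient result tables
#'
#' CSVs with a stable column order and full floating-point precision
#' (15 significant digits); missing scores are emitted as empty fields.
#'
#' @param cell_table Per-cell results (scores, categories).
#' @param patient_table Per-patient summary.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_results <- function(cell_table, patient_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- file.path(dir, "cells.csv")
  pf <- file.path(dir, "patients.csv")
  write_precise_csv(cell_table, cf)
  write_precise_csv(patient_table, pf)
  invisible(c(cells = cf, patients = pf))
}

write_precise_csv <- function(tab, path) {
  tab <- as.data.frame(tab)
  for (j in seq_along(tab)) {
    if (is.double(tab[[j]])) {
      v <- sprintf("%.15g", tab[[j]])
      v[!is.finite(tab[[j]])] <- NA_character_
      tab[[j]] <- v
    }
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path CSV file path.
#' @return A data.frame; empty numeric fields come back as `NA`.
#' @export
read_results <- function(path) {
  utils::read.csv(path, na.strings = "", check.names = FALSE)
}
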