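# Shared fixtures, built in code.

# Small fully-annotated count matrix with hand-set flags.
toy_counts <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 4,
                7, 1, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"),
                              c("gA", "gB", "gC", "gD")))
  genes <- data.frame(gene = colnames(m), chromosome = NA_character_)
  cells <- data.frame(cell = rownames(m), patient = c("P1", "P1", "P2"),
                      source = "BM")
  cell_counts(m, genes = genes, cells = cells)
}

# Tiny default-scale-down simulation config used by many tests.
small_config <- function(seed = 11, ...) {
  sim_config(n_patients = 4, cells_per_patient = 120, n_genes = 600,
             n_sens_genes = 80, n_res_genes = 40,
             contaminant_fraction = 0, seed = seed, ...)
}

# norm_matrix wrapper around an arbitrary dense value matrix.
as_norm <- function(values, target_sum = 3500) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("c%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("g%d", seq_len(ncol(values)))
  }
  structure(list(values = values, target_sum = target_sum,
                 genes = data.frame(gene = colnames(values)),
                 cells = data.frame(cell = rownames(values),
                                    patient = NA_character_,
                                    source = NA_character_),
                 provenance = character()),
            class = "norm_matrix")
}
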