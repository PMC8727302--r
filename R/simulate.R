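#' Configuration for the synthetic cohort generator
#'
#' Parameterizes a negative-binomial scRNA-seq cohort whose statistical
#' structure mirrors what the classification pipeline assumes: strong
#' patient-wise expression offsets, a latent per-cell resistance level in
#' \[0, 1\] driving anti-correlated expression of a resistance and a
#' sensitivity gene program, lower total transcript counts in resistant
#' cells, optional healthy T-like contaminant cells, and patient outcome
#' labels tied to the planted resistant fraction.
#'
#' The latent resistance level of blasts from patient *i* is drawn from a
#' Beta distribution. By default the per-patient Beta parameters are derived
#' (at fixed concentration `beta_concentration`) so that the expected planted
#' resistant fraction, `P(latent > 0.5)`, sweeps `planted_fraction_targets`
#' across patients — by default 15 patients spanning 0.05 to 0.6, emulating a
#' cohort in which the abundance of therapy-resistant blasts varies from
#' marginal to dominant. A patient's true outcome is "relapse" when the
#' realized planted fraction exceeds `relapse_rule_threshold`.
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Cells per patient; a single count or a
#'   `c(min, max)` range sampled uniformly per patient.
#' @param n_genes Genes in the simulated genome (including flagged
#'   mitochondrial/hemoglobin/Y/XIST-TSIX/T-marker genes).
#' @param n_sens_genes,n_res_genes Sizes of the sensitivity ("down") and
#'   resistance ("up") programs. Defaults 370 and 78.
#' @param patient_effect_sd SD of per-patient log-scale mean offsets.
#' @param patient_effect_frac Fraction of genes receiving a patient offset.
#' @param resistance_beta_params Optional `n_patients x 2` matrix of Beta
#'   `(a, b)` parameters for the latent resistance level; overrides the
#'   target-fraction derivation.
#' @param planted_fraction_targets Per-patient target expected resistant
#'   fractions; default `seq(0.05, 0.6, length.out = n_patients)`.
#' @param beta_concentration Concentration `a + b` used when deriving Beta
#'   parameters from targets.
#' @param program_effect Log-scale effect of the latent level on program
#'   genes: resistance-gene means scale by `exp(+effect * latent)`,
#'   sensitivity-gene means by `exp(-effect * latent)`.
#' @param depth_mean_sensitive,depth_mean_resistant Expected library size
#'   (transcripts/cell) at latent 0 and 1; the per-cell expectation
#'   interpolates linearly in the latent level.
#' @param nb_dispersion Negative-binomial size (inverse-dispersion) of
#'   per-gene counts.
#' @param contaminant_fraction Fraction of healthy T-like contaminant cells.
#' @param relapse_rule_threshold Planted resistant-fraction cutoff defining
#'   the true outcome label.
#' @param outcome_noise Probability of flipping a patient's outcome label
#'   (for label-robustness experiments); default 0.
#' @param seed Master seed; all sub-draws use per-patient derived streams so
#'   adding patients does not perturb existing ones.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_patients = 15,
                       cells_per_patient = 300,
                       n_genes = 2000,
                       n_sens_genes = 370,
                       n_res_genes = 78,
                       patient_effect_sd = 0.6,
                       patient_effect_frac = 0.25,
                       resistance_beta_params = NULL,
                       planted_fraction_targets = NULL,
                       beta_concentration = 10,
                       program_effect = 1,
                       depth_mean_sensitive = 4000,
                       depth_mean_resistant = 1500,
                       nb_dispersion = 2,
                       contaminant_fraction = 0.05,
                       relapse_rule_threshold = 0.3,
                       outcome_noise = 0,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes),
              n_sens_genes = as.integer(n_sens_genes),
              n_res_genes = as.integer(n_res_genes),
              patient_effect_sd = patient_effect_sd,
              patient_effect_frac = patient_effect_frac,
              resistance_beta_params = resistance_beta_params,
              planted_fraction_targets = planted_fraction_targets,
              beta_concentration = beta_concentration,
              program_effect = program_effect,
              depth_mean_sensitive = depth_mean_sensitive,
              depth_mean_resistant = depth_mean_resistant,
              nb_dispersion = nb_dispersion,
              contaminant_fraction = contaminant_fraction,
              relapse_rule_threshold = relapse_rule_threshold,
              outcome_noise = outcome_noise,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, all(cfg$cells_per_patient >= 1),
            cfg$n_genes >= 1, cfg$n_sens_genes >= 1, cfg$n_res_genes >= 1)
  if (!length(cfg$cells_per_patient) %in% c(1, 2)) {
    stop("`cells_per_patient` must be a count or a c(min, max) range")
  }
  n_special <- length(special_gene_table()$gene)
  if (cfg$n_sens_genes + cfg$n_res_genes + n_special > cfg$n_genes) {
    stop(sprintf(paste0("programs larger than genome: %d sensitivity + %d ",
                        "resistance + %d flagged genes exceed n_genes = %d"),
                 cfg$n_sens_genes, cfg$n_res_genes, n_special, cfg$n_genes))
  }
  if (cfg$depth_mean_sensitive <= 0 || cfg$depth_mean_resistant <= 0) {
    stop("depth means must be > 0")
  }
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (!is.null(cfg$resistance_beta_params)) {
    bp <- cfg$resistance_beta_params
    if (!is.matrix(bp) || nrow(bp) != cfg$n_patients || ncol(bp) != 2 ||
        any(bp <= 0)) {
      stop("resistance_beta_params must be an n_patients x 2 matrix of positive values")
    }
  }
  if (is.null(cfg$planted_fraction_targets)) {
    cfg$planted_fraction_targets <-
      if (cfg$n_patients == 1) 0.325
      else seq(0.05, 0.6, length.out = cfg$n_patients)
  }
  if (length(cfg$planted_fraction_targets) != cfg$n_patients ||
      any(cfg$planted_fraction_targets <= 0) ||
      any(cfg$planted_fraction_targets >= 1)) {
    stop("planted_fraction_targets must give one value in (0, 1) per patient")
  }
  structure(cfg, class = "sim_config")
}

# Fixed roster of flagged genes. A handful of real symbols for each class;
# the flags, not the names, drive the filters.
special_gene_table <- function() {
  tab <- rbind(
    data.frame(gene = sprintf("MT-%02d", 1:13), chromosome = "MT",
               flag = "mito"),
    data.frame(gene = c("HBA1", "HBA2", "HBB", "HBD", "HBG1", "HBG2"),
               chromosome = "16", flag = "hemoglobin"),
    data.frame(gene = c("RPS4Y1", "DDX3Y", "EIF1AY", "KDM5D",
                        "UTY", "USP9Y", "NLGN4Y", "ZFY"),
               chromosome = "Y", flag = "y_linked"),
    data.frame(gene = c("XIST", "TSIX"), chromosome = "X",
               flag = "xist_tsix"),
    data.frame(gene = c("CD3D", "CD3E", "CD3G", "CD2", "CD7", "TRAC",
                        "TRBC1", "TRBC2", "IL7R", "LCK", "ZAP70", "CD8A",
                        "CD8B", "CCL5", "GZMA", "GZMK", "KLRB1", "CD27",
                        "CD28", "ITK", "SKAP1", "THEMIS", "TCF7", "LEF1",
                        "CD5"),
               chromosome = "T", flag = "tcell_marker"))
  tab
}

# Solve per-patient Beta(a, b) at fixed concentration so that
# P(latent > 0.5) equals each target fraction.
beta_params_for_targets <- function(targets, concentration) {
  t(vapply(targets, function(f) {
    g <- function(m) (1 - stats::pbeta(0.5, m * concentration,
                                       (1 - m) * concentration)) - f
    m <- stats::uniroot(g, c(1e-4, 1 - 1e-4), tol = 1e-10)$root
    c(m * concentration, (1 - m) * concentration)
  }, numeric(2)))
}

#' Generate a synthetic single-cell cohort
#'
#' Draws a cell x gene UMI count matrix from a gamma-Poisson (negative
#' binomial) model. Each blast carries a latent resistance level
#' `latent ~ Beta(a_i, b_i)`; its expected library size interpolates between
#' `depth_mean_sensitive` (latent 0) and `depth_mean_resistant` (latent 1);
#' resistance-program gene means scale up and sensitivity-program means
#' scale down multiplicatively with the latent level; a random per-patient
#' gene subset receives log-normal mean offsets so cells cluster by patient.
#' Contaminant T-like cells have no latent level, a shuffled baseline
#' profile, and strongly elevated T-cell marker genes. Counts are
#' reproducible from the config seed; per-patient streams are derived from
#' it, so extending the cohort leaves existing patients' cells unchanged.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `counts`
#'   (a [cell_counts()]), `truth` (per-cell data.frame: `cell`, `patient`,
#'   `latent_resistance`, `is_contaminant`, `true_library_size`), `patients`
#'   (per-patient data.frame: `patient`, `source`, `n_cells`,
#'   `planted_fraction`, `outcome`), and `modules` (list with `sensitivity`
#'   and `resistance` [gene_module()]s matching the planted programs).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  spec <- special_gene_table()
  n_special <- nrow(spec)
  n_generic <- cfg$n_genes - n_special
  gene_ids <- c(spec$gene, sprintf("G%05d", seq_len(n_generic)))

  genes <- data.frame(gene = gene_ids,
                      chromosome = c(spec$chromosome,
                                     rep(NA_character_, n_generic)))
  for (fl in gene_flag_columns) {
    genes[[fl]] <- c(spec$flag == fl, rep(FALSE, n_generic))
  }

  # Program genes come from the unflagged part of the genome.
  res_idx <- n_special + seq_len(cfg$n_res_genes)
  sens_idx <- n_special + cfg$n_res_genes + seq_len(cfg$n_sens_genes)
  modules <- list(
    sensitivity = gene_module("sensitivity", "down", gene_ids[sens_idx]),
    resistance = gene_module("resistance", "up", gene_ids[res_idx]))

  bp <- cfg$resistance_beta_params %||%
    beta_params_for_targets(cfg$planted_fraction_targets,
                            cfg$beta_concentration)

  # Cohort-level draws (baseline means, contaminant profile) from the
  # master seed.
  base <- with_seed(cfg$seed, {
    b <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    b[genes$mito] <- b[genes$mito] * 8  # mito genes are highly expressed
    b
  })
  cont_base <- with_seed(derive_seed(cfg$seed, "contaminant"), {
    cb <- base[sample.int(cfg$n_genes)]
    cb[genes$tcell_marker] <- base[genes$tcell_marker] * 20
    cb[c(res_idx, sens_idx)] <- base[c(res_idx, sens_idx)] * 0.5
    cb
  })

  per_patient <- lapply(seq_len(cfg$n_patients), function(p) {
    simulate_patient(p, cfg, base, cont_base, bp[p, ], res_idx, sens_idx)
  })

  counts <- do.call(rbind, lapply(per_patient, `[[`, "counts"))
  colnames(counts) <- gene_ids
  truth <- do.call(rbind, lapply(per_patient, `[[`, "truth"))
  rownames(truth) <- NULL

  planted <- vapply(per_patient, `[[`, numeric(1), "planted_fraction")
  outcome <- ifelse(planted > cfg$relapse_rule_threshold,
                    "relapse", "no-relapse")
  if (cfg$outcome_noise > 0) {
    flip <- with_seed(derive_seed(cfg$seed, "patient", index = -1),
                      stats::runif(cfg$n_patients) < cfg$outcome_noise)
    outcome[flip] <- ifelse(outcome[flip] == "relapse",
                            "no-relapse", "relapse")
  }
  patients <- data.frame(
    patient = sprintf("P%02d", seq_len(cfg$n_patients)),
    source = "BM",
    n_cells = vapply(per_patient, function(x) nrow(x$truth), integer(1)),
    planted_fraction = planted,
    outcome = outcome)

  cells_df <- data.frame(cell = truth$cell, patient = truth$patient,
                         source = "BM")
  cc <- cell_counts(counts, genes = genes, cells = cells_df,
                    provenance = "simulated")
  structure(list(counts = cc, truth = truth, patients = patients,
                 modules = modules, config = cfg),
            class = "sim_cohort")
}

simulate_patient <- function(p, cfg, base, cont_base, bp, res_idx, sens_idx) {
  with_seed(derive_seed(cfg$seed, "patient", index = p), {
    n_c <- if (length(cfg$cells_per_patient) == 2) {
      sample(cfg$cells_per_patient[1]:cfg$cells_per_patient[2], 1)
    } else {
      cfg$cells_per_patient
    }
    G <- cfg$n_genes
    is_cont <- stats::runif(n_c) < cfg$contaminant_fraction
    n_blast <- sum(!is_cont)
    latent <- rep(NA_real_, n_c)
    latent[!is_cont] <- stats::rbeta(n_blast, bp[1], bp[2])

    lib <- ifelse(is_cont, cfg$depth_mean_sensitive,
                  cfg$depth_mean_sensitive +
                    latent * (cfg$depth_mean_resistant -
                              cfg$depth_mean_sensitive))

    # Patient-specific log-normal offsets on a random gene subset.
    n_off <- round(cfg$patient_effect_frac * G)
    off <- rep(1, G)
    if (n_off > 0 && cfg$patient_effect_sd > 0) {
      idx <- sample.int(G, n_off)
      off[idx] <- exp(stats::rnorm(n_off, 0, cfg$patient_effect_sd))
    }
    mean_blast <- base * off

    E <- matrix(mean_blast, nrow = n_c, ncol = G, byrow = TRUE)
    lat0 <- ifelse(is.na(latent), 0, latent)
    E[, res_idx] <- E[, res_idx] * exp(cfg$program_effect * lat0)
    E[, sens_idx] <- E[, sens_idx] * exp(-cfg$program_effect * lat0)
    if (any(is_cont)) {
      E[is_cont, ] <- matrix(cont_base, nrow = sum(is_cont), ncol = G,
                             byrow = TRUE)
    }
    mu <- E / rowSums(E) * lib
    counts <- matrix(stats::rnbinom(n_c * G, mu = mu,
                                    size = cfg$nb_dispersion),
                     nrow = n_c, ncol = G)
    pid <- sprintf("P%02d", p)
    rownames(counts) <- sprintf("%s_c%04d", pid, seq_len(n_c))

    planted <- if (n_blast > 0) mean(latent[!is_cont] > 0.5) else 0
    list(counts = counts,
         truth = data.frame(cell = rownames(counts), patient = pid,
                            latent_resistance = latent,
                            is_contaminant = is_cont,
                            true_library_size = rowSums(counts)),
         planted_fraction = planted)
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d patients, %d cells x %d genes\n",
              nrow(x$patients), nrow(x$counts$counts),
              ncol(x$counts$counts)))
  cat(sprintf("  planted resistant fractions: %.2f .. %.2f; %d relapse / %d no-relapse\n",
              min(x$patients$planted_fraction),
              max(x$patients$planted_fraction),
              sum(x$patients$outcome == "relapse"),
              sum(x$patients$outcome == "no-relapse")))
  invisible(x)
}

#' Build a gene-module table over a gene universe
#'
#' Draws disjoint "up" (resistance) and "down" (sensitivity) gene sets from a
#' gene universe and returns them both as [gene_module()] objects and as a
#' CSV-serializable two-column table. Pass `up_genes`/`down_genes` to pin the
#' sets (e.g. to a simulator's planted programs) instead of sampling.
#'
#' @param gene_universe Character vector of candidate gene ids.
#' @param n_up,n_down Module sizes; defaults 78 and 370.
#' @param up_genes,down_genes Optional explicit gene sets (must be disjoint
#'   subsets of the universe).
#' @param seed Optional seed for the sampling.
#' @return List with `modules` (list of `resistance`, `sensitivity`) and
#'   `table` (data.frame with columns `gene`, `direction`).
#' @export
generate_module_table <- function(gene_universe, n_up = 78, n_down = 370,
                                  up_genes = NULL, down_genes = NULL,
                                  seed = NULL) {
  gene_universe <- as.character(gene_universe)
  if (anyDuplicated(gene_universe)) stop("gene universe contains duplicates")
  if (is.null(up_genes) || is.null(down_genes)) {
    if (n_up + n_down > length(gene_universe)) {
      stop(sprintf("requested %d + %d module genes from a universe of %d",
                   n_up, n_down, length(gene_universe)))
    }
    picked <- with_seed(seed, sample(gene_universe, n_up + n_down))
    up_genes <- picked[seq_len(n_up)]
    down_genes <- picked[n_up + seq_len(n_down)]
  }
  if (!all(c(up_genes, down_genes) %in% gene_universe)) {
    stop("explicit module genes must lie in the gene universe")
  }
  if (length(intersect(up_genes, down_genes)) > 0) {
    stop("up and down modules must be disjoint")
  }
  list(modules = list(resistance = gene_module("resistance", "up", up_genes),
                      sensitivity = gene_module("sensitivity", "down",
                                                down_genes)),
       table = data.frame(gene = c(up_genes, down_genes),
                          direction = c(rep("up", length(up_genes)),
                                        rep("down", length(down_genes)))))
}

#' In-silico treatment selection
#'
#' Emulates in vitro glucocorticoid exposure: each cell survives
#' independently with probability `kill_curve(latent_resistance)`, so an
#' increasing curve enriches for resistant cells. Contaminant (healthy)
#' cells, which have no latent resistance level, always survive.
#'
#' @param counts A `cell_counts` object.
#' @param truth The matching per-cell truth table from [generate_cohort()].
#' @param kill_curve Function mapping latent resistance in \[0, 1\] to a
#'   survival probability in \[0, 1\].
#' @param seed Optional seed for the survival draws.
#' @return List with `counts` and `truth` restricted to surviving cells.
#'   Signals a `relapsescore_empty` condition if no cell survives.
#' @export
apply_selection <- function(counts, truth, kill_curve, seed = NULL) {
  stopifnot(inherits(counts, "cell_counts"),
            identical(truth$cell, counts$cells$cell))
  grid <- seq(0, 1, by = 0.01)
  pg <- kill_curve(grid)
  if (any(!is.finite(pg)) || any(pg < 0) || any(pg > 1)) {
    stop("kill_curve must map [0, 1] into [0, 1]")
  }
  surv_p <- ifelse(truth$is_contaminant, 1,
                   kill_curve(truth$latent_resistance))
  if (any(!is.finite(surv_p)) || any(surv_p < 0) || any(surv_p > 1)) {
    stop("kill_curve must map [0, 1] into [0, 1]")
  }
  keep <- with_seed(seed, stats::runif(length(surv_p)) < surv_p)
  if (!any(keep)) stop_empty("no cells survived selection")
  out_counts <- counts[which(keep), ]
  out_counts$provenance <- c(out_counts$provenance, "selection")
  list(counts = out_counts, truth = truth[keep, , drop = FALSE])
}
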