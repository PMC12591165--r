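# Shared fixture builders: everything is generated in code at test time.

# Small three-group study configuration; overrides are merged on top.
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 120, n_cell_types = 2, samples_per_group = 3,
         cells_per_sample_per_type = 40, n_aging_genes_per_type = 10,
         aging_effect_size = 0.15, dispersion = 10, seed = 42),
    list(...))
  do.call(simulation_config, args)
}

# Hand-built bundle with explicit counts (genes x cells).
tiny_bundle <- function(counts, gene_ids = NULL, groups = NULL,
                        cell_types = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  n_genes <- nrow(counts)
  n_cells <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n_genes))
  barcodes <- sprintf("cell%03d", seq_len(n_cells))
  meta <- data.frame(
    barcode = barcodes,
    sample = if (is.null(samples)) rep("S1", n_cells) else samples,
    group = if (is.null(groups)) rep("young_vehicle", n_cells) else groups,
    age_months = 3,
    cell_type = if (is.null(cell_types)) rep("CT01", n_cells) else cell_types,
    stringsAsFactors = FALSE)
  dataset_bundle(counts, gene_ids, barcodes, meta)
}

# Pseudocell set fabricated directly from an expression matrix
# (genes x pseudocells), bypassing aggregation, for clock unit tests.
fabricated_pset <- function(expr, samples, ages, groups = NULL,
                            cell_type = "CT01") {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(expr)))
  rownames(expr) <- gene_ids
  labels <- data.frame(
    pseudocell_id = sprintf("pc%04d", seq_len(n)),
    sample = samples,
    group = if (is.null(groups)) rep("young_vehicle", n) else groups,
    cell_type = cell_type,
    replicate_index = seq_len(n),
    age_months = ages,
    stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(matrix(1, nrow(expr), n), sparse = TRUE)
  norm <- Matrix::Matrix(expr, sparse = TRUE)
  dimnames(counts) <- dimnames(norm) <- list(gene_ids, labels$pseudocell_id)
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 labels = labels,
                 member_ids = stats::setNames(vector("list", n),
                                              labels$pseudocell_id),
                 gene_ids = gene_ids,
                 cells_per_pseudocell = 1L, n_reps = n,
                 normalized = methods::as(norm, "CsparseMatrix")),
            class = "pseudocell_set")
}

# Hand-built clock model for prediction/importance unit tests.
manual_clock <- function(genes, coefficients, intercept,
                         means = rep(0, length(genes)),
                         sds = rep(1, length(genes)),
                         cell_type = "CT01") {
  structure(list(cell_type = cell_type,
                 feature_genes = genes,
                 coefficients = coefficients,
                 intercept = intercept,
                 feature_means = means,
                 feature_sds = sds,
                 training_samples = c("S1", "S2"),
                 hyperparameters = list(alpha = 0.5, lambda = 0,
                                        inner_cv_folds = 5L, seed = 1L)),
            class = "clock_model")
}
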