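#' Configuration for the synthetic single-nucleus simulator
#'
#' Describes a three-group aging/intervention study: young vehicle-treated,
#' aged vehicle-treated, and aged treated animals, each contributing one
#' single-nucleus sample, with a configurable number of hippocampal-style
#' cell types per sample. Counts follow a negative-binomial model: each
#' gene has a log-normal baseline mean, each cell a log-normal library-size
#' factor, and planted "aging program" genes have a log-linear age trend so
#' downstream clock recovery can be checked against closed-form
#' expectations.
#'
#' Treated animals are simulated through an *effective age*: in
#' rejuvenated cell types their planted genes behave as if the animal were
#' `aged - r * (aged - young)` months old (with `r =
#' rejuvenation_fraction`), and elsewhere as fully aged. This makes
#' rejuvenation detection a scalar parameter-recovery problem.
#'
#' @param n_genes Number of genes.
#' @param n_cell_types Number of cell types (default 15).
#' @param cell_type_names Cell-type labels; autogenerated if `NULL`.
#' @param samples_per_group Animals per group (default 5).
#' @param cells_per_sample_per_type Nuclei per sample in each cell type;
#'   defaults to a ~4000-nuclei sample split evenly across cell types.
#' @param young_age_months,aged_age_months Chronological ages in months
#'   since birth (defaults 3 and 12).
#' @param n_aging_genes_per_type Planted age-responsive genes per cell
#'   type (default 50).
#' @param aging_effect_size Log-fold change per month for planted genes
#'   (default 0.15).
#' @param rejuvenated_cell_types Cell types in which treatment lowers the
#'   effective age; must be a subset of `cell_type_names`.
#' @param rejuvenation_fraction Fraction r in \[0, 1\] by which treatment
#'   reverses the young-to-aged gap (default 0.7).
#' @param dispersion Negative-binomial size (inverse-dispersion) parameter
#'   (default 10).
#' @param sample_effect_sd SD (log scale) of the per-animal, per-gene
#'   random effect modelling biological replicate variability between
#'   animals of the same group (default 0.1; 0 disables it).
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of the per-cell library-size factor.
#' @param mean_counts_per_cell Target expected total counts per cell at a
#'   unit library factor, used to anchor baseline gene means.
#' @param baseline_log_sd SD of the log-normal baseline gene means.
#' @param frac_mito_genes,frac_ribo_genes Fractions of genes given
#'   mitochondrial (`mt-`) and ribosomal (`Rps`/`Rpl`) names.
#' @param n_qc_outlier_cells Cells to perturb into QC outliers after
#'   simulation (default 0).
#' @param aging_genes Optional named list (one entry per cell type) of
#'   planted gene ids, e.g. to share one aging program across cell types;
#'   by default disjoint programs are drawn per type when enough genes are
#'   available.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_cell_types = 15,
                              cell_type_names = NULL,
                              samples_per_group = 5,
                              cells_per_sample_per_type = NULL,
                              young_age_months = 3,
                              aged_age_months = 12,
                              n_aging_genes_per_type = 50,
                              aging_effect_size = 0.15,
                              rejuvenated_cell_types = character(),
                              rejuvenation_fraction = 0.7,
                              dispersion = 10,
                              sample_effect_sd = 0.1,
                              library_size_mean = 1,
                              library_size_cv = 0.3,
                              mean_counts_per_cell = 2500,
                              baseline_log_sd = 1,
                              frac_mito_genes = 0.05,
                              frac_ribo_genes = 0.05,
                              n_qc_outlier_cells = 0,
                              aging_genes = NULL,
                              seed = 1) {
  if (is.null(cell_type_names)) {
    cell_type_names <- sprintf("CT%02d", seq_len(n_cell_types))
  }
  if (length(cell_type_names) != n_cell_types) {
    stop("cell_type_names must have length n_cell_types", call. = FALSE)
  }
  if (is.null(cells_per_sample_per_type)) {
    cells_per_sample_per_type <- max(1L, round(4000 / n_cell_types))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              cell_type_names = as.character(cell_type_names),
              samples_per_group = as.integer(samples_per_group),
              cells_per_sample_per_type = as.integer(cells_per_sample_per_type),
              young_age_months = young_age_months,
              aged_age_months = aged_age_months,
              n_aging_genes_per_type = as.integer(n_aging_genes_per_type),
              aging_effect_size = aging_effect_size,
              rejuvenated_cell_types = as.character(rejuvenated_cell_types),
              rejuvenation_fraction = rejuvenation_fraction,
              dispersion = dispersion,
              sample_effect_sd = sample_effect_sd,
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              mean_counts_per_cell = mean_counts_per_cell,
              baseline_log_sd = baseline_log_sd,
              frac_mito_genes = frac_mito_genes,
              frac_ribo_genes = frac_ribo_genes,
              n_qc_outlier_cells = as.integer(n_qc_outlier_cells),
              aging_genes = aging_genes,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  pos <- c("n_genes", "n_cell_types", "samples_per_group",
           "cells_per_sample_per_type")
  for (f in pos) {
    if (cfg[[f]] < 1L) {
      stop("configuration error: ", f, " must be a positive count",
           call. = FALSE)
    }
  }
  if (cfg$rejuvenation_fraction < 0 || cfg$rejuvenation_fraction > 1) {
    stop("configuration error: rejuvenation_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$young_age_months >= cfg$aged_age_months) {
    stop("configuration error: young_age_months must be < aged_age_months",
         call. = FALSE)
  }
  unknown <- setdiff(cfg$rejuvenated_cell_types, cfg$cell_type_names)
  if (length(unknown)) {
    stop("configuration error: rejuvenated cell type(s) not in ",
         "cell_type_names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$frac_mito_genes + cfg$frac_ribo_genes >= 1) {
    stop("configuration error: mito + ribo gene fractions must be < 1",
         call. = FALSE)
  }
  if (cfg$dispersion <= 0) {
    stop("configuration error: dispersion must be positive", call. = FALSE)
  }
  if (cfg$sample_effect_sd < 0) {
    stop("configuration error: sample_effect_sd must be non-negative",
         call. = FALSE)
  }
  invisible(cfg)
}

sim_gene_ids <- function(cfg) {
  n_mito <- round(cfg$frac_mito_genes * cfg$n_genes)
  n_ribo <- round(cfg$frac_ribo_genes * cfg$n_genes)
  n_other <- cfg$n_genes - n_mito - n_ribo
  mito <- if (n_mito > 0) sprintf("mt-Gene%03d", seq_len(n_mito)) else character()
  ribo <- if (n_ribo > 0) {
    ifelse(seq_len(n_ribo) %% 2 == 1,
           sprintf("Rps%03d", seq_len(n_ribo)),
           sprintf("Rpl%03d", seq_len(n_ribo)))
  } else {
    character()
  }
  other <- sprintf("Gene%05d", seq_len(n_other))
  c(other, mito, ribo)
}

sim_sample_table <- function(cfg) {
  n <- cfg$samples_per_group
  data.frame(
    sample = c(sprintf("YV%d", seq_len(n)), sprintf("AV%d", seq_len(n)),
               sprintf("AT%d", seq_len(n))),
    group = rep(GROUP_LEVELS, each = n),
    age_months = rep(c(cfg$young_age_months, cfg$aged_age_months,
                       cfg$aged_age_months), each = n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single-nucleus aging study with known ground truth
#'
#' Generates a three-group study (young vehicle, aged vehicle, aged
#' treated; `samples_per_group` animals each) of negative-binomial
#' single-nucleus counts across `n_cell_types` cell types. For each cell
#' type a planted aging program of genes has expected log mean expression
#' `baseline + aging_effect_size * effective_age`, where the effective age
#' of treated samples in rejuvenated cell types is
#' `aged - r * (aged - young)` months.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{bundle}{A [dataset_bundle()] with counts and full cell
#'       metadata.}
#'     \item{truth}{Ground truth: `aging_genes` (named list per cell
#'       type), `samples` (sample table), `effective_age` (samples x cell
#'       types matrix of effective ages in months), `rejuvenated` (named
#'       logical per cell type), and `outlier_barcodes` (if QC outliers
#'       were injected).}
#'   }
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  cfg <- config
  validate_simulation_config(cfg)
  gene_ids <- sim_gene_ids(cfg)
  samples <- sim_sample_table(cfg)

  out <- with_seed(cfg$seed, {
    # baseline log-means anchored so an average cell totals
    # ~mean_counts_per_cell counts at unit library factor
    m0 <- log(cfg$mean_counts_per_cell / cfg$n_genes) -
      cfg$baseline_log_sd^2 / 2
    base_log_mu <- stats::rnorm(cfg$n_genes, m0, cfg$baseline_log_sd)
    names(base_log_mu) <- gene_ids

    aging_genes <- cfg$aging_genes
    if (is.null(aging_genes)) {
      candidates <- gene_ids[!grepl("^mt-|^Rp[sl]", gene_ids)]
      need <- cfg$n_aging_genes_per_type * cfg$n_cell_types
      if (need <= length(candidates)) {
        pool <- sample(candidates, need)
        aging_genes <- split(pool, rep(cfg$cell_type_names,
                                       each = cfg$n_aging_genes_per_type))
      } else {
        aging_genes <- lapply(seq_len(cfg$n_cell_types), function(i) {
          sample(candidates, min(cfg$n_aging_genes_per_type,
                                 length(candidates)))
        })
        names(aging_genes) <- cfg$cell_type_names
      }
      aging_genes <- aging_genes[cfg$cell_type_names]
    } else {
      if (!all(cfg$cell_type_names %in% names(aging_genes))) {
        stop("configuration error: aging_genes must name every cell type",
             call. = FALSE)
      }
      aging_genes <- lapply(aging_genes[cfg$cell_type_names], as.character)
      bad <- setdiff(unlist(aging_genes), gene_ids)
      if (length(bad)) {
        stop("configuration error: unknown aging gene id(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }

    eff_age <- matrix(rep(samples$age_months, cfg$n_cell_types),
                      nrow = nrow(samples),
                      dimnames = list(samples$sample, cfg$cell_type_names))
    rejuv_age <- cfg$aged_age_months - cfg$rejuvenation_fraction *
      (cfg$aged_age_months - cfg$young_age_months)
    treated <- samples$group == "aged_treated"
    for (ct in cfg$rejuvenated_cell_types) {
      eff_age[treated, ct] <- rejuv_age
    }

    lib_sigma2 <- log(1 + cfg$library_size_cv^2)
    lib_meanlog <- log(cfg$library_size_mean) - lib_sigma2 / 2

    # animal-level biological variability: each sample perturbs every
    # gene's log mean by a fixed random offset shared by all its cells
    sample_fx <- matrix(stats::rnorm(nrow(samples) * cfg$n_genes, 0,
                                     cfg$sample_effect_sd),
                        nrow = nrow(samples))

    n_cells_block <- cfg$cells_per_sample_per_type
    n_blocks <- nrow(samples) * cfg$n_cell_types
    trip_i <- vector("list", n_blocks)
    trip_j <- vector("list", n_blocks)
    trip_x <- vector("list", n_blocks)
    meta <- vector("list", n_blocks)
    k <- 0L
    col_offset <- 0L
    for (si in seq_len(nrow(samples))) {
      for (ct in cfg$cell_type_names) {
        k <- k + 1L
        log_mu <- base_log_mu + sample_fx[si, ]
        planted <- aging_genes[[ct]]
        log_mu[planted] <- log_mu[planted] +
          cfg$aging_effect_size * eff_age[si, ct]
        lib <- stats::rlnorm(n_cells_block, lib_meanlog, sqrt(lib_sigma2))
        mu <- exp(log_mu) %o% lib
        cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                     size = cfg$dispersion),
                      nrow = cfg$n_genes)
        nz <- which(cnt != 0)
        trip_i[[k]] <- ((nz - 1L) %% cfg$n_genes) + 1L
        trip_j[[k]] <- ((nz - 1L) %/% cfg$n_genes) + 1L + col_offset
        trip_x[[k]] <- cnt[nz]
        col_offset <- col_offset + n_cells_block
        meta[[k]] <- data.frame(
          barcode = sprintf("%s_%s_c%03d", samples$sample[si], ct,
                            seq_len(n_cells_block)),
          sample = samples$sample[si],
          group = samples$group[si],
          age_months = samples$age_months[si],
          cell_type = ct,
          stringsAsFactors = FALSE
        )
      }
    }
    counts <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                   x = as.numeric(unlist(trip_x)),
                                   dims = c(cfg$n_genes, col_offset))
    cell_metadata <- do.call(rbind, meta)
    list(counts = counts, cell_metadata = cell_metadata,
         aging_genes = aging_genes, eff_age = eff_age)
  })

  bundle <- dataset_bundle(out$counts, gene_ids, out$cell_metadata$barcode,
                           out$cell_metadata)
  rejuv <- stats::setNames(cfg$cell_type_names %in% cfg$rejuvenated_cell_types,
                           cfg$cell_type_names)
  truth <- list(aging_genes = out$aging_genes,
                samples = samples,
                effective_age = out$eff_age,
                rejuvenated = rejuv,
                outlier_barcodes = character())
  if (cfg$n_qc_outlier_cells > 0) {
    inj <- inject_qc_outliers(bundle, cfg$n_qc_outlier_cells,
                              seed = stage_seed(cfg$seed, "qc_outliers"))
    bundle <- inj$bundle
    truth$outlier_barcodes <- inj$outlier_barcodes
  }
  list(bundle = bundle, truth = truth, config = cfg)
}

#' Inject QC-outlier cells into a bundle
#'
#' Perturbs `n` randomly chosen cells so that at least one of their QC
#' metrics (total counts or mitochondrial percentage) lands more than 5
#' pre-injection population standard deviations from the pre-injection
#' mean, making them detectable by a 3-SD outlier filter.
#'
#' @param bundle A [dataset_bundle()].
#' @param n Number of cells to perturb (`n = 0` returns the bundle
#'   unchanged).
#' @param seed Integer seed; fixed seed gives identical outlier ids.
#' @return A list with the perturbed `bundle` and the character vector
#'   `outlier_barcodes` of perturbed cell ids.
#' @export
inject_qc_outliers <- function(bundle, n, seed = 1) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (n > length(bundle$barcodes)) {
    stop("n exceeds the number of cells (", length(bundle$barcodes), ")",
         call. = FALSE)
  }
  if (n == 0L) {
    return(list(bundle = bundle, outlier_barcodes = character()))
  }
  qc_genes <- detect_qc_genes(bundle$gene_ids)
  metrics <- compute_qc_metrics(bundle, qc_genes$mito, qc_genes$ribo)
  mu_tot <- mean(metrics$total_counts)
  sd_tot <- stats::sd(metrics$total_counts)
  mu_mito <- mean(metrics$mito_pct)
  sd_mito <- stats::sd(metrics$mito_pct)

  counts <- bundle$counts
  mito_idx <- match(qc_genes$mito, bundle$gene_ids)
  with_seed(seed, {
    chosen <- sample(seq_along(bundle$barcodes), n)
    mode <- sample(c("total", "mito"), n, replace = TRUE)
    for (i in seq_len(n)) {
      ci <- chosen[i]
      use_mito <- mode[i] == "mito" && length(mito_idx) > 0 && sd_mito > 0
      if (use_mito) {
        target_pct <- mu_mito + 8 * sd_mito
        if (target_pct >= 95) use_mito <- FALSE
      }
      if (use_mito) {
        tot <- sum(counts[, ci])
        mito_now <- sum(counts[mito_idx, ci])
        p <- target_pct / 100
        add <- ceiling((p * tot - mito_now) / (1 - p)) + 1
        counts[mito_idx[1], ci] <- counts[mito_idx[1], ci] + max(add, 1)
      } else {
        # inflate total counts well past the 5-SD band
        target <- if (sd_tot > 0) mu_tot + 8 * sd_tot else 10 * mu_tot + 100
        tot <- sum(counts[, ci])
        add <- ceiling(target - tot) + 1
        top_gene <- which.max(counts[, ci])
        counts[top_gene, ci] <- counts[top_gene, ci] + max(add, 1)
      }
    }
    bundle$counts <- as_sparse_counts(counts)
    list(bundle = dataset_bundle(bundle$counts, bundle$gene_ids,
                                 bundle$barcodes, bundle$cell_metadata,
                                 bundle$gene_names),
         outlier_barcodes = bundle$barcodes[sort(chosen)])
  })
}
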