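#' Compute per-cell QC metrics
#'
#' For each cell, computes total counts, number of genes detected, and the
#' percentage of counts in mitochondrial and ribosomal genes. Cells with
#' zero total counts get 0% for both percentages and are flagged.
#'
#' @param bundle A [dataset_bundle()].
#' @param mito_gene_ids,ribo_gene_ids Gene-id sets for the two percentage
#'   metrics; default to prefix detection via [detect_qc_genes()]. Unknown
#'   ids are an error.
#' @return A data frame with one row per cell: `barcode`, `total_counts`,
#'   `genes_detected`, `mito_pct`, `ribo_pct`, `zero_total`.
#' @export
compute_qc_metrics <- function(bundle,
                               mito_gene_ids = NULL,
                               ribo_gene_ids = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (is.null(mito_gene_ids) && is.null(ribo_gene_ids)) {
    auto <- detect_qc_genes(bundle$gene_ids)
    mito_gene_ids <- auto$mito
    ribo_gene_ids <- auto$ribo
  }
  mito_gene_ids <- as.character(mito_gene_ids %||% character())
  ribo_gene_ids <- as.character(ribo_gene_ids %||% character())
  for (set in list(mito = mito_gene_ids, ribo = ribo_gene_ids)) {
    bad <- setdiff(set, bundle$gene_ids)
    if (length(bad)) {
      stop("unknown gene id(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  counts <- bundle$counts
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  sub_pct <- function(ids) {
    if (length(ids) == 0) return(rep(0, ncol(counts)))
    s <- Matrix::colSums(counts[match(ids, bundle$gene_ids), , drop = FALSE])
    ifelse(total > 0, 100 * s / total, 0)
  }
  data.frame(barcode = bundle$barcodes,
             total_counts = as.numeric(total),
             genes_detected = as.numeric(detected),
             mito_pct = sub_pct(mito_gene_ids),
             ribo_pct = sub_pct(ribo_gene_ids),
             zero_total = total == 0,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

QC_METRIC_NAMES <- c("total_counts", "genes_detected", "mito_pct", "ribo_pct")

#' Filter cells outside 3 standard deviations of the mean QC metrics
#'
#' A cell is removed if and only if any of the four metrics (total counts,
#' genes detected, mitochondrial %, ribosomal %) lies outside the closed
#' interval `[mean - 3 SD, mean + 3 SD]`. Means and sample SDs are
#' computed once on the full input (single pass; bounds are not
#' re-estimated after removal, so re-filtering an already filtered set may
#' remove further cells). Zero-count cells are removed up front with a
#' warning because their percentage metrics are undefined.
#'
#' @param metrics QC metric table from [compute_qc_metrics()].
#' @param n_sd Width of the band in standard deviations (default 3).
#' @return A list with `kept_barcodes`, `removed_barcodes`, and `report`
#'   (one row per metric: mean, sd, lower, upper, n_removed, where
#'   `n_removed` counts cells violating that metric).
#' @export
filter_cells_3sd <- function(metrics, n_sd = 3) {
  stopifnot(is.data.frame(metrics), all(QC_METRIC_NAMES %in% names(metrics)))
  zero <- if ("zero_total" %in% names(metrics)) metrics$zero_total
          else metrics$total_counts == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count cell(s) removed before QC filtering",
            call. = FALSE)
  }
  m <- metrics[!zero, , drop = FALSE]
  if (nrow(m) < 2) {
    stop("need at least 2 cells with non-zero counts to define SD bounds",
         call. = FALSE)
  }
  report <- do.call(rbind, lapply(QC_METRIC_NAMES, function(nm) {
    x <- m[[nm]]
    mu <- mean(x)
    s <- stats::sd(x)
    lower <- mu - n_sd * s
    upper <- mu + n_sd * s
    data.frame(metric = nm, mean = mu, sd = s, lower = lower, upper = upper,
               n_removed = sum(x < lower | x > upper),
               stringsAsFactors = FALSE)
  }))
  viol <- Reduce(`|`, lapply(QC_METRIC_NAMES, function(nm) {
    x <- m[[nm]]
    row <- report[report$metric == nm, ]
    x < row$lower | x > row$upper
  }))
  kept <- m$barcode[!viol]
  if (length(kept) == 0) {
    stop("degenerate input: QC filter removed every cell", call. = FALSE)
  }
  list(kept_barcodes = kept,
       removed_barcodes = c(metrics$barcode[zero], m$barcode[viol]),
       report = report)
}

#' Apply the 3-SD QC filter to a bundle
#'
#' Convenience wrapper: computes metrics, applies [filter_cells_3sd()],
#' and returns the filtered bundle plus the report.
#'
#' @inheritParams compute_qc_metrics
#' @inheritParams filter_cells_3sd
#' @return A list with `bundle` (filtered), `metrics`, `report`, and
#'   `removed_barcodes`.
#' @export
qc_filter_bundle <- function(bundle, mito_gene_ids = NULL,
                             ribo_gene_ids = NULL, n_sd = 3) {
  metrics <- compute_qc_metrics(bundle, mito_gene_ids, ribo_gene_ids)
  res <- filter_cells_3sd(metrics, n_sd = n_sd)
  list(bundle = subset_cells(bundle, res$kept_barcodes),
       metrics = metrics,
       report = res$report,
       removed_barcodes = res$removed_barcodes)
}

#' Count meaningful principal components
#'
#' A PC is "meaningful" when its variance fraction strictly exceeds the
#' equal-share level `1 / (number of computed PCs)` — i.e. it contributes
#' more variance than it would if all computed PCs contributed equally.
#' The input need not be normalized: raw variances work because the rule
#' is invariant to rescaling by a positive constant.
#'
#' @param variance_fractions Non-negative per-PC variances or variance
#'   fractions, ordered by PC.
#' @return Integer count of meaningful PCs.
#' @export
count_meaningful_pcs <- function(variance_fractions) {
  v <- as.numeric(variance_fractions)
  if (length(v) == 0) stop("variance_fractions must be non-empty",
                           call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("variance_fractions must be finite and non-negative", call. = FALSE)
  }
  # fraction_i > 1/n  <=>  v_i > mean(v); ties do not count
  sum(v > sum(v) / length(v))
}
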