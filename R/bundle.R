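#' Assemble a single-nucleus dataset bundle
#'
#' A `dataset_bundle` is the pipeline's universal input: a sparse genes x
#' cells matrix of non-negative integer counts together with per-cell
#' metadata (sample of origin, experimental group, chronological age in
#' months, and cell-type label), mirroring a 10x-style feature-barcode
#' matrix plus a metadata table.
#'
#' @param counts Genes x cells matrix of non-negative integer counts
#'   (coerced to a sparse `dgCMatrix`).
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param barcodes Character vector of unique cell barcodes (columns).
#' @param cell_metadata Data frame keyed by `barcode` with columns
#'   `sample`, `group` (one of `young_vehicle`, `aged_vehicle`,
#'   `aged_treated`), `age_months`, and `cell_type`.
#' @param gene_names Optional display names for genes; defaults to
#'   `gene_ids`.
#' @return An object of class `dataset_bundle` with elements `counts`
#'   (dimnames set to genes x barcodes), `gene_ids`, `gene_names`,
#'   `barcodes`, and `cell_metadata` (ordered to match `barcodes`).
#' @export
dataset_bundle <- function(counts, gene_ids, barcodes, cell_metadata,
                           gene_names = gene_ids) {
  counts <- as_sparse_counts(counts)
  if (nrow(counts) != length(gene_ids)) {
    stop("dimension mismatch: counts has ", nrow(counts),
         " rows but gene_ids has ", length(gene_ids), " entries",
         call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("dimension mismatch: counts has ", ncol(counts),
         " columns but barcodes has ", length(barcodes), " entries",
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)])[1:5], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids", call. = FALSE)
  }
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  required <- c("barcode", "sample", "group", "age_months", "cell_type")
  missing_cols <- setdiff(required, names(cell_metadata))
  if (length(missing_cols)) {
    stop("cell_metadata missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(barcodes, cell_metadata$barcode)
  if (anyNA(idx)) {
    stop("missing metadata rows for barcodes: ",
         paste(barcodes[is.na(idx)][1:5], collapse = ", "), call. = FALSE)
  }
  meta <- cell_metadata[idx, required, drop = FALSE]
  rownames(meta) <- NULL
  meta$age_months <- as.numeric(meta$age_months)
  meta$barcode <- as.character(meta$barcode)
  bad_group <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group labels: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts,
         gene_ids = as.character(gene_ids),
         gene_names = as.character(gene_names),
         barcodes = as.character(barcodes),
         cell_metadata = meta),
    class = "dataset_bundle"
  )
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle:", length(x$gene_ids), "genes x",
      length(x$barcodes), "cells\n")
  cat("  samples:", length(unique(x$cell_metadata$sample)),
      "| cell types:", length(unique(x$cell_metadata$cell_type)),
      "| groups:", paste(sort(unique(x$cell_metadata$group)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset bundle to a set of cells
#'
#' @param bundle A `dataset_bundle`.
#' @param barcodes Barcodes to keep (order preserved as given).
#' @return A `dataset_bundle` restricted to those cells.
#' @export
subset_cells <- function(bundle, barcodes) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  idx <- match(barcodes, bundle$barcodes)
  if (anyNA(idx)) {
    stop("unknown barcodes: ",
         paste(barcodes[is.na(idx)][1:5], collapse = ", "), call. = FALSE)
  }
  dataset_bundle(bundle$counts[, idx, drop = FALSE],
                 gene_ids = bundle$gene_ids,
                 barcodes = bundle$barcodes[idx],
                 cell_metadata = bundle$cell_metadata[idx, , drop = FALSE],
                 gene_names = bundle$gene_names)
}

#' Identify mitochondrial / ribosomal genes by mouse-style prefixes
#'
#' Mitochondrial genes are matched by the `mt-` prefix and ribosomal genes
#' by the `Rps`/`Rpl` prefixes, following mouse gene nomenclature.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @return A list with character vectors `mito` and `ribo`.
#' @export
detect_qc_genes <- function(gene_ids) {
  list(mito = gene_ids[grepl("^mt-", gene_ids)],
       ribo = gene_ids[grepl("^Rp[sl]", gene_ids)])
}
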