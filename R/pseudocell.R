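#' Bootstrap-aggregate cells into pseudocells
#'
#' Within every (sample, cell type) stratum, repeatedly draws
#' `cells_per_pseudocell` distinct cells and sums their raw counts to form
#' one pseudocell; `n_reps` pseudocells are generated per stratum.
#' Selection is without replacement from a shuffled pool that persists
#' across successive pseudocells; when the pool runs out mid-draw it is
#' refilled with the full stratum (excluding cells already in the current
#' pseudocell) and reshuffled. This guarantees each pseudocell has
#' distinct members while spreading cells as evenly as possible across the
#' replicate set. Strata with fewer than `min_cells_per_stratum` cells are
#' skipped with a warning.
#'
#' @param bundle A QC-filtered [dataset_bundle()] with complete labels.
#' @param cells_per_pseudocell Cells aggregated per pseudocell (default
#'   15).
#' @param n_reps Pseudocells per stratum (default 100).
#' @param min_cells_per_stratum Minimum stratum size to emit pseudocells
#'   (default `cells_per_pseudocell`).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `pseudocell_set`: `counts` (sparse genes x
#'   pseudocells aggregated counts), `labels` (data frame with
#'   `pseudocell_id`, `sample`, `group`, `cell_type`, `replicate_index`,
#'   `age_months`), `member_ids` (list of member barcodes per pseudocell),
#'   `gene_ids`, and `normalized` (`NULL` until
#'   [normalize_pseudocells()]).
#' @export
make_pseudocells <- function(bundle, cells_per_pseudocell = 15,
                             n_reps = 100,
                             min_cells_per_stratum = cells_per_pseudocell,
                             seed = 1) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  k <- as.integer(cells_per_pseudocell)
  n_reps <- as.integer(n_reps)
  stopifnot(k >= 1, n_reps >= 1)
  if (min_cells_per_stratum < k) {
    stop("min_cells_per_stratum must be at least cells_per_pseudocell ",
         "(pseudocell members are distinct)", call. = FALSE)
  }
  meta <- bundle$cell_metadata
  if (anyNA(meta$cell_type) || anyNA(meta$sample)) {
    stop("missing cell_type or sample label in cell metadata", call. = FALSE)
  }
  strata <- split(seq_len(nrow(meta)),
                  list(sample = meta$sample, cell_type = meta$cell_type),
                  drop = TRUE, sep = "\r")
  # deterministic stratum order, independent of split()'s factor ordering
  strata <- strata[order(names(strata))]

  with_seed(seed, {
    member_blocks <- list()
    labels <- list()
    skipped <- character()
    for (snm in names(strata)) {
      idx <- strata[[snm]]
      if (length(idx) < min_cells_per_stratum) {
        skipped <- c(skipped, gsub("\r", " / ", snm))
        next
      }
      # Depleting shuffled queue; refilled with a fresh shuffle of the
      # whole stratum on exhaustion. Cells already in the current
      # pseudocell are deferred back to the queue front instead of being
      # drawn twice, which keeps members distinct and guarantees each cell
      # is used floor- or ceiling-many times across the replicate set.
      pool <- sample(idx)
      members <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        mem <- integer(0)
        deferred <- integer(0)
        while (length(mem) < k) {
          if (length(pool) == 0) {
            pool <- sample(idx)
          }
          cand <- pool[1]
          pool <- pool[-1]
          if (cand %in% mem) {
            deferred <- c(deferred, cand)
          } else {
            mem <- c(mem, cand)
          }
        }
        pool <- c(deferred, pool)
        members[[r]] <- mem
      }
      first <- idx[1]
      member_blocks[[snm]] <- members
      labels[[snm]] <- data.frame(
        pseudocell_id = sprintf("%s.%s.pc%03d", meta$sample[first],
                                meta$cell_type[first], seq_len(n_reps)),
        sample = meta$sample[first],
        group = meta$group[first],
        cell_type = meta$cell_type[first],
        replicate_index = seq_len(n_reps),
        age_months = meta$age_months[first],
        stringsAsFactors = FALSE
      )
    }
    if (length(skipped)) {
      warning("skipped ", length(skipped), " stratum/strata with fewer than ",
              min_cells_per_stratum, " cells: ",
              paste(utils::head(skipped, 5), collapse = "; "),
              call. = FALSE)
    }
    if (length(member_blocks) == 0) {
      stop("all strata were skipped: no stratum has at least ",
           min_cells_per_stratum, " cells", call. = FALSE)
    }
    lab <- do.call(rbind, labels)
    rownames(lab) <- NULL
    members_flat <- unlist(member_blocks, recursive = FALSE,
                           use.names = FALSE)
    # aggregation as one sparse membership product:
    # (genes x cells) %*% (cells x pseudocells indicator) = summed counts
    n_pc <- length(members_flat)
    memb <- Matrix::sparseMatrix(
      i = unlist(members_flat, use.names = FALSE),
      j = rep(seq_len(n_pc), each = k),
      x = 1,
      dims = c(ncol(bundle$counts), n_pc))
    counts <- methods::as(bundle$counts %*% memb, "CsparseMatrix")
    mids <- lapply(members_flat, function(m) bundle$barcodes[m])
    names(mids) <- lab$pseudocell_id
    dimnames(counts) <- list(bundle$gene_ids, lab$pseudocell_id)
    structure(
      list(counts = counts, labels = lab, member_ids = mids,
           gene_ids = bundle$gene_ids,
           cells_per_pseudocell = k, n_reps = n_reps,
           normalized = NULL),
      class = "pseudocell_set"
    )
  })
}

#' @export
print.pseudocell_set <- function(x, ...) {
  cat("pseudocell_set:", ncol(x$counts), "pseudocells x",
      nrow(x$counts), "genes\n")
  cat("  ", x$cells_per_pseudocell, "cells/pseudocell,",
      x$n_reps, "replicates/stratum,",
      length(unique(x$labels$cell_type)), "cell types,",
      length(unique(x$labels$sample)), "samples\n")
  cat("  normalized view:", if (is.null(x$normalized)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Library-size normalize pseudocell expression
#'
#' Adds a normalized expression view: `log(1 + scale * count / total)`
#' per pseudocell, with natural log and `total` the pseudocell's summed
#' counts. The raw aggregated counts are retained unchanged. The
#' normalized value is invariant to scaling all of a pseudocell's counts
#' by a constant.
#'
#' @param pset A [make_pseudocells()] result.
#' @param scale Scale factor applied to the count fraction (default 1e4).
#' @return The `pseudocell_set` with its `normalized` matrix (genes x
#'   pseudocells, sparse) filled in.
#' @export
normalize_pseudocells <- function(pset, scale = 1e4) {
  stopifnot(inherits(pset, "pseudocell_set"))
  totals <- Matrix::colSums(pset$counts)
  if (any(totals <= 0)) {
    stop("zero-total pseudocell(s): ",
         paste(utils::head(pset$labels$pseudocell_id[totals <= 0], 5),
               collapse = ", "), call. = FALSE)
  }
  norm <- pset$counts
  # scale each column by scale/total, then log1p; sparsity is preserved
  norm@x <- norm@x * rep.int(scale / totals, diff(norm@p))
  norm@x <- log1p(norm@x)
  pset$normalized <- norm
  pset$normalize_scale <- scale
  pset
}

#' Subset a pseudocell set
#'
#' @param pset A `pseudocell_set`.
#' @param which Logical or integer index over pseudocells.
#' @return The subsetted `pseudocell_set`.
#' @export
subset_pseudocells <- function(pset, which) {
  stopifnot(inherits(pset, "pseudocell_set"))
  pset$counts <- pset$counts[, which, drop = FALSE]
  if (!is.null(pset$normalized)) {
    pset$normalized <- pset$normalized[, which, drop = FALSE]
  }
  pset$labels <- pset$labels[which, , drop = FALSE]
  rownames(pset$labels) <- NULL
  pset$member_ids <- pset$member_ids[which]
  pset
}
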