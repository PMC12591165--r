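#' Write a dataset bundle as a 10x-style directory
#'
#' Writes `matrix.mtx` (Matrix Market, 1-based indices), `features.tsv`
#' (id, name, type), `barcodes.tsv`, and `metadata.tsv` (barcode, sample,
#' group, age_months, cell_type).
#'
#' @param bundle A [dataset_bundle()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- bundle$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  utils::write.table(
    data.frame(id = bundle$gene_ids, name = bundle$gene_names,
               type = "Gene Expression"),
    file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(bundle$barcodes, file.path(path, "barcodes.tsv"))
  utils::write.table(bundle$cell_metadata, file.path(path, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

find_triplet_file <- function(path, base) {
  for (cand in c(base, paste0(base, ".gz"))) {
    f <- file.path(path, cand)
    if (file.exists(f)) return(f)
  }
  stop("missing file '", base, "' (or '", base, ".gz') in ", path,
       call. = FALSE)
}

read_text_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

read_mm_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp))
    writeLines(read_text_maybe_gz(path), tmp)
    Matrix::readMM(tmp)
  } else {
    Matrix::readMM(path)
  }
}

#' Read a 10x-style dataset bundle
#'
#' Reads the `matrix.mtx` / `features.tsv` / `barcodes.tsv` triplet (plain
#' or gzipped) plus `metadata.tsv`, validating dimensions, barcode
#' uniqueness, and metadata completeness. On-disk Matrix Market indices
#' are 1-based; in-memory positions follow R's 1-based indexing of the
#' sparse matrix.
#'
#' @param path Directory holding the four files.
#' @return A [dataset_bundle()].
#' @export
read_bundle <- function(path) {
  m <- read_mm_maybe_gz(find_triplet_file(path, "matrix.mtx"))
  feat_lines <- read_text_maybe_gz(find_triplet_file(path, "features.tsv"))
  feats <- utils::read.table(text = feat_lines, sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- read_text_maybe_gz(find_triplet_file(path, "barcodes.tsv"))
  if (nrow(feats) != nrow(m)) {
    stop("dimension mismatch: matrix.mtx declares ", nrow(m),
         " genes but features.tsv has ", nrow(feats), " rows", call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop("dimension mismatch: matrix.mtx declares ", ncol(m),
         " cells but barcodes.tsv has ", length(barcodes), " rows",
         call. = FALSE)
  }
  meta_file <- find_triplet_file(path, "metadata.tsv")
  meta <- utils::read.table(text = read_text_maybe_gz(meta_file),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  dataset_bundle(m, gene_ids = feats[[1]], barcodes = barcodes,
                 cell_metadata = meta,
                 gene_names = if (ncol(feats) >= 2) feats[[2]] else feats[[1]])
}

#' Write a pseudocell set to disk
#'
#' Writes the aggregated counts as Matrix Market, labels as TSV, and the
#' per-pseudocell member lists as JSON for audit.
#'
#' @param pset A `pseudocell_set`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_pseudocells <- function(pset, path) {
  stopifnot(inherits(pset, "pseudocell_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- pset$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(path, "pseudocells.mtx"))
  utils::write.table(pset$labels, file.path(path, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(pset$gene_ids, file.path(path, "genes.tsv"))
  jsonlite::write_json(pset$member_ids, file.path(path, "members.json"))
  invisible(path)
}

#' Default pipeline configuration
#'
#' Assembles the full stage-parameter tree used by [run_pipeline()],
#' which round-trips losslessly through YAML/JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Root seed; every stage derives its own sub-seed from it.
#' @param simulate List of [simulation_config()] overrides, or `NULL` to
#'   read `input_path` instead.
#' @param input_path Bundle directory to read when not simulating.
#' @param qc List: `enabled`, `n_sd`.
#' @param pseudocell List: `cells_per_pseudocell`, `n_reps`,
#'   `min_cells_per_stratum`, `scale`.
#' @param clock List: `alpha`, `inner_cv_folds`, `min_detect_frac`.
#' @param cv List: `enabled`.
#' @param k_values Driver-gene sharing thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = list(),
                            input_path = NULL,
                            qc = list(),
                            pseudocell = list(),
                            clock = list(),
                            cv = list(),
                            k_values = c(2, 3)) {
  merge_defaults <- function(user, defaults) {
    utils::modifyList(defaults, as.list(user))
  }
  cfg <- list(
    seed = as.integer(seed),
    simulate = if (is.null(simulate)) NULL else as.list(simulate),
    input_path = input_path,
    qc = merge_defaults(qc, list(enabled = TRUE, n_sd = 3)),
    pseudocell = merge_defaults(pseudocell,
                                list(cells_per_pseudocell = 15L,
                                     n_reps = 100L,
                                     min_cells_per_stratum = 15L,
                                     scale = 1e4)),
    clock = merge_defaults(clock, list(alpha = 0.5, inner_cv_folds = 5L,
                                       min_detect_frac = 0.05)),
    cv = merge_defaults(cv, list(enabled = TRUE)),
    k_values = as.integer(k_values)
  )
  if (is.null(cfg$simulate) && is.null(cfg$input_path)) {
    stop("pipeline config needs either a simulate block or an input_path",
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, chosen by extension.
#'
#' @param path Config file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' @param config A `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
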