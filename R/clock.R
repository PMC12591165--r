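#' Train an elastic-net aging clock for one cell type
#'
#' Fits an elastic-net linear regression of chronological age (months) on
#' standardized normalized pseudocell expression, with the penalty
#' strength chosen by inner cross-validation (the lambda minimizing
#' inner-CV mean squared error along a descending lambda path). Features
#' are optionally pre-filtered to genes detected in a minimum fraction of
#' training pseudocells, then centered and scaled on the training set;
#' zero-variance features are dropped. If no usable features remain, an
#' intercept-only model predicting the mean training age is returned.
#'
#' @param pset A normalized [pseudocell_set][make_pseudocells()]
#'   (see [normalize_pseudocells()]).
#' @param cell_type Cell type to train on; may be omitted if `pset` holds
#'   a single cell type.
#' @param alpha Elastic-net mixing weight in \[0, 1\] (1 = lasso,
#'   0 = ridge; default 0.5).
#' @param inner_cv_folds Folds for the inner lambda-selection CV
#'   (default 5).
#' @param min_detect_frac Keep genes with non-zero counts in at least this
#'   fraction of training pseudocells (default 0.05; set 0 to disable).
#' @param seed Integer seed controlling inner-CV fold assignment.
#' @return An object of class `clock_model`: `cell_type`,
#'   `feature_genes`, `coefficients` (months per standardized-expression
#'   unit), `intercept` (months), `feature_means`, `feature_sds`,
#'   `hyperparameters` (`alpha`, `lambda`, `inner_cv_folds`, `seed`), and
#'   `training_samples`.
#' @export
train_clock <- function(pset, cell_type = NULL, alpha = 0.5,
                        inner_cv_folds = 5, min_detect_frac = 0.05,
                        seed = 1) {
  stopifnot(inherits(pset, "pseudocell_set"))
  if (is.null(pset$normalized)) {
    pset <- normalize_pseudocells(pset)
  }
  if (!is.null(cell_type)) {
    keep <- pset$labels$cell_type == cell_type
    if (!any(keep)) {
      stop("no pseudocells of cell type '", cell_type, "'", call. = FALSE)
    }
    pset <- subset_pseudocells(pset, keep)
  } else {
    cts <- unique(pset$labels$cell_type)
    if (length(cts) > 1) {
      stop("pset holds ", length(cts),
           " cell types; pass cell_type explicitly", call. = FALSE)
    }
    cell_type <- cts
  }
  y <- pset$labels$age_months
  if (length(unique(y)) < 2) {
    stop("degenerate labels: a clock needs at least 2 distinct ages",
         call. = FALSE)
  }
  if (length(unique(pset$labels$sample)) < 2) {
    stop("a clock needs pseudocells from at least 2 samples", call. = FALSE)
  }

  detect_frac <- Matrix::rowMeans(pset$counts > 0)
  keep_genes <- detect_frac >= min_detect_frac
  x <- Matrix::t(pset$normalized[keep_genes, , drop = FALSE])
  genes <- pset$gene_ids[keep_genes]

  mu <- Matrix::colMeans(x)
  xc <- as.matrix(x)
  sds <- apply(xc, 2, stats::sd)
  usable <- is.finite(sds) & sds > 0
  genes <- genes[usable]
  mu <- mu[usable]
  sds <- sds[usable]

  model <- list(cell_type = cell_type,
                feature_genes = genes,
                feature_means = unname(mu),
                feature_sds = unname(sds),
                training_samples = sort(unique(pset$labels$sample)),
                hyperparameters = list(alpha = alpha, lambda = NA_real_,
                                       inner_cv_folds = as.integer(inner_cv_folds),
                                       min_detect_frac = min_detect_frac,
                                       seed = as.integer(seed)))

  if (length(genes) == 0) {
    model$coefficients <- numeric(0)
    model$intercept <- mean(y)
    class(model) <- "clock_model"
    return(model)
  }

  xs <- scale(xc[, usable, drop = FALSE], center = mu, scale = sds)

  if (length(genes) == 1) {
    # glmnet needs >= 2 predictors; a one-gene clock is ordinary least
    # squares (lambda = 0)
    fit <- stats::lm.fit(cbind(1, xs), y)
    model$coefficients <- unname(fit$coefficients[2])
    model$intercept <- unname(fit$coefficients[1])
    model$hyperparameters$lambda <- 0
    class(model) <- "clock_model"
    return(model)
  }

  cvfit <- with_seed(seed, {
    # inner folds are grouped by sample: pseudocells of one animal never
    # straddle an inner train/validation split, otherwise the penalty is
    # chosen against leaked animal signatures and the clock overfits the
    # training animals
    samp <- pset$labels$sample
    uniq <- sample(unique(samp))
    if (length(uniq) >= 3) {
      nf <- min(inner_cv_folds, length(uniq))
      fold_of_sample <- stats::setNames(rep(seq_len(nf), length.out =
                                              length(uniq)), uniq)
      foldid <- unname(fold_of_sample[samp])
    } else {
      # cv.glmnet needs >= 3 folds; with < 3 animals fall back to
      # pseudocell-level folds
      foldid <- sample(rep(seq_len(max(inner_cv_folds, 3)),
                           length.out = nrow(xs)))
    }
    glmnet::cv.glmnet(xs, y, alpha = alpha, foldid = foldid,
                      standardize = FALSE, family = "gaussian")
  })
  lam <- cvfit$lambda.min
  beta <- stats::coef(cvfit, s = "lambda.min")
  model$coefficients <- as.numeric(beta)[-1]
  model$intercept <- as.numeric(beta)[1]
  model$hyperparameters$lambda <- lam
  model$cv_lambda_path <- cvfit$lambda
  model$cv_nzero_path <- as.integer(cvfit$nzero)
  # inner-CV R^2 at lambda.min: 1 - CV-MSE / Var(age); ~0 for label noise
  model$inner_cv_r2 <- 1 - min(cvfit$cvm) / mean((y - mean(y))^2)
  class(model) <- "clock_model"
  model
}

#' @export
print.clock_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("clock_model for cell type", x$cell_type, "\n")
  cat("  ", length(x$feature_genes), "features,", nz,
      "with non-zero coefficients; intercept",
      format(x$intercept, digits = 4), "months\n")
  cat("   alpha =", x$hyperparameters$alpha, ", lambda =",
      format(x$hyperparameters$lambda, digits = 4), "\n")
  invisible(x)
}

clock_design_matrix <- function(model, pset) {
  missing <- setdiff(model$feature_genes, pset$gene_ids)
  if (length(missing)) {
    stop("pseudocell set is missing model feature gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  x <- Matrix::t(pset$normalized[match(model$feature_genes, pset$gene_ids), ,
                                 drop = FALSE])
  scale(as.matrix(x), center = model$feature_means, scale = model$feature_sds)
}

#' Predict transcriptional age of pseudocells
#'
#' Applies a trained clock: `predicted_age = intercept +
#' sum(coefficients * standardized expression)` using the standardization
#' parameters learned at training time. Per-sample summaries are the
#' arithmetic means of each sample's pseudocell predictions.
#'
#' @param model A [train_clock()] model.
#' @param pset A normalized `pseudocell_set` covering all of the model's
#'   feature genes (missing genes are an error, never silently
#'   zero-filled).
#' @return An object of class `age_prediction`: `predictions` (data frame
#'   with `pseudocell_id`, `sample`, `group`, `cell_type`, `age_months`,
#'   `predicted_age`) and `sample_summary` (per-sample mean predicted
#'   age).
#' @export
predict_age <- function(model, pset) {
  stopifnot(inherits(model, "clock_model"), inherits(pset, "pseudocell_set"))
  if (is.null(pset$normalized)) {
    pset <- normalize_pseudocells(pset)
  }
  if (length(model$feature_genes) == 0) {
    pred <- rep(model$intercept, nrow(pset$labels))
  } else {
    xs <- clock_design_matrix(model, pset)
    pred <- as.numeric(xs %*% model$coefficients) + model$intercept
  }
  predictions <- cbind(pset$labels[, c("pseudocell_id", "sample", "group",
                                       "cell_type", "age_months")],
                       predicted_age = pred)
  agg <- stats::aggregate(predicted_age ~ sample + group + cell_type +
                            age_months, data = predictions, FUN = mean)
  names(agg)[names(agg) == "predicted_age"] <- "mean_predicted_age"
  agg <- agg[order(agg$cell_type, agg$sample), ]
  rownames(agg) <- NULL
  structure(list(predictions = predictions, sample_summary = agg,
                 cell_type = model$cell_type),
            class = "age_prediction")
}

#' @export
print.age_prediction <- function(x, ...) {
  cat("age_prediction:", nrow(x$predictions), "pseudocells,",
      nrow(x$sample_summary), "sample summaries\n")
  invisible(x)
}

#' Variable importance of clock features
#'
#' Importance is the absolute value of the fitted coefficient on the
#' standardized-expression scale; the clock's driver genes are those with
#' non-zero importance.
#'
#' @param model A [train_clock()] model.
#' @return A data frame with `gene`, `coefficient`, `importance`, sorted
#'   by decreasing importance.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  vi <- data.frame(gene = model$feature_genes,
                   coefficient = model$coefficients,
                   importance = abs(model$coefficients),
                   stringsAsFactors = FALSE)
  vi <- vi[order(-vi$importance, vi$gene), , drop = FALSE]
  rownames(vi) <- NULL
  vi
}

#' Genes with non-zero clock importance
#'
#' @param model A [train_clock()] model.
#' @return Character vector of driver genes (non-zero coefficients).
#' @export
nonzero_importance_genes <- function(model) {
  vi <- variable_importance(model)
  vi$gene[vi$importance > 0]
}

#' Serialize a clock model to JSON
#'
#' @param model A [train_clock()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- list(format = "cellclock_model", version = 1L,
              cell_type = model$cell_type,
              feature_genes = model$feature_genes,
              coefficients = model$coefficients,
              intercept = model$intercept,
              feature_means = model$feature_means,
              feature_sds = model$feature_sds,
              hyperparameters = model$hyperparameters,
              training_samples = model$training_samples)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized clock model
#'
#' @param path JSON file written by [write_clock_model()].
#' @return A `clock_model`.
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cellclock_model")) {
    stop("not a cellclock model file: ", path, call. = FALSE)
  }
  model <- list(cell_type = obj$cell_type,
                feature_genes = as.character(obj$feature_genes),
                coefficients = as.numeric(obj$coefficients),
                intercept = as.numeric(obj$intercept),
                feature_means = as.numeric(obj$feature_means),
                feature_sds = as.numeric(obj$feature_sds),
                hyperparameters = obj$hyperparameters,
                training_samples = as.character(obj$training_samples))
  class(model) <- "clock_model"
  model
}
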