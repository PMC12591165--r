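#' Build leave-pair-out cross-validation folds
#'
#' Randomly pairs each young vehicle sample with one aged vehicle sample,
#' drawing without replacement until both groups are exhausted: an
#' n-per-group design yields n folds. Each fold holds out its pair as the
#' test set and trains on all remaining vehicle samples.
#'
#' @param young_ids,aged_ids Sample ids for the two vehicle groups; must
#'   be the same length (>= 2) with no duplicates.
#' @param seed Integer seed; the pairing is deterministic given the seed.
#' @return A list of folds, each a list with `test` (the young/aged pair)
#'   and `train` (all remaining vehicle samples).
#' @export
build_pair_folds <- function(young_ids, aged_ids, seed = 1) {
  young_ids <- as.character(young_ids)
  aged_ids <- as.character(aged_ids)
  if (length(young_ids) != length(aged_ids)) {
    stop("unequal group sizes (", length(young_ids), " young vs ",
         length(aged_ids), " aged): pairing undefined", call. = FALSE)
  }
  if (length(young_ids) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (anyDuplicated(c(young_ids, aged_ids))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  all_ids <- c(young_ids, aged_ids)
  with_seed(seed, {
    yo <- sample(young_ids)
    ao <- sample(aged_ids)
    lapply(seq_along(yo), function(i) {
      test <- c(yo[i], ao[i])
      list(test = test, train = setdiff(all_ids, test))
    })
  })
}

check_folds <- function(folds, vehicle_ids) {
  test_ids <- unlist(lapply(folds, `[[`, "test"))
  if (anyDuplicated(test_ids)) {
    stop("invalid folds: a sample appears in more than one test pair",
         call. = FALSE)
  }
  if (!setequal(test_ids, vehicle_ids)) {
    stop("invalid folds: union of test pairs must equal the vehicle samples",
         call. = FALSE)
  }
  for (f in folds) {
    if (length(intersect(f$test, f$train))) {
      stop("invalid folds: a test sample appears in its own training set",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Leave-pair-out cross-validation of cell-type clocks
#'
#' For every cell type, trains one clock per fold on the training
#' animals' pseudocells, predicts the held-out pair's pseudocells, pools
#' the held-out predictions across folds, and computes the Pearson
#' correlation between pooled predicted and chronological age. Per-fold R
#' over a single young/aged pair is degenerate at the sample level, so
#' pooling is the primary statistic; per-fold mean predictions are kept as
#' diagnostics.
#'
#' @param pset A normalized `pseudocell_set` containing the vehicle
#'   samples (other samples are ignored).
#' @param folds Folds from [build_pair_folds()].
#' @param cell_types Cell types to evaluate; default all in `pset`.
#' @param alpha,inner_cv_folds,min_detect_frac,seed Clock hyperparameters
#'   passed to [train_clock()].
#' @return An object of class `cv_result`: `summary` (data frame with
#'   `cell_type`, `pearson_r`, `n_pseudocells`), `predictions` (pooled
#'   held-out predictions), `folds`, and `fold_diagnostics` (per fold and
#'   cell type, mean predicted age of each held-out sample).
#' @export
run_cv <- function(pset, folds, cell_types = NULL, alpha = 0.5,
                   inner_cv_folds = 5, min_detect_frac = 0.05, seed = 1) {
  stopifnot(inherits(pset, "pseudocell_set"))
  if (is.null(pset$normalized)) pset <- normalize_pseudocells(pset)
  vehicle_ids <- unique(unlist(lapply(folds, function(f) c(f$test, f$train))))
  check_folds(folds, vehicle_ids)
  pset <- subset_pseudocells(pset, pset$labels$sample %in% vehicle_ids)
  if (is.null(cell_types)) cell_types <- sort(unique(pset$labels$cell_type))

  pooled <- list()
  diags <- list()
  summary_rows <- list()
  for (ct in cell_types) {
    ct_idx <- pset$labels$cell_type == ct
    ok <- TRUE
    ct_pred <- list()
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      train_idx <- ct_idx & pset$labels$sample %in% f$train
      test_idx <- ct_idx & pset$labels$sample %in% f$test
      if (!any(train_idx) || !any(test_idx) ||
          length(unique(pset$labels$age_months[train_idx])) < 2) {
        warning("cell type '", ct, "' unavailable in fold ", fi,
                "; reporting NA", call. = FALSE)
        ok <- FALSE
        break
      }
      model <- train_clock(subset_pseudocells(pset, train_idx),
                           cell_type = ct, alpha = alpha,
                           inner_cv_folds = inner_cv_folds,
                           min_detect_frac = min_detect_frac,
                           seed = stage_seed(seed, paste0("cv.", ct, ".", fi)))
      pred <- predict_age(model, subset_pseudocells(pset, test_idx))
      p <- pred$predictions
      p$fold <- fi
      ct_pred[[fi]] <- p
      d <- pred$sample_summary
      d$fold <- fi
      diags[[paste(ct, fi)]] <- d
    }
    if (!ok) {
      summary_rows[[ct]] <- data.frame(cell_type = ct, pearson_r = NA_real_,
                                       n_pseudocells = 0L)
      next
    }
    p <- do.call(rbind, ct_pred)
    pooled[[ct]] <- p
    summary_rows[[ct]] <- data.frame(
      cell_type = ct,
      pearson_r = stats::cor(p$predicted_age, p$age_months),
      n_pseudocells = nrow(p))
  }
  structure(
    list(summary = do.call(rbind, c(summary_rows,
                                    list(make.row.names = FALSE))),
         predictions = if (length(pooled)) {
           do.call(rbind, c(pooled, list(make.row.names = FALSE)))
         } else {
           NULL
         },
         folds = folds,
         fold_diagnostics = if (length(diags)) {
           do.call(rbind, c(diags, list(make.row.names = FALSE)))
         } else {
           NULL
         }),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result over", nrow(x$summary), "cell types;",
      length(x$folds), "leave-pair-out folds\n")
  print(x$summary)
  invisible(x)
}

TUKEY_CONTRASTS <- c(av_vs_yv = "aged_vehicle-young_vehicle",
                     at_vs_yv = "aged_treated-young_vehicle",
                     at_vs_av = "aged_treated-aged_vehicle")

#' Test for rejuvenation of predicted transcriptional age
#'
#' For each cell type, reduces pseudocell predictions to per-sample mean
#' predicted ages (the statistical unit, n = samples per group), runs a
#' one-way ANOVA across the three groups, and applies Tukey's HSD
#' multiple-comparison correction to the pairwise contrasts. A cell type
#' is flagged `significant_rejuvenation` when the aged treated group mean
#' is below the aged vehicle group mean with a Tukey-adjusted p below
#' `alpha`.
#'
#' @param predictions Either an `age_prediction`, a list of them, or a
#'   data frame of pseudocell-level predictions with columns `cell_type`,
#'   `sample`, `group`, `predicted_age`.
#' @param alpha Significance threshold on adjusted p-values (default
#'   0.05).
#' @return An object of class `rejuvenation_result`: `summary` (per cell
#'   type: group means of per-sample mean predicted age, ANOVA F and p,
#'   the three Tukey-adjusted p-values, and the rejuvenation flag) and
#'   `sample_means` (the per-sample means the statistics ran on).
#' @export
assess_rejuvenation <- function(predictions, alpha = 0.05) {
  preds <- collect_predictions(predictions)
  need <- c("cell_type", "sample", "group", "predicted_age")
  stopifnot(all(need %in% names(preds)))
  sm <- stats::aggregate(predicted_age ~ cell_type + sample + group,
                         data = preds, FUN = mean)
  names(sm)[names(sm) == "predicted_age"] <- "mean_predicted_age"
  rows <- list()
  for (ct in sort(unique(sm$cell_type))) {
    d <- sm[sm$cell_type == ct, , drop = FALSE]
    tab <- table(d$group)
    missing_groups <- setdiff(GROUP_LEVELS, names(tab))
    if (length(missing_groups) || any(tab < 2)) {
      stop("cell type '", ct, "': every group needs at least 2 samples ",
           "for the rejuvenation test", call. = FALSE)
    }
    d$group <- factor(d$group, levels = GROUP_LEVELS)
    fit <- stats::aov(mean_predicted_age ~ group, data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    padj <- stats::setNames(tk[unname(TUKEY_CONTRASTS), "p adj"],
                            names(TUKEY_CONTRASTS))
    gm <- tapply(d$mean_predicted_age, d$group, mean)
    flag <- gm["aged_treated"] < gm["aged_vehicle"] &&
      padj[["at_vs_av"]] < alpha
    rows[[ct]] <- data.frame(
      cell_type = ct,
      mean_young_vehicle = gm[["young_vehicle"]],
      mean_aged_vehicle = gm[["aged_vehicle"]],
      mean_aged_treated = gm[["aged_treated"]],
      anova_f = an[1, "F value"],
      anova_p = an[1, "Pr(>F)"],
      p_aged_vehicle_vs_young = unname(padj["av_vs_yv"]),
      p_aged_treated_vs_young = unname(padj["at_vs_yv"]),
      p_aged_treated_vs_aged_vehicle = unname(padj["at_vs_av"]),
      significant_rejuvenation = flag,
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(rows,
                                            list(make.row.names = FALSE))),
                 sample_means = sm, alpha = alpha),
            class = "rejuvenation_result")
}

collect_predictions <- function(predictions) {
  if (inherits(predictions, "age_prediction")) {
    return(predictions$predictions)
  }
  if (is.data.frame(predictions)) {
    return(predictions)
  }
  if (is.list(predictions)) {
    return(do.call(rbind, lapply(predictions, collect_predictions)))
  }
  stop("cannot interpret predictions of class ",
       paste(class(predictions), collapse = "/"), call. = FALSE)
}

#' @export
print.rejuvenation_result <- function(x, ...) {
  n_sig <- sum(x$summary$significant_rejuvenation)
  cat("rejuvenation_result:", n_sig, "of", nrow(x$summary),
      "cell types flagged (alpha =", x$alpha, ")\n")
  print(x$summary[, c("cell_type", "mean_young_vehicle", "mean_aged_vehicle",
                      "mean_aged_treated", "p_aged_treated_vs_aged_vehicle",
                      "significant_rejuvenation")])
  invisible(x)
}

#' Cross-cell-type clock-driver gene summary
#'
#' Collects each cell type's non-zero-importance gene set and tallies the
#' genes present in at least k cell types, optionally restricted to the
#' cell types flagged as significantly rejuvenated.
#'
#' @param models A named list of [train_clock()] models (names = cell
#'   types), or a named list of character gene sets.
#' @param rejuvenation_flags Optional named logical vector per cell type;
#'   when `restrict_to_significant` is `TRUE`, only flagged cell types
#'   contribute.
#' @param k_values Thresholds k to tally (default `c(2, 3)`).
#' @param restrict_to_significant Restrict to flagged cell types (default
#'   `TRUE` when flags are supplied).
#' @return An object of class `driver_gene_summary`: `gene_sets` (per
#'   contributing cell type), `shared` (named list: for each k, the genes
#'   in >= k sets), and `counts` (data frame `k`, `n_genes`).
#' @export
summarize_drivers <- function(models, rejuvenation_flags = NULL,
                              k_values = c(2, 3),
                              restrict_to_significant =
                                !is.null(rejuvenation_flags)) {
  gene_sets <- lapply(models, function(m) {
    if (inherits(m, "clock_model")) nonzero_importance_genes(m)
    else as.character(m)
  })
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop("models must be a named list (names = cell types)", call. = FALSE)
  }
  if (restrict_to_significant) {
    if (is.null(rejuvenation_flags)) {
      stop("rejuvenation_flags required when restrict_to_significant = TRUE",
           call. = FALSE)
    }
    flagged <- names(rejuvenation_flags)[rejuvenation_flags]
    gene_sets <- gene_sets[intersect(names(gene_sets), flagged)]
    if (length(gene_sets) == 0) {
      warning("no cell types flagged as rejuvenated: empty driver summary",
              call. = FALSE)
    }
  }
  tally <- table(unlist(lapply(gene_sets, unique)))
  shared <- lapply(k_values, function(k) {
    sort(names(tally)[tally >= k])
  })
  names(shared) <- paste0("k", k_values)
  structure(list(gene_sets = gene_sets,
                 shared = shared,
                 counts = data.frame(k = k_values,
                                     n_genes = lengths(shared))),
            class = "driver_gene_summary")
}

#' @export
print.driver_gene_summary <- function(x, ...) {
  cat("driver_gene_summary over", length(x$gene_sets), "cell types\n")
  print(x$counts)
  invisible(x)
}
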