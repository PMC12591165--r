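test_that("pair folds exhaust both vehicle groups", {
  young <- sprintf("YV%d", 1:5)
  aged <- sprintf("AV%d", 1:5)
  folds <- build_pair_folds(young, aged, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$train, 8)
    expect_length(f$test, 2)
    expect_true(f$test[1] %in% young && f$test[2] %in% aged)
    expect_length(intersect(f$test, f$train), 0)
  }
  test_ids <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(test_ids, c(young, aged))
  expect_false(anyDuplicated(test_ids) > 0)

  # 2 + 2 design: exhaustive pairing, reproducible
  f2 <- build_pair_folds(c("y1", "y2"), c("a1", "a2"), seed = 11)
  expect_length(f2, 2)
  expect_identical(f2, build_pair_folds(c("y1", "y2"), c("a1", "a2"),
                                        seed = 11))

  expect_error(build_pair_folds("y1", c("a1", "a2")), "unequal")
  expect_error(build_pair_folds(c("y1", "y1"), c("a1", "a2")), "duplicate")
})

test_that("random pairing is approximately uniform over pairs", {
  young <- c("y1", "y2", "y3")
  aged <- c("a1", "a2", "a3")
  hits <- matrix(0, 3, 3, dimnames = list(young, aged))
  for (s in 1:1000) {
    folds <- build_pair_folds(young, aged, seed = s)
    for (f in folds) hits[f$test[1], f$test[2]] <- hits[f$test[1], f$test[2]] + 1
  }
  freq <- hits / 1000
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("ANOVA and Tukey reproduce an independent reference computation", {
  # 3 groups x 5 values; reference F and Tukey-adjusted p computed with an
  # independent statistics stack (scipy f_oneway / statsmodels
  # pairwise_tukeyhsd) and frozen here
  vals <- list(young_vehicle = c(24, 28, 37, 30, 31),
               aged_vehicle = c(37, 44, 31, 35, 41),
               aged_treated = c(42, 47, 52, 38, 49))
  preds <- do.call(rbind, lapply(names(vals), function(g) {
    data.frame(cell_type = "CT", group = g,
               sample = sprintf("%s_%d", g, seq_along(vals[[g]])),
               predicted_age = vals[[g]], stringsAsFactors = FALSE)
  }))
  res <- assess_rejuvenation(preds)
  s <- res$summary
  expect_equal(s$anova_f, 11.467336683417, tolerance = 1e-4)
  expect_equal(s$anova_p, 0.001642658760, tolerance = 1e-4)
  expect_equal(s$p_aged_vehicle_vs_young, 0.089259136994, tolerance = 1e-4)
  expect_equal(s$p_aged_treated_vs_young, 0.001187503860, tolerance = 1e-4)
  expect_equal(s$p_aged_treated_vs_aged_vehicle, 0.072356707558,
               tolerance = 1e-4)
  # treated mean is above vehicle here: no rejuvenation flag
  expect_false(s$significant_rejuvenation)
})

test_that("rejuvenation flag requires direction and adjusted significance", {
  set.seed(20)
  mk_preds <- function(treated_shift) {
    samples <- c(sprintf("YV%d", 1:5), sprintf("AV%d", 1:5),
                 sprintf("AT%d", 1:5))
    groups <- rep(c("young_vehicle", "aged_vehicle", "aged_treated"),
                  each = 5)
    centers <- c(young_vehicle = 3, aged_vehicle = 12,
                 aged_treated = 12 + treated_shift)
    do.call(rbind, lapply(seq_along(samples), function(i) {
      data.frame(cell_type = "CT", sample = samples[i], group = groups[i],
                 predicted_age = rnorm(40, centers[groups[i]], 0.5),
                 stringsAsFactors = FALSE)
    }))
  }
  expect_true(assess_rejuvenation(mk_preds(-6))$summary$significant_rejuvenation)
  expect_false(assess_rejuvenation(mk_preds(0))$summary$significant_rejuvenation)
  # treated OLDER than vehicle must never flag, however significant
  expect_false(assess_rejuvenation(mk_preds(+6))$summary$significant_rejuvenation)
  # group means equal means of per-sample means
  res <- assess_rejuvenation(mk_preds(-6))
  sm <- res$sample_means
  expect_equal(res$summary$mean_aged_vehicle,
               mean(sm$mean_predicted_age[sm$group == "aged_vehicle"]))
  d <- mk_preds(0)
  d <- d[!(d$sample %in% sprintf("AT%d", 1:4)), ]  # one treated sample left
  expect_error(assess_rejuvenation(d), "at least 2 samples")
})

test_that("driver summaries follow exact set arithmetic", {
  sets <- list(A = c("g1", "g2"), B = c("g1", "g3"))
  s <- summarize_drivers(sets)
  expect_equal(s$shared$k2, "g1")
  expect_length(s$shared$k3, 0)
  s3 <- summarize_drivers(list(A = "g7", B = c("g7", "g9"), C = "g7"))
  expect_true("g7" %in% s3$shared$k3)
  # restriction to flagged cell types
  flags <- c(A = TRUE, B = FALSE)
  expect_warning(
    s4 <- summarize_drivers(list(A = character(0), B = "g1"),
                            rejuvenation_flags = c(A = FALSE, B = FALSE)),
    "no cell types flagged")
  expect_length(s4$gene_sets, 0)
})

test_that("driver tallies match a brute-force intersection oracle", {
  set.seed(77)
  universe <- sprintf("g%03d", 1:60)
  for (trial in 1:200) {
    n_types <- sample(2:6, 1)
    sets <- lapply(seq_len(n_types),
                   function(i) sample(universe, sample(0:25, 1)))
    names(sets) <- sprintf("T%d", seq_len(n_types))
    ks <- 2:4
    s <- summarize_drivers(sets, k_values = ks)
    for (k in ks) {
      oracle <- sort(Filter(function(g) {
        sum(vapply(sets, function(st) g %in% st, logical(1))) >= k
      }, universe))
      expect_identical(s$shared[[paste0("k", k)]], oracle)
    }
    # monotone non-increasing in k
    expect_true(all(diff(s$counts$n_genes) <= 0))
  }
})

test_that("cross-validation pools held-out predictions per cell type", {
  cfg <- small_sim_config(n_cell_types = 2, samples_per_group = 3,
                          cells_per_sample_per_type = 50,
                          n_aging_genes_per_type = 15, seed = 55)
  sim <- simulate_dataset(cfg)
  vehicle <- sim$bundle$cell_metadata$group %in% c("young_vehicle",
                                                   "aged_vehicle")
  b <- subset_cells(sim$bundle, sim$bundle$barcodes[vehicle])
  pset <- normalize_pseudocells(make_pseudocells(b, n_reps = 25, seed = 6))
  folds <- build_pair_folds(sprintf("YV%d", 1:3), sprintf("AV%d", 1:3),
                            seed = 2)
  cv <- run_cv(pset, folds, seed = 3)
  expect_equal(sort(cv$summary$cell_type), c("CT01", "CT02"))
  expect_true(all(cv$summary$pearson_r > 0.8))
  # every vehicle sample's pseudocells appear exactly once as held-out
  per_sample <- table(cv$predictions$sample, cv$predictions$cell_type)
  expect_true(all(per_sample == 25))
  # pooled Pearson R equals an independent recomputation
  for (ct in c("CT01", "CT02")) {
    p <- cv$predictions[cv$predictions$cell_type == ct, ]
    expect_equal(cv$summary$pearson_r[cv$summary$cell_type == ct],
                 cor(p$predicted_age, p$age_months), tolerance = 1e-12)
  }
})

test_that("noise-free linear expression gives near-perfect pooled R", {
  set.seed(30)
  samples <- c(sprintf("YV%d", 1:3), sprintf("AV%d", 1:3))
  ages <- rep(c(3, 12), each = 3)
  n_rep <- 20
  expr <- do.call(cbind, lapply(seq_along(samples), function(i) {
    matrix(rep(ages[i] * c(1, -0.5, 2), n_rep), nrow = 3) +
      matrix(rnorm(3 * n_rep, 0, 1e-6), nrow = 3)
  }))
  rownames(expr) <- c("gA", "gB", "gC")
  pset <- fabricated_pset(expr, samples = rep(samples, each = n_rep),
                          ages = rep(ages, each = n_rep),
                          groups = rep(rep(c("young_vehicle", "aged_vehicle"),
                                           each = 3), each = n_rep))
  folds <- build_pair_folds(sprintf("YV%d", 1:3), sprintf("AV%d", 1:3),
                            seed = 4)
  cv <- run_cv(pset, folds, min_detect_frac = 0, seed = 5)
  expect_true(all(cv$summary$pearson_r > 0.98))
})

test_that("a cell type missing from a training fold is reported NA", {
  cfg <- small_sim_config(n_cell_types = 2, samples_per_group = 3,
                          cells_per_sample_per_type = 40, seed = 17)
  sim <- simulate_dataset(cfg)
  md <- sim$bundle$cell_metadata
  vehicle <- md$group %in% c("young_vehicle", "aged_vehicle")
  # CT02 exists only in YV1 and AV1: absent from any fold training on them
  keep <- vehicle & (md$cell_type == "CT01" |
                       md$sample %in% c("YV1", "AV1"))
  b <- subset_cells(sim$bundle, sim$bundle$barcodes[keep])
  pset <- normalize_pseudocells(make_pseudocells(b, n_reps = 10, seed = 1))
  folds <- build_pair_folds(sprintf("YV%d", 1:3), sprintf("AV%d", 1:3),
                            seed = 6)
  expect_warning(cv <- run_cv(pset, folds, seed = 2), "unavailable in fold")
  expect_true(is.na(cv$summary$pearson_r[cv$summary$cell_type == "CT02"]))
  expect_false(is.na(cv$summary$pearson_r[cv$summary$cell_type == "CT01"]))
})
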