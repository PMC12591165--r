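test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$bundle$counts), as.matrix(b$bundle$counts))
  expect_identical(a$bundle$cell_metadata, b$bundle$cell_metadata)
  expect_identical(a$truth$aging_genes, b$truth$aging_genes)
  c2 <- simulate_dataset(small_sim_config(seed = 12))
  expect_false(identical(as.matrix(a$bundle$counts),
                         as.matrix(c2$bundle$counts)))
})

test_that("invalid configurations are rejected", {
  expect_error(small_sim_config(rejuvenated_cell_types = "NOPE"),
               "not in cell_type_names")
  expect_error(small_sim_config(cells_per_sample_per_type = 0),
               "positive count")
  expect_error(small_sim_config(rejuvenation_fraction = 1.4), "\\[0, 1\\]")
  expect_error(small_sim_config(young_age_months = 12, aged_age_months = 12),
               "young_age_months")
})

test_that("cell counts and metadata obey the configured design", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_dataset(cfg)
  md <- sim$bundle$cell_metadata
  expect_equal(nrow(md),
               3 * cfg$samples_per_group * cfg$n_cell_types *
                 cfg$cells_per_sample_per_type)
  expect_setequal(unique(md$group),
                  c("young_vehicle", "aged_vehicle", "aged_treated"))
  expect_true(all(table(md$sample, md$cell_type) ==
                    cfg$cells_per_sample_per_type))
  x <- sim$bundle$counts@x
  expect_true(all(x >= 0) && all(x == round(x)))
  # effective-age bookkeeping
  expect_equal(unname(sim$truth$effective_age["YV1", ]),
               rep(cfg$young_age_months, cfg$n_cell_types))
  expect_equal(unname(sim$truth$effective_age["AV1", ]),
               rep(cfg$aged_age_months, cfg$n_cell_types))
})

test_that("planted aging genes match the closed-form NB mean ratio", {
  # strong signal: aged/young fold change of a planted gene should be
  # exp(effect * (aged - young)) within 10% at >= 5000 cells per group
  cfg <- simulation_config(n_genes = 60, n_cell_types = 1,
                           samples_per_group = 2,
                           cells_per_sample_per_type = 2500,
                           n_aging_genes_per_type = 5,
                           aging_effect_size = 0.15, dispersion = 10,
                           sample_effect_sd = 0,
                           frac_mito_genes = 0.05, frac_ribo_genes = 0.05,
                           seed = 5)
  sim <- simulate_dataset(cfg)
  md <- sim$bundle$cell_metadata
  young <- md$group == "young_vehicle"
  aged <- md$group == "aged_vehicle"
  expected <- exp(0.15 * (12 - 3))
  for (g in sim$truth$aging_genes[[1]]) {
    gi <- match(g, sim$bundle$gene_ids)
    ratio <- mean(sim$bundle$counts[gi, aged]) /
      mean(sim$bundle$counts[gi, young])
    expect_lt(abs(ratio / expected - 1), 0.10)
  }
})

test_that("zero effect size leaves group means indistinguishable", {
  cfg <- simulation_config(n_genes = 40, n_cell_types = 1,
                           samples_per_group = 2,
                           cells_per_sample_per_type = 1500,
                           n_aging_genes_per_type = 10,
                           aging_effect_size = 0, dispersion = 10,
                           sample_effect_sd = 0,
                           rejuvenated_cell_types = "CT01",
                           rejuvenation_fraction = 0.9, seed = 8)
  sim <- simulate_dataset(cfg)
  md <- sim$bundle$cell_metadata
  young <- md$group == "young_vehicle"
  aged <- md$group == "aged_vehicle"
  pvals <- vapply(sim$truth$aging_genes[[1]], function(g) {
    gi <- match(g, sim$bundle$gene_ids)
    stats::t.test(as.numeric(sim$bundle$counts[gi, young]),
                  as.numeric(sim$bundle$counts[gi, aged]))$p.value
  }, numeric(1))
  # no planted signal: at most a chance-level number of rejections
  expect_lte(sum(pvals < 0.05), 3)
})

test_that("planted group means are monotone in effective age", {
  cfg <- simulation_config(n_genes = 50, n_cell_types = 1,
                           samples_per_group = 2,
                           cells_per_sample_per_type = 1200,
                           n_aging_genes_per_type = 8,
                           aging_effect_size = 0.15, dispersion = 10,
                           sample_effect_sd = 0,
                           rejuvenated_cell_types = "CT01",
                           rejuvenation_fraction = 0.5, seed = 13)
  sim <- simulate_dataset(cfg)
  md <- sim$bundle$cell_metadata
  grp_mean <- function(g, grp) {
    gi <- match(g, sim$bundle$gene_ids)
    mean(sim$bundle$counts[gi, md$group == grp])
  }
  for (g in sim$truth$aging_genes[[1]]) {
    expect_lt(grp_mean(g, "young_vehicle"), grp_mean(g, "aged_treated"))
    expect_lt(grp_mean(g, "aged_treated"), grp_mean(g, "aged_vehicle"))
  }
})

test_that("QC outlier injection perturbs exactly n cells past 5 SD", {
  cfg <- small_sim_config(n_cell_types = 1, samples_per_group = 3,
                          cells_per_sample_per_type = 250, seed = 21)
  sim <- simulate_dataset(cfg)
  expect_equal(ncol(sim$bundle$counts), 2250)

  # identity at n = 0
  inj0 <- inject_qc_outliers(sim$bundle, 0, seed = 1)
  expect_identical(as.matrix(inj0$bundle$counts), as.matrix(sim$bundle$counts))
  expect_length(inj0$outlier_barcodes, 0)

  # pre-injection metrics via an independent dense computation
  dense <- as.matrix(sim$bundle$counts)
  mito <- grepl("^mt-", sim$bundle$gene_ids)
  pre_total <- colSums(dense)
  pre_mito <- 100 * colSums(dense[mito, , drop = FALSE]) / pre_total
  inj <- inject_qc_outliers(sim$bundle, 10, seed = 99)
  expect_length(inj$outlier_barcodes, 10)
  post <- as.matrix(inj$bundle$counts)
  post_total <- colSums(post)
  post_mito <- 100 * colSums(post[mito, , drop = FALSE]) / post_total
  for (bc in inj$outlier_barcodes) {
    i <- match(bc, sim$bundle$barcodes)
    z_total <- abs(post_total[i] - mean(pre_total)) / sd(pre_total)
    z_mito <- abs(post_mito[i] - mean(pre_mito)) / sd(pre_mito)
    expect_true(z_total > 5 || z_mito > 5)
  }
  # untouched cells unchanged
  untouched <- setdiff(sim$bundle$barcodes, inj$outlier_barcodes)
  expect_identical(post[, match(untouched, sim$bundle$barcodes)],
                   dense[, match(untouched, sim$bundle$barcodes)])

  # determinism and bounds
  inj2 <- inject_qc_outliers(sim$bundle, 10, seed = 99)
  expect_identical(inj$outlier_barcodes, inj2$outlier_barcodes)
  expect_identical(as.matrix(inj$bundle$counts), as.matrix(inj2$bundle$counts))
  expect_error(inject_qc_outliers(sim$bundle, 1e6), "exceeds")
})
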