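test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(censoring_rate = 1), "censoring_rate")
  expect_error(simulation_config(censoring_rate = -0.1), "censoring_rate")
  expect_error(simulation_config(regulator_target_corr = 0.2), "regulator_target_corr")
  expect_error(simulation_config(regulator_target_corr = -0.99,
                                 regulator_set_size = 2),
               "regulator_target_corr")
  expect_error(simulation_config(n_datasets = 0), "n_datasets")
  expect_error(simulation_config(tumor_n = 1), "tumor_n")
  expect_error(simulation_config(genes_per_dataset = 50,
                                 planted_down_genes = 40,
                                 planted_up_genes = 40),
               "genes_per_dataset")
  expect_error(simulation_config(dataset_scale_range = c(2, 1)),
               "dataset_scale_range")
  expect_error(simulation_config(baseline_hazard = 0), "baseline_hazard")
})

test_that("identical seed and config give bit-identical cohorts", {
  s1 <- generate_cohorts(small_sim_config(seed = 1))
  s2 <- generate_cohorts(small_sim_config(seed = 1))
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$truth$planted_down, s2$truth$planted_down)
  s3 <- generate_cohorts(small_sim_config(seed = 2))
  expect_false(identical(s1$expression[[1]], s3$expression[[1]]))
})

test_that("generated datasets share the gene universe and truth is coherent", {
  sim <- generate_cohorts(small_sim_config(seed = 5))
  tr <- sim$truth
  expect_length(intersect(tr$planted_down, tr$planted_up), 0)
  genes <- sim$expression[[1]]$gene_id
  for (e in sim$expression) expect_identical(e$gene_id, genes)
  listed <- c(tr$planted_down, tr$planted_up, tr$regulator_set, tr$target_genes)
  expect_true(all(listed %in% genes))
  expect_true(all(tr$target_genes %in% tr$planted_down))
})

test_that("clinical table carries fields for tumors only, with valid outcomes", {
  sim <- generate_cohorts(small_sim_config(seed = 5))
  cl <- sim$clinical
  expect_false(anyDuplicated(cl$sample_id) > 0)
  nm <- cl[cl$condition == "normal", ]
  for (col in c("stage", "grade", "prognosis", "vascular_invasion")) {
    expect_true(all(is.na(nm[[col]])))
  }
  expect_true(all(is.na(nm$survival_time)))
  tm <- cl[cl$condition == "tumor", ]
  expect_true(all(tm$survival_time > 0))
  expect_true(all(tm$event %in% c(0L, 1L)))
  expect_true(all(tm$stage %in% c("I", "II", "III")))
  expect_true(all(tm$grade %in% c("G1", "G2", "G3")))
  expect_true(all(tm$prognosis %in% c("good", "intermediate", "poor")))
})

test_that("within-dataset Z-scores of generated data have mean 0 and sample SD 1", {
  sim <- generate_cohorts(small_sim_config(seed = 8))
  for (e in sim$expression) {
    z <- zscore_normalize(e)
    m <- as.matrix(z[setdiff(names(z), "gene_id")])
    expect_lt(max(abs(rowMeans(m))), 1e-9)
    expect_lt(max(abs(apply(m, 1, sd) - 1)), 1e-9)
  }
})

test_that("a null simulation shows type-I-level differential calls only", {
  cfg <- small_sim_config(seed = 13, genes_per_dataset = 2000,
                          planted_down_genes = 0, planted_up_genes = 0,
                          tumor_n = 25, normal_n = 25)
  sim <- generate_cohorts(cfg)
  pooled <- suppressMessages(pool_datasets(lapply(sim$expression, zscore_normalize)))
  de <- differential_test(pooled, sim$clinical)
  frac <- mean(de$p_raw < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("zero effect size leaves planted genes indistinguishable", {
  cfg <- small_sim_config(seed = 17, effect_size_sd = 0,
                          planted_down_genes = 100, genes_per_dataset = 1000)
  sim <- generate_cohorts(cfg)
  pooled <- suppressMessages(pool_datasets(lapply(sim$expression, zscore_normalize)))
  de <- differential_test(pooled, sim$clinical)
  planted_p <- de$p_raw[de$gene_id %in% sim$truth$planted_down]
  expect_lt(mean(planted_p < 0.05), 0.15)
  expect_equal(sum(de$p_bonferroni < 0.05), 0)
})

test_that("regulator-program score tracks the configured target anti-correlation", {
  rs <- purrr::map(1:20, function(s) {
    cfg <- small_sim_config(seed = s, n_datasets = 1, genes_per_dataset = 300,
                            tumor_n = 200, normal_n = 10,
                            planted_down_genes = 20, planted_up_genes = 10)
    sim <- generate_cohorts(cfg)
    z <- zscore_normalize(sim$expression[[1]])
    sets <- truth_gene_sets(sim$truth)
    sc <- suppressWarnings(patient_scores(z, sets))
    ids <- paste("d1", sc$sample_id, sep = ".")
    tumor <- sim$clinical$condition[match(ids, sim$clinical$sample_id)] == "tumor"
    zm <- as.matrix(z[setdiff(names(z), "gene_id")])
    rownames(zm) <- z$gene_id
    vapply(sim$truth$target_genes, function(g) {
      correlate(sc$regulator_program[tumor], zm[g, tumor])$r
    }, numeric(1))
  })
  mean_r <- colMeans(do.call(rbind, rs))
  expect_true(all(abs(mean_r - (-0.6)) < 0.1))
})

test_that("severity labels are linked to the planted signature score", {
  sim <- generate_cohorts(small_sim_config(seed = 21, tumor_n = 60, normal_n = 10))
  pooled <- suppressMessages(pool_datasets(lapply(sim$expression, zscore_normalize)))
  sc <- suppressWarnings(patient_scores(pooled, truth_gene_sets(sim$truth)))
  df <- dplyr::inner_join(
    tibble::tibble(sample_id = sc$sample_id, score = sc$planted_down_module),
    sim$clinical, by = "sample_id"
  )
  tum <- df[df$condition == "tumor", ]
  m <- tapply(tum$score, tum$stage, mean)
  expect_gt(m[["I"]], m[["III"]])
})

test_that("survival generation honors the censoring and hazard contracts", {
  cfg <- small_sim_config(seed = 2, censoring_rate = 0)
  sc <- tibble::tibble(sample_id = sprintf("s%d", 1:50), score = rnorm(50))
  sv <- generate_survival(sc, cfg, seed = 4)
  expect_true(all(sv$event == 1L))
  expect_true(all(sv$survival_time > 0))
  expect_error(generate_survival(sc[0, ], cfg), "empty")

  # null hazard link: median-split groups separate no more than chance
  cfg0 <- small_sim_config(seed = 2, log_hazard_per_score_sd = 0)
  sig <- vapply(1:100, function(s) {
    set.seed(s)
    scores <- tibble::tibble(sample_id = sprintf("s%d", 1:100),
                             score = rnorm(100))
    sv <- generate_survival(scores, cfg0)
    grp <- split_groups(scores$score, "median")
    logrank_test(sv$survival_time, sv$event, grp)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.90)
})

test_that("a negative hazard link gives the high-score group longer survival", {
  cfg <- small_sim_config(seed = 2, log_hazard_per_score_sd = -0.8)
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    scores <- tibble::tibble(sample_id = sprintf("s%d", 1:200),
                             score = rnorm(200))
    sv <- generate_survival(scores, cfg)
    grp <- split_groups(scores$score, "median")
    hi <- km_estimate(sv$survival_time[grp == "G1"], sv$event[grp == "G1"])
    lo <- km_estimate(sv$survival_time[grp == "G0"], sv$event[grp == "G0"])
    km_median_time(hi) > km_median_time(lo)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
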