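test_that("patient scores are sums of member-gene Z-scores", {
  z <- tibble::tibble(gene_id = c("A", "B", "D"),
                      s1 = c(1.5, -0.5, 9), s2 = c(2, 1, -9))
  sets <- tibble::tibble(set_name = c("S", "S", "S2"),
                         gene_id = c("A", "B", "A"))
  sc <- patient_scores(z, sets)
  expect_equal(sc$S, c(1.0, 3.0))
  expect_equal(sc$S2, c(1.5, 2))
  # genes absent from the matrix are skipped
  sets_c <- tibble::tibble(set_name = "S", gene_id = c("A", "B", "C"))
  sc2 <- patient_scores(z, sets_c)
  expect_equal(sc2$S, sc$S)
  expect_equal(attr(sc2, "genes_used")[["S"]], 2L)
  # a set with no gene present scores zero with a warning
  expect_warning(sc3 <- patient_scores(z, tibble::tibble(set_name = "X",
                                                         gene_id = "nope")),
                 "no gene")
  expect_equal(sc3$X, c(0, 0))
})

test_that("patient scores match a brute-force per-element loop exactly", {
  set.seed(5)
  z <- zscore_normalize(rand_expr(50, 20, seed = 5, na_frac = 0.05))
  sets <- purrr::map(1:10, function(i) {
    tibble::tibble(set_name = paste0("S", i),
                   gene_id = sample(z$gene_id, sample(3:15, 1)))
  }) |> dplyr::bind_rows()
  sc <- patient_scores(z, sets)
  zm <- as.matrix(z[-1]); rownames(zm) <- z$gene_id
  for (s in unique(sets$set_name)) {
    members <- sets$gene_id[sets$set_name == s]
    for (j in seq_len(ncol(zm))) {
      acc <- 0
      for (g in members) {
        v <- zm[g, j]
        if (!is.na(v)) acc <- acc + v
      }
      expect_equal(sc[[s]][j], acc, tolerance = 1e-12)
    }
  }
  # composition: score of a union of disjoint sets is the sum of the parts
  u <- dplyr::bind_rows(
    tibble::tibble(set_name = "U", gene_id = z$gene_id[1:10]),
    tibble::tibble(set_name = "A", gene_id = z$gene_id[1:5]),
    tibble::tibble(set_name = "B", gene_id = z$gene_id[6:10])
  )
  scu <- patient_scores(z, u)
  expect_equal(scu$U, scu$A + scu$B, tolerance = 1e-12)
})

test_that("composite scores average their components", {
  tbl <- tibble::tibble(sample_id = c("s1", "s2"),
                        a = c(1, 4), b = c(2, 5), c = c(3, 6))
  cs <- composite_score(tbl, c("a", "b", "c"), "hdac1_activity")
  expect_equal(cs$hdac1_activity, c(2, 5))
  single <- composite_score(tbl, "b", "solo")
  expect_equal(single$solo, tbl$b)
  expect_error(composite_score(tbl, c("a", "zz"), "x"), "zz")
})

test_that("group splitting follows the median rule with ties to G0", {
  expect_identical(split_groups(c(1, 2, 3, 4)), c("G0", "G0", "G1", "G1"))
  expect_identical(split_groups(c(1, 2, 2, 3)), c("G0", "G0", "G0", "G1"))
  expect_identical(split_groups(c(1, 2, 3, 4), "supplied",
                                labels = c("G1", "G0", "G1", "G0")),
                   c("G1", "G0", "G1", "G0"))
  tert <- split_groups(c(1:9), "tertile")
  expect_identical(tert, c(rep("G0", 3), rep(NA, 3), rep("G1", 3)))
  expect_error(split_groups(rep(2, 6)), "identical")
  expect_error(split_groups(c(1, 2, 3)), "4 samples")
})

test_that("pathway score evaluates the signed log10 formula", {
  mk <- function(m0, m1, sd = 0.05, n = 6, seed = 1) {
    set.seed(seed)
    noise <- rnorm(2 * n, 0, sd); noise <- noise - ave(noise, rep(1:2, each = n))
    tibble::tibble(sample_id = sprintf("s%d", 1:(2 * n)),
                   S = rep(c(m0, m1), each = n) + noise)
  }
  lab <- rep(c("G0", "G1"), each = 6)
  rec <- pathway_score(mk(5, 3), lab, "S")
  expect_equal(rec$g0_avg, 5, tolerance = 1e-9)
  expect_equal(rec$g1_avg, 3, tolerance = 1e-9)
  expect_lt(rec$p_value, 0.05)
  expect_equal(rec$magnitude, log10(2), tolerance = 1e-9)
  expect_equal(rec$sign, -1L)
  expect_equal(rec$pathway_score, -log10(2), tolerance = 1e-9)
  # sign symmetry
  rec2 <- pathway_score(mk(3, 5), lab, "S")
  expect_equal(rec2$pathway_score, log10(2), tolerance = 1e-9)
  # identical groups: p = 1, score 0
  tie <- tibble::tibble(sample_id = sprintf("s%d", 1:8), S = rep(c(1, 2), 4))
  rec3 <- pathway_score(tie, rep(c("G0", "G1"), each = 4), "S")
  expect_equal(rec3$p_value, 1)
  expect_equal(rec3$pathway_score, 0)
  expect_error(pathway_score(mk(1, 2), c("G0", rep("G1", 11)), "S"), "2 samples")
})

test_that("sign rules hold over random group draws and flip under label swap", {
  set.seed(77)
  for (i in 1:1000) {
    n0 <- sample(3:10, 1); n1 <- sample(3:10, 1)
    vals <- c(rnorm(n0, rnorm(1, 0, 3)), rnorm(n1, rnorm(1, 0, 3)))
    lab <- rep(c("G0", "G1"), c(n0, n1))
    tbl <- tibble::tibble(sample_id = seq_along(vals), S = vals)
    rec <- pathway_score(tbl, lab, "S")
    if (rec$p_value >= 0.05) {
      expect_identical(rec$sign, 0L)
      expect_identical(rec$pathway_score, 0)
    } else if (rec$g0_avg > rec$g1_avg) {
      expect_identical(rec$sign, -1L)
    } else {
      expect_identical(rec$sign, 1L)
    }
    # antisymmetry: swapping G0/G1 negates the score, magnitude unchanged
    swap <- ifelse(lab == "G0", "G1", "G0")
    rec_s <- pathway_score(tbl, swap, "S")
    expect_equal(rec_s$magnitude, rec$magnitude, tolerance = 1e-12)
    expect_equal(rec_s$pathway_score, -rec$pathway_score, tolerance = 1e-12)
  }
})

test_that("the enrichment matrix composes per-cohort pathway scores", {
  set.seed(9)
  tbl <- tibble::tibble(sample_id = sprintf("s%d", 1:20), S = rnorm(20, 5))
  lab <- rep(c("G0", "G1"), each = 10)
  em <- enrichment_matrix(list(c1 = list(scores = tbl, labels = lab)))
  rec <- pathway_score(tbl, lab, "S")
  expect_equal(nrow(em), 1)
  expect_equal(em$pathway_score, rec$pathway_score)
  expect_equal(em$p_value, rec$p_value)
  # per-cell failure becomes an NA cell, not an abort
  bad <- list(scores = tbl[1:3, ], labels = c("G0", "G0", "G1"))
  expect_warning(em2 <- enrichment_matrix(list(ok = list(scores = tbl, labels = lab),
                                               bad = bad)),
                 "failed")
  expect_true(is.na(em2$pathway_score[em2$cohort == "bad"]))
})

test_that("planted-down signature is enriched in normals across cohorts", {
  sim <- generate_cohorts(small_sim_config(seed = 29, n_datasets = 3,
                                           effect_size_sd = 1.5))
  sets <- truth_gene_sets(sim$truth)
  cohorts <- purrr::imap(sim$expression, function(e, id) {
    z <- zscore_normalize(e)
    sc <- suppressWarnings(patient_scores(z, sets))
    ids <- paste(id, sc$sample_id, sep = ".")
    cond <- sim$clinical$condition[match(ids, sim$clinical$sample_id)]
    list(scores = sc, labels = ifelse(cond == "normal", "G0", "G1"))
  })
  em <- enrichment_matrix(cohorts, sets = "planted_down_module")
  expect_true(all(em$sign == -1L))
  expect_true(all(em$pathway_score < 0))
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  universe <- sprintf("u%03d", 1:100)
  sets <- tibble::tibble(set_name = "K",
                         gene_id = universe[1:10])
  query <- c(universe[1:3], universe[21:37])  # overlap 3, |query| 20
  res <- hypergeometric_enrichment(query, sets, universe)
  tail_sum <- sum(vapply(3:10, function(k) {
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)
  }, numeric(1)))
  expect_equal(res$p_value, tail_sum, tolerance = 1e-12)
  expect_equal(res$overlap, 3L)
  # query equal to a set in a big universe: p ~ 0, ranked first
  sets2 <- dplyr::bind_rows(sets,
                            tibble::tibble(set_name = "rand",
                                           gene_id = universe[50:80]))
  res2 <- hypergeometric_enrichment(universe[1:10], sets2, universe)
  expect_identical(res2$set_name[1], "K")
  expect_lt(res2$p_value[1], 1e-10)
  # disjoint query: upper tail including 0 is 1
  res3 <- hypergeometric_enrichment(universe[90:99], sets, universe)
  expect_equal(res3$p_value, 1)
  expect_error(hypergeometric_enrichment("x", sets, character()), "universe")
  expect_error(hypergeometric_enrichment("not-there", sets, universe),
               "outside the universe")
})

test_that("random small instances agree with the reference hypergeometric tail", {
  set.seed(123)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    universe <- sprintf("u%d", seq_len(N))
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    sets <- tibble::tibble(set_name = "S", gene_id = sample(universe, K))
    query <- sample(universe, n)
    res <- hypergeometric_enrichment(query, sets, universe)
    k <- length(intersect(query, sets$gene_id))
    brute <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
    expect_equal(res$p_value, brute, tolerance = 1e-8)
  }
})
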