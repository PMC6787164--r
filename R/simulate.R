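#' Simulation configuration for synthetic multi-cohort expression data
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' generator emulates the statistical structure of a multi-cohort tumor
#' meta-analysis: several datasets measured on different "platforms"
#' (per-dataset additive offset and multiplicative scale applied per gene),
#' paired tumor/normal groups, a planted down-regulated gene module and a
#' planted up-regulated module (shifts expressed in within-dataset SD units),
#' a co-expressed regulator program whose summed score is anti-correlated
#' with two designated target genes, severity-linked ordinal clinical labels,
#' and exponential survival times whose log-hazard is linear in the planted
#' signature score.
#'
#' @param n_datasets Number of cohorts to generate.
#' @param genes_per_dataset Size of the shared gene universe.
#' @param tumor_n,normal_n Samples per condition in every dataset (>= 2 each
#'   so that two-group tests are defined).
#' @param planted_down_genes,planted_up_genes Number of genes shifted down /
#'   up in tumors. May be 0 (null simulation).
#' @param effect_size_sd Tumor shift of planted genes, in within-dataset SD
#'   units. 0 means no effect.
#' @param dataset_offset_sd SD of the per-dataset, per-gene additive offset
#'   (batch location effect).
#' @param dataset_scale_range Length-2 numeric, the Uniform range of the
#'   per-dataset, per-gene multiplicative scale (batch scale effect). Both
#'   endpoints must be positive.
#' @param regulator_set_size Number of co-expressed regulator genes (the
#'   synthetic analogue of a hyperactive signaling program).
#' @param regulator_target_corr Desired Pearson correlation, in `[-1, 0]`,
#'   between the summed regulator score and each of the two target genes
#'   across tumor samples. Must be achievable given `regulator_set_size`
#'   (see Details).
#' @param baseline_hazard Baseline exponential event rate per time unit.
#' @param log_hazard_per_score_sd Log hazard ratio per SD of the planted
#'   signature score. Negative values make high-score patients survive
#'   longer.
#' @param censoring_rate Probability, in `[0, 1)`, that a subject is censored
#'   (uniformly before its event time).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @details The regulator program is built from a shared latent factor with
#' loading `a = 0.7` on every regulator gene; the two target genes load with
#' the opposite sign, scaled so the sum-score correlation hits
#' `regulator_target_corr`. The attainable magnitude is
#' `a * sqrt(m) / sqrt(m * a^2 + 1 - a^2)` for `m = regulator_set_size`
#' (about 0.97 for m = 20); configs demanding more are rejected.
#'
#' @return A `sim_config` object (a validated named list).
#' @seealso [generate_cohorts()], [generate_survival()]
#' @export
#' @examples
#' cfg <- simulation_config(n_datasets = 2, genes_per_dataset = 200,
#'                          tumor_n = 10, normal_n = 10, seed = 1)
simulation_config <- function(n_datasets = 4,
                              genes_per_dataset = 5000,
                              tumor_n = 50,
                              normal_n = 50,
                              planted_down_genes = 100,
                              planted_up_genes = 100,
                              effect_size_sd = 1.5,
                              dataset_offset_sd = 1,
                              dataset_scale_range = c(0.5, 2),
                              regulator_set_size = 20,
                              regulator_target_corr = -0.6,
                              baseline_hazard = 0.05,
                              log_hazard_per_score_sd = -0.8,
                              censoring_rate = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    genes_per_dataset = as.integer(genes_per_dataset),
    tumor_n = as.integer(tumor_n),
    normal_n = as.integer(normal_n),
    planted_down_genes = as.integer(planted_down_genes),
    planted_up_genes = as.integer(planted_up_genes),
    effect_size_sd = as.numeric(effect_size_sd),
    dataset_offset_sd = as.numeric(dataset_offset_sd),
    dataset_scale_range = as.numeric(dataset_scale_range),
    regulator_set_size = as.integer(regulator_set_size),
    regulator_target_corr = as.numeric(regulator_target_corr),
    baseline_hazard = as.numeric(baseline_hazard),
    log_hazard_per_score_sd = as.numeric(log_hazard_per_score_sd),
    censoring_rate = as.numeric(censoring_rate),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# Latent-factor loading shared by all regulator genes.
REGULATOR_LOADING <- 0.7

regulator_sum_corr_max <- function(m, a = REGULATOR_LOADING) {
  a * sqrt(m) / sqrt(m * a^2 + 1 - a^2)
}

validate_sim_config <- function(cfg) {
  need_pos <- c("n_datasets", "genes_per_dataset", "tumor_n", "normal_n",
                "regulator_set_size")
  for (f in need_pos) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      abort(sprintf("`%s` must be a count >= 1.", f))
    }
  }
  if (cfg$tumor_n < 2L || cfg$normal_n < 2L) {
    abort("`tumor_n` and `normal_n` must each be >= 2 for two-group testing.")
  }
  for (f in c("planted_down_genes", "planted_up_genes")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      abort(sprintf("`%s` must be a count >= 0.", f))
    }
  }
  n_assigned <- cfg$planted_down_genes + cfg$planted_up_genes +
    cfg$regulator_set_size
  if (n_assigned > cfg$genes_per_dataset) {
    abort(paste0(
      "`planted_down_genes` + `planted_up_genes` + `regulator_set_size` ",
      "must not exceed `genes_per_dataset`."
    ))
  }
  if (is.na(cfg$regulator_target_corr) ||
      cfg$regulator_target_corr < -1 || cfg$regulator_target_corr > 0) {
    abort("`regulator_target_corr` must lie in [-1, 0].")
  }
  r_max <- regulator_sum_corr_max(cfg$regulator_set_size)
  if (abs(cfg$regulator_target_corr) > r_max) {
    abort(sprintf(
      "`regulator_target_corr` magnitude %.3f exceeds the attainable %.3f for regulator_set_size = %d.",
      abs(cfg$regulator_target_corr), r_max, cfg$regulator_set_size
    ))
  }
  if (is.na(cfg$censoring_rate) || cfg$censoring_rate < 0 ||
      cfg$censoring_rate >= 1) {
    abort("`censoring_rate` must lie in [0, 1).")
  }
  if (length(cfg$dataset_scale_range) != 2L ||
      any(cfg$dataset_scale_range <= 0) ||
      diff(cfg$dataset_scale_range) < 0) {
    abort("`dataset_scale_range` must be an increasing positive pair.")
  }
  if (cfg$dataset_offset_sd < 0) abort("`dataset_offset_sd` must be >= 0.")
  if (cfg$baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (cfg$effect_size_sd < 0) abort("`effect_size_sd` must be >= 0.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d dataset(s) x %d genes, %d tumor + %d normal each\n",
              x$n_datasets, x$genes_per_dataset, x$tumor_n, x$normal_n))
  cat(sprintf("  planted: %d down / %d up at %.2f SD; regulator set %d (target corr %.2f)\n",
              x$planted_down_genes, x$planted_up_genes, x$effect_size_sd,
              x$regulator_set_size, x$regulator_target_corr))
  cat(sprintf("  hazard: h0 = %.3g, log HR/SD = %.2f, censoring %.0f%%; seed %d\n",
              x$baseline_hazard, x$log_hazard_per_score_sd,
              100 * x$censoring_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic multi-cohort tumor/normal expression study
#'
#' Produces one expression matrix per dataset over a shared gene universe, a
#' clinical annotation table, and the ground truth needed for recovery
#' testing. Tumor samples carry the planted down/up shifts (in within-dataset
#' SD units) on top of dataset-specific per-gene offset and scale batch
#' effects, which makes per-dataset Z-score normalization necessary before
#' pooling. Stage, grade, prognosis and vascular invasion are drawn by
#' thresholding noisy monotone transforms of the planted-signature score, so
#' the score decreases stochastically with severity. Survival times follow an
#' exponential model with log-hazard linear in the standardized score.
#'
#' @param config A [simulation_config()] object.
#'
#' @return A `cohort_sim` list with elements:
#' \describe{
#'   \item{expression}{Named list of expression tibbles (`gene_id` first
#'     column, one numeric column per sample), one per dataset; each carries
#'     a `dataset_id` attribute.}
#'   \item{clinical}{Tibble with one row per sample across all datasets:
#'     `sample_id` (already dataset-prefixed, matching [pool_datasets()]),
#'     `dataset_id`, `condition` (tumor/normal), `stage`, `grade`,
#'     `prognosis`, `vascular_invasion`, `survival_time`, `event`. Normal
#'     samples carry NA for all clinical/survival fields.}
#'   \item{truth}{A `cohort_truth` list: `planted_down`, `planted_up`,
#'     `regulator_set`, `target_genes`, `effect_sizes` tibble, process-set
#'     memberships and enzyme-role annotations for the planted module, and
#'     the hazard model parameters.}
#'   \item{config}{The input config.}
#' }
#' @export
#' @examples
#' sim <- generate_cohorts(simulation_config(n_datasets = 2,
#'   genes_per_dataset = 300, tumor_n = 12, normal_n = 12, seed = 7))
#' names(sim$expression)
generate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with simulation_config().")
  }
  set.seed(config$seed)
  G <- config$genes_per_dataset
  genes <- sprintf("g%05d", seq_len(G))
  n_down <- config$planted_down_genes
  n_up <- config$planted_up_genes
  m_reg <- config$regulator_set_size

  assigned <- sample(genes, n_down + n_up + m_reg)
  planted_down <- assigned[seq_len(n_down)]
  planted_up <- assigned[n_down + seq_len(n_up)]
  regulator_set <- assigned[n_down + n_up + seq_len(m_reg)]
  free_genes <- setdiff(genes, assigned)
  if (n_down >= 2L) {
    target_genes <- planted_down[1:2]
  } else if (length(free_genes) >= 2L) {
    target_genes <- sample(free_genes, 2L)
  } else {
    abort("Gene universe too small to place the two regulator target genes.")
  }

  a <- REGULATOR_LOADING
  b <- abs(config$regulator_target_corr) / regulator_sum_corr_max(m_reg)

  mu_g <- rnorm(G, mean = 8, sd = 2)
  names(mu_g) <- genes
  reg_idx <- match(regulator_set, genes)
  tgt_idx <- match(target_genes, genes)
  down_idx <- match(planted_down, genes)
  up_idx <- match(planted_up, genes)

  n_t <- config$tumor_n
  n_n <- config$normal_n
  n <- n_t + n_n
  dataset_ids <- sprintf("d%d", seq_len(config$n_datasets))
  local_samples <- c(sprintf("t%02d", seq_len(n_t)), sprintf("n%02d", seq_len(n_n)))
  tumor_cols <- seq_len(n_t)

  expression <- vector("list", config$n_datasets)
  names(expression) <- dataset_ids
  for (d in seq_len(config$n_datasets)) {
    u <- rnorm(n)                       # shared latent factor, one per sample
    x <- mu_g + matrix(rnorm(G * n), nrow = G, ncol = n)
    if (m_reg > 0L) {
      eps <- matrix(rnorm(m_reg * n), nrow = m_reg)
      x[reg_idx, ] <- mu_g[reg_idx] + a * rep(u, each = m_reg) +
        sqrt(1 - a^2) * eps
    }
    eps_t <- matrix(rnorm(2L * n), nrow = 2L)
    x[tgt_idx, ] <- mu_g[tgt_idx] - b * rep(u, each = 2L) +
      sqrt(1 - b^2) * eps_t
    if (n_down > 0L) {
      x[down_idx, tumor_cols] <- x[down_idx, tumor_cols] - config$effect_size_sd
    }
    if (n_up > 0L) {
      x[up_idx, tumor_cols] <- x[up_idx, tumor_cols] + config$effect_size_sd
    }
    # regulator program hyperactive in tumors
    x[reg_idx, tumor_cols] <- x[reg_idx, tumor_cols] + config$effect_size_sd
    offset <- rnorm(G, 0, config$dataset_offset_sd)
    scale_f <- runif(G, config$dataset_scale_range[1], config$dataset_scale_range[2])
    x <- scale_f * x + offset
    dimnames(x) <- list(genes, local_samples)
    expression[[d]] <- matrix_to_expr(x, dataset_id = dataset_ids[d])
  }

  # Planted-signature score per sample, computed on within-dataset Z-scores
  # exactly as the analysis will see them.
  pooled <- pool_datasets(lapply(expression, zscore_normalize))
  zm <- expr_to_matrix(pooled)
  all_ids <- colnames(zm)
  cond <- rep(rep(c("tumor", "normal"), times = c(n_t, n_n)), config$n_datasets)
  tumor_ids <- all_ids[cond == "tumor"]
  if (n_down > 0L) {
    sig_score <- colSums(zm[down_idx, tumor_ids, drop = FALSE])
  } else {
    sig_score <- rnorm(length(tumor_ids))
    names(sig_score) <- tumor_ids
  }
  z_sig <- if (sd(sig_score) > 0) as.numeric(scale(sig_score)) else rep(0, length(sig_score))

  severity_noise_sd <- 0.5
  cut3 <- function(latent, labels) {
    cuts <- quantile(latent, c(1 / 3, 2 / 3), names = FALSE)
    labels[1L + (latent > cuts[1]) + (latent > cuts[2])]
  }
  lat_stage <- -z_sig + rnorm(length(z_sig), 0, severity_noise_sd)
  lat_grade <- -z_sig + rnorm(length(z_sig), 0, severity_noise_sd)
  lat_prog <- -z_sig + rnorm(length(z_sig), 0, severity_noise_sd)
  lat_vasc <- -z_sig + rnorm(length(z_sig), 0, severity_noise_sd)
  stage <- cut3(lat_stage, c("I", "II", "III"))
  grade <- cut3(lat_grade, c("G1", "G2", "G3"))
  prognosis <- cut3(lat_prog, c("good", "intermediate", "poor"))
  vascular <- ifelse(stats::plogis(lat_vasc) > runif(length(z_sig)), "yes", "no")

  surv <- generate_survival(
    tibble::tibble(sample_id = tumor_ids, score = unname(sig_score)),
    config
  )

  clinical <- tibble::tibble(
    sample_id = all_ids,
    dataset_id = rep(dataset_ids, each = n),
    condition = cond
  )
  tum <- match(tumor_ids, clinical$sample_id)
  clinical$stage <- NA_character_; clinical$stage[tum] <- stage
  clinical$grade <- NA_character_; clinical$grade[tum] <- grade
  clinical$prognosis <- NA_character_; clinical$prognosis[tum] <- prognosis
  clinical$vascular_invasion <- NA_character_
  clinical$vascular_invasion[tum] <- vascular
  clinical$survival_time <- NA_real_
  clinical$survival_time[tum] <- surv$survival_time
  clinical$event <- NA_integer_
  clinical$event[tum] <- surv$event

  truth <- structure(list(
    planted_down = planted_down,
    planted_up = planted_up,
    regulator_set = regulator_set,
    target_genes = target_genes,
    effect_sizes = tibble::tibble(
      gene_id = c(planted_down, planted_up, regulator_set),
      effect = c(rep(-config$effect_size_sd, n_down),
                 rep(config$effect_size_sd, n_up),
                 rep(config$effect_size_sd, m_reg))
    ),
    process_sets = draw_process_sets(planted_down),
    roles = draw_roles(genes, planted_down),
    hazard = list(baseline = config$baseline_hazard,
                  log_hr_per_sd = config$log_hazard_per_score_sd,
                  censoring_rate = config$censoring_rate),
    regulator_loading = a,
    target_loading = b,
    severity_noise_sd = severity_noise_sd
  ), class = "cohort_truth")

  structure(
    list(expression = expression, clinical = clinical, truth = truth,
         config = config),
    class = "cohort_sim"
  )
}

# Assign each planted-down gene to 1-3 (occasionally more) of five metabolic
# processes; emulates overlapping pathway membership of a catabolic module.
draw_process_sets <- function(planted_down) {
  processes <- c("aa_met", "lipid_met", "carb_met", "drug_met", "retinol_met")
  if (length(planted_down) == 0L) {
    return(tibble::tibble(set_name = character(), gene_id = character()))
  }
  k <- sample(1:5, length(planted_down), replace = TRUE,
              prob = c(0.45, 0.30, 0.15, 0.07, 0.03))
  membership <- purrr::map2(planted_down, k, function(g, kk) {
    tibble::tibble(set_name = sample(processes, kk), gene_id = g)
  })
  dplyr::arrange(dplyr::bind_rows(membership), .data$set_name, .data$gene_id)
}

# Enzyme-role annotation: ~90% of the planted-down module is catabolic,
# the rest anabolic; background genes are mostly non-enzymatic/unknown.
draw_roles <- function(genes, planted_down) {
  role <- sample(c("catabolic", "anabolic", "non-enzymatic", "unknown"),
                 length(genes), replace = TRUE,
                 prob = c(0.1, 0.1, 0.5, 0.3))
  names(role) <- genes
  if (length(planted_down) > 0L) {
    role[planted_down] <- sample(c("catabolic", "anabolic"),
                                 length(planted_down), replace = TRUE,
                                 prob = c(0.9, 0.1))
  }
  tibble::tibble(gene_id = genes, role = unname(role))
}

#' Simulate survival outcomes linked to a per-patient score
#'
#' Event times are exponential with log-hazard linear in the standardized
#' score: `hazard = baseline_hazard * exp(log_hazard_per_score_sd * z)`.
#' Each subject is independently censored with probability `censoring_rate`;
#' censored subjects are observed at a uniform fraction of their latent event
#' time.
#'
#' @param scores Data frame with a `sample_id` column and a numeric `score`
#'   column (one row per tumor sample), or a named numeric vector.
#' @param config A [simulation_config()]; only the hazard fields are used.
#' @param seed Optional integer; when supplied the RNG is seeded locally so
#'   standalone calls are reproducible. Inside [generate_cohorts()] the
#'   surrounding seeded stream is used.
#'
#' @return Tibble with `sample_id`, `survival_time` (> 0), `event` (0/1).
#' @export
generate_survival <- function(scores, config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with simulation_config().")
  }
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble::tibble(sample_id = names(scores), score = unname(scores))
  }
  if (!is.data.frame(scores) || !all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` must have `sample_id` and `score` columns.")
  }
  if (nrow(scores) == 0L) abort("`scores` is empty; nothing to simulate.")
  if (!is.null(seed)) set.seed(seed)
  s <- scores$score
  z <- if (sd(s) > 0) as.numeric(scale(s)) else rep(0, length(s))
  hazard <- config$baseline_hazard * exp(config$log_hazard_per_score_sd * z)
  t_event <- rexp(length(z), rate = hazard)
  censored <- runif(length(z)) < config$censoring_rate
  obs_time <- ifelse(censored, runif(length(z)) * t_event, t_event)
  # guard against a zero observed time from underflow
  obs_time <- pmax(obs_time, .Machine$double.xmin)
  tibble::tibble(
    sample_id = scores$sample_id,
    survival_time = obs_time,
    event = as.integer(!censored)
  )
}

#' Ground-truth gene sets of a synthetic cohort
#'
#' Assembles the generator's planted structure as a gene-set table usable by
#' the scoring and signature stages: the planted down/up modules, the
#' regulator program, and the five overlapping metabolic process sets drawn
#' within the planted-down module.
#'
#' @param truth A `cohort_truth` object from [generate_cohorts()].
#' @return A gene-set tibble with columns `set_name`, `category`, `gene_id`
#'   (the long format used throughout the package; see [read_gmt()]).
#' @export
truth_gene_sets <- function(truth) {
  if (!inherits(truth, "cohort_truth")) {
    abort("`truth` must be the `truth` element of a cohort_sim.")
  }
  base <- dplyr::bind_rows(
    tibble::tibble(set_name = "planted_down_module",
                   category = "liver-cancer-down",
                   gene_id = truth$planted_down),
    tibble::tibble(set_name = "planted_up_module",
                   category = "liver-cancer-up",
                   gene_id = truth$planted_up),
    tibble::tibble(set_name = "regulator_program",
                   category = "activity-component",
                   gene_id = truth$regulator_set)
  )
  proc <- dplyr::mutate(truth$process_sets, category = "metabolic-pathway")
  dplyr::bind_rows(base, proc[c("set_name", "category", "gene_id")])
}

#' Ground-truth enzyme-role annotation of a synthetic cohort
#'
#' @param truth A `cohort_truth` object from [generate_cohorts()].
#' @return Tibble with `gene_id` and `role` in
#'   catabolic/anabolic/non-enzymatic/unknown.
#' @export
truth_roles <- function(truth) {
  if (!inherits(truth, "cohort_truth")) {
    abort("`truth` must be the `truth` element of a cohort_sim.")
  }
  truth$roles
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>\n")
  cat(sprintf("  %d dataset(s), %d genes, %d samples total\n",
              length(x$expression),
              nrow(x$expression[[1]]),
              nrow(x$clinical)))
  cat(sprintf("  planted: %d down, %d up; regulator set of %d\n",
              length(x$truth$planted_down), length(x$truth$planted_up),
              length(x$truth$regulator_set)))
  invisible(x)
}
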