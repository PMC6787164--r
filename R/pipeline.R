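#' Pipeline configuration
#'
#' Collects the inputs and constants of the end-to-end workflow. Defaults
#' mirror the analysis constants used throughout: significance cutoff 0.05
#' (Bonferroni-adjusted for the differential stage), directional top lists
#' of 1,000 genes, single-pair Z-difference threshold 1.96, and a median
#' low/high split.
#'
#' Inputs can be given as file paths (expression TSVs, clinical TSV, GMT
#' gene sets, enzyme-role TSV) or, when `expression_paths` is NULL, the
#' pipeline simulates a cohort from `sim` and derives gene sets and roles
#' from the simulation truth.
#'
#' @param expression_paths Character vector of expression TSV paths, or
#'   NULL to simulate.
#' @param clinical_path Clinical TSV path (ignored when simulating).
#' @param gmt_path GMT gene-set path (ignored when simulating).
#' @param roles_path Enzyme-role TSV path with columns `gene_id`, `role`
#'   (ignored when simulating).
#' @param sim A [simulation_config()] used when `expression_paths` is NULL.
#' @param alpha Significance cutoff (differential stage: on Bonferroni-
#'   adjusted p; enrichment sign rule and survival flags: raw p).
#' @param top_n Length of the directional top gene lists.
#' @param zdiff_threshold Single-pair Z-difference threshold.
#' @param split_rule Low/high grouping rule: "median" or "tertile".
#' @param signature_role Enzyme role kept in the primary signature.
#' @param seed Integer seed for any stage randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_paths = NULL,
                            clinical_path = NULL,
                            gmt_path = NULL,
                            roles_path = NULL,
                            sim = simulation_config(),
                            alpha = 0.05,
                            top_n = 1000,
                            zdiff_threshold = 1.96,
                            split_rule = c("median", "tertile"),
                            signature_role = "catabolic",
                            seed = 1L) {
  split_rule <- match.arg(split_rule)
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  if (top_n < 1) abort("`top_n` must be >= 1.")
  if (zdiff_threshold <= 0) abort("`zdiff_threshold` must be > 0.")
  structure(list(
    expression_paths = expression_paths,
    clinical_path = clinical_path,
    gmt_path = gmt_path,
    roles_path = roles_path,
    sim = sim,
    alpha = alpha,
    top_n = as.integer(top_n),
    zdiff_threshold = zdiff_threshold,
    split_rule = split_rule,
    signature_role = signature_role,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the end-to-end signature discovery and validation workflow
#'
#' Executes: simulate-or-load, per-dataset Z-score normalization, pooling,
#' pooled differential testing with Bonferroni control, directional top
#' lists, hypergeometric over-representation of the top downregulated list,
#' signature construction (pathway intersection + enzyme-role filter),
#' per-gene survival flagging of signature members, multi-process hit
#' selection, per-cohort patient scoring with the signed pathway-score
#' enrichment matrix (G0 = normal, G1 = tumor), score-based survival
#' stratification of tumor samples, clinical covariate comparisons, and the
#' regulator-score vs target-gene correlations. Every intermediate table is
#' written to `outdir` as TSV, together with a JSON manifest (config, seed,
#' package version, per-file MD5 checksums) and a stage log.
#'
#' Any stage failure aborts with the stage name attached, so partial output
#' directories identify the offending input.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; created if needed.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config().")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }
  written <- character()
  emit <- function(obj, file) {
    path <- file.path(outdir, file)
    if (is.data.frame(obj)) readr::write_tsv(obj, path, progress = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    written <<- c(written, path)
    path
  }

  # -- stage 1: inputs ------------------------------------------------------
  inputs <- stage("load_inputs", {
    if (is.null(config$expression_paths)) {
      sim_cfg <- config$sim
      sim <- generate_cohorts(sim_cfg)
      say("simulate: %d dataset(s), %d genes, %d samples",
          length(sim$expression), nrow(sim$expression[[1]]), nrow(sim$clinical))
      list(expression = sim$expression, clinical = sim$clinical,
           sets = truth_gene_sets(sim$truth), roles = truth_roles(sim$truth),
           truth = sim$truth)
    } else {
      for (p in c(config$expression_paths, config$clinical_path,
                  config$gmt_path, config$roles_path)) {
        if (!is.null(p) && !file.exists(p)) {
          abort(sprintf("Input file not found: %s", p))
        }
      }
      expr <- purrr::map(config$expression_paths, read_expression_tsv)
      names(expr) <- purrr::map_chr(expr, dataset_id_of)
      clin <- read_clinical_tsv(config$clinical_path)
      sets <- read_gmt(config$gmt_path)
      roles <- readr::read_tsv(config$roles_path, show_col_types = FALSE,
                               progress = FALSE)
      say("load: %d dataset(s), %d clinical rows, %d gene-set entries",
          length(expr), nrow(clin), nrow(sets))
      list(expression = expr, clinical = clin, sets = sets, roles = roles,
           truth = NULL)
    }
  })
  emit(inputs$clinical, "clinical.tsv")

  # -- stage 2: normalize + pool -------------------------------------------
  zlist <- stage("zscore_normalize", purrr::map(inputs$expression, zscore_normalize))
  pooled <- stage("pool_datasets", pool_datasets(zlist))
  say("pool: %d shared genes, %d samples", nrow(pooled), ncol(pooled) - 1L)

  # -- stage 3: meta differential expression -------------------------------
  de <- stage("differential_test", differential_test(pooled, inputs$clinical))
  emit(de, "differential.tsv")
  top_down <- top_n_genes(de, n = config$top_n, direction = "down",
                          alpha = config$alpha)
  top_up <- top_n_genes(de, n = config$top_n, direction = "up",
                        alpha = config$alpha)
  say("meta-DE: %d tested, %d top-down, %d top-up", nrow(de),
      length(top_down), length(top_up))
  emit(tibble::tibble(gene_id = top_down), "top_down.tsv")
  emit(tibble::tibble(gene_id = top_up), "top_up.tsv")

  # -- stage 4: over-representation ----------------------------------------
  ora <- stage("hypergeometric_enrichment", {
    universe <- de$gene_id
    hypergeometric_enrichment(intersect(top_down, universe), inputs$sets,
                              universe)
  })
  emit(ora, "ora_top_down.tsv")

  # -- stage 5: signature construction -------------------------------------
  pathway_sets <- if ("category" %in% names(inputs$sets)) {
    dplyr::filter(inputs$sets, .data$category == "metabolic-pathway")
  } else {
    inputs$sets
  }
  sig <- stage("build_signature", {
    if (nrow(pathway_sets) == 0L || length(top_down) == 0L) {
      abort("No pathway sets or no downregulated genes to intersect.")
    }
    candidates <- intersect_with_pathways(top_down, pathway_sets)
    say("signature: %d of %d top-down genes are in pathways",
        nrow(candidates), length(top_down))
    build_signature(candidates, inputs$roles, config$signature_role, "Cat-GS")
  })
  say("signature: %d genes after role filter (%s)", nrow(sig$genes),
      config$signature_role)
  subsigs <- stage("derive_sub_signatures",
                   derive_sub_signatures(sig, pathway_sets))

  # -- stage 6: survival flags + multi-process hits ------------------------
  has_surv <- any(!is.na(inputs$clinical$survival_time) &
                    !is.na(inputs$clinical$event))
  flags <- NULL
  hits <- NULL
  if (has_surv) {
    flags <- stage("flag_survival_genes",
                   flag_survival_genes(pooled, inputs$clinical,
                                       alpha = config$alpha,
                                       genes = signature_genes(sig)))
    sig$genes$survival_associated <-
      flags$flagged[match(sig$genes$gene_id, flags$gene_id)]
    emit(flags, "survival_flags.tsv")
    hits <- stage("select_multiprocess_genes",
                  select_multiprocess_genes(subsigs, min_processes = 3,
                                            survival_flags = setNames(flags$flagged, flags$gene_id)))
    emit(hits, "multiprocess_hits.tsv")
    say("survival flags: %d/%d signature genes associated; %d multi-process hits",
        sum(flags$flagged, na.rm = TRUE), nrow(flags), nrow(hits))
  }
  sig_flat <- tidy(sig)
  sig_flat$pathways <- purrr::map_chr(sig_flat$pathways, paste, collapse = ";")
  emit(sig_flat, "signature.tsv")
  sig_gmt <- tibble::tibble(set_name = sig$name, category = "signature",
                            gene_id = signature_genes(sig))
  write_gmt(sig_gmt, file.path(outdir, "signature.gmt"))
  written <- c(written, file.path(outdir, "signature.gmt"))

  # -- stage 7: scoring + enrichment matrix --------------------------------
  score_sets <- dplyr::bind_rows(inputs$sets, sig_gmt)
  cohorts <- stage("patient_scores", {
    purrr::imap(zlist, function(z, id) {
      sc <- suppressWarnings(patient_scores(z, score_sets))
      ids <- paste(dataset_id_of(z) %||% id, sc$sample_id, sep = ".")
      cond <- inputs$clinical$condition[match(ids, inputs$clinical$sample_id)]
      labels <- ifelse(cond == "normal", "G0",
                       ifelse(cond == "tumor", "G1", NA_character_))
      list(scores = sc, labels = labels)
    })
  })
  enrich <- stage("enrichment_matrix",
                  enrichment_matrix(cohorts, alpha = config$alpha))
  emit(enrich, "enrichment_matrix.tsv")

  pooled_scores <- stage("pooled_scores",
                         suppressWarnings(patient_scores(pooled, score_sets)))
  emit(pooled_scores, "patient_scores.tsv")

  # -- stage 8: clinical association of the signature score ----------------
  tumor_clin <- dplyr::filter(inputs$clinical, .data$condition == "tumor")
  sig_col <- sig$name
  tumor_scores <- pooled_scores[pooled_scores$sample_id %in% tumor_clin$sample_id, ]
  covars <- list()
  for (cv in intersect(c("stage", "grade", "prognosis", "vascular_invasion"),
                       names(inputs$clinical))) {
    if (sum(!is.na(tumor_clin[[cv]])) >= 4L && nrow(sig$genes) > 0L) {
      cmp <- tryCatch(
        compare_by_covariate(
          tibble::tibble(sample_id = tumor_scores$sample_id,
                         score = tumor_scores[[sig_col]]),
          inputs$clinical, cv),
        error = function(e) NULL)
      if (!is.null(cmp)) {
        covars[[cv]] <- cmp
        emit(tidy(cmp), sprintf("covariate_%s.tsv", cv))
      }
    }
  }

  surv_result <- NULL
  if (has_surv && nrow(sig$genes) > 0L) {
    surv_result <- stage("survival_stratification", {
      cl <- dplyr::filter(tumor_clin, !is.na(.data$survival_time),
                          !is.na(.data$event),
                          .data$sample_id %in% tumor_scores$sample_id)
      sc <- tumor_scores[match(cl$sample_id, tumor_scores$sample_id), ][[sig_col]]
      grp <- split_groups(sc, rule = config$split_rule)
      lr <- logrank_test(cl$survival_time, cl$event, grp)
      km <- list(G0 = km_estimate(cl$survival_time[grp == "G0"],
                                  cl$event[grp == "G0"]),
                 G1 = km_estimate(cl$survival_time[grp == "G1"],
                                  cl$event[grp == "G1"]))
      list(logrank = lr, km = km, groups = grp)
    })
    emit(glance(surv_result$logrank), "survival_logrank.tsv")
    say("survival: log-rank chi-square %.3f, p = %.3g",
        surv_result$logrank$chi_square, surv_result$logrank$p_value)
  }

  # -- stage 9: regulator correlations -------------------------------------
  correlations <- NULL
  if (!is.null(inputs$truth)) {
    correlations <- stage("correlate_regulator", {
      reg <- composite_score(pooled_scores, "regulator_program", "regulator")
      zm <- expr_to_matrix(pooled)
      tumor_ids <- intersect(tumor_clin$sample_id, reg$sample_id)
      purrr::map(inputs$truth$target_genes, function(g) {
        correlate(reg$regulator[match(tumor_ids, reg$sample_id)],
                  zm[g, tumor_ids])
      }) |>
        setNames(inputs$truth$target_genes) |>
        dplyr::bind_rows(.id = "target_gene")
    })
    emit(correlations, "regulator_correlations.tsv")
  }

  # -- manifest -------------------------------------------------------------
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  written <- c(written, file.path(outdir, "pipeline.log"))
  manifest <- list(
    package = "metasig",
    version = as.character(utils::packageVersion("metasig")),
    seed = config$seed,
    alpha = config$alpha,
    top_n = config$top_n,
    zdiff_threshold = config$zdiff_threshold,
    split_rule = config$split_rule,
    simulated = is.null(config$expression_paths),
    files = lapply(setNames(nm = basename(written)), function(f) {
      unname(tools::md5sum(file.path(outdir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    inputs = inputs, pooled = pooled, differential = de,
    top_down = top_down, top_up = top_up, ora = ora,
    signature = sig, sub_signatures = subsigs,
    survival_flags = flags, multiprocess_hits = hits,
    cohorts = cohorts, enrichment = enrich,
    pooled_scores = pooled_scores, covariates = covars,
    survival = surv_result, correlations = correlations,
    manifest = manifest, outdir = outdir
  ))
}
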