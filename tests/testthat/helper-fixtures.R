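# Shared fixture builders; everything is generated in code under fixed seeds.

# A small, fast cohort simulation for smoke/unit tests.
small_sim_config <- function(seed = 3, ...) {
  args <- list(
    n_datasets = 2, genes_per_dataset = 400, tumor_n = 15, normal_n = 15,
    planted_down_genes = 30, planted_up_genes = 20, regulator_set_size = 10,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Random expression tibble (genes x samples) with optional NAs.
rand_expr <- function(n_genes, n_samples, seed = 1, na_frac = 0,
                      dataset_id = "dX") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5, sd = 2),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (na_frac > 0) {
    idx <- sample(length(m), floor(na_frac * length(m)))
    m[idx] <- NA
  }
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1)
  attr(out, "dataset_id") <- dataset_id
  out
}

# Random right-censored survival data.
rand_surv <- function(n, seed = 1, cens = 0.3) {
  set.seed(seed)
  tibble::tibble(
    time = rexp(n, 0.1) + 1e-6,
    event = as.integer(runif(n) > cens),
    group = sample(c("G0", "G1"), n, replace = TRUE)
  )
}

# First time at which a KM curve drops to or below 0.5 (Inf if never).
km_median_time <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0) Inf else curve$time[min(idx)]
}
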