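#' Configuration of the synthetic GWAS enrichment study
#'
#' Defines a desk-scale generative mirror of the enrichment model: genes on
#' one chromosome with evenly spaced transcription start sites, a
#' genes x cell-types expression matrix, per-gene causal status drawn from
#' the logistic feature-level prior, a single causal variant per causal gene
#' placed with the exponential TSS-proximity prior, and summary statistics
#' observed with Gaussian noise (no linkage disequilibrium).
#'
#' @param n_genes Number of genes (>= 50).
#' @param variants_per_gene Variants placed uniformly in each gene's cis
#'   window (>= 1).
#' @param spacing Inter-TSS spacing in bp (default 1e6, so 1-Mb windows of
#'   adjacent genes are effectively disjoint).
#' @param window Cis-window width in bp (default 1e6).
#' @param gamma0,gamma_base,gamma_c True prior coefficients on the
#'   standardized baseline and focal-cell-type features.
#' @param prior_variance_true Variance of the causal effect size
#'   (default 0.04).
#' @param decay_rate_true Exponential TSS-proximity decay per bp used to
#'   place the causal variant (default 1e-5).
#' @param se Per-variant standard error: a single value (default 0.03, a
#'   typical large-GWAS log-OR scale) or a length-2 range sampled uniformly.
#' @param n_cell_types Number of cell types in the expression matrix.
#' @param focal_cell_type Index of the cell type whose feature drives
#'   causality (default 1).
#' @param seed Mandatory integer seed; all randomness is derived from it.
#' @return A list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(n_genes = 5000L, variants_per_gene = 10L,
                            spacing = 1e6, window = 1e6,
                            gamma0 = -2, gamma_base = 0, gamma_c = 1,
                            prior_variance_true = 0.04,
                            decay_rate_true = 1e-5,
                            se = 0.03, n_cell_types = 10L,
                            focal_cell_type = 1L, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` is required (no implicit randomness).")
  }
  if (n_genes < 50) abort("`n_genes` must be >= 50.")
  if (variants_per_gene < 1) abort("`variants_per_gene` must be >= 1.")
  check_scalar_positive(prior_variance_true, "prior_variance_true")
  check_scalar_positive(spacing, "spacing")
  check_scalar_positive(window, "window")
  if (decay_rate_true < 0) abort("`decay_rate_true` must be >= 0.")
  if (any(se <= 0) || !length(se) %in% 1:2) {
    abort("`se` must be a positive value or a length-2 positive range.")
  }
  if (n_cell_types < 2) abort("`n_cell_types` must be >= 2.")
  structure(as.list(environment()), class = "gwas_sim_config")
}

#' Simulate a GWAS enrichment study with known ground truth
#'
#' Draws, per [gwas_sim_config()]: (1) an expression matrix whose log1p
#' values are Gaussian, so the standardized features are approximately
#' standard normal across genes; (2) causal gene indicators
#' `c_g ~ Bernoulli(logistic(gamma0 + gamma_base x_base + gamma_c x_c))`
#' using exactly the features [build_features()] computes; (3) variant
#' positions uniform in each cis window, with one causal variant per causal
#' gene chosen with probability proportional to `exp(-lambda * distance)`
#' and effect `beta ~ N(0, W_true)`; (4) observed effects equal to the true
#' effect plus `N(0, se^2)` noise, independent across variants. Separate
#' random-number streams are used for expression, causal draws, variant
#' placement, effects, and noise, so the components can be varied
#' independently.
#'
#' @param cfg A [gwas_sim_config()].
#' @return A list with elements `sumstats` (tibble), `genes` (tibble),
#'   `expression` (matrix), and `truth` (tibble of per-gene causal status,
#'   true prior, features, causal variant and true effect).
#' @export
simulate_gwas_study <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  n_g <- as.integer(cfg$n_genes)
  n_v <- as.integer(cfg$variants_per_gene)
  n_ct <- as.integer(cfg$n_cell_types)
  half <- cfg$window / 2
  gene_id <- sprintf("gene%05d", seq_len(n_g))
  ct <- sprintf("ct%03d", seq_len(n_ct))

  # expression: log1p-scale values ~ N(4, 1), clipped at zero (negligible mass)
  set.seed(cfg$seed)
  f <- matrix(rnorm(n_g * n_ct, mean = 4, sd = 1), n_g, n_ct,
              dimnames = list(gene_id, ct))
  expression <- expm1(pmax(f, 0))

  features <- build_features(expression, ct[cfg$focal_cell_type])
  pi_g <- plogis(cfg$gamma0 + cfg$gamma_base * features$x_baseline +
                   cfg$gamma_c * features$x_celltype)

  set.seed(cfg$seed + 1L)
  causal <- rbinom(n_g, 1L, pi_g) == 1L

  # variant placement, uniform within each window; genes are laid out on
  # synthetic chromosomes of ~200 genes so positions stay within a realistic
  # (and 32-bit-safe) coordinate range
  set.seed(cfg$seed + 2L)
  genes_per_chrom <- 200L
  chrom <- as.character((seq_len(n_g) - 1L) %/% genes_per_chrom + 1L)
  rank_in_chrom <- (seq_len(n_g) - 1L) %% genes_per_chrom + 1L
  tss <- as.integer(cfg$spacing * rank_in_chrom + half)
  gene_of_variant <- rep(seq_len(n_g), each = n_v)
  offset <- sample.int(cfg$window + 1L, n_g * n_v, replace = TRUE) - 1L - half
  pos <- tss[gene_of_variant] + as.integer(offset)

  # causal variant + true effect per causal gene
  set.seed(cfg$seed + 3L)
  beta_true <- numeric(n_g * n_v)
  causal_variant <- rep(NA_integer_, n_g)
  w_idx <- which(causal)
  if (length(w_idx) > 0) {
    effects <- rnorm(length(w_idx), 0, sqrt(cfg$prior_variance_true))
    for (k in seq_along(w_idx)) {
      g <- w_idx[k]
      rows <- ((g - 1L) * n_v + 1L):(g * n_v)
      wt <- exp(-cfg$decay_rate_true * abs(pos[rows] - tss[g]))
      j <- if (n_v == 1L) rows else sample(rows, 1L, prob = wt)
      beta_true[j] <- effects[k]
      causal_variant[g] <- j
    }
  }

  # observation noise
  set.seed(cfg$seed + 4L)
  se_v <- if (length(cfg$se) == 2L) {
    runif(n_g * n_v, min(cfg$se), max(cfg$se))
  } else rep(cfg$se, n_g * n_v)
  beta_obs <- beta_true + rnorm(n_g * n_v, 0, se_v)

  variant_id <- sprintf("v%07d", seq_len(n_g * n_v))
  sumstats <- tibble(
    variant_id = variant_id, chrom = chrom[gene_of_variant],
    pos = as.integer(pos), beta = beta_obs, se = se_v
  )
  genes <- tibble(gene_id = gene_id, chrom = chrom, strand = "+", tss = tss)
  truth <- tibble(
    gene_id = gene_id,
    causal = causal,
    pi = pi_g,
    x_celltype = features$x_celltype,
    x_baseline = features$x_baseline,
    causal_variant = ifelse(is.na(causal_variant), NA_character_,
                            variant_id[causal_variant]),
    beta_true = ifelse(is.na(causal_variant), 0, beta_true[pmax(causal_variant, 1L)])
  )
  list(sumstats = sumstats, genes = genes, expression = expression,
       truth = truth)
}

#' Configuration of the synthetic composition study
#'
#' @param n_samples Number of samples.
#' @param n_cell_types Number of cell types.
#' @param factors Named integer vector of level counts per categorical
#'   factor (each >= 2).
#' @param sigma Named numeric vector (same names as `factors`) of true
#'   random-effect standard deviations, each >= 0.
#' @param sigma_sample True standard deviation of the per-sample random
#'   intercept (>= 0).
#' @param base_log_mean Baseline log mean count per cell type: a single
#'   value or one per cell type (default `log(100)`).
#' @param seed Mandatory integer seed.
#' @return A list of class `composition_sim_config`.
#' @export
composition_sim_config <- function(n_samples = 159L, n_cell_types = 9L,
                                   factors = c(disease = 2L, region = 3L),
                                   sigma = c(disease = 0.5, region = 0.3),
                                   sigma_sample = 0.3,
                                   base_log_mean = log(100), seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` is required (no implicit randomness).")
  }
  if (any(factors < 2)) abort("every factor needs >= 2 levels.")
  if (is.null(names(factors)) || any(names(factors) == "")) {
    abort("`factors` must be a named vector of level counts.")
  }
  if (!setequal(names(sigma), names(factors))) {
    abort("`sigma` must carry one value per named factor.")
  }
  if (any(sigma < 0) || sigma_sample < 0) abort("all sigma values must be >= 0.")
  if (!length(base_log_mean) %in% c(1L, n_cell_types)) {
    abort("`base_log_mean` must have length 1 or n_cell_types.")
  }
  structure(as.list(environment()), class = "composition_sim_config")
}

#' Simulate a cell-type composition study with known ground truth
#'
#' Assigns factor levels to samples in balanced random fashion, draws the
#' (level x cell type) random effects `u ~ N(0, sigma_f^2)` and per-sample
#' intercepts `a_s ~ N(0, sigma_sample^2)`, and generates counts
#' `y_st ~ Poisson(exp(base_t + a_s + sum_f u_f[l_f(s), t]))`.
#'
#' @param cfg A [composition_sim_config()].
#' @return A list with `counts` (integer matrix), `metadata` (tibble), and
#'   `truth` (list: tibble `u` of true random effects, `a` of sample
#'   intercepts, the true `sigma` values and the linear predictor matrix).
#' @export
simulate_composition <- function(cfg) {
  stopifnot(inherits(cfg, "composition_sim_config"))
  n_s <- as.integer(cfg$n_samples)
  n_t <- as.integer(cfg$n_cell_types)
  cell_types <- sprintf("ct%02d", seq_len(n_t))
  sample_id <- sprintf("sample%04d", seq_len(n_s))
  base <- rep(cfg$base_log_mean, length.out = n_t)

  set.seed(cfg$seed)
  metadata <- tibble(sample_id = sample_id)
  eta <- matrix(rep(base, each = n_s), n_s, n_t,
                dimnames = list(sample_id, cell_types))
  u_tabs <- list()
  for (f in names(cfg$factors)) {
    L <- cfg$factors[[f]]
    lev_names <- sprintf("%s%d", f, seq_len(L))
    assign_ <- sample(rep_len(seq_len(L), n_s))     # balanced random assignment
    metadata[[f]] <- lev_names[assign_]
    u <- matrix(rnorm(L * n_t, 0, cfg$sigma[[f]]), L, n_t,
                dimnames = list(lev_names, cell_types))
    eta <- eta + u[assign_, , drop = FALSE]
    u_tabs[[f]] <- tibble(
      factor = f,
      level = rep(lev_names, times = n_t),
      cell_type = rep(cell_types, each = L),
      u = as.vector(u)
    )
  }
  a <- rnorm(n_s, 0, cfg$sigma_sample)
  eta <- eta + a
  counts <- matrix(rpois(n_s * n_t, exp(as.vector(eta))), n_s, n_t,
                   dimnames = list(sample_id, cell_types))
  storage.mode(counts) <- "integer"

  list(
    counts = counts,
    metadata = metadata,
    truth = list(
      u = dplyr::bind_rows(u_tabs),
      a = tibble(sample_id = sample_id, a = a),
      sigma = cfg$sigma,
      sigma_sample = cfg$sigma_sample,
      eta = eta
    )
  )
}
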