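#' Wakefield approximate Bayes factor on the natural-log scale
#'
#' Converts a per-variant association estimate (log odds ratio and its
#' standard error) into the log of Wakefield's approximate Bayes factor,
#' oriented so that values above zero favour association over the null. The
#' effect-size prior is Gaussian, `N(0, prior_variance)`.
#'
#' The closed form is
#' \deqn{\ln \mathrm{ABF} = \tfrac12 \ln\frac{s^2}{s^2+W} +
#'   \frac{z^2}{2}\,\frac{W}{s^2+W}, \qquad z = \hat\beta / s,}
#' the Bayes factor comparing the marginal likelihood of the estimate under
#' the `N(0, W)` effect prior against the point-null model.
#'
#' @param beta Estimated effect (log odds ratio). Vectorised.
#' @param se Standard error of `beta`; must be positive. Vectorised.
#' @param prior_variance Variance `W` of the Gaussian effect prior
#'   (default 0.04, i.e. prior standard deviation 0.2 on the log-OR scale).
#' @return Numeric vector of log Bayes factors (natural log).
#' @examples
#' wakefield_lnabf(beta = 0.3, se = 0.1)
#' @export
wakefield_lnabf <- function(beta, se, prior_variance = 0.04) {
  check_scalar_positive(prior_variance, "prior_variance")
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be positive and finite.")
  if (any(!is.finite(beta))) abort("`beta` must be finite.")
  v <- se^2
  z2 <- (beta / se)^2
  shrink <- prior_variance / (v + prior_variance)
  0.5 * log(v / (v + prior_variance)) + 0.5 * z2 * shrink
}

#' Maximum-likelihood exponential decay rate from a distance distribution
#'
#' Fits the rate of an exponential distribution to a sample of positive
#' regulatory-interaction distances (in base pairs). Used to set the
#' TSS-proximity prior weight `exp(-lambda * distance)` from empirical
#' enhancer-promoter distance data.
#'
#' @param distances Numeric vector of positive distances in bp.
#' @return The MLE rate, `1 / mean(distances)`, in units of 1/bp.
#' @examples
#' estimate_decay_rate(c(5e4, 1e5, 1.5e5))
#' @export
estimate_decay_rate <- function(distances) {
  if (length(distances) == 0) abort("`distances` must be a nonempty vector.")
  if (any(!is.finite(distances) | distances <= 0)) {
    abort("`distances` must all be positive and finite.")
  }
  1 / mean(distances)
}

#' Pair GWAS variants with genes whose cis window contains them
#'
#' Emits one row per (gene, variant) pair where the variant lies within the
#' cis window centred on the gene's transcription start site (inclusive at
#' both edges). A variant falling inside two overlapping windows is paired
#' with both genes. Chromosome names are matched after stripping any leading
#' `"chr"` prefix. Each pair carries the variant's log approximate Bayes
#' factor and the log of its unnormalised TSS-proximity prior weight,
#' `-decay_rate * distance`.
#'
#' @param stats Data frame of summary statistics with columns `variant_id`,
#'   `chrom`, `pos`, `beta`, `se` (extra columns ignored).
#' @param genes Data frame of gene annotation with columns `gene_id`,
#'   `chrom`, `tss` (an optional `strand` column is ignored here; strand is
#'   resolved when the TSS is derived from a GTF).
#' @param window Total cis-window width in bp (even, default 1e6); the window
#'   is `tss +/- window/2`.
#' @param decay_rate Exponential decay per bp of the proximity prior
#'   (default 1e-5, a mean regulatory distance of 100 kb); see
#'   [estimate_decay_rate()].
#' @param prior_variance Wakefield effect-prior variance passed to
#'   [wakefield_lnabf()].
#' @return A tibble with columns `gene_id`, `variant_id`, `distance`,
#'   `ln_abf`, `ln_weight`.
#' @export
map_variants_to_genes <- function(stats, genes, window = 1e6,
                                  decay_rate = 1e-5, prior_variance = 0.04) {
  validate_sumstats(stats)
  validate_gene_annotation(genes)
  check_scalar_positive(window, "window")
  if (window %% 2 != 0) abort("`window` must be an even number of base pairs.")
  if (!is.numeric(decay_rate) || length(decay_rate) != 1L || decay_rate < 0) {
    abort("`decay_rate` must be a single number >= 0.")
  }

  empty <- tibble(gene_id = character(), variant_id = character(),
                  distance = numeric(), ln_abf = numeric(), ln_weight = numeric())
  if (nrow(stats) == 0) {
    warn("empty variant table; no variant-gene pairs produced.")
    return(empty)
  }
  if (nrow(genes) == 0) return(empty)

  half <- window / 2
  stats_chrom <- normalize_chrom(stats$chrom)
  genes_chrom <- normalize_chrom(genes$chrom)
  unmatched <- setdiff(unique(stats_chrom), unique(genes_chrom))
  if (length(unmatched) > 0) {
    n_drop <- sum(stats_chrom %in% unmatched)
    inform(sprintf(
      "%d variant(s) on %d chromosome(s) absent from the gene annotation were not paired.",
      n_drop, length(unmatched)))
  }

  pieces <- lapply(intersect(unique(stats_chrom), unique(genes_chrom)), function(ch) {
    vi <- which(stats_chrom == ch)
    gi <- which(genes_chrom == ch)
    ord <- order(genes$tss[gi])
    gi <- gi[ord]
    tss <- genes$tss[gi]
    pos <- stats$pos[vi]
    # inclusive window: tss in [pos - half, pos + half]; integer coordinates
    lo <- findInterval(pos - half - 0.5, tss) + 1L
    hi <- findInterval(pos + half + 0.5, tss)
    n_hit <- hi - lo + 1L
    keep <- n_hit > 0L
    if (!any(keep)) return(NULL)
    vrep <- rep(vi[keep], n_hit[keep])
    grep_ <- gi[sequence(n_hit[keep], from = lo[keep])]
    tibble(
      gene_id = genes$gene_id[grep_],
      variant_id = stats$variant_id[vrep],
      distance = abs(stats$pos[vrep] - genes$tss[grep_]),
      ln_abf = wakefield_lnabf(stats$beta[vrep], stats$se[vrep], prior_variance),
      ln_weight = -decay_rate * abs(stats$pos[vrep] - genes$tss[grep_])
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) empty else out
}

#' Gene-level regional Bayes factors by prior-weighted averaging
#'
#' Aggregates per-variant approximate Bayes factors within each gene's cis
#' window into a single regional Bayes factor: the average of the variant
#' Bayes factors weighted by the TSS-proximity prior,
#' \deqn{\mathrm{RBF}_g = \frac{\sum_j w_j\,\mathrm{ABF}_j}{\sum_j w_j},
#'   \qquad w_j = e^{-\lambda d_j}.}
#' Under a single-causal-variant assumption this is the Bayes factor for
#' "some variant in the region is associated". Computation is in log space
#' via log-sum-exp, so variant log Bayes factors of several hundred do not
#' overflow.
#'
#' @param pairs Tibble of variant-gene pairs from [map_variants_to_genes()]
#'   (columns `gene_id`, `ln_abf`, `ln_weight`).
#' @return A tibble with one row per gene: `gene_id`, `ln_rbf`, `n_variants`.
#' @export
regional_bf <- function(pairs) {
  required <- c("gene_id", "ln_abf", "ln_weight")
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0) {
    abort(sprintf("`pairs` is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(pairs) == 0) {
    return(tibble(gene_id = character(), ln_rbf = numeric(), n_variants = integer()))
  }
  pairs |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      ln_rbf = logsumexp(.data$ln_weight + .data$ln_abf) - logsumexp(.data$ln_weight),
      n_variants = dplyr::n(),
      .groups = "drop"
    )
}
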