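#' Per-gene log marginal likelihood of the hierarchical enrichment model
#'
#' For a gene with regional Bayes factor `RBF` and prior probability `pi` of
#' harbouring a causal association, the marginal likelihood (relative to the
#' all-null model) is `(1 - pi) + pi * RBF`. This function returns its log,
#' computed as a log-add-exp of `log(1 - pi)` and `log(pi) + ln_rbf` so that
#' very large regional Bayes factors do not overflow. Summing across genes
#' gives the model log likelihood that the enrichment fit maximizes.
#'
#' @param ln_rbf Per-gene log regional Bayes factor (natural log).
#' @param pi Per-gene prior probability in `[0, 1]`; recycled against
#'   `ln_rbf`.
#' @return Numeric vector of per-gene log marginal likelihoods.
#' @export
gene_marginal_loglik <- function(ln_rbf, pi) {
  if (any(!is.finite(ln_rbf))) abort("`ln_rbf` must be finite.")
  if (any(pi < 0 | pi > 1 | is.na(pi))) abort("`pi` must lie in [0, 1].")
  logaddexp(log1p(-pi), log(pi) + ln_rbf)
}

# Internal: negative log likelihood, gradient, and Hessian of the
# three-parameter prior model on linked scale. eta = X gamma; pi = logistic(eta);
# per-gene loglik l = log((1-pi) + pi e^r). Writing t = logistic(eta + r)
# (the posterior probability the gene is causal), dl/deta = t - pi and
# d2l/deta2 = t(1-t) - pi(1-pi), all numerically stable.
enrich_nll <- function(gamma, X, r) {
  eta <- drop(X %*% gamma)
  -sum(logaddexp(plogis(eta, lower.tail = FALSE, log.p = TRUE),
                 plogis(eta, log.p = TRUE) + r))
}

enrich_nll_grad <- function(gamma, X, r) {
  eta <- drop(X %*% gamma)
  -drop(crossprod(X, plogis(eta + r) - plogis(eta)))
}

enrich_nll_hess <- function(gamma, X, r) {
  eta <- drop(X %*% gamma)
  t_ <- plogis(eta + r)
  p_ <- plogis(eta)
  w <- p_ * (1 - p_) - t_ * (1 - t_)   # = -d2l/deta2
  crossprod(X * w, X)
}

#' Configuration of the enrichment maximum-likelihood fit
#'
#' @param max_iter Maximum quasi-Newton iterations per start (default 500).
#' @param grad_tol Convergence tolerance on the gradient infinity norm after
#'   Newton polishing (default 1e-8, relative to `max(1, |loglik|)`).
#' @param starts Matrix of starting values, one row per start, columns
#'   `(gamma0, gamma_base, gamma_c)`. The defaults start from sparse and
#'   moderately sparse prior means with and without a seeded enrichment
#'   effect; the best log likelihood wins, ties broken by the first start.
#' @return A list of class `enrich_config`.
#' @export
enrich_config <- function(max_iter = 500L, grad_tol = 1e-8,
                          starts = NULL) {
  if (is.null(starts)) {
    starts <- rbind(
      c(qlogis(0.01), 0, 0),
      c(qlogis(0.05), 0, 0),
      c(qlogis(0.01), 0, 0.5),
      c(qlogis(0.01), 0, -0.5)
    )
  }
  structure(list(max_iter = max_iter, grad_tol = grad_tol, starts = starts),
            class = "enrich_config")
}

#' Fit the enrichment model for one cell type
#'
#' Maximizes the hierarchical model log likelihood
#' `sum_g log((1 - pi_g) + pi_g * RBF_g)` over the prior coefficients
#' `(gamma0, gamma_base, gamma_c)`, where
#' `pi_g = logistic(gamma0 + gamma_base * x_baseline + gamma_c * x_celltype)`.
#' `gamma_c` is the cell type's enrichment coefficient. Optimization is
#' quasi-Newton (BFGS with analytic gradient) from multiple starts, followed
#' by Newton polishing with the analytic Hessian; standard errors come from
#' the inverse observed information at the MLE.
#'
#' If all regional Bayes factors are equal the likelihood carries no
#' information about the prior and the fit is flagged `degenerate` (as it is
#' when the focal feature column was constant); `gamma_c` is then reported
#' as 0 with an infinite standard error.
#'
#' @param gene_bfs Tibble from [regional_bf()] (`gene_id`, `ln_rbf`, ...).
#' @param features Tibble from [build_features()].
#' @param config An [enrich_config()].
#' @return An object of class `enrich_fit`: coefficients, standard errors,
#'   the variance-covariance matrix, log likelihood at the MLE, Wald `z` and
#'   two-sided `p` for `gamma_c`, and `converged` / `degenerate` flags.
#'   Use [tidy()] and [glance()] to extract tables.
#' @export
fit_enrichment <- function(gene_bfs, features, config = enrich_config()) {
  joined <- dplyr::inner_join(
    gene_bfs[c("gene_id", "ln_rbf")],
    features[c("gene_id", "x_celltype", "x_baseline")],
    by = "gene_id"
  )
  if (nrow(joined) < 50) {
    abort(sprintf(
      "only %d genes shared between Bayes factors and features; >= 50 required for an identifiable fit.",
      nrow(joined)))
  }
  if (any(!is.finite(joined$ln_rbf))) abort("`ln_rbf` must be finite for all genes.")

  r <- joined$ln_rbf
  X <- cbind(intercept = 1, x_baseline = joined$x_baseline,
             x_celltype = joined$x_celltype)
  focal <- attr(features, "focal_cell_type") %||% NA_character_

  make_fit <- function(coef, vcov, se, loglik, converged, degenerate) {
    structure(list(
      cell_type = focal, coef = coef, se = se, vcov = vcov,
      loglik = loglik, n_genes = nrow(joined),
      converged = converged, degenerate = degenerate
    ), class = "enrich_fit")
  }
  cname <- c("gamma0", "gamma_base", "gamma_c")

  degenerate_features <- isTRUE(attr(features, "degenerate")) ||
    sd(joined$x_celltype) == 0
  if (sd(r) == 0 || degenerate_features) {
    coef <- setNames(c(qlogis(0.01), 0, 0), cname)
    if (sd(r) == 0) coef[] <- 0
    return(make_fit(coef, vcov = NULL,
                    se = setNames(c(Inf, Inf, Inf), cname),
                    loglik = -enrich_nll(coef, X, r),
                    converged = TRUE, degenerate = TRUE))
  }

  best <- NULL
  for (i in seq_len(nrow(config$starts))) {
    opt <- tryCatch(
      optim(config$starts[i, ], fn = enrich_nll, gr = enrich_nll_grad,
            X = X, r = r, method = "BFGS",
            control = list(maxit = config$max_iter, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) {
    return(make_fit(setNames(rep(NA_real_, 3), cname), NULL,
                    setNames(rep(NA_real_, 3), cname), NA_real_,
                    converged = FALSE, degenerate = FALSE))
  }

  # Newton polish to drive the gradient norm to tolerance
  gamma <- best$par
  for (k in 1:25) {
    g <- enrich_nll_grad(gamma, X, r)
    if (max(abs(g)) < config$grad_tol * max(1, abs(best$value))) break
    H <- enrich_nll_hess(gamma, X, r)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- gamma - step
    if (enrich_nll(cand, X, r) <= enrich_nll(gamma, X, r)) gamma <- cand else break
  }
  nll_hat <- enrich_nll(gamma, X, r)
  gnorm <- max(abs(enrich_nll_grad(gamma, X, r)))
  info <- enrich_nll_hess(gamma, X, r)  # observed information (of nll)
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch)) {
    vc <- NULL
    se <- setNames(rep(NA_real_, 3), cname)
    converged <- FALSE
  } else {
    vc <- chol2inv(ch)
    dimnames(vc) <- list(cname, cname)
    se <- setNames(sqrt(diag(vc)), cname)
    converged <- gnorm < config$grad_tol * max(1, abs(nll_hat))
  }
  make_fit(setNames(gamma, cname), vc, se, -nll_hat,
           converged = converged, degenerate = FALSE)
}

#' @export
print.enrich_fit <- function(x, ...) {
  cat("Hierarchical enrichment fit",
      if (!is.na(x$cell_type)) sprintf("for cell type '%s'", x$cell_type), "\n")
  cat(sprintf("  genes: %d   loglik: %.4f   converged: %s   degenerate: %s\n",
              x$n_genes, x$loglik, x$converged, x$degenerate))
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

#' @rdname fit_enrichment
#' @param x An `enrich_fit` object.
#' @param ... Unused.
#' @method tidy enrich_fit
#' @export
tidy.enrich_fit <- function(x, ...) {
  est <- x$coef
  se <- x$se
  z <- est / se
  tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname fit_enrichment
#' @method glance enrich_fit
#' @export
glance.enrich_fit <- function(x, ...) {
  tibble(cell_type = x$cell_type, logLik = x$loglik, n_genes = x$n_genes,
         converged = x$converged, degenerate = x$degenerate)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; the
#' adjusted value of a test is the smallest FDR level at which it would be
#' called.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("`pvalues` must all lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Score every cell type for enrichment of disease-associated genes
#'
#' Runs [build_features()] and [fit_enrichment()] once per cell type (each
#' fit uses the focal cell type's standardized expression plus the shared
#' baseline), then adjusts the two-sided Wald p-values across cell types by
#' Benjamini-Hochberg and flags cell types below the FDR level.
#'
#' @param gene_bfs Tibble from [regional_bf()].
#' @param expr Genes x cell-types expression matrix (>= 2 cell types).
#' @param fdr_level FDR threshold for the `significant` flag (default 0.10).
#' @param config An [enrich_config()].
#' @return A tibble of class `enrich_result`, one row per cell type, ordered
#'   by `z` descending: `cell_type`, `gamma0`, `gamma_base`, `gamma_c`,
#'   `se`, `z`, `p`, `q`, `significant`, `converged`, `degenerate`. A fit
#'   that fails outright is recorded with `converged = FALSE`, not fatal.
#' @export
enrich_all <- function(gene_bfs, expr, fdr_level = 0.10,
                       config = enrich_config()) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 2) abort("`expr` must contain at least 2 cell types.")
  if (fdr_level <= 0 || fdr_level > 1) abort("`fdr_level` must lie in (0, 1].")

  rows <- purrr::map(colnames(expr), function(ct) {
    fit <- tryCatch(
      fit_enrichment(gene_bfs, build_features(expr, ct), config),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble(cell_type = ct, gamma0 = NA_real_, gamma_base = NA_real_,
                    gamma_c = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, converged = FALSE, degenerate = FALSE))
    }
    z <- unname(fit$coef["gamma_c"] / fit$se["gamma_c"])
    if (fit$degenerate) z <- NA_real_
    tibble(
      cell_type = ct,
      gamma0 = unname(fit$coef["gamma0"]),
      gamma_base = unname(fit$coef["gamma_base"]),
      gamma_c = unname(fit$coef["gamma_c"]),
      se = unname(fit$se["gamma_c"]),
      z = z,
      p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
      converged = fit$converged,
      degenerate = fit$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])
  out$significant <- !is.na(out$q) & out$q <= fdr_level
  out <- dplyr::arrange(out, dplyr::desc(.data$z))
  out <- out[c("cell_type", "gamma0", "gamma_base", "gamma_c", "se", "z",
               "p", "q", "significant", "converged", "degenerate")]
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("enrich_result", class(out))
  out
}
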