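#' Build the long-format design for the composition GLMM
#'
#' Flattens a samples x cell-types count matrix into one row per
#' (sample, cell type), joins per-sample metadata, and constructs the model
#' structure: a global intercept with cell-type fixed effects
#' (reference-level constraint), an optional per-sample random intercept
#' that absorbs per-sample totals, and, for each clinical or technical
#' factor, one random-effect block with one coefficient per
#' (factor level x cell type) pair — the interaction through which a
#' factor's effect on composition is estimated.
#'
#' @param counts Integer matrix (or data frame with sample identifiers in
#'   the first column), samples in rows, cell types in columns, values >= 0.
#' @param metadata Data frame with a `sample_id` column and one column per
#'   categorical factor; every sample in `counts` must appear with complete
#'   metadata.
#' @param factors Character vector of metadata columns to model as random
#'   effects; defaults to all non-`sample_id` columns.
#' @param sample_intercept Include a per-sample random intercept
#'   (default TRUE).
#' @return A list of class `composition_design`: the long `data` tibble, the
#'   model `formula`, and index maps (`blocks`, `cell_types`, ...) for
#'   decoding fitted coefficients.
#' @export
build_design <- function(counts, metadata, factors = NULL,
                         sample_intercept = TRUE) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1L]])
    counts <- as.matrix(counts[-1L])
    rownames(counts) <- ids
  }
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be a matrix of nonnegative integers.")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (all(counts == 0)) abort("`counts` is all zero; nothing to model.")
  if (!"sample_id" %in% names(metadata)) abort("`metadata` must contain a sample_id column.")
  if (is.null(factors)) factors <- setdiff(names(metadata), "sample_id")

  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) {
    abort(sprintf("metadata missing for sample(s): %s",
                  paste(utils::head(setdiff(rownames(counts), metadata$sample_id), 5),
                        collapse = ", ")))
  }
  missing_fac <- setdiff(factors, names(metadata))
  if (length(missing_fac) > 0) {
    abort(sprintf("factor(s) not in metadata: %s", paste(missing_fac, collapse = ", ")))
  }

  n_s <- nrow(counts); n_t <- ncol(counts)
  cell_types <- colnames(counts) %||% paste0("ct", seq_len(n_t))
  long <- tibble(
    sample_id = factor(rep(rownames(counts), times = n_t), levels = rownames(counts)),
    cell_type = factor(rep(cell_types, each = n_s), levels = cell_types),
    count = as.integer(as.vector(counts))
  )

  blocks <- list()
  for (i in seq_along(factors)) {
    f <- factors[i]
    lev <- md[[f]]
    if (any(is.na(lev))) abort(sprintf("metadata factor '%s' has missing values.", f))
    lev <- as.character(lev)
    ulev <- sort(unique(lev))
    if (length(ulev) < 2) {
      abort(sprintf("factor '%s' has a single level; >= 2 required.", f))
    }
    col <- paste0(".re_", i)
    long[[f]] <- factor(rep(lev, times = n_t), levels = ulev)
    long[[col]] <- factor(paste(rep(lev, times = n_t),
                                as.character(long$cell_type), sep = "||"))
    blocks[[f]] <- list(column = col, levels = ulev,
                        n_cols = length(ulev) * n_t)
  }

  re_terms <- c(
    if (sample_intercept) "(1 | sample_id)",
    vapply(blocks, function(b) sprintf("(1 | %s)", b$column), character(1))
  )
  rhs <- paste(c("cell_type", re_terms), collapse = " + ")
  formula <- as.formula(paste("count ~", rhs))

  structure(list(
    data = long, formula = formula, factors = factors, blocks = blocks,
    sample_intercept = sample_intercept, n_samples = n_s,
    n_cell_types = n_t, cell_types = cell_types
  ), class = "composition_design")
}

#' Fit the Poisson GLMM of cell-type composition
#'
#' Fits, by the Laplace approximation, the mixed model
#' `log E(y_st) = mu + b_t + a_s + sum_f u^(f)[l_f(s), t]` with independent
#' Gaussian random effects `u^(f) ~ N(0, sigma_f^2)` per factor and
#' `a_s ~ N(0, sigma_sample^2)`, and Poisson-distributed counts. Returns
#' per-factor random-effect standard deviations, per-coefficient posterior
#' means and standard deviations (conditional modes and curvature of the
#' penalized likelihood at the mode), and the local true sign rate of each
#' effect. With no random terms the model reduces to a fixed-effects Poisson
#' regression.
#'
#' @param design A `composition_design` from [build_design()].
#' @param max_iter Maximum optimizer evaluations for the outer variance
#'   fit (default 100000).
#' @return An object of class `composition_fit` with elements `varcomp`
#'   (factor, sigma, se_sigma), `effects` (factor, level, cell_type,
#'   post_mean, post_sd, ltsr), `fixef`, `loglik` (Laplace marginal log
#'   likelihood), `converged`, and the underlying `model`. Use [tidy()],
#'   [glance()] and [variance_components()] to extract tables.
#' @export
fit_poisson_glmm <- function(design, max_iter = 100000L) {
  stopifnot(inherits(design, "composition_design"))
  data <- design$data
  has_re <- design$sample_intercept || length(design$blocks) > 0

  if (!has_re) {
    model <- glm(count ~ cell_type, family = poisson(), data = data)
    out <- structure(list(
      model = model, design = design,
      varcomp = tibble(factor = character(), sigma = numeric(), se_sigma = numeric()),
      effects = tibble(factor = character(), level = character(),
                       cell_type = character(), post_mean = numeric(),
                       post_sd = numeric(), ltsr = numeric()),
      sample_effects = NULL,
      fixef = stats::coef(model),
      loglik = as.numeric(logLik(model)),
      converged = model$converged
    ), class = "composition_fit")
    return(out)
  }

  model <- lme4::glmer(design$formula, data = data, family = poisson(),
                       nAGQ = 1L,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa",
                         optCtrl = list(maxfun = max_iter),
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
  converged <- model@optinfo$conv$opt == 0 &&
    length(model@optinfo$conv$lme4$messages %||% character(0)) == 0

  vc <- lme4::VarCorr(model)
  sigma_of <- function(col) unname(attr(vc[[col]], "stddev"))
  varcomp <- tibble(
    factor = names(design$blocks),
    sigma = vapply(design$blocks, function(b) sigma_of(b$column), numeric(1)),
    se_sigma = NA_real_
  )

  re <- lme4::ranef(model, condVar = TRUE)
  effects <- purrr::imap(design$blocks, function(b, fname) {
    df <- re[[b$column]]
    pv <- attr(df, "postVar")
    labels <- rownames(df)
    parts <- strsplit(labels, "||", fixed = TRUE)
    m <- df[["(Intercept)"]]
    s <- sqrt(pmax(as.vector(pv), 0))
    sig <- sigma_of(b$column)
    if (sig < 1e-8) { m <- rep(0, length(m)); s <- rep(0, length(s)) }
    ltsr <- ifelse(s > 0, pnorm(abs(m) / s), 0.5)
    tibble(
      factor = fname,
      level = vapply(parts, `[`, character(1), 1L),
      cell_type = vapply(parts, `[`, character(1), 2L),
      post_mean = m, post_sd = s, ltsr = ltsr
    )
  }) |> dplyr::bind_rows()

  sample_effects <- NULL
  sigma_sample <- NA_real_
  if (design$sample_intercept) {
    df <- re[["sample_id"]]
    sigma_sample <- sigma_of("sample_id")
    sample_effects <- tibble(
      sample_id = rownames(df),
      post_mean = df[["(Intercept)"]],
      post_sd = sqrt(pmax(as.vector(attr(df, "postVar")), 0))
    )
  }

  structure(list(
    model = model, design = design, varcomp = varcomp, effects = effects,
    sample_effects = sample_effects, sigma_sample = sigma_sample,
    fixef = lme4::fixef(model), loglik = as.numeric(logLik(model)),
    converged = converged
  ), class = "composition_fit")
}

# Central finite-difference Hessian with fixed step.
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  shift <- function(i, d) { y <- x; y[i] <- y[i] + d; y }
  for (i in seq_len(p)) {
    H[i, i] <- (f(shift(i, h)) - 2 * f0 + f(shift(i, -h))) / h^2
    if (i < p) for (j in (i + 1):p) {
      xpp <- shift(i, h); xpp[j] <- xpp[j] + h
      xpm <- shift(i, h); xpm[j] <- xpm[j] - h
      xmp <- shift(i, -h); xmp[j] <- xmp[j] + h
      xmm <- shift(i, -h); xmm[j] <- xmm[j] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}

#' Standard errors of the random-effect standard deviations
#'
#' Differentiates the Laplace marginal log likelihood numerically (central
#' finite differences, step 1e-4) with respect to the log standard
#' deviations and the fixed effects jointly, inverts the observed
#' information, and maps the log-scale standard errors back to the standard
#' deviation scale by the delta method. A variance component estimated at
#' the zero boundary, or a non-positive-definite information matrix, yields
#' a missing standard error with a warning.
#'
#' @param fit A converged `composition_fit` from [fit_poisson_glmm()].
#' @return The `varcomp` tibble (`factor`, `sigma`, `se_sigma`) with
#'   standard errors filled in.
#' @export
sd_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "composition_fit"))
  if (!fit$converged) abort("standard errors require a converged fit.")
  if (!inherits(fit$model, "glmerMod")) return(fit$varcomp)

  model <- fit$model
  design <- fit$design
  devf <- lme4::glmer(design$formula, data = design$data, family = poisson(),
                      nAGQ = 1L, devFunOnly = TRUE)
  th <- lme4::getME(model, "theta")
  be <- lme4::fixef(model)
  active <- which(th > 1e-4)
  k <- length(active)
  varcomp <- fit$varcomp
  # map varcomp rows to theta entries via the grouping-column names
  theta_cols <- sub("\\.\\(Intercept\\)$", "", names(th))
  vc_idx <- match(vapply(design$blocks, function(b) b$column, character(1)), theta_cols)

  if (k == 0) {
    warn("all variance components at the boundary; no standard errors available.")
    return(varcomp)
  }
  ll <- function(p) {
    thfull <- th
    thfull[active] <- exp(p[seq_len(k)])
    -0.5 * devf(c(thfull, p[-seq_len(k)]))
  }
  p0 <- c(log(th[active]), be)
  H <- fd_hessian(ll, p0, h = 1e-4)
  ch <- tryCatch(chol(-H), error = function(e) NULL)
  if (is.null(ch)) {
    warn("observed information not positive definite; standard errors reported as missing.")
    return(varcomp)
  }
  covm <- chol2inv(ch)
  se_ln <- sqrt(diag(covm))[seq_len(k)]
  se_theta <- setNames(rep(NA_real_, length(th)), names(th))
  se_theta[active] <- th[active] * se_ln   # delta method: d sigma = sigma d ln(sigma)
  varcomp$se_sigma <- unname(se_theta[vc_idx])
  if (any(th[vc_idx] <= 1e-4)) {
    warn("variance component(s) at the zero boundary; their standard errors are missing.")
  }
  varcomp
}

#' Local true sign rate of a Gaussian posterior
#'
#' The posterior probability that an effect has the same sign as its
#' posterior mean, `Phi(|m| / s)` for a Gaussian posterior with mean `m`
#' and standard deviation `s`. Ranges from 0.5 (signless) to 1.
#'
#' @param post_mean Posterior mean(s).
#' @param post_sd Posterior standard deviation(s), > 0.
#' @return Numeric vector of LTSR values in `[0.5, 1]`.
#' @examples
#' compute_ltsr(1, 0.5)   # Phi(2)
#' @export
compute_ltsr <- function(post_mean, post_sd) {
  if (any(!is.finite(post_sd) | post_sd <= 0)) abort("`post_sd` must be > 0.")
  pnorm(abs(post_mean) / post_sd)
}

#' Fit the composition model from counts and metadata
#'
#' One-call wrapper: builds the design with [build_design()], fits the
#' Poisson GLMM with [fit_poisson_glmm()], and (optionally) fills in the
#' standard errors of the variance components with [sd_standard_errors()].
#'
#' @inheritParams build_design
#' @param se Compute standard errors of the random-effect standard
#'   deviations (default TRUE; the numerical Hessian is the slow step).
#' @param ... Passed to [fit_poisson_glmm()].
#' @return A `composition_fit`.
#' @export
fit_composition <- function(counts, metadata, factors = NULL,
                            sample_intercept = TRUE, se = TRUE, ...) {
  design <- build_design(counts, metadata, factors, sample_intercept)
  fit <- fit_poisson_glmm(design, ...)
  if (se && fit$converged && inherits(fit$model, "glmerMod")) {
    fit$varcomp <- sd_standard_errors(fit)
  }
  fit
}

#' @export
print.composition_fit <- function(x, ...) {
  cat("Poisson GLMM of cell-type composition\n")
  cat(sprintf("  %d samples x %d cell types; Laplace loglik %.3f; converged: %s\n",
              x$design$n_samples, x$design$n_cell_types, x$loglik, x$converged))
  cat("Variance components:\n")
  print(as.data.frame(x$varcomp), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_poisson_glmm
#' @param x A `composition_fit`.
#' @param effects Which table [tidy()] returns: per-coefficient random
#'   effects (default), the variance components, or the fixed effects.
#' @param ... Unused.
#' @method tidy composition_fit
#' @export
tidy.composition_fit <- function(x, effects = c("random", "variance", "fixed"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    random = x$effects,
    variance = x$varcomp,
    fixed = tibble(term = names(x$fixef), estimate = unname(x$fixef))
  )
}

#' @rdname fit_poisson_glmm
#' @method glance composition_fit
#' @export
glance.composition_fit <- function(x, ...) {
  tibble(
    n_samples = x$design$n_samples, n_cell_types = x$design$n_cell_types,
    n_factors = length(x$design$blocks), logLik = x$loglik,
    sigma_sample = x$sigma_sample %||% NA_real_, converged = x$converged
  )
}

#' @rdname fit_poisson_glmm
#' @param fit A `composition_fit`.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "composition_fit"))
  fit$varcomp
}
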