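test_that("the long design has one row per sample-by-cell-type combination", {
  sim <- simulate_composition(composition_sim_config(
    n_samples = 159, n_cell_types = 9, seed = 21))
  d <- build_design(sim$counts, sim$metadata)
  expect_equal(nrow(d$data), 159 * 9)
  # one random-effect column per (level x cell type) pair
  expect_equal(d$blocks$disease$n_cols, 2 * 9)
  expect_equal(d$blocks$region$n_cols, 3 * 9)
  expect_equal(nlevels(d$data$.re_1), 2 * 9)
})

test_that("design construction validates its inputs", {
  counts <- matrix(5L, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  md <- tibble::tibble(sample_id = paste0("s", 1:4), grp = c("x", "x", "x", "x"))
  expect_error(build_design(counts, md), "single level")
  md_missing <- md[1:3, ]
  expect_error(build_design(counts, md_missing), "missing")
  expect_error(build_design(matrix(0L, 3, 2), tibble::tibble(sample_id = 1:3)),
               "all zero")
  expect_error(build_design(counts, md, factors = "nope"), "nope")
})

test_that("without factors or sample intercept the model is a plain Poisson GLM", {
  set.seed(22)
  counts <- matrix(rpois(40, 30), 10, 4,
                   dimnames = list(paste0("s", 1:10), paste0("ct", 1:4)))
  md <- tibble::tibble(sample_id = paste0("s", 1:10))
  d <- build_design(counts, md, factors = character(0), sample_intercept = FALSE)
  fit <- fit_poisson_glmm(d)
  expect_s3_class(fit$model, "glm")
  expect_equal(nrow(fit$varcomp), 0L)
  ref <- glm(count ~ cell_type, family = poisson(), data = d$data)
  expect_equal(unname(fit$fixef), unname(coef(ref)), tolerance = 1e-10)
})

test_that("LTSR is the folded normal CDF with its symmetries", {
  expect_equal(compute_ltsr(0, 3), 0.5)
  expect_equal(compute_ltsr(1, 0.5), pnorm(2))
  expect_equal(compute_ltsr(1, 0.5), 0.97725, tolerance = 1e-5)
  expect_equal(compute_ltsr(-1, 0.5), compute_ltsr(1, 0.5))
  expect_error(compute_ltsr(1, 0), "post_sd")
  expect_error(compute_ltsr(1, -2), "post_sd")
  # monotone in |mean|, antitone in sd
  m <- seq(0, 3, by = 0.25)
  expect_true(all(diff(compute_ltsr(m, 1)) >= 0))
  s <- seq(0.2, 3, by = 0.2)
  expect_true(all(diff(compute_ltsr(1, s)) <= 0))
})

test_that("Laplace marginal log likelihood matches dense numerical integration", {
  counts <- rbind(c(950L, 1200L), c(800L, 1400L))
  rownames(counts) <- c("s1", "s2"); colnames(counts) <- c("ctA", "ctB")
  md <- tibble::tibble(sample_id = c("s1", "s2"), batch = c("b1", "b2"))
  fit <- fit_poisson_glmm(build_design(counts, md, sample_intercept = FALSE))
  sig <- fit$varcomp$sigma
  b <- fit$fixef
  eta_fixed <- c(b[1], b[1], b[1] + b[2], b[1] + b[2])
  y <- c(950, 800, 1200, 1400)
  # each random coefficient touches exactly one observation, so the marginal
  # likelihood factorises into four one-dimensional integrals
  exact <- sum(vapply(1:4, function(i) {
    f <- function(u) dpois(y[i], exp(eta_fixed[i] + u)) * dnorm(u, 0, sig)
    log(integrate(f, -10 * sig, 10 * sig, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_lt(abs(exact - fit$loglik), 1e-3)
})

test_that("a pure fixed-effects truth yields near-zero variance components", {
  sim <- simulate_composition(composition_sim_config(
    n_samples = 200, n_cell_types = 5,
    factors = c(f1 = 3L, f2 = 4L), sigma = c(f1 = 0, f2 = 0),
    sigma_sample = 0, base_log_mean = log(60), seed = 3))
  fit <- fit_composition(sim$counts, sim$metadata, se = FALSE)
  expect_true(all(fit$varcomp$sigma < 0.05))
  # zero-variance blocks report zero posterior means and LTSR 1/2
  zero_blocks <- fit$varcomp$factor[fit$varcomp$sigma < 1e-8]
  if (length(zero_blocks) > 0) {
    eff <- fit$effects[fit$effects$factor %in% zero_blocks, ]
    expect_true(all(eff$post_mean == 0))
    expect_true(all(eff$ltsr == 0.5))
  }
})

test_that("shifting the intercept leaves the variance components unchanged", {
  base_cfg <- function(b) composition_sim_config(
    n_samples = 120, n_cell_types = 5, factors = c(f1 = 4L),
    sigma = c(f1 = 0.5), sigma_sample = 0.2, base_log_mean = b, seed = 31)
  sim1 <- simulate_composition(base_cfg(log(50)))
  fit1 <- fit_composition(sim1$counts, sim1$metadata, se = FALSE)
  sim2 <- simulate_composition(base_cfg(log(50) + 1))
  fit2 <- fit_composition(sim2$counts, sim2$metadata, se = FALSE)
  # same seed, so the same true effects; only the count scale moves
  expect_lt(abs(fit1$varcomp$sigma - fit2$varcomp$sigma), 0.1)
  expect_lt(abs((fit2$fixef[["(Intercept)"]] - fit1$fixef[["(Intercept)"]]) - 1), 0.15)
})

test_that("the fit is invariant to relabeling cell types", {
  sim <- simulate_composition(composition_sim_config(
    n_samples = 80, n_cell_types = 4, factors = c(f1 = 3L),
    sigma = c(f1 = 0.4), sigma_sample = 0.2, base_log_mean = log(40), seed = 33))
  fit1 <- fit_composition(sim$counts, sim$metadata, se = FALSE)
  perm <- c(3, 1, 4, 2)
  fit2 <- fit_composition(sim$counts[, perm], sim$metadata, se = FALSE)
  expect_equal(fit1$varcomp$sigma, fit2$varcomp$sigma, tolerance = 1e-4)
  e1 <- dplyr::arrange(fit1$effects, level, cell_type)
  e2 <- dplyr::arrange(fit2$effects, level, cell_type)
  expect_equal(e1$post_mean, e2$post_mean, tolerance = 1e-4)
})

test_that("interior variance optima get positive standard errors, boundaries none", {
  sim <- simulate_composition(composition_sim_config(
    n_samples = 100, n_cell_types = 4, factors = c(f1 = 4L),
    sigma = c(f1 = 0.6), sigma_sample = 0.2, base_log_mean = log(50), seed = 35))
  fit <- fit_composition(sim$counts, sim$metadata, se = TRUE)
  expect_gt(fit$varcomp$se_sigma, 0)
  expect_lt(fit$varcomp$se_sigma, fit$varcomp$sigma)  # informative data

  sim0 <- simulate_composition(composition_sim_config(
    n_samples = 100, n_cell_types = 4, factors = c(f1 = 4L),
    sigma = c(f1 = 0), sigma_sample = 0, base_log_mean = log(50), seed = 36))
  fit0 <- fit_poisson_glmm(build_design(sim0$counts, sim0$metadata))
  if (any(fit0$varcomp$sigma <= 1e-4)) {
    expect_warning(vc <- sd_standard_errors(fit0), "boundary")
    expect_true(all(is.na(vc$se_sigma[vc$sigma <= 1e-4])))
  }
  # a non-converged fit is refused
  fake <- fit0; fake$converged <- FALSE
  expect_error(sd_standard_errors(fake), "converged")
})
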