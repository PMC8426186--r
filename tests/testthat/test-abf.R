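test_that("Wakefield log ABF matches its closed form at anchor points", {
  # z = 0: the formula collapses to the shrinkage term alone
  expect_equal(wakefield_lnabf(0, 1, 0.04), 0.5 * log(1 / 1.04))
  # a vanishing prior variance makes the two models identical
  expect_equal(wakefield_lnabf(0.7, 0.2, 1e-12), 0, tolerance = 1e-9)
  # moderate association
  expect_equal(wakefield_lnabf(0.3, 0.1, 0.04),
               0.5 * log(0.2) + 4.5 * 0.8, tolerance = 1e-12)
  expect_equal(wakefield_lnabf(0.3, 0.1, 0.04), 2.79528, tolerance = 1e-5)
  # symmetric in the sign of beta
  expect_equal(wakefield_lnabf(-0.3, 0.1, 0.04), wakefield_lnabf(0.3, 0.1, 0.04))
})

test_that("Wakefield log ABF agrees with numerical quadrature", {
  for (W in c(0.01, 0.04, 0.1)) {
    for (beta in c(-0.8, -0.1, 0, 0.25, 1)) {
      for (se in c(0.02, 0.1, 0.4)) {
        expected <- lnabf_quadrature(beta, se, W)
        got <- wakefield_lnabf(beta, se, W)
        expect_equal(got, expected, tolerance = 1e-8)
      }
    }
  }
})

test_that("Wakefield conversion rejects invalid parameters", {
  expect_error(wakefield_lnabf(0.1, 0, 0.04), "se")
  expect_error(wakefield_lnabf(0.1, -1, 0.04), "se")
  expect_error(wakefield_lnabf(0.1, 0.1, 0), "prior_variance")
  expect_error(wakefield_lnabf(0.1, 0.1, -0.04), "prior_variance")
})

test_that("decay-rate estimation is the closed-form exponential MLE", {
  expect_equal(estimate_decay_rate(c(5e4, 1e5, 1.5e5)), 1e-5)
  expect_equal(estimate_decay_rate(7e4), 1 / 7e4)
  set.seed(42)
  draws <- rexp(10000, rate = 1e-5)
  expect_lt(abs(estimate_decay_rate(draws) - 1e-5) / 1e-5, 0.02)
  expect_error(estimate_decay_rate(numeric(0)))
  expect_error(estimate_decay_rate(c(1e4, -5)))
})

make_stats <- function(pos, chrom = "1") {
  tibble::tibble(variant_id = paste0("v", seq_along(pos)), chrom = chrom,
                 pos = pos, beta = 0.1, se = 0.05)
}

test_that("variant-gene pairing respects the inclusive 1-Mb window", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", strand = "+", tss = 2e6)
  inside <- map_variants_to_genes(make_stats(2e6 + 5e5), genes)
  expect_equal(nrow(inside), 1L)
  expect_equal(inside$distance, 5e5)
  outside <- map_variants_to_genes(make_stats(2e6 + 5e5 + 1), genes)
  expect_equal(nrow(outside), 0L)
  below <- map_variants_to_genes(make_stats(2e6 - 5e5), genes)
  expect_equal(nrow(below), 1L)
})

test_that("a variant inside two overlapping windows pairs with both genes", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "1",
                          strand = "+", tss = c(2e6, 2.6e6))
  pairs <- map_variants_to_genes(make_stats(2.3e6), genes)
  expect_setequal(pairs$gene_id, c("g1", "g2"))
  expect_equal(nrow(pairs), 2L)
  expect_equal(sort(pairs$distance), c(3e5, 3e5))
})

test_that("chromosome dialects are matched after stripping the chr prefix", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 2e6)
  pairs <- map_variants_to_genes(make_stats(2e6, chrom = "1"), genes)
  expect_equal(nrow(pairs), 1L)
  expect_message(
    map_variants_to_genes(make_stats(2e6, chrom = "7"), genes),
    "not paired")
})

test_that("pairing validates its inputs", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", strand = "+", tss = 2e6)
  dup <- make_stats(c(2e6, 2e6 + 10))
  dup$variant_id <- c("v1", "v1")
  expect_error(map_variants_to_genes(dup, genes), "duplicate variant_id")
  empty <- make_stats(numeric(0))
  expect_warning(out <- map_variants_to_genes(empty, genes), "empty")
  expect_equal(nrow(out), 0L)
  bad_se <- make_stats(2e6); bad_se$se <- 0
  expect_error(map_variants_to_genes(bad_se, genes), "se")
  expect_error(map_variants_to_genes(make_stats(2e6), genes, window = 1e6 + 1),
               "even")
})

test_that("regional Bayes factors are prior-weighted averages", {
  # one variant: the weight cancels
  one <- tibble::tibble(gene_id = "g", ln_abf = 3.3, ln_weight = -2)
  expect_equal(regional_bf(one)$ln_rbf, 3.3)
  # equal ABFs: any weights give back the common value
  eq <- tibble::tibble(gene_id = "g", ln_abf = c(1.7, 1.7, 1.7),
                       ln_weight = c(0, -1, -4))
  expect_equal(regional_bf(eq)$ln_rbf, 1.7)
  # distances 0 and 100 kb at lambda = 1e-5: RBF = (10 + e^-1) / (1 + e^-1)
  two <- tibble::tibble(gene_id = "g", ln_abf = log(c(10, 1)),
                        ln_weight = -1e-5 * c(0, 1e5))
  expect_equal(exp(regional_bf(two)$ln_rbf), (10 + exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(exp(regional_bf(two)$ln_rbf), 7.5796, tolerance = 1e-4)
})

test_that("regional BF is invariant to pair order and weight scaling, and bounded", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    pairs <- tibble::tibble(
      gene_id = "g",
      ln_abf = rnorm(n, 0, 3),
      ln_weight = -runif(n, 0, 8)
    )
    got <- regional_bf(pairs)$ln_rbf
    # brute-force raw-scale oracle
    expect_equal(got, log(rbf_bruteforce(exp(pairs$ln_abf), exp(pairs$ln_weight))),
                 tolerance = 1e-10)
    # order invariance
    expect_equal(regional_bf(pairs[sample(n), ])$ln_rbf, got)
    # multiplying all weights by a positive constant
    shifted <- pairs; shifted$ln_weight <- shifted$ln_weight + 2.5
    expect_equal(regional_bf(shifted)$ln_rbf, got, tolerance = 1e-10)
    # weighted-mean bounds
    expect_gte(got, min(pairs$ln_abf) - 1e-10)
    expect_lte(got, max(pairs$ln_abf) + 1e-10)
  }
})

test_that("with zero decay the regional BF is the unweighted mean of ABFs", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(1:9, 1)
    pairs <- tibble::tibble(gene_id = "g", ln_abf = rnorm(n, 0, 2),
                            ln_weight = 0)
    expect_equal(exp(regional_bf(pairs)$ln_rbf), mean(exp(pairs$ln_abf)),
                 tolerance = 1e-10)
  }
})

test_that("regional BF survives variant log Bayes factors of several hundred", {
  pairs <- tibble::tibble(gene_id = "g", ln_abf = c(700, 650, 2),
                          ln_weight = c(0, -1, -2))
  got <- regional_bf(pairs)$ln_rbf
  expect_true(is.finite(got))
  expect_lte(got, 700)
  expect_gte(got, 2)
})
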