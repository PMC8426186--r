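# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the ABF oracle integrates the defining ratio of
# marginal likelihoods numerically, the BH oracle applies the step-up rule
# literally, and the regional-BF oracle averages on the raw scale.

# ln ABF by numerical quadrature of
#   integral N(beta_hat; b, se^2) N(b; 0, W) db  /  N(beta_hat; 0, se^2),
# stabilised around the integrand's mode so that huge Bayes factors do not
# overflow.
lnabf_quadrature <- function(beta, se, W) {
  g <- function(b) dnorm(beta, mean = b, sd = se, log = TRUE) +
    dnorm(b, mean = 0, sd = sqrt(W), log = TRUE)
  post_mean <- beta * W / (W + se^2)
  post_sd <- sqrt(W * se^2 / (W + se^2))
  M <- g(post_mean)
  val <- integrate(function(b) exp(g(b) - M),
                   lower = post_mean - 15 * post_sd,
                   upper = post_mean + 15 * post_sd,
                   rel.tol = 1e-12, abs.tol = 0)$value
  (M + log(val)) - dnorm(beta, mean = 0, sd = se, log = TRUE)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min over j >= i of p_(j) * n / j.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * n / seq_len(n)))))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Raw-scale weighted average of Bayes factors for one gene.
rbf_bruteforce <- function(abf, weight) sum(weight * abf) / sum(weight)

# Two-point z-scores with the sample standard deviation.
expect_close <- function(actual, expected, tol = 1e-8) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max abs diff %.3g <= %.3g",
                              max(abs(actual - expected)), tol))
}
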