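# Two-component gamma-Poisson mixture (the multi-item gamma-Poisson
# shrinker). Observed counts a_i are modelled as Poisson(lambda_i * E_i)
# with lambda drawn from a mixture
#   lambda ~ P * Gamma(alpha1, beta1) + (1 - P) * Gamma(alpha2, beta2)
# so that marginally a_i follows a mixture of negative binomials. The five
# hyperparameters are estimated by maximum likelihood over all tables of a
# run; per-table posteriors give the shrunk geometric mean EBGM and its
# 5th percentile EBGM05.

gps_default_theta <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                       P = 1 / 3)

gps_nll <- function(par, n, e) {
  a1 <- exp(par[1]); b1 <- exp(par[2])
  a2 <- exp(par[3]); b2 <- exp(par[4])
  p <- stats::plogis(par[5])
  f1 <- stats::dnbinom(n, size = a1, prob = b1 / (b1 + e))
  f2 <- stats::dnbinom(n, size = a2, prob = b2 / (b2 + e))
  -sum(log(pmax(p * f1 + (1 - p) * f2, 1e-300)))
}

#' Fit the gamma-Poisson mixture hyperparameters
#'
#' @param n Integer vector of observed counts (the `a` cells).
#' @param e Numeric vector of expected counts under row/column independence.
#' @param theta0 Starting hyperparameters (alpha1, beta1, alpha2, beta2, P).
#' @return A list with `theta` (named numeric vector), `nll` and `convergence`.
#' @keywords internal
fit_gps_mixture <- function(n, e, theta0 = gps_default_theta) {
  par0 <- c(log(theta0[1:4]), stats::qlogis(theta0[5]))
  opt <- stats::optim(par0, gps_nll, n = n, e = e, method = "BFGS",
                      control = list(maxit = 500))
  theta <- c(exp(opt$par[1:4]), stats::plogis(opt$par[5]))
  names(theta) <- names(gps_default_theta)
  list(theta = theta, nll = opt$value, convergence = opt$convergence)
}

# Posterior EBGM (geometric mean) and 5th percentile for each table.
gps_scores <- function(n, e, theta) {
  a1 <- theta[1]; b1 <- theta[2]; a2 <- theta[3]; b2 <- theta[4]
  p <- theta[5]
  f1 <- stats::dnbinom(n, size = a1, prob = b1 / (b1 + e))
  f2 <- stats::dnbinom(n, size = a2, prob = b2 / (b2 + e))
  q <- p * f1 / pmax(p * f1 + (1 - p) * f2, 1e-300)
  # posterior mixture of Gamma(a_k + n, b_k + E); E[ln lambda] is available
  # in closed form via digamma
  eln <- q * (digamma(a1 + n) - log(b1 + e)) +
    (1 - q) * (digamma(a2 + n) - log(b2 + e))
  ebgm <- exp(eln)
  ebgm05 <- vapply(seq_along(n), function(i) {
    cdf <- function(x) {
      q[i] * stats::pgamma(x, shape = a1 + n[i], rate = b1 + e[i]) +
        (1 - q[i]) * stats::pgamma(x, shape = a2 + n[i], rate = b2 + e[i]) -
        0.05
    }
    hi <- max(ebgm[i] * 4, 1)
    while (cdf(hi) < 0) hi <- hi * 4
    stats::uniroot(cdf, c(0, hi), tol = 1e-8)$root
  }, numeric(1))
  list(ebgm = ebgm, ebgm05 = ebgm05, q = q)
}
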