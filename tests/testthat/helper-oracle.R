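# Brute-force oracle for the JZS one-sample Bayes factor.
#
# The noncentral-t likelihood is built from first principles by numerically
# integrating the normal density over the chi-distributed scale factor
# (t = (Z + ncp) / U with U = sqrt(chisq_nu / nu)), and the Cauchy prior on
# the standardized effect size is integrated on a fine grid. Completely
# independent of the package's inverse-gamma mixture quadrature: different
# derivation, different integration method, no shared special-function code.
bf10_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  du <- 0.002
  u <- seq(du / 2, 5, by = du) # support of sqrt(chisq_nu / nu)
  log_gu <- (nu / 2) * log(nu) - lgamma(nu / 2) - (nu / 2 - 1) * log(2) +
    (nu - 1) * log(u) - nu * u^2 / 2
  gu <- exp(log_gu)
  dens_t <- function(ncp) sum(u * stats::dnorm(t * u - ncp) * gu) * du
  dd <- 0.02 / sqrt(n) # effect-size grid with ~0.02 spacing in ncp units
  delta <- seq((-12 - 4 * abs(t)) / sqrt(n), (12 + 4 * abs(t)) / sqrt(n),
               by = dd)
  like <- vapply(delta * sqrt(n), dens_t, numeric(1))
  alt <- sum(like * stats::dcauchy(delta, 0, r)) * dd
  alt / dens_t(0)
}

# t statistic of a sample against a null location
t_stat <- function(x, null = 0) (mean(x) - null) / (sd(x) / sqrt(length(x)))
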