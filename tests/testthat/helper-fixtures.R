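# shared fixtures, built in code

# minimal two-variable lognormal config with one target rank correlation;
# single-sex draw because the copula targets are conditional on sex (the
# study's correlations are sex-adjusted) and a sex mixture over sex-shifted
# marginals would add its own dependence
bivariate_config <- function(rho, n, seed) {
  marg <- dplyr::filter(default_marginals(), variable %in% c("plt", "amax_adp"))
  simulation_config(
    n_subjects = n, female_fraction = 0, seed = seed,
    marginals = marg,
    rank_correlation = tibble::tibble(var1 = "plt", var2 = "amax_adp",
                                      rho = rho))
}

# small default-structure cohort for pipeline-level tests
small_cohort <- function(n = 80, seed = 11) {
  generate_cohort(simulation_config(n_subjects = n, seed = seed))
}

# brute-force van der Waerden oracle: rank then normal quantile, no shortcuts
vdw_oracle <- function(x) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    r <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    qnorm(r / (n + 1))
  })
}

# hand Mantel-Haenszel oracle (a = exposed cases = tab[2,2])
mh_oracle <- function(tabs) {
  num <- sum(sapply(tabs, function(t) t[2, 2] * t[1, 1] / sum(t)))
  den <- sum(sapply(tabs, function(t) t[2, 1] * t[1, 2] / sum(t)))
  num / den
}
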