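# Gaussian-copula cohort generator: structure, fidelity, determinism

test_that("cohort has the configured size and sex split", {
  co <- generate_cohort(simulation_config(n_subjects = 251,
                                          female_fraction = 125 / 251,
                                          seed = 7))
  expect_equal(nrow(co), 251)
  expect_equal(sum(co$sex == "female"), 125)
  expect_equal(sum(co$sex == "male"), 126)
  expect_equal(anyDuplicated(co$subject_id), 0L)
  # physical invariants
  num <- co[vapply(co, is.numeric, logical(1))]
  expect_true(all(as.matrix(num) >= 0))
  expect_true(all(co$hct <= 100 & co$pct <= 100))
  expect_true(all(co$hct[co$rbc > 0] > 0))
  # every measurement column in exactly one variable set
  vs <- variable_sets(co)
  expect_equal(sort(unlist(vs, use.names = FALSE)),
               sort(setdiff(names(num), character(0))))
  expect_equal(anyDuplicated(unlist(vs)), 0L)
})

test_that("generation is bitwise reproducible and config is validated", {
  cfg <- simulation_config(n_subjects = 60, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(simulation_config(n_subjects = 0), class = "ps_bad_argument")
  expect_error(simulation_config(missing_rate = 0.05),
               class = "ps_bad_argument")
  bad <- tibble::tibble(var1 = "plt", var2 = "pct", rho = 1.4)
  expect_error(simulation_config(rank_correlation = bad),
               class = "ps_bad_correlation")
})

test_that("identity copula yields near-zero sample rank correlations", {
  marg <- dplyr::filter(default_marginals(),
                        variable %in% c("plt", "uric_acid", "amax_adp"))
  # single sex: the copula controls dependence conditional on sex, and a
  # mixture over sex-shifted marginals would correlate the margins by itself
  cfg <- simulation_config(n_subjects = 20000, female_fraction = 0,
                           seed = 5, marginals = marg,
                           rank_correlation = tibble::tibble(
                             var1 = character(), var2 = character(),
                             rho = numeric()))
  co <- generate_cohort(cfg)
  R <- cor(cbind(co$plt, co$uric_acid, co$amax_adp), method = "spearman")
  expect_lt(max(abs(R[upper.tri(R)])), 0.025)   # 3 / sqrt(n) bound
})

test_that("target Spearman correlations are recovered at large n", {
  for (rho in c(-0.17, 0.35, 0.42)) {
    co <- generate_cohort(bivariate_config(rho, n = 20000,
                                           seed = 100 + round(100 * rho)))
    r_hat <- cor(co$plt, co$amax_adp, method = "spearman")
    expect_lt(abs(r_hat - rho), 0.02)
  }
})

test_that("published marginal targets are matched in median and IQR", {
  # single-sex draw so every variable is checked against its own targets
  cfg <- simulation_config(n_subjects = 50000, female_fraction = 0,
                           seed = 2024)
  co <- generate_cohort(cfg)
  marg <- cfg$marginals
  # variables with published summaries (morphology, metabolic, Amax)
  check <- marg[marg$set %in% c("morphology", "metabolic") |
                  grepl("^amax", marg$variable), ]
  for (i in seq_len(nrow(check))) {
    v <- check$variable[i]
    q <- quantile(co[[v]], c(0.25, 0.5, 0.75), names = FALSE)
    expect_lt(abs(q[2] - check$med_m[i]) / check$med_m[i], 0.02)
    iqr_target <- check$q75_m[i] - check$q25_m[i]
    expect_lt(abs((q[3] - q[1]) - iqr_target) / iqr_target, 0.02)
  }
})

test_that("infeasible correlation targets are repaired to positive definite", {
  marg <- dplyr::filter(default_marginals(),
                        variable %in% c("plt", "pct", "uric_acid"))
  # jointly impossible triple: two strong positives with a strong negative
  tri <- tibble::tibble(var1 = c("plt", "plt", "pct"),
                        var2 = c("pct", "uric_acid", "uric_acid"),
                        rho = c(0.95, 0.9, -0.9))
  cfg <- simulation_config(n_subjects = 100, seed = 1, marginals = marg,
                           rank_correlation = tri)
  expect_true(cfg$pd_repaired)
  ev <- eigen(cfg$copula_pearson, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_s3_class(generate_cohort(cfg), "tbl_df")
  # the shipped default needs repair too and must stay usable
  expect_true(simulation_config()$pd_repaired)
})

test_that("missingness injection is MCAR at the requested rate", {
  co <- small_cohort(n = 251, seed = 4)
  expect_identical(inject_missing(co, 0), co)
  expect_error(inject_missing(co, 0.05), class = "ps_rate_too_high")
  block <- names(co)[4:13]                    # 10 numeric columns
  counts <- vapply(1:300, function(s) {
    masked <- inject_missing(co, 0.02, seed = s)
    sum(is.na(masked[block]))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 251 * 10 * 0.02), 2)  # binomial expectation
  # protected columns never masked
  masked <- inject_missing(co, 0.03, seed = 99)
  expect_false(anyNA(masked$sex))
  expect_false(anyNA(masked$age))
  expect_false(anyNA(masked$subject_id))
})

test_that("column dictionary describes every measurement column", {
  co <- small_cohort(n = 20)
  dict <- column_dictionary(co)
  expect_true(all(c("name", "units", "set") %in% names(dict)))
  expect_setequal(dict$name, setdiff(names(co), c("subject_id", "sex")))
})
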