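# rank correlations with resampling, gated comparisons, ANCOVA, sample size

test_that("spearman_boosted recovers perfect monotone association", {
  x <- 1:20
  up <- spearman_boosted(x, x^3, seed = 1)
  expect_equal(up$rho, 1)
  dn <- spearman_boosted(x, -exp(x / 5), seed = 1)
  expect_equal(dn$rho, -1)
  expect_error(spearman_boosted(1:10, rep(1, 10)),
               class = "ps_zero_variance")
  expect_error(spearman_boosted(1:3, 1:3), class = "ps_bad_argument")
})

test_that("null data give small correlation and a CI covering zero", {
  set.seed(2)
  x <- rnorm(1000); y <- rnorm(1000)
  res <- spearman_boosted(x, y, B = 500, seed = 3)
  expect_lt(abs(res$rho), 0.08)            # ~2.5 / sqrt(n) null bound
  expect_lt(res$conf_low, 0)
  expect_gt(res$conf_high, 0)
  expect_true(res$conf_low <= res$rho && res$rho <= res$conf_high)
  expect_true(res$jackknife_min <= res$rho & res$rho <= res$jackknife_max)
})

test_that("estimate is invariant to monotone transforms; exact p for tiny n", {
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30)
  a <- spearman_boosted(x, y, B = 200, seed = 5)
  b <- spearman_boosted(exp(x), y^3 + 10, B = 200, seed = 5)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
  # n <= 10 route: exact enumeration agrees with cor.test's exact p
  xs <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9)
  ys <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 3.1)
  res <- spearman_boosted(xs, ys, B = 50, seed = 6)
  ref <- cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(res$rho, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("influence flag reacts to a single high-leverage pair", {
  set.seed(7)
  x <- c(rnorm(20), 6); y <- c(rnorm(20), 6)
  flagged <- spearman_boosted(x, y, B = 100, seed = 8)
  expect_true(flagged$influence_flag)
})

test_that("sex-adjusted correlation pools Fisher-z across strata", {
  set.seed(9)
  n <- 400
  sex <- rep(c("female", "male"), each = n / 2)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  res <- spearman_sex_adjusted(x, y, sex)
  per <- res$strata[[1]]
  expect_equal(nrow(per), 2)
  z <- sum((per$n - 3) * atanh(per$rho)) / sum(per$n - 3)
  expect_equal(res$rho, tanh(z))
})

test_that("compare_groups selects the test the gate dictates", {
  # 1-SD shift between normal groups: power ~ 1 whatever branch is taken,
  # and the parametric branch dominates (gate passes ~ 0.95^3 of the time)
  set.seed(10)
  grp <- rep(c("g1", "g2"), each = 200)
  runs <- purrr::map_dfr(1:40, function(i) {
    compare_groups(c(rnorm(200), rnorm(200, mean = 1)), grp)
  })
  expect_gte(mean(runs$test == "t"), 0.75)
  expect_true(all(runs$p_value < 0.001))
  a <- rnorm(200)
  ident <- compare_groups(c(a, a), rep(c("g1", "g2"), each = 200))
  expect_gt(ident$p_value, 0.999)
  skewed <- c(rlnorm(150, sdlog = 1.5), rlnorm(150, sdlog = 2.4))
  res2 <- compare_groups(skewed, rep(c("g1", "g2"), each = 150))
  expect_equal(res2$test, "mann-whitney")
  expect_error(compare_groups(rnorm(9), rep(c("a", "b", "c"), 3)),
               class = "ps_bad_argument")
})

test_that("ancova with no covariates agrees with one-way ANOVA", {
  set.seed(11)
  y <- rnorm(120); g <- rep(c("a", "b"), each = 60)
  res <- ancova_boosted(y, g, B = 4000, seed = 12)
  aov_p <- summary(stats::aov(y ~ g))[[1]][["Pr(>F)"]][1]
  expect_equal(res$p_parametric, aov_p, tolerance = 1e-10)
  expect_lt(abs(res$p_boot - aov_p), 0.03)  # Monte-Carlo error at B = 4000
})

test_that("ancova detects a 1-SD group effect behind an age confounder", {
  set.seed(13)
  n <- 251
  age <- runif(n, 60, 65)
  g <- rbinom(n, 1, 0.5)
  y <- 0.3 * (age - 62.5) + 1 * g + rnorm(n)
  res <- ancova_boosted(y, g, covariates = data.frame(age = age),
                        B = 2000, seed = 14)
  expect_lt(res$p_boot, 0.01)
  expect_equal(unname(diff(res$adjusted_means[[1]])), 1, tolerance = 0.4)
  expect_error(
    ancova_boosted(y, g, covariates = data.frame(a = age, b = 2 * age)),
    class = "ps_collinear")
})

test_that("required_n reproduces the Fisher-z closed form", {
  target <- required_n(0.22, alpha = 0.01, power = 0.90)
  expect_equal(target$n_rounded_ten, 300L)
  # hand computation at a strong correlation
  hand <- ((qnorm(0.975) + qnorm(0.80)) / atanh(0.9))^2 + 3
  expect_equal(required_n(0.9, 0.05, 0.80)$n_ceiling, as.integer(ceiling(hand)))
  expect_equal(required_n(0.9, 0.05, 0.80)$n_ceiling, 7L)
  expect_error(required_n(0), class = "ps_bad_argument")
})

test_that("batch association returns one tidy row per variable", {
  co <- add_reactivity_scores(small_cohort(n = 60))
  res <- associate_sets(co, "cum_reactivity_aggregation",
                        sets = c("morphology", "metabolic"),
                        B = 100, seed = 1)
  vs <- variable_sets(co)
  expect_equal(nrow(res), length(vs$morphology) + length(vs$metabolic))
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(all(res$conf_low <= res$conf_high))
  expect_error(associate_sets(co, "cum_reactivity_aggregation",
                              sets = "nope"), class = "ps_bad_argument")
})
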