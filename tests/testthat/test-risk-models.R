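# odds ratios, Mantel-Haenszel pooling, logistic models, forest data

test_that("or_2x2 matches hand arithmetic with and without correction", {
  expect_equal(or_2x2(matrix(c(10, 10, 10, 10), 2))$or, 1)
  expect_equal(or_2x2(matrix(c(20, 10, 10, 20), 2))$or, 4)
  # zero cell: every cell shifted by 0.5
  tab <- matrix(c(5, 5, 0, 5), 2)          # d=5, b=5, c=0, a=5
  res <- or_2x2(tab)
  hand <- (5.5 * 5.5) / (5.5 * 0.5)
  expect_true(res$corrected)
  expect_equal(res$or, hand, tolerance = 1e-12)
  se <- sqrt(1 / 5.5 + 1 / 5.5 + 1 / 0.5 + 1 / 5.5)
  expect_equal(res$conf_high, exp(log(hand) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_error(or_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "ps_empty_margin")
})

test_that("mh_pooled reduces to the single-table OR and matches the hand formula", {
  t1 <- matrix(c(12, 7, 5, 11), 2)
  expect_equal(mh_pooled(list(t1))$or, or_2x2(t1)$or, tolerance = 1e-12)
  # homogeneous strata leave the common OR unchanged
  expect_equal(mh_pooled(rep(list(t1), 5))$or, or_2x2(t1)$or,
               tolerance = 1e-12)
  # heterogeneous strata against the brute-force estimator
  t2 <- matrix(c(30, 4, 9, 22), 2)
  t3 <- matrix(c(8, 14, 3, 20), 2)
  for (tabs in list(list(t1, t2), list(t1, t2, t3))) {
    expect_equal(mh_pooled(tabs)$or, mh_oracle(tabs), tolerance = 1e-12)
  }
})

test_that("transposing both margins of every stratum inverts the pooled OR", {
  set.seed(15)
  tabs <- lapply(1:4, function(i) matrix(rpois(4, 12) + 1, 2))
  flipped <- lapply(tabs, function(t) t[2:1, ])   # swap exposure rows
  expect_equal(mh_pooled(flipped)$or, 1 / mh_pooled(tabs)$or,
               tolerance = 1e-12)
})

test_that("logistic fit covers the null and is deterministic", {
  set.seed(16)
  n <- 2000
  df <- tibble::tibble(y = rbinom(n, 1, 0.5), x = rnorm(n))
  fit <- fit_logistic(df, "y", "x")
  expect_true(fit$terms$conf_low[1] < 1 & 1 < fit$terms$conf_high[1])
  expect_identical(tidy(fit), tidy(fit_logistic(df, "y", "x")))
  expect_true(fit$hosmer_lemeshow$p_value >= 0 &
                fit$hosmer_lemeshow$p_value <= 1)
  expect_error(fit_logistic(df, "y", "zzz"), class = "ps_missing_column")
  dfna <- df; dfna$x[1] <- NA
  expect_error(fit_logistic(dfna, "y", "x"), class = "ps_missing_values")
})

test_that("logistic OR recovers a planted ln(2) per-SD effect", {
  set.seed(17)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(log(2) * x))
  fit <- fit_logistic(tibble::tibble(y = y, x = x), "y", "x")
  expect_gt(fit$terms$or[1], 1.9)
  expect_lt(fit$terms$or[1], 2.1)
  expect_lt(fit$terms$p_value[1], 1e-10)
  expect_gt(fit$terms$lr_chisq[1], 100)
})

test_that("complete separation is flagged", {
  df <- tibble::tibble(y = rep(0:1, each = 25),
                       x = c(rnorm(25), rnorm(25) + 30))
  expect_warning(fit <- fit_logistic(df, "y", "x"), "separation")
  expect_true(fit$separation)
})

test_that("forest rows have full-cohort margins and a plottable shape", {
  co <- add_reactivity_scores(small_cohort(n = 251, seed = 18))
  fr <- build_forest(co, "class_reactivity_aggregation",
                     c("plt", "pct", "uric_acid"))
  per <- dplyr::filter(fr, !pooled)
  expect_equal(nrow(per), 3)
  expect_true(all(per$a + per$b + per$c + per$d == 251))
  # outcome margins are the 126/125 class split for every predictor
  expect_true(all(per$b + per$d == 126))
  expect_true(all(per$a + per$c == 125))
  expect_s3_class(autoplot(fr), "ggplot")
  # sex stratification partitions the cohort
  frs <- build_forest(co, "class_reactivity_aggregation", c("plt", "pct"),
                      stratify_by_sex = TRUE)
  per_s <- dplyr::filter(frs, !pooled)
  expect_equal(sum(per_s$a + per_s$b + per_s$c + per_s$d),
               2 * 251)
})

test_that("pooled OR covers 1 for predictors independent of the outcome", {
  set.seed(19)
  n <- 2000
  co <- tibble::tibble(
    p1 = rnorm(n), p2 = rlnorm(n), p3 = rnorm(n),
    cls = rep(0:1, each = n / 2))
  fr <- build_forest(co, "cls", c("p1", "p2", "p3"))
  pooled <- dplyr::filter(fr, pooled)
  expect_lt(pooled$conf_low, 1)
  expect_gt(pooled$conf_high, 1)
  # a predictor equal to the outcome gives a corrected, flagged, huge OR
  co$px <- co$cls + seq_len(n) * 1e-9
  fr2 <- build_forest(co, "cls", "px")
  expect_gt(dplyr::filter(fr2, !pooled)$or, 100)
})
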