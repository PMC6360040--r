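# outlier flagging, kNN imputation and the assumption gate

test_that("tukey fences flag only points beyond 1.5 IQR", {
  expect_identical(detect_outliers(1:5, method = "tukey"), integer(0))
  x <- c(1, 2, 3, 4, 100)
  expect_identical(detect_outliers(x, method = "tukey"), 5L)
  # hand oracle: fences from type-7 quartiles
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  expect_true(x[5] > q[2] + 1.5 * (q[2] - q[1]))
  expect_error(detect_outliers(1:4, method = "tukey"),
               class = "ps_bad_argument")
})

test_that("grubbs is iterative, capped, and rejects degenerate input", {
  expect_error(detect_outliers(c(5, 5, 5, 5), method = "grubbs"),
               class = "ps_zero_variance")
  x <- c(rnorm(30), 50, -60, 70)
  flagged <- detect_outliers(x, method = "grubbs")
  expect_lte(length(flagged), 2)         # default cap of two removals
  expect_true(all(flagged %in% 31:33))
  more <- detect_outliers(x, method = "grubbs", max_remove = 5L)
  expect_setequal(more, 31:33)
})

test_that("grubbs flags a planted 10-SD outlier essentially always", {
  set.seed(20)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(100)
    x[37] <- 10
    37L %in% detect_outliers(x, method = "grubbs")
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("imputation is the identity on complete data and never touches observed cells", {
  co <- small_cohort(n = 40)
  out <- impute_knn(co)
  expect_equal(out$data, co, ignore_attr = TRUE)
  expect_equal(nrow(out$report), 0)

  # low rate so every column stays under the 3% imputation ceiling
  co <- small_cohort(n = 251, seed = 12)
  masked <- inject_missing(co, 0.005, seed = 8)
  imp <- impute_knn(masked, k = 5)
  expect_false(anyNA(imp$data[unlist(variable_sets(co))]))
  # observed cells unchanged
  for (v in unlist(variable_sets(co))) {
    obs <- !is.na(masked[[v]])
    expect_identical(imp$data[[v]][obs], masked[[v]][obs])
  }
  expect_equal(nrow(imp$report), sum(is.na(as.matrix(
    masked[vapply(masked, is.numeric, logical(1))]))))
})

test_that("kNN imputation tracks a deterministic linear relation", {
  set.seed(5)
  x <- runif(60, 1, 10)
  df <- tibble::tibble(x = x, y = 2 * x, z = x + rnorm(60, sd = 0.01))
  df$y[17] <- NA
  imp <- impute_knn(df, k = 3)
  expect_lt(abs(imp$data$y[17] - 2 * x[17]) / (2 * x[17]), 0.05)
  expect_equal(imp$report$variable, "y")
  expect_length(imp$report$donors[[1]], 3)
})

test_that("variables at or above 3% missingness are skipped and reported", {
  set.seed(6)
  df <- tibble::tibble(a = rnorm(251), b = rnorm(251))
  df$a[1:10] <- NA                        # 4% missing
  df$b[3] <- NA
  expect_warning(imp <- impute_knn(df), "3%")
  expect_true(anyNA(imp$data$a))
  expect_false(anyNA(imp$data$b))
  expect_identical(attr(imp$report, "skipped"), "a")
})

test_that("assumption gate routes normal, lognormal and degenerate input", {
  set.seed(30)
  g <- rep(c("a", "b"), each = 200)
  gate_ln <- assumption_gate(rlnorm(400, sdlog = 1.2), g)
  expect_equal(gate_ln$decision, "transform-then-parametric")
  expect_lt(abs(gate_ln$lambda), 0.25)    # Box-Cox MLE near log-transform
  expect_error(assumption_gate(rnorm(4), c("a", "a", "b", "b")),
               class = "ps_bad_argument")
})

test_that("gate passes normal homoscedastic data at about the composite rate", {
  set.seed(31)
  g <- rep(c("a", "b"), each = 80)
  first_pass <- vapply(1:200, function(i) {
    assumption_gate(rnorm(160), g)$decision == "parametric"
  }, logical(1))
  # two Shapiro-Wilk tests + Brown-Forsythe at alpha = 0.05:
  # pass rate ~ 0.95^3 = 0.857; band = +/- 3 binomial SE at 200 reps
  expect_gt(mean(first_pass), 0.78)
  expect_lt(mean(first_pass), 0.94)
})

test_that("box-cox lambda recovery matches the MASS profile on lognormal data", {
  set.seed(32)
  x <- rlnorm(300, meanlog = 1, sdlog = 0.8)
  lam <- plateletscore:::boxcox_lambda(x)
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.05), plotit = FALSE)
  lam_mass <- bc$x[which.max(bc$y)]
  expect_lt(abs(lam - lam_mass), 0.06)
})
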