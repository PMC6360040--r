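# van der Waerden scoring, cumulative scores and median dichotomization

test_that("vdw_scores matches hand quantiles and handles ties", {
  expect_equal(vdw_scores(c(5, 1, 9)),
               qnorm(c(0.50, 0.25, 0.75)), tolerance = 1e-12)
  expect_equal(vdw_scores(c(2, 2)), c(0, 0))
  # tie-free scores sum to zero by quantile symmetry
  set.seed(1)
  for (n in c(3, 10, 101)) {
    expect_lt(abs(sum(vdw_scores(sample(n)))), 1e-9)
  }
  expect_error(vdw_scores(c(1, NA, 3)), class = "ps_nonfinite")
  expect_error(vdw_scores(1), class = "ps_bad_argument")
})

test_that("vdw_scores equals the brute-force oracle on all small inputs", {
  set.seed(42)
  for (n in 2:8) {
    for (rep in 1:20) {
      x <- rnorm(n)
      expect_equal(vdw_scores(x), vdw_oracle(x), tolerance = 1e-12)
    }
  }
})

test_that("vdw_scores is monotone and invariant to increasing transforms", {
  set.seed(7)
  x <- rnorm(40)
  s <- vdw_scores(x)
  expect_true(all(diff(s[order(x)]) > 0))
  expect_equal(s, vdw_scores(exp(x)))
  expect_equal(s, vdw_scores(x^3))
  # bounded strictly inside the extreme quantiles
  n <- length(x)
  expect_true(all(s > qnorm(1 / (n + 1)) - 1e-12 &
                  s < qnorm(n / (n + 1)) + 1e-12))
})

test_that("integrative indicator follows (Amax x AUC)/1000", {
  expect_equal(integrative_indicator(100, 500), 50)
  expect_equal(integrative_indicator(0, 741), 0)
  expect_equal(integrative_indicator(127.9, 1000), 127.9)
  expect_error(integrative_indicator(-1, 5), class = "ps_bad_argument")
})

test_that("cumulate sums component normal scores", {
  df <- tibble::tibble(a = c(10, 20, 30, 40))
  one <- cumulate(df, "single", components = "a")
  expect_equal(one$score, vdw_scores(df$a))
  df3 <- tibble::tibble(amax_aa = c(10, 20, 30, 40),
                        amax_col = c(10, 20, 30, 40),
                        amax_adp = c(10, 20, 30, 40))
  agg <- cumulate(df3, "reactivity_aggregation")
  expect_equal(agg$score, 3 * qnorm(c(0.2, 0.4, 0.6, 0.8)),
               tolerance = 1e-12)
  expect_error(cumulate(tibble::tibble(x = 1:4), "reactivity_aggregation"),
               class = "ps_missing_column")
})

test_that("dichotomize splits at the sample median, lower class inclusive", {
  d <- dichotomize(c(1, 2, 3, 4))
  expect_equal(d$rank, c(0L, 0L, 1L, 1L))
  expect_equal(d$median, 2.5)
  expect_warning(dall <- dichotomize(rep(2, 6)), "constant")
  expect_true(all(dall$rank == 0L))
  # odd n with distinct values: (n + 1) / 2 subjects in rank 0
  set.seed(3)
  for (n in c(5, 51, 251)) {
    r <- dichotomize(rnorm(n))$rank
    expect_equal(sum(r == 0), (n + 1) / 2)
  }
})

test_that("class membership is invariant to monotone transforms of inputs", {
  set.seed(9)
  df <- tibble::tibble(amax_aa = rlnorm(41), amax_col = rlnorm(41),
                       amax_adp = rlnorm(41))
  base <- cumulate(df, "reactivity_aggregation")
  warped <- dplyr::mutate(df, amax_aa = log(amax_aa),
                          amax_col = amax_col^3,
                          amax_adp = sqrt(amax_adp))
  again <- cumulate(warped, "reactivity_aggregation")
  expect_equal(base$rank, again$rank)
  expect_equal(base$score, again$score)
})

test_that("add_reactivity_scores appends vdw_, cum_ and class_ columns", {
  co <- small_cohort(n = 40)
  sc <- add_reactivity_scores(co)
  expect_true(all(c("cum_reactivity_aggregation", "class_global_reactivity",
                    "vdw_amax_aa") %in% names(sc)))
  expect_equal(sc$cum_reactivity_aggregation,
               cumulate(co, "reactivity_aggregation")$score)
  g <- glance(cumulate(co, "global_reactivity"))
  expect_equal(g$n_lower + g$n_higher, 40)
})
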