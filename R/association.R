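# Resampling-validated rank correlations, assumption-gated two-group tests,
# permutation-bootstrapped ANCOVA and the Fisher-z sample-size rationale.

spearman_rho <- function(x, y) {
  stats::cor(mid_rank(x), mid_rank(y))
}

spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Spearman correlation with bootstrap CI and jackknife stability
#'
#' Rank correlation by the mid-rank Pearson formula, with (i) a
#' t-approximation p-value (exact permutation enumeration for n <= 10),
#' (ii) a seeded percentile-bootstrap confidence interval, and (iii)
#' leave-one-out jackknife diagnostics: the min/max correlation over all
#' single-subject deletions and an influence flag raised when any deletion
#' flips the sign or moves the estimate by more than 0.1.
#'
#' @param x,y Paired numeric vectors, n >= 5, no missing values.
#' @param level CI level (default 0.95).
#' @param B Bootstrap iterations (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `ps_association` with columns `n`, `rho`,
#'   `p_value`, `conf_low`, `conf_high`, `jackknife_min`, `jackknife_max`,
#'   `influence_flag`, `level`, `iterations`, `seed`.
#' @export
spearman_boosted <- function(x, y, level = 0.95, B = 2000L, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) ps_abort("need at least 5 complete pairs.", "ps_bad_argument")
  if (sd(x) == 0 || sd(y) == 0) {
    ps_abort("correlation undefined for a constant vector.",
             "ps_zero_variance")
  }
  rho <- spearman_rho(x, y)
  p <- if (n <= 10) {
    # exact permutation p-value by full enumeration
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(pr) spearman_rho(x, y[pr]))
    mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    spearman_p(rho, n)
  }
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
      spearman_rho(x[i], y[i])
    }, numeric(1))
  })
  ci <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  loo <- vapply(seq_len(n), function(i) spearman_rho(x[-i], y[-i]),
                numeric(1))
  influence <- any(sign(loo) != sign(rho) & loo != 0) ||
    max(abs(loo - rho)) > 0.1
  structure(
    tibble::tibble(n = n, rho = rho, p_value = p,
                   conf_low = ci[1], conf_high = ci[2],
                   jackknife_min = min(loo), jackknife_max = max(loo),
                   influence_flag = influence,
                   level = level, iterations = as.integer(B),
                   seed = as.integer(seed)),
    class = c("ps_association", class(tibble::tibble())))
}

# all permutations of 1..n (n <= 10), rows = permutations
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Sex-adjusted rank correlation
#'
#' Spearman correlation within each sex stratum, pooled on the Fisher-z
#' scale with weights `n_stratum - 3`.
#'
#' @param x,y Paired numeric vectors.
#' @param sex Stratification factor.
#' @return Tibble with the pooled `rho`, `p_value` (normal approximation on
#'   the pooled z) and per-stratum estimates in a list column.
#' @export
spearman_sex_adjusted <- function(x, y, sex) {
  sex <- droplevels(as.factor(sex))
  per <- purrr::map_dfr(levels(sex), function(s) {
    i <- sex == s & is.finite(x) & is.finite(y)
    tibble::tibble(stratum = s, n = sum(i),
                   rho = spearman_rho(x[i], y[i]))
  })
  w <- per$n - 3
  z <- sum(w * atanh(per$rho)) / sum(w)
  se <- 1 / sqrt(sum(w))
  tibble::tibble(rho = tanh(z),
                 p_value = 2 * pnorm(-abs(z / se)),
                 strata = list(per))
}

#' Assumption-gated two-group comparison
#'
#' Routes through [assumption_gate()]: Student's t-test on raw (or
#' Box-Cox-transformed) data when normality and homoscedasticity hold,
#' Mann-Whitney U otherwise.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector.
#' @param alpha Gate level.
#' @return Tibble with `test` (`"t"` or `"mann-whitney"`), `statistic`,
#'   `p_value`, `gate_decision`, `lambda`.
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) {
    ps_abort("exactly two groups required; use ANOVA for more.",
             "ps_bad_argument")
  }
  gate <- assumption_gate(values, group, alpha = alpha)
  if (gate$decision == "nonparametric") {
    ht <- stats::wilcox.test(values ~ group, exact = FALSE, correct = TRUE)
    test <- "mann-whitney"
  } else {
    v <- if (gate$decision == "transform-then-parametric")
      gate$transformed else values
    ht <- stats::t.test(v ~ group, var.equal = TRUE)
    test <- "t"
  }
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, gate_decision = gate$decision,
                 lambda = gate$lambda)
}

#' Covariate-adjusted comparison with a resampling p-value
#'
#' Fits the linear model `dependent ~ group + covariates` and computes the
#' group-effect F statistic; its p-value is the fraction of `B` resamples
#' with the group labels permuted (covariates fixed) whose F statistic is at
#' least as large.  The permutation scheme residualizes both the response
#' and the permuted group indicator on the covariates, so each resample
#' costs only vector arithmetic.
#'
#' @param dependent Numeric response.
#' @param group Factor (binary or categorical).
#' @param covariates Data frame of adjustment covariates (may be empty).
#' @param B Resampling iterations (default 10000).
#' @param seed Integer seed.
#' @return Tibble of class `ps_ancova`: `f_statistic`, `p_boot`,
#'   `p_parametric`, adjusted group means in a list column, `iterations`,
#'   `seed`.
#' @export
ancova_boosted <- function(dependent, group, covariates = NULL,
                           B = 10000L, seed = 1L) {
  group <- droplevels(as.factor(group))
  n <- length(dependent)
  G <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  X <- if (is.null(covariates) || !NCOL(covariates)) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  if (qr(X)$rank < ncol(X)) {
    ps_abort("collinear covariates.", "ps_collinear")
  }
  qx <- qr(X)
  resid_on_X <- function(M) M - X %*% qr.coef(qx, M)
  ey <- drop(resid_on_X(cbind(dependent)))
  eG <- resid_on_X(G)
  rss_reduced <- sum(ey^2)
  df2 <- n - ncol(X) - ncol(G)
  fstat_from <- function(eg) {
    rss_full <- if (ncol(eg) == 1) {
      # closed form for a single residualized group column
      g <- eg[, 1]
      rss_reduced - sum(g * ey)^2 / sum(g * g)
    } else {
      fit <- qr.fitted(qr(eg), ey)
      sum((ey - fit)^2)
    }
    ((rss_reduced - rss_full) / ncol(eg)) / (rss_full / df2)
  }
  f_obs <- fstat_from(eG)
  f_null <- with_seed(seed, {
    if (ncol(G) == 1) {
      # all permutations at once: residualize the n x B permuted-group
      # matrix on the covariates in a single solve
      P <- vapply(seq_len(B), function(b) G[sample.int(n), 1], numeric(n))
      EP <- P - X %*% qr.coef(qx, P)
      num <- colSums(EP * ey)^2 / colSums(EP * EP)
      rss_full <- rss_reduced - num
      (num / 1) / (rss_full / df2)
    } else {
      vapply(seq_len(B), function(b) {
        fstat_from(resid_on_X(G[sample.int(n), , drop = FALSE]))
      }, numeric(1))
    }
  })
  p_boot <- (1 + sum(f_null >= f_obs)) / (B + 1)
  p_par <- stats::pf(f_obs, ncol(G), df2, lower.tail = FALSE)
  # adjusted means: model prediction per group at the covariate means
  dat <- data.frame(.y = dependent, .g = group)
  if (!is.null(covariates) && NCOL(covariates)) {
    dat <- cbind(dat, as.data.frame(covariates))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  newdat <- dat[rep(1, nlevels(group)), , drop = FALSE]
  newdat$.g <- factor(levels(group), levels = levels(group))
  for (v in setdiff(names(newdat), c(".y", ".g"))) {
    newdat[[v]] <- if (is.numeric(dat[[v]])) mean(dat[[v]]) else dat[[v]][1]
  }
  adj_means <- rlang::set_names(stats::predict(fit, newdata = newdat),
                                levels(group))
  structure(
    tibble::tibble(f_statistic = f_obs, p_boot = p_boot,
                   p_parametric = p_par,
                   adjusted_means = list(adj_means),
                   iterations = as.integer(B), seed = as.integer(seed)),
    class = c("ps_ancova", class(tibble::tibble())))
}

#' Required sample size for detecting a correlation
#'
#' Fisher-z formula: `n = ((z_{1-alpha/2} + z_power) / atanh(r))^2 + 3`.
#'
#' @param r Minimal correlation to detect, in (0, 1).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0.5, 1).
#' @return Tibble with `n_ceiling` and `n_rounded_ten`.
#' @export
#' @examples
#' required_n(0.22, alpha = 0.01, power = 0.90)
required_n <- function(r, alpha = 0.05, power = 0.80) {
  assert_number(r, "r"); assert_number(alpha, "alpha", 0, 1)
  assert_number(power, "power", 0.5, 1)
  if (r <= 0 || r >= 1) {
    ps_abort("`r` must lie strictly in (0, 1); the formula diverges at 0.",
             "ps_bad_argument")
  }
  n <- ((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(r))^2 + 3
  tibble::tibble(n_exact = n,
                 n_ceiling = as.integer(ceiling(n)),
                 n_rounded_ten = as.integer(round(n / 10) * 10))
}

#' Correlate a cumulative score against whole variable sets
#'
#' Batch interface: runs [spearman_boosted()] of one score column against
#' every variable in the requested sets and returns a tidy table.
#'
#' @param cohort Cohort with score columns (see [add_reactivity_scores()]).
#' @param against Name of the score column (e.g. `"cum_reactivity_aggregation"`).
#' @param sets Character vector of variable-set names.
#' @param B,seed,level Passed to [spearman_boosted()].
#' @param fdr Add a Benjamini-Hochberg adjusted column (off by default; the
#'   primary outputs are unadjusted).
#' @return Tidy tibble: one row per (score, variable) pair.
#' @export
associate_sets <- function(cohort, against,
                           sets = c("morphology", "metabolic", "oxidative"),
                           B = 2000L, seed = 1L, level = 0.95, fdr = FALSE) {
  vs <- variable_sets(cohort)
  bad <- setdiff(sets, names(vs))
  if (length(bad)) {
    ps_abort(paste0("unknown variable sets: ", paste(bad, collapse = ", ")),
             "ps_bad_argument")
  }
  vars <- unlist(vs[sets], use.names = FALSE)
  out <- purrr::imap_dfr(rlang::set_names(vars), function(v, nm) {
    res <- spearman_boosted(cohort[[against]], cohort[[v]],
                            level = level, B = B,
                            seed = derive_seed(seed, match(v, vars)))
    dplyr::mutate(res, score = against, variable = v, .before = 1)
  })
  if (fdr) out$p_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
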