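# Screening and conditioning: outlier flagging (Grubbs / Tukey), kNN
# imputation of sparse missingness, and the distribution-assumption gate
# (Shapiro-Wilk + Brown-Forsythe, with Box-Cox rescue) that routes every
# comparison to a parametric or nonparametric test.

# iterative two-sided Grubbs critical value at level alpha
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Flag outlying observations
#'
#' `method = "tukey"` flags values outside the fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.  `method = "grubbs"` applies the
#' two-sided Grubbs test iteratively: the most extreme point is flagged and
#' removed while its statistic exceeds the alpha-level critical value, up to
#' `max_remove` removals.  Flags only — nothing is dropped.
#'
#' @param values Numeric vector; `NA`s are ignored.
#' @param method `"grubbs"` or `"tukey"`.
#' @param alpha Significance level for Grubbs (default 0.05).
#' @param k Tukey fence multiplier (default 1.5).
#' @param max_remove Maximum Grubbs removals per variable (default 2).
#' @return Integer vector of flagged indices into `values` (possibly empty).
#' @export
#' @examples
#' detect_outliers(c(1, 2, 3, 4, 100), method = "tukey")
detect_outliers <- function(values, method = c("grubbs", "tukey"),
                            alpha = 0.05, k = 1.5, max_remove = 2L) {
  method <- match.arg(method)
  finite <- which(is.finite(values))
  x <- values[finite]
  if (method == "tukey") {
    if (length(x) < 5) {
      ps_abort("tukey fences need at least 5 finite values.", "ps_bad_argument")
    }
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    out <- x < q[1] - k * iqr | x > q[2] + k * iqr
    return(finite[out])
  }
  if (length(x) < 3) {
    ps_abort("grubbs test needs at least 3 finite values.", "ps_bad_argument")
  }
  if (sd(x) == 0) {
    ps_abort("grubbs test undefined for a zero-variance vector.",
             "ps_zero_variance")
  }
  flagged <- integer(0)
  live <- seq_along(x)
  for (i in seq_len(max_remove)) {
    xi <- x[live]
    n <- length(xi)
    if (n < 3 || sd(xi) == 0) break
    dev <- abs(xi - mean(xi)) / sd(xi)
    j <- which.max(dev)
    if (dev[j] > grubbs_critical(n, alpha)) {
      flagged <- c(flagged, live[j])
      live <- live[-j]
    } else break
  }
  sort(finite[flagged])
}

#' Impute sparse missingness by k nearest neighbours
#'
#' Each missing cell in a variable with under 3% missingness is replaced by
#' the mean of that variable over the `k` donor subjects nearest in
#' Euclidean distance, computed on the standardized columns observed for
#' both subjects.  Variables at or above 3% missingness are left untouched
#' and reported.  Observed cells are never altered.
#'
#' @param cohort A data frame; non-numeric columns are carried through.
#' @param k Number of donor neighbours (default 5).
#' @return A list with `data` (imputed tibble) and `report` (tibble of
#'   `subject`, `variable`, `imputed_value`, `donors`, plus a `skipped`
#'   attribute listing variables over the 3% rule).
#' @export
impute_knn <- function(cohort, k = 5L) {
  if (!is.numeric(k) || k < 1) {
    ps_abort("`k` must be a positive integer.", "ps_bad_argument")
  }
  num_vars <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  X <- as.matrix(cohort[num_vars])
  n <- nrow(X)
  miss_frac <- colMeans(is.na(X))
  skipped <- num_vars[miss_frac >= 0.03]
  targets <- num_vars[miss_frac > 0 & miss_frac < 0.03]

  # standardize on observed values for distance computation
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0 | is.na(attr(Z, "scaled:scale"))] <- 0

  registry <- list()
  for (v in targets) {
    for (i in which(is.na(X[, v]))) {
      donors <- which(!is.na(X[, v]) & seq_len(n) != i)
      if (!length(donors)) {
        ps_abort(sprintf("no complete donor rows for variable '%s'.", v),
                 "ps_no_donors")
      }
      shared <- which(!is.na(Z[i, ]))
      d <- vapply(donors, function(jj) {
        common <- shared[!is.na(Z[jj, shared])]
        if (!length(common)) return(Inf)
        sqrt(sum((Z[i, common] - Z[jj, common])^2) / length(common))
      }, numeric(1))
      sel <- donors[order(d)][seq_len(min(k, length(donors)))]
      val <- mean(X[sel, v])
      X[i, v] <- val
      registry[[length(registry) + 1L]] <- tibble::tibble(
        subject = i, variable = v, imputed_value = val,
        donors = list(sel))
    }
  }
  report <- if (length(registry)) dplyr::bind_rows(registry) else
    tibble::tibble(subject = integer(), variable = character(),
                   imputed_value = numeric(), donors = list())
  attr(report, "skipped") <- skipped
  if (length(skipped)) {
    rlang::warn(paste0("variables at/above 3% missingness left unimputed: ",
                       paste(skipped, collapse = ", ")))
  }
  out <- cohort
  for (v in num_vars) out[[v]] <- X[, v]
  list(data = out, report = report)
}

# profile-likelihood Box-Cox lambda on a single positive sample
boxcox_lambda <- function(x, grid = seq(-2, 2, by = 0.05)) {
  stopifnot(all(x > 0))
  n <- length(x)
  lx <- log(x)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-8) lx else (x^l - 1) / l
    -n / 2 * log(var(y) * (n - 1) / n) + (l - 1) * sum(lx)
  }, numeric(1))
  grid[which.max(ll)]
}

boxcox_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Assumption gate for group comparisons
#'
#' Tests normality per group (Shapiro-Wilk) and homoscedasticity across
#' groups (Brown-Forsythe, i.e. Levene's test on deviations from medians)
#' at level `alpha`.  If either fails, a Box-Cox transform (maximum
#' likelihood lambda on positivity-shifted data) is attempted and the
#' assumptions re-checked.  The decision routes downstream comparisons.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (>= 2 groups, each with n >= 3).
#' @param alpha Gate level (default 0.05).
#' @return A list of class `ps_gate`: `decision` in
#'   `"parametric"` / `"transform-then-parametric"` / `"nonparametric"`,
#'   `lambda` (`NA` when no transform applied), `shift`, per-stage
#'   Shapiro-Wilk and Brown-Forsythe p-values, and `transformed` values
#'   when a transform was applied.
#' @export
assumption_gate <- function(values, group, alpha = 0.05) {
  group <- as.factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2) {
    ps_abort("need at least two groups.", "ps_bad_argument")
  }
  if (any(table(group) < 3)) {
    ps_abort("each group needs at least 3 observations.", "ps_bad_argument")
  }
  check <- function(x) {
    sw <- tapply(x, group, function(g) {
      if (length(unique(g)) < 3) return(0)       # degenerate: treat as failing
      stats::shapiro.test(g)$p.value
    })
    bf <- car::leveneTest(x, group, center = median)[1, "Pr(>F)"]
    list(sw = sw, bf = bf, ok = all(sw > alpha) && bf > alpha)
  }
  first <- check(values)
  if (first$ok) {
    return(structure(list(decision = "parametric", lambda = NA_real_,
                          shift = 0, shapiro_p = first$sw,
                          brown_forsythe_p = first$bf,
                          transformed = NULL),
                     class = "ps_gate"))
  }
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  lambda <- boxcox_lambda(values + shift)
  tx <- boxcox_apply(values + shift, lambda)
  second <- check(tx)
  if (second$ok) {
    structure(list(decision = "transform-then-parametric", lambda = lambda,
                   shift = shift, shapiro_p = second$sw,
                   brown_forsythe_p = second$bf, transformed = tx),
              class = "ps_gate")
  } else {
    structure(list(decision = "nonparametric", lambda = lambda,
                   shift = shift, shapiro_p = second$sw,
                   brown_forsythe_p = second$bf, transformed = NULL),
              class = "ps_gate")
  }
}

#' Screen a cohort: outliers, imputation and per-variable gating
#'
#' Convenience wrapper running [detect_outliers()] over every numeric
#' measurement column and [impute_knn()] over the table.
#'
#' @param cohort A cohort tibble.
#' @param outlier_method `"grubbs"` or `"tukey"`.
#' @param k Imputation neighbours.
#' @return List with `data` (imputed cohort), `outliers` (tibble
#'   `variable`, `index`, `value`, `method`) and `imputation` report.
#' @export
preprocess_cohort <- function(cohort, outlier_method = "tukey", k = 5L) {
  num_vars <- setdiff(
    names(cohort)[vapply(cohort, is.numeric, logical(1))], "age")
  flags <- purrr::map_dfr(num_vars, function(v) {
    idx <- tryCatch(detect_outliers(cohort[[v]], method = outlier_method),
                    plateletscore_error = function(e) integer(0))
    if (!length(idx)) return(NULL)
    tibble::tibble(variable = v, index = idx, value = cohort[[v]][idx],
                   method = outlier_method)
  })
  imp <- impute_knn(cohort, k = k)
  list(data = imp$data, outliers = flags, imputation = imp$report)
}
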