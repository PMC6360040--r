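# Logistic odds-ratio models with Hosmer-Lemeshow calibration, and the
# Cochrane forest construction: median-split 2x2 tables per predictor with a
# fixed-effects Mantel-Haenszel pooled odds ratio.

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Haldane-Anscombe 0.5 continuity correction
#' applied to every cell when any cell is zero, and a Woolf log-scale
#' confidence interval.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = exposure
#'   (0/1), columns = outcome (0/1), so `a = tab[2, 2]` exposed cases.
#' @param level CI level (default 0.95).
#' @return Tibble with `or`, `conf_low`, `conf_high`, `corrected`.
#' @export
#' @examples
#' or_2x2(matrix(c(10, 10, 10, 10), 2))  # OR = 1
or_2x2 <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    ps_abort("`tab` must be a 2x2 matrix of non-negative integer counts.",
             "ps_bad_argument")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ps_abort("odds ratio undefined: a margin of the table is empty.",
             "ps_empty_margin")
  }
  corrected <- any(tab == 0)
  tt <- if (corrected) tab + 0.5 else tab
  a <- tt[2, 2]; b <- tt[2, 1]; c <- tt[1, 2]; d <- tt[1, 1]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(or = or,
                 conf_low = exp(log(or) - z * se),
                 conf_high = exp(log(or) + z * se),
                 corrected = corrected)
}

#' Fixed-effects Mantel-Haenszel pooled odds ratio
#'
#' Pooled estimate `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over 2x2
#' strata, with the Robins-Breslow-Greenland variance for the CI and a
#' two-sided p-value from the log-OR z statistic.
#'
#' @param strata List of 2x2 count matrices with consistent orientation
#'   (rows = exposure 0/1, columns = outcome 0/1).
#' @param level CI level.
#' @return Tibble with `or`, `conf_low`, `conf_high`, `p_value`,
#'   `n_strata`.
#' @export
mh_pooled <- function(strata, level = 0.95) {
  if (is.matrix(strata)) strata <- list(strata)
  if (!length(strata)) ps_abort("need at least one stratum.",
                                "ps_bad_argument")
  get <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == c(2, 2)))
    c(a = tab[2, 2], b = tab[2, 1], c = tab[1, 2], d = tab[1, 1],
      n = sum(tab))
  }
  M <- t(vapply(strata, get, numeric(5)))
  R <- sum(M[, "a"] * M[, "d"] / M[, "n"])
  S <- sum(M[, "b"] * M[, "c"] / M[, "n"])
  if (R == 0 && S == 0) {
    ps_abort("all cross-products zero: pooled odds ratio undefined.",
             "ps_empty_margin")
  }
  or <- R / S
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (M[, "a"] + M[, "d"]) / M[, "n"]
  Q <- (M[, "b"] + M[, "c"]) / M[, "n"]
  Rv <- M[, "a"] * M[, "d"] / M[, "n"]
  Sv <- M[, "b"] * M[, "c"] / M[, "n"]
  var_log <- sum(P * Rv) / (2 * sum(Rv)^2) +
    sum(P * Sv + Q * Rv) / (2 * sum(Rv) * sum(Sv)) +
    sum(Q * Sv) / (2 * sum(Sv)^2)
  se <- sqrt(var_log)
  z <- qnorm(1 - (1 - level) / 2)
  zstat <- log(or) / se
  tibble::tibble(or = or,
                 conf_low = exp(log(or) - z * se),
                 conf_high = exp(log(or) + z * se),
                 p_value = 2 * pnorm(-abs(zstat)),
                 n_strata = length(strata))
}

# Hosmer-Lemeshow goodness of fit on fitted probabilities
hosmer_lemeshow <- function(y, phat, g = 10L) {
  breaks <- unique(quantile(phat, probs = seq(0, 1, length.out = g + 1)))
  grp <- cut(phat, breaks = breaks, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  nk <- tapply(y, grp, length)
  pk <- tapply(phat, grp, mean)
  exp_k <- nk * pk
  chi2 <- sum((obs - exp_k)^2 / (exp_k * (1 - pk)))
  df <- length(levels(droplevels(grp))) - 2
  tibble::tibble(chi_squared = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Multiple logistic regression with odds ratios and calibration
#'
#' Maximum-likelihood logistic fit of a dichotomized reactivity class on
#' one or more predictors plus an adjustment set; per-predictor odds ratios
#' with Wald 95% CIs, a likelihood-ratio chi-squared for dropping each
#' predictor, and the Hosmer-Lemeshow test on `g` groups of fitted risk.
#'
#' @param data Data frame (post-imputation, no missing cells used by the
#'   model).
#' @param outcome Name of the 0/1 outcome column.
#' @param predictors Character vector of predictor columns.
#' @param adjust Character vector of adjustment columns (e.g. age, sex).
#' @param g Hosmer-Lemeshow groups (default 10).
#' @param level CI level.
#' @return Object of class `ps_logistic`: list with `terms` tibble
#'   (`term`, `or`, `conf_low`, `conf_high`, `p_value`, `lr_chisq`,
#'   `lr_p`), `hosmer_lemeshow` tibble, `separation` flag and the `glm`
#'   fit.
#' @export
fit_logistic <- function(data, outcome, predictors, adjust = character(),
                         g = 10L, level = 0.95) {
  vars <- c(outcome, predictors, adjust)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    ps_abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
             "ps_missing_column")
  }
  df <- data[vars]
  if (anyNA(df)) ps_abort("impute missing cells before model fitting.",
                          "ps_missing_values")
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1))) {
    ps_abort("outcome must be a 0/1 class.", "ps_bad_argument")
  }
  rhs <- paste(c(predictors, adjust), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  sep_signal <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        sep_signal <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  separation <- sep_signal || !fit$converged
  if (separation) {
    rlang::warn("possible complete separation: coefficients unstable.")
  }
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - level) / 2)
  terms <- tibble::tibble(
    term = rownames(sm)[-1],
    estimate = sm[-1, 1],
    or = exp(sm[-1, 1]),
    conf_low = exp(sm[-1, 1] - z * sm[-1, 2]),
    conf_high = exp(sm[-1, 1] + z * sm[-1, 2]),
    p_value = sm[-1, 4])
  # likelihood-ratio chi-squared for dropping each named predictor
  lr <- purrr::map_dfr(predictors, function(v) {
    red <- stats::update(fit, stats::as.formula(paste(". ~ . -", v)))
    tibble::tibble(term = v,
                   lr_chisq = red$deviance - fit$deviance,
                   lr_p = stats::pchisq(red$deviance - fit$deviance,
                                        df = 1, lower.tail = FALSE))
  })
  terms <- dplyr::left_join(terms, lr, by = "term")
  hl <- hosmer_lemeshow(y, stats::fitted(fit), g = g)
  structure(list(terms = terms, hosmer_lemeshow = hl,
                 separation = separation, fit = fit,
                 outcome = outcome),
            class = "ps_logistic")
}

#' @rdname tidy-plateletscore
#' @method tidy ps_logistic
#' @export
tidy.ps_logistic <- function(x, ...) x$terms

#' @rdname tidy-plateletscore
#' @method glance ps_logistic
#' @export
glance.ps_logistic <- function(x, ...) {
  tibble::tibble(n = length(x$fit$y),
                 deviance = x$fit$deviance,
                 aic = x$fit$aic,
                 hl_chisq = x$hosmer_lemeshow$chi_squared,
                 hl_p = x$hosmer_lemeshow$p_value,
                 separation = x$separation)
}

#' Build Cochrane forest data over median-split predictors
#'
#' Dichotomizes every predictor at its own median (`<= Me` to 0, above to
#' 1, the same rule as the outcome classes), forms the 2x2 table of
#' predictor rank against outcome rank, computes per-predictor odds ratios
#' and pools them with the fixed-effects Mantel-Haenszel estimator.
#' Because the "strata" are correlated predictors measured on the same
#' subjects rather than independent subgroups, the pooled value is labelled
#' a descriptive pooled OR.  Optionally repeated within each sex.
#'
#' @param cohort Cohort with class columns (see [add_reactivity_scores()]).
#' @param outcome Name of a 0/1 class column (e.g.
#'   `"class_reactivity_aggregation"`).
#' @param predictors Character vector of numeric predictor columns.
#' @param stratify_by_sex Repeat the construction within each sex.
#' @return Object of class `ps_forest`: tibble with one row per
#'   (stratum, predictor) plus pooled rows (`predictor = "(pooled)"`),
#'   columns `stratum`, `predictor`, `a`, `b`, `c`, `d`, `or`, `conf_low`,
#'   `conf_high`, `p_value`, `pooled`.
#' @export
build_forest <- function(cohort, outcome, predictors,
                         stratify_by_sex = FALSE) {
  if (!outcome %in% names(cohort)) {
    ps_abort(sprintf("outcome column '%s' not found.", outcome),
             "ps_missing_column")
  }
  y <- cohort[[outcome]]
  if (!all(y %in% c(0, 1))) {
    ps_abort("outcome must be a 0/1 class column.", "ps_bad_argument")
  }
  strata_def <- if (stratify_by_sex) {
    lapply(rlang::set_names(levels(as.factor(cohort$sex))),
           function(s) cohort$sex == s)
  } else {
    list(all = rep(TRUE, nrow(cohort)))
  }
  rows <- purrr::imap_dfr(strata_def, function(idx, stratum) {
    tabs <- list()
    per <- purrr::map_dfr(predictors, function(v) {
      x <- cohort[[v]][idx]
      if (length(unique(x)) < 2) {
        rlang::warn(sprintf("predictor '%s' constant in stratum '%s': excluded.",
                            v, stratum))
        return(NULL)
      }
      xr <- dichotomize(x)$rank
      tab <- table(factor(xr, 0:1), factor(y[idx], 0:1))
      tabs[[v]] <<- unclass(tab)
      orr <- or_2x2(tab)
      tibble::tibble(stratum = stratum, predictor = v,
                     a = tab[2, 2], b = tab[2, 1],
                     c = tab[1, 2], d = tab[1, 1],
                     or = orr$or, conf_low = orr$conf_low,
                     conf_high = orr$conf_high,
                     p_value = NA_real_, pooled = FALSE)
    })
    pooled <- mh_pooled(tabs)
    dplyr::bind_rows(per, tibble::tibble(
      stratum = stratum, predictor = "(pooled)",
      a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
      or = pooled$or, conf_low = pooled$conf_low,
      conf_high = pooled$conf_high, p_value = pooled$p_value,
      pooled = TRUE))
  })
  structure(rows, class = c("ps_forest", class(rows)),
            outcome = outcome,
            note = paste("descriptive pooled OR: strata are correlated",
                         "predictors on the same subjects, not independent",
                         "subgroups"))
}

#' Forest plot of median-split odds ratios
#'
#' Log-scaled OR axis with square markers per predictor and a diamond-style
#' pooled row, mirroring the Cochrane convention.
#'
#' @param object A `ps_forest` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ps_forest
#' @export
autoplot.ps_forest <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      predictor = factor(.data$predictor,
                                         levels = rev(unique(.data$predictor))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "solid",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2.5, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ stratum) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = attr(object, "outcome")) +
    ggplot2::theme_minimal()
}
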