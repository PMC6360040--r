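# Discrimination machinery: forward-stepwise discriminant ranking by partial
# Wilks' lambda, canonical correlation with redundancy indices, and a
# four-classifier panel combined by majority voting.

# Wilks' lambda det(W)/det(T) for the given feature columns
wilks_lambda <- function(X, class, cols, ridge = 0) {
  if (!length(cols)) return(1)
  Xs <- X[, cols, drop = FALSE]
  Tm <- crossprod(scale(Xs, scale = FALSE))
  W <- Reduce(`+`, lapply(split(seq_len(nrow(Xs)), class), function(i) {
    crossprod(scale(Xs[i, , drop = FALSE], scale = FALSE))
  }))
  if (ridge > 0) {
    d <- diag(Tm)
    W <- W + diag(ridge * d, ncol(W))
    Tm <- Tm + diag(ridge * d, ncol(Tm))
  }
  dW <- det(W); dT <- det(Tm)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  max(min(dW / dT, 1), .Machine$double.eps)
}

#' Forward-stepwise discriminant ranking by partial Wilks' lambda
#'
#' Forward selection of discriminating variables between the two
#' reactivity classes: at each step the candidate with the smallest
#' partial Wilks' lambda (model lambda with the variable over model lambda
#' without it) enters if its F-test (the Mahalanobis-distance F
#' approximation) is significant at `p_enter`; after each entry, variables
#' whose removal F exceeds `p_remove` are dropped.  Lower partial lambda
#' means greater unique discriminatory contribution.
#'
#' @param data Data frame of numeric features.
#' @param class 0/1 (or two-level) class vector.
#' @param features Character vector of feature columns (default: all
#'   numeric columns of `data`).
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.05 / 0.10).
#' @return Object of class `ps_lda_rank`: `ranking` tibble (`term`,
#'   `lambda_partial`, `f_statistic`, `p_value`, ordered by lambda),
#'   `path` tibble of stepwise actions, `lambda_model`, `ridged` flag.
#' @export
lda_rank <- function(data, class, features = NULL,
                     p_enter = 0.05, p_remove = 0.10) {
  class <- droplevels(as.factor(class))
  if (nlevels(class) != 2 || any(table(class) == 0)) {
    ps_abort("`class` must have two non-empty levels.", "ps_bad_argument")
  }
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(features) < 2) {
    ps_abort("need at least two candidate features.", "ps_bad_argument")
  }
  X <- as.matrix(data[features])
  if (anyNA(X)) ps_abort("missing cells: impute first.", "ps_missing_values")
  n <- nrow(X); g <- nlevels(class)
  if (n <= length(features) + 2) {
    ps_abort("need n > p + 2 subjects.", "ps_bad_argument")
  }
  ridge <- 0
  lam <- function(cols) {
    l <- wilks_lambda(X, class, cols, ridge)
    if (is.na(l) && ridge == 0) {
      ridge <<- 1e-6
      rlang::warn("singular within-group covariance: ridge-stabilized.")
      l <- wilks_lambda(X, class, cols, ridge)
    }
    l
  }
  step_f <- function(l_partial, p_in_model) {
    # F for one variable given p_in_model others already in the model
    df2 <- n - g - p_in_model
    f <- ((1 - l_partial) / l_partial) * df2 / (g - 1)
    c(f = f, p = stats::pf(f, g - 1, df2, lower.tail = FALSE))
  }

  included <- character(0)
  path <- list()
  repeat {
    candidates <- setdiff(features, included)
    if (!length(candidates)) break
    l_now <- lam(included)
    cand <- purrr::map_dfr(candidates, function(v) {
      lp <- lam(c(included, v)) / l_now
      fp <- step_f(lp, length(included))
      tibble::tibble(term = v, lambda_partial = lp,
                     f_statistic = fp["f"], p_value = fp["p"])
    })
    best <- cand[which.min(cand$lambda_partial), ]
    if (best$p_value >= p_enter) break
    included <- c(included, best$term)
    path[[length(path) + 1L]] <- dplyr::mutate(best, action = "enter")
    # backward check
    repeat {
      if (length(included) < 2) break
      l_full <- lam(included)
      rem <- purrr::map_dfr(included, function(v) {
        lp <- l_full / lam(setdiff(included, v))
        fp <- step_f(lp, length(included) - 1)
        tibble::tibble(term = v, lambda_partial = lp,
                       f_statistic = fp["f"], p_value = fp["p"])
      })
      worst <- rem[which.max(rem$p_value), ]
      if (worst$p_value <= p_remove) break
      included <- setdiff(included, worst$term)
      path[[length(path) + 1L]] <- dplyr::mutate(worst, action = "remove")
    }
  }

  l_full <- lam(included)
  ranking <- if (length(included)) {
    purrr::map_dfr(included, function(v) {
      lp <- if (length(included) == 1) l_full else
        l_full / lam(setdiff(included, v))
      fp <- step_f(lp, length(included) - 1)
      tibble::tibble(term = v, lambda_partial = lp,
                     f_statistic = fp["f"], p_value = fp["p"])
    })
  } else {
    tibble::tibble(term = character(), lambda_partial = numeric(),
                   f_statistic = numeric(), p_value = numeric())
  }
  ranking <- dplyr::arrange(ranking, .data$lambda_partial)
  structure(list(ranking = ranking,
                 path = if (length(path)) dplyr::bind_rows(path) else
                   tibble::tibble(),
                 lambda_model = l_full,
                 included = included,
                 ridged = ridge > 0,
                 thresholds = c(p_enter = p_enter, p_remove = p_remove)),
            class = "ps_lda_rank")
}

#' @rdname tidy-plateletscore
#' @method tidy ps_lda_rank
#' @export
tidy.ps_lda_rank <- function(x, ...) x$ranking

#' Canonical correlation analysis with redundancy indices
#'
#' Canonical correlations between two standardized variable sets, with per
#' canonical pair Wilks' lambda and Bartlett chi-squared p-value, structure
#' loadings, extracted variance (mean squared loading per set, summed over
#' the significant variates) and total redundancy (extracted variance
#' weighted by the paired variate's squared canonical correlation).
#' Variates with Bartlett p below `report_alpha` are the "reported" ones
#' entering the extracted-variance and redundancy totals.
#'
#' @param set1,set2 Numeric matrices or data frames on the same subjects.
#' @param report_alpha Significance cut-off selecting reported variates
#'   (default 0.05); if none is significant the first variate is reported.
#' @return Object of class `ps_canonical`: `pairs` tibble (`variate`,
#'   `correlation`, `r_squared`, `wilks_lambda`, `chi_squared`, `df`,
#'   `p_value`), `extracted_variance` and `redundancy` (named per set, %),
#'   `loadings` (list of two matrices), `contributors` (per set,
#'   |loading| >= 0.3 on the first reported variate).
#' @export
canonical <- function(set1, set2, report_alpha = 0.05) {
  X <- scale(as.matrix(set1)); Y <- scale(as.matrix(set2))
  if (nrow(X) != nrow(Y)) ps_abort("sets must share subjects.",
                                   "ps_bad_argument")
  if (anyNA(X) || anyNA(Y)) ps_abort("sets must be column-complete.",
                                     "ps_missing_values")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (qr(X)$rank < p || qr(Y)$rank < q) {
    ps_abort(paste0("rank-deficient variable set: remove collinear or ",
                    "constant variables."), "ps_rank_deficient")
  }
  cc <- stats::cancor(X, Y)
  k <- length(cc$cor)
  rho <- pmin(pmax(cc$cor, 0), 1)    # guard numerical overshoot at 1
  # canonical variates and structure loadings
  U <- X %*% cc$xcoef[, seq_len(k), drop = FALSE]
  V <- Y %*% cc$ycoef[, seq_len(k), drop = FALSE]
  LX <- stats::cor(X, U)
  LY <- stats::cor(Y, V)
  # Bartlett sequential test: variate k against all later ones
  wilks <- vapply(seq_len(k), function(i)
    max(prod(1 - rho[i:k]^2), .Machine$double.xmin), numeric(1))
  chi <- -(n - 1 - (p + q + 1) / 2) * log(wilks)
  df <- (p - seq_len(k) + 1) * (q - seq_len(k) + 1)
  pval <- stats::pchisq(chi, df, lower.tail = FALSE)
  pairs <- tibble::tibble(variate = seq_len(k), correlation = rho,
                          r_squared = rho^2, wilks_lambda = wilks,
                          chi_squared = chi, df = df, p_value = pval)
  reported <- which(pval < report_alpha)
  if (!length(reported)) reported <- 1L
  ev1 <- 100 * sum(colMeans(LX[, reported, drop = FALSE]^2))
  ev2 <- 100 * sum(colMeans(LY[, reported, drop = FALSE]^2))
  rd1 <- 100 * sum(colMeans(LX[, reported, drop = FALSE]^2) * rho[reported]^2)
  rd2 <- 100 * sum(colMeans(LY[, reported, drop = FALSE]^2) * rho[reported]^2)
  contrib <- function(L) {
    l1 <- L[, reported[1]]
    names(l1)[abs(l1) >= 0.3]
  }
  structure(list(pairs = pairs,
                 extracted_variance = c(set1 = ev1, set2 = ev2),
                 redundancy = c(set1 = rd1, set2 = rd2),
                 reported_variates = reported,
                 loadings = list(set1 = LX, set2 = LY),
                 contributors = list(set1 = contrib(LX),
                                     set2 = contrib(LY)),
                 n = n),
            class = "ps_canonical")
}

#' @rdname tidy-plateletscore
#' @method tidy ps_canonical
#' @export
tidy.ps_canonical <- function(x, ...) x$pairs

#' @rdname tidy-plateletscore
#' @method glance ps_canonical
#' @export
glance.ps_canonical <- function(x, ...) {
  tibble::tibble(n = x$n,
                 first_correlation = x$pairs$correlation[1],
                 first_r_squared = x$pairs$r_squared[1],
                 wilks_lambda = x$pairs$wilks_lambda[1],
                 p_value = x$pairs$p_value[1],
                 extracted_variance_set2 = x$extracted_variance["set2"],
                 redundancy_set2 = x$redundancy["set2"])
}
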