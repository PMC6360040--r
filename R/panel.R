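# Classifier panel (kNN, SVM, naive Bayes, adaptive-spline logistic) with
# leave-one-out evaluation and majority-vote consensus scoring.

# ---- minimal multivariate adaptive regression splines (degree 1) ----

mars_basis <- function(X, terms) {
  B <- matrix(1, nrow(X), 1)
  for (tm in terms) {
    h <- if (tm$dir > 0) pmax(X[, tm$var] - tm$knot, 0) else
      pmax(tm$knot - X[, tm$var], 0)
    B <- cbind(B, h)
  }
  B
}

# forward pair-wise hinge selection, GCV backward prune, logistic refit
fit_mars_logistic <- function(X, y, max_terms = 10L, n_knots = 7L,
                              penalty = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    unique(quantile(X[, j], probs = seq(0.1, 0.9, length.out = n_knots),
                    names = FALSE))
  })
  terms <- list()
  rss <- function(B) {
    f <- .lm.fit(B, y)
    sum(f$residuals^2)
  }
  best_rss <- rss(mars_basis(X, terms))
  repeat {
    if (length(terms) >= max_terms) break
    cand_best <- NULL
    for (j in seq_len(ncol(X))) {
      for (t in knots[[j]]) {
        pair <- list(list(var = j, knot = t, dir = 1),
                     list(var = j, knot = t, dir = -1))
        B <- mars_basis(X, c(terms, pair))
        if (qr(B)$rank < ncol(B)) next
        r <- rss(B)
        if (is.null(cand_best) || r < cand_best$rss) {
          cand_best <- list(pair = pair, rss = r)
        }
      }
    }
    if (is.null(cand_best) || cand_best$rss > best_rss * (1 - 1e-4)) break
    terms <- c(terms, cand_best$pair)
    best_rss <- cand_best$rss
  }
  # backward prune on the GCV criterion
  gcv <- function(tms) {
    B <- mars_basis(X, tms)
    m <- ncol(B)
    cm <- m + penalty * (m - 1) / 2
    if (cm >= n) return(Inf)
    (rss(B) / n) / (1 - cm / n)^2
  }
  best_gcv <- gcv(terms)
  # never prune below one hinge: a constant model evaluated leave-one-out
  # degenerates to anti-majority prediction under balanced classes
  while (length(terms) > 1) {
    drop_gcv <- vapply(seq_along(terms),
                       function(i) gcv(terms[-i]), numeric(1))
    i <- which.min(drop_gcv)
    if (drop_gcv[i] <= best_gcv) {
      terms <- terms[-i]
      best_gcv <- drop_gcv[i]
    } else break
  }
  B <- mars_basis(X, terms)
  fit <- suppressWarnings(
    stats::glm.fit(B, y, family = stats::binomial()))
  list(terms = terms, coef = fit$coefficients)
}

predict_mars_logistic <- function(model, X) {
  B <- mars_basis(as.matrix(X), model$terms)
  co <- model$coef
  co[is.na(co)] <- 0
  as.integer(stats::plogis(drop(B %*% co)) > 0.5)
}

# ---- k nearest neighbours with configurable metric ----

pairwise_dist <- function(A, B, metric) {
  if (metric == "euclidean") {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  } else {                                    # chebyshev
    out <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A))) {
      out <- pmax(out, abs(outer(A[, j], B[, j], "-")))
    }
    out
  }
}

knn_predict_loo <- function(D, y, k) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    nb <- order(D[i, -i])[seq_len(k)]
    votes <- y[-i][nb]
    as.integer(mean(votes) >= 0.5)
  }, integer(1))
}

# ---- the panel ----

#' Run the classifier panel
#'
#' Trains and evaluates k nearest neighbours (Chebyshev distance by
#' default, `k` selected by leave-one-out error over `k_grid`), a linear
#' support vector machine, a naive Bayes classifier and an adaptive-spline
#' logistic classifier, each predicting the dichotomized reactivity class.
#' Evaluation is leave-one-out by default (`cv = "none"` scores in-sample).
#'
#' @param data Data frame of features.
#' @param class 0/1 class vector.
#' @param features Feature columns (default: all numeric columns).
#' @param methods Subset of `c("knn", "svm", "naive_bayes", "mars")`.
#' @param cv `"loo"` or `"none"`.
#' @param knn_distance `"chebyshev"` or `"euclidean"`.
#' @param k_grid Candidate neighbourhood sizes for kNN.
#' @param svm_cost Linear-SVM cost parameter.
#' @param mars_max_terms Maximum hinge bases for the spline classifier.
#' @param seed Integer seed (logged; the panel is deterministic given it).
#' @return Object of class `ps_panel`: `predictions` tibble (subject, true
#'   class, one column per classifier), `accuracy` tibble (`method`,
#'   `percent_correct`), `config` list.
#' @export
run_panel <- function(data, class, features = NULL,
                      methods = c("knn", "svm", "naive_bayes", "mars"),
                      cv = c("loo", "none"),
                      knn_distance = c("chebyshev", "euclidean"),
                      k_grid = c(3, 5, 7, 9),
                      svm_cost = 1, mars_max_terms = 10L, seed = 1L) {
  cv <- match.arg(cv)
  knn_distance <- match.arg(knn_distance)
  methods <- match.arg(methods, several.ok = TRUE)
  y <- as.integer(class)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    ps_abort("`class` must be 0/1 with both classes present.",
             "ps_bad_argument")
  }
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  X <- scale(as.matrix(data[features]))
  if (anyNA(X)) ps_abort("complete feature matrix required.",
                         "ps_missing_values")
  n <- nrow(X)
  preds <- list()

  loo_refit <- function(fit_fun, pred_fun) {
    vapply(seq_len(n), function(i) {
      m <- fit_fun(X[-i, , drop = FALSE], y[-i])
      pred_fun(m, X[i, , drop = FALSE])
    }, integer(1))
  }

  with_seed(seed, {
    if ("knn" %in% methods) {
      D <- pairwise_dist(X, X, knn_distance)
      k_err <- vapply(k_grid, function(k) {
        mean(knn_predict_loo(D, y, k) != y)
      }, numeric(1))
      k_best <- k_grid[which.min(k_err)]
      preds$knn <- if (cv == "loo") knn_predict_loo(D, y, k_best) else
        vapply(seq_len(n), function(i) {
          nb <- order(D[i, ])[seq_len(k_best)]   # self included in-sample
          as.integer(mean(y[nb]) >= 0.5)
        }, integer(1))
      attr(preds$knn, "k") <- k_best
    }
    if ("svm" %in% methods) {
      fit_svm <- function(Xt, yt) {
        e1071::svm(Xt, factor(yt, levels = 0:1), kernel = "linear",
                   cost = svm_cost, scale = FALSE)
      }
      pred_svm <- function(m, Xn) {
        as.integer(as.character(stats::predict(m, Xn)))
      }
      preds$svm <- if (cv == "loo") loo_refit(fit_svm, pred_svm) else {
        m <- fit_svm(X, y); pred_svm(m, X)
      }
    }
    if ("naive_bayes" %in% methods) {
      fit_nb <- function(Xt, yt) {
        e1071::naiveBayes(as.data.frame(Xt), factor(yt, levels = 0:1))
      }
      pred_nb <- function(m, Xn) {
        as.integer(as.character(
          stats::predict(m, as.data.frame(Xn), type = "class")))
      }
      preds$naive_bayes <- if (cv == "loo") loo_refit(fit_nb, pred_nb) else {
        m <- fit_nb(X, y); pred_nb(m, X)
      }
    }
    if ("mars" %in% methods) {
      fit_m <- function(Xt, yt) {
        fit_mars_logistic(Xt, yt, max_terms = mars_max_terms)
      }
      pred_m <- function(m, Xn) predict_mars_logistic(m, Xn)
      preds$mars <- if (cv == "loo") loo_refit(fit_m, pred_m) else {
        m <- fit_m(X, y); pred_m(m, X)
      }
    }
  })

  predictions <- tibble::tibble(subject = seq_len(n), truth = y)
  for (m in names(preds)) predictions[[m]] <- as.integer(preds[[m]])
  accuracy <- purrr::map_dfr(names(preds), function(m) {
    tibble::tibble(method = m,
                   percent_correct = 100 * mean(preds[[m]] == y))
  })
  config <- list(methods = methods, cv = cv, knn_distance = knn_distance,
                 knn_k = attr(preds$knn, "k"), k_grid = k_grid,
                 svm_cost = svm_cost, mars_max_terms = mars_max_terms,
                 seed = seed, features = features)
  structure(list(predictions = predictions, accuracy = accuracy,
                 config = config),
            class = "ps_panel")
}

#' Majority-vote consensus over the classifier panel
#'
#' Per-subject majority vote across the panel's predictions; an exact tie
#' is an abstention, counted as incorrect (the tie-break rule is recorded
#' in the output).
#'
#' @param panel A `ps_panel` object, or a data frame whose first two
#'   columns are `subject` and `truth` followed by one 0/1 prediction
#'   column per judge.
#' @return Tibble of class `ps_consensus` with `n`, `n_judges`,
#'   `consensus_percent_correct`, `n_abstain`, `tie_rule`, per-judge
#'   agreement with the consensus in a list column, and the per-subject
#'   consensus in a list column.
#' @export
vote_judges <- function(panel) {
  predictions <- if (inherits(panel, "ps_panel")) panel$predictions else
    tibble::as_tibble(panel)
  judges <- setdiff(names(predictions), c("subject", "truth"))
  if (length(judges) < 2) {
    ps_abort("need at least two judges.", "ps_bad_argument")
  }
  P <- as.matrix(predictions[judges])
  votes1 <- rowSums(P)
  half <- length(judges) / 2
  consensus <- ifelse(votes1 > half, 1L, ifelse(votes1 < half, 0L, NA_integer_))
  truth <- predictions$truth
  correct <- !is.na(consensus) & consensus == truth
  agreement <- purrr::map_dbl(judges, function(j) {
    mean(P[, j] == consensus, na.rm = TRUE)
  })
  structure(
    tibble::tibble(n = nrow(P), n_judges = length(judges),
                   consensus_percent_correct = 100 * mean(correct),
                   n_abstain = sum(is.na(consensus)),
                   tie_rule = "abstain-counted-incorrect",
                   judge_agreement = list(
                     rlang::set_names(agreement, judges)),
                   consensus = list(consensus)),
    class = c("ps_consensus", class(tibble::tibble())))
}

#' @rdname tidy-plateletscore
#' @method tidy ps_panel
#' @export
tidy.ps_panel <- function(x, ...) x$accuracy

#' @rdname tidy-plateletscore
#' @method glance ps_panel
#' @export
glance.ps_panel <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$accuracy, names_from = "method",
                             values_from = "percent_correct")
  dplyr::mutate(wide, n = nrow(x$predictions), cv = x$config$cv)
}
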