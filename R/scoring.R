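# The composite reactivity construct: van der Waerden normal scores,
# cumulative scores over named variable sets, and median dichotomization
# into lower (rank 0) / higher (rank 1) reactivity classes.

#' van der Waerden normal scores
#'
#' Maps each value to the standard-normal quantile of its mid-rank:
#' `score_i = qnorm(r_i / (n + 1))` where `r_i` is the average rank
#' (ties share a score).  Strictly monotone in the input and invariant
#' under any strictly increasing transform of it.
#'
#' @param values Numeric vector, all finite, length >= 2.
#' @return Numeric vector of normal scores.
#' @export
#' @examples
#' vdw_scores(c(5, 1, 9))   # 0, -0.6745, +0.6745
vdw_scores <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    ps_abort("`values` must be numeric with length >= 2.", "ps_bad_argument")
  }
  if (any(!is.finite(values))) {
    ps_abort("non-finite values: impute before normal-scoring.",
             "ps_nonfinite")
  }
  qnorm(mid_rank(values) / (length(values) + 1))
}

#' Integrative aggregometry indicator
#'
#' The summary combining the maximal aggregation amplitude and the area
#' under the aggregometric curve for one agonist: `(Amax * AUC) / 1000`.
#'
#' @param amax Maximal aggregation (aggregometer units), >= 0.
#' @param auc Area under the aggregation curve, >= 0.
#' @return `(amax * auc) / 1000`, vectorized.
#' @export
#' @examples
#' integrative_indicator(100, 500)  # 50
integrative_indicator <- function(amax, auc) {
  if (any(!is.finite(amax)) || any(!is.finite(auc)) ||
      any(amax < 0) || any(auc < 0)) {
    ps_abort("`amax` and `auc` must be finite and non-negative.",
             "ps_bad_argument")
  }
  amax * auc / 1000
}

#' Component definitions of the cumulative platelet scores
#'
#' The named variable sets each cumulative score sums over:
#' * `reactivity_aggregation` — Amax under AA, collagen and ADP;
#' * `activation` — P-selectin and activated GPIIb/IIIa on resting platelets;
#' * `p_selectin_expression` — agonist-stimulated P-selectin (AA, collagen);
#' * `gpiibiiia_expression` — agonist-stimulated activated GPIIb/IIIa;
#' * `reactivity_flow_cytometry` — the four stimulated antigen expressions;
#' * `global_reactivity` — the three Amax plus the four stimulated
#'   antigen expressions (aggregometry and flow cytometry together).
#'
#' @return Named list of character vectors of cohort column names.
#' @export
score_sets <- function() {
  list(
    reactivity_aggregation = c("amax_aa", "amax_col", "amax_adp"),
    activation = c("psel_rest", "gp_rest"),
    p_selectin_expression = c("psel_aa", "psel_col"),
    gpiibiiia_expression = c("gp_aa", "gp_col"),
    reactivity_flow_cytometry = c("psel_aa", "psel_col", "gp_aa", "gp_col"),
    global_reactivity = c("amax_aa", "amax_col", "amax_adp",
                          "psel_aa", "psel_col", "gp_aa", "gp_col")
  )
}

#' Cumulative normal score over a component set
#'
#' Normal-scores each component column and sums the scores per subject
#' (summation, not averaging, so the composite's spread grows with the
#' number of components).
#'
#' @param data Data frame holding the component columns.
#' @param score_name One of `names(score_sets())`, or any name if
#'   `components` is given explicitly.
#' @param components Optional character vector of column names overriding
#'   the built-in set definitions.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return An object of class `ps_cum_score`: a list with `score_name`,
#'   `components`, `score` (numeric per subject), `median`, and `rank`
#'   (0/1 class from [dichotomize()]).
#' @export
cumulate <- function(data, score_name, components = NULL,
                     aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(components)) {
    sets <- score_sets()
    if (!score_name %in% names(sets)) {
      ps_abort(sprintf("unknown score '%s'; give `components` explicitly.",
                       score_name), "ps_bad_argument")
    }
    components <- sets[[score_name]]
  }
  missing_cols <- setdiff(components, names(data))
  if (length(missing_cols)) {
    ps_abort(paste0("missing component columns: ",
                    paste(missing_cols, collapse = ", ")),
             "ps_missing_column")
  }
  S <- vapply(components, function(v) vdw_scores(data[[v]]),
              numeric(nrow(data)))
  score <- if (aggregate == "sum") rowSums(S) else rowMeans(S)
  d <- dichotomize(score)
  structure(list(score_name = score_name, components = components,
                 aggregate = aggregate, score = score,
                 median = d$median, rank = d$rank),
            class = "ps_cum_score")
}

#' Median dichotomization into lower/higher classes
#'
#' Rank 0 ("lower") when the score is at or below the sample median
#' (interpolated, type 7), rank 1 ("higher") above it.  With distinct
#' scores and odd n this puts `(n + 1) / 2` subjects in rank 0.
#'
#' @param score Numeric vector, length >= 2.
#' @return List with `rank` (integer 0/1 vector) and `median`.
#' @export
#' @examples
#' dichotomize(c(1, 2, 3, 4))$rank   # 0 0 1 1
dichotomize <- function(score) {
  if (!is.numeric(score) || length(score) < 2 || any(!is.finite(score))) {
    ps_abort("`score` must be finite numeric with length >= 2.",
             "ps_bad_argument")
  }
  me <- median(score)
  rank <- as.integer(score > me)
  if (all(rank == 0L)) {
    rlang::warn("constant score: every subject assigned rank 0.")
  }
  list(rank = rank, median = me)
}

#' Append all cumulative scores and classes to a cohort
#'
#' Adds, per score in [score_sets()], a `cum_<name>` column with the
#' cumulative normal score and a `class_<name>` 0/1 column with its
#' median-dichotomized class; per-variable normal scores of the component
#' columns are added under `vdw_<column>`.
#'
#' @param cohort Complete (post-imputation) cohort data frame.
#' @param scores Character vector of score names (default: all).
#' @return The cohort with score columns appended.
#' @export
add_reactivity_scores <- function(cohort, scores = names(score_sets())) {
  all_components <- unique(unlist(score_sets()[scores]))
  for (v in intersect(all_components, names(cohort))) {
    cohort[[paste0("vdw_", v)]] <- vdw_scores(cohort[[v]])
  }
  for (s in scores) {
    cs <- cumulate(cohort, s)
    cohort[[paste0("cum_", s)]] <- cs$score
    cohort[[paste0("class_", s)]] <- cs$rank
  }
  cohort
}

#' @export
print.ps_cum_score <- function(x, ...) {
  cat(sprintf("Cumulative score '%s' (%s of %d components)\n",
              x$score_name, x$aggregate, length(x$components)))
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  cat(sprintf("  median %.4f; class sizes: rank0 = %d, rank1 = %d\n",
              x$median, sum(x$rank == 0), sum(x$rank == 1)))
  invisible(x)
}

#' @rdname tidy-plateletscore
#' @method tidy ps_cum_score
#' @export
tidy.ps_cum_score <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$score),
                 score_name = x$score_name,
                 score = x$score,
                 rank = x$rank)
}

#' @rdname tidy-plateletscore
#' @method glance ps_cum_score
#' @export
glance.ps_cum_score <- function(x, ...) {
  tibble::tibble(score_name = x$score_name,
                 n = length(x$score),
                 n_components = length(x$components),
                 median = x$median,
                 n_lower = sum(x$rank == 0),
                 n_higher = sum(x$rank == 1))
}
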