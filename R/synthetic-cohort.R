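# Gaussian-copula synthetic cohort generator
#
# Reproduces the statistical shape assumed by the downstream stages: per-sex
# marginal distributions (back-solved from published medians/IQRs) coupled by
# a Gaussian copula whose Pearson matrix is derived from target Spearman
# correlations via r = 2*sin(pi*rho_s/6).

#' Marginal specification for the default study population
#'
#' One row per measured variable: distribution family, per-sex median and
#' quartile targets, variable-set membership and units.  Families are
#' `"normal"` (symmetric analytes reported as mean +/- SD),
#' `"lognormal"` (right-skewed biochemistry and reactivity readouts; an
#' optional positivity `shift` is supported) and `"beta"` (bounded
#' variables, scaled to `[lower, upper]`).  Parameters are back-solved so
#' that the configured median and IQR are matched exactly (normal,
#' shifted-lognormal) or by moments (scaled beta).
#'
#' Variables without published summaries (thromboxane, TAS/TOS, aggregometry
#' AUC) carry synthetic defaults chosen to be physiologically plausible; see
#' the methods vignette.
#'
#' @return A tibble with columns `variable`, `set`, `family`, `units`,
#'   `q25_f`, `med_f`, `q75_f`, `q25_m`, `med_m`, `q75_m`, `shift`,
#'   `lower`, `upper`.
#' @export
default_marginals <- function() {
  # helper: quartile triplet of a normal with given mean and sd
  nq <- function(m, s) c(m - 0.6745 * s, m, m + 0.6745 * s)
  row <- function(variable, set, family, units, f, m,
                  shift = 0, lower = 0, upper = NA_real_) {
    tibble::tibble(variable = variable, set = set, family = family,
                   units = units,
                   q25_f = f[1], med_f = f[2], q75_f = f[3],
                   q25_m = m[1], med_m = m[2], q75_m = m[3],
                   shift = shift, lower = lower, upper = upper)
  }
  dplyr::bind_rows(
    row("age",      "demographic", "beta",   "years", c(61.25, 62.5, 63.75), c(61.25, 62.5, 63.75), lower = 60, upper = 65),
    # blood morphology
    row("wbc",      "morphology", "lognormal", "10^3/mm^3", c(4.9, 5.6, 6.6),    c(5.2, 6.0, 7.1)),
    row("rbc",      "morphology", "normal",    "10^6/mm^3", nq(4.3, 0.3),        nq(4.6, 0.4)),
    row("hgb",      "morphology", "normal",    "g/dl",      c(12.7, 13.3, 13.8), c(13.8, 14.4, 15.1)),
    row("hct",      "morphology", "beta",      "%",         c(36.9, 38.6, 40.0), c(39.5, 41.1, 43.0), upper = 100),
    row("mcv",      "morphology", "normal",    "fl",        c(86.4, 88.4, 90.3), c(86.2, 88.1, 91.7)),
    row("plt",      "morphology", "lognormal", "10^3/mm^3", c(198.5, 225.5, 265.0), c(168, 196, 226)),
    row("mpv",      "morphology", "normal",    "um^3",      c(10.8, 11.3, 12.1), c(10.7, 11.4, 12.1)),
    row("pct",      "morphology", "lognormal", "%",         c(0.23, 0.26, 0.29), c(0.19, 0.22, 0.25)),
    row("pdw",      "morphology", "lognormal", "fl",        c(12.6, 13.5, 15.6), c(12.3, 13.9, 15.7)),
    row("p_lcr",    "morphology", "normal",    "%",         nq(36.6, 8.0),       nq(36.0, 7.5)),
    row("lymph",    "morphology", "lognormal", "10^3/mm^3", c(1.6, 1.96, 2.3),  c(1.6, 1.94, 2.4)),
    row("mono",     "morphology", "lognormal", "10^3/mm^3", c(0.40, 0.50, 0.58), c(0.48, 0.57, 0.72)),
    row("neu",      "morphology", "lognormal", "10^3/mm^3", c(2.50, 3.00, 3.76), c(2.66, 3.18, 3.89)),
    row("eos",      "morphology", "lognormal", "10^3/mm^3", c(0.09, 0.13, 0.18), c(0.11, 0.16, 0.25)),
    row("baso",     "morphology", "lognormal", "10^3/mm^3", c(0.02, 0.03, 0.045), c(0.02, 0.03, 0.045)),
    # metabolic / serum biochemistry
    row("tc",       "metabolic", "lognormal", "mg/dl",   c(183.5, 222.0, 253.1), c(166.4, 187.2, 219.0)),
    row("tg",       "metabolic", "lognormal", "mg/dl",   c(76.8, 111.7, 159.8),  c(78.4, 111.2, 167.1)),
    row("hdl",      "metabolic", "lognormal", "mg/dl",   c(45.7, 54.1, 64.3),    c(38.7, 44.3, 51.1)),
    row("ldl",      "metabolic", "lognormal", "mg/dl",   c(108.8, 140.0, 170.8), c(100.1, 115.6, 146.5)),
    row("glucose",  "metabolic", "lognormal", "mg/dl",   c(89.3, 96.3, 105.8),   c(93.8, 101.0, 113.1)),
    row("uric_acid","metabolic", "normal",    "mg/dl",   nq(4.3, 1.2),           nq(5.4, 1.1)),
    row("hcy",      "metabolic", "lognormal", "umol/l",  c(12.3, 14.2, 16.2),    c(13.1, 15.7, 18.1)),
    row("vwf",      "metabolic", "lognormal", "ug/ml",   c(4.9, 5.5, 6.1),       c(4.9, 5.5, 6.1)),
    row("vcam",     "metabolic", "lognormal", "ng/ml",   c(248, 270, 295),       c(248, 270, 295)),
    row("icam",     "metabolic", "lognormal", "ng/ml",   c(203, 210, 217),       c(203, 210, 217)),
    row("txb2",     "metabolic", "lognormal", "ng/ml",   c(90, 150, 250),        c(90, 150, 250)),
    # oxidative stress markers
    row("nh2_plt",    "oxidative", "lognormal", "nmol/ug protein", c(0.05, 0.20, 2.0),  c(0.05, 0.20, 2.0)),
    row("nh2_plasma", "oxidative", "lognormal", "mmol/mg protein", c(11.0, 17.0, 26.0), c(11.0, 17.0, 26.0)),
    row("sh_plt",     "oxidative", "lognormal", "umol/ug protein", c(2.0, 2.9, 30.0),   c(2.0, 2.9, 30.0)),
    row("sh_plasma",  "oxidative", "lognormal", "umol/ug protein", c(0.02, 0.03, 0.045), c(0.02, 0.03, 0.045)),
    row("pox_plt",    "oxidative", "lognormal", "nmol/ug protein", c(0.5, 1.2, 25.0),   c(0.5, 1.2, 25.0)),
    row("pox_plasma", "oxidative", "lognormal", "mmol/l",          c(0.02, 0.25, 1.3),  c(0.02, 0.25, 1.3)),
    row("o2_plt",     "oxidative", "lognormal", "nmol/min",        c(0.15, 0.45, 5.0),  c(0.15, 0.45, 5.0)),
    row("o2_plt_hcy", "oxidative", "lognormal", "nmol/min",        c(0.15, 0.55, 6.5),  c(0.15, 0.55, 6.5)),
    row("tas",        "oxidative", "lognormal", "mmol/l",          c(1.3, 1.6, 1.9),    c(1.3, 1.6, 1.9)),
    row("tos",        "oxidative", "lognormal", "umol/l",          c(8, 12, 18),        c(8, 12, 18)),
    # platelet reactivity readouts
    row("amax_aa",  "reactivity", "lognormal", "AU", c(117.4, 134.6, 152.4), c(101.3, 123.2, 137.3)),
    row("amax_col", "reactivity", "lognormal", "AU", c(137.3, 158.3, 184.9), c(121.9, 146.8, 166.5)),
    row("amax_adp", "reactivity", "lognormal", "AU", c(114.8, 128.3, 144.8), c(94.0, 113.0, 131.0)),
    row("auc_aa",   "reactivity", "lognormal", "AU*min", c(1150, 1350, 1550), c(1000, 1230, 1400)),
    row("auc_col",  "reactivity", "lognormal", "AU*min", c(1400, 1600, 1850), c(1200, 1470, 1700)),
    row("auc_adp",  "reactivity", "lognormal", "AU*min", c(1150, 1280, 1450), c(940, 1130, 1310)),
    row("psel_rest","reactivity", "lognormal", "% positive", c(2.2, 6.1, 14.5), c(2.2, 6.1, 14.5)),
    row("gp_rest",  "reactivity", "lognormal", "% positive", c(2.0, 7.0, 22.0), c(2.0, 7.0, 22.0)),
    row("psel_aa",  "reactivity", "lognormal", "% positive", c(15, 33, 52),     c(15, 33, 52)),
    row("psel_col", "reactivity", "lognormal", "% positive", c(12, 28, 48),     c(12, 28, 48)),
    row("gp_aa",    "reactivity", "lognormal", "% positive", c(18, 35, 53),     c(18, 35, 53)),
    row("gp_col",   "reactivity", "lognormal", "% positive", c(17, 36, 56),     c(17, 36, 56))
  )
}

#' Target Spearman correlations of the default cohort
#'
#' Pairwise rank-correlation targets combining (i) the study's reported
#' associations between platelet reactivity and morphology, biochemistry and
#' oxidative markers, and (ii) conventional within-panel structure (e.g.
#' PLT-PCT, RBC-HGB-HCT, agonist-to-agonist reactivity coupling) needed for a
#' realistic joint distribution.  Returned in long form; assembled into a
#' matrix (with nearest-positive-definite repair if required) by
#' [simulation_config()].
#'
#' @return A tibble with columns `var1`, `var2`, `rho` (target Spearman).
#' @export
default_rank_correlations <- function() {
  p <- function(a, b, r) tibble::tibble(var1 = a, var2 = b, rho = r)
  dplyr::bind_rows(
    # within blood morphology
    p("plt", "pct", 0.90), p("mpv", "p_lcr", 0.85), p("mpv", "pdw", 0.80),
    p("pdw", "p_lcr", 0.75), p("mpv", "plt", -0.30), p("mpv", "pct", 0.05),
    p("rbc", "hgb", 0.80), p("rbc", "hct", 0.85), p("hgb", "hct", 0.90),
    p("wbc", "neu", 0.85), p("wbc", "lymph", 0.55), p("wbc", "mono", 0.50),
    p("wbc", "eos", 0.30), p("neu", "lymph", 0.20),
    # within metabolic panel
    p("tc", "ldl", 0.90), p("tc", "hdl", 0.30), p("tc", "tg", 0.30),
    p("tg", "hdl", -0.35),
    # within reactivity panel
    p("amax_aa", "amax_col", 0.60), p("amax_aa", "amax_adp", 0.60),
    p("amax_col", "amax_adp", 0.60),
    p("auc_aa", "amax_aa", 0.85), p("auc_col", "amax_col", 0.85),
    p("auc_adp", "amax_adp", 0.85),
    p("auc_aa", "auc_col", 0.55), p("auc_aa", "auc_adp", 0.55),
    p("auc_col", "auc_adp", 0.55),
    p("psel_aa", "psel_col", 0.70), p("gp_aa", "gp_col", 0.70),
    p("psel_aa", "gp_aa", 0.50), p("psel_col", "gp_col", 0.50),
    p("psel_rest", "gp_rest", 0.50),
    p("o2_plt", "o2_plt_hcy", 0.80),
    # reported morphology-reactivity associations, per agonist
    p("plt", "amax_aa", 0.173), p("plt", "amax_col", 0.283), p("plt", "amax_adp", 0.345),
    p("pct", "amax_aa", 0.182), p("pct", "amax_col", 0.312), p("pct", "amax_adp", 0.423),
    p("p_lcr", "amax_aa", 0.123), p("p_lcr", "amax_adp", 0.176),
    p("mpv", "amax_adp", 0.169), p("pdw", "amax_adp", 0.173),
    p("mono", "amax_aa", -0.121),
    p("neu", "amax_col", 0.121), p("neu", "amax_adp", 0.120),
    p("rbc", "amax_adp", -0.127), p("hgb", "amax_adp", -0.206),
    p("hct", "amax_adp", -0.152),
    p("age", "amax_aa", -0.113), p("age", "amax_adp", -0.118),
    # reported biochemical and oxidative associations
    p("uric_acid", "amax_aa", -0.140), p("uric_acid", "amax_adp", -0.184),
    p("pox_plt", "amax_aa", 0.147), p("pox_plt", "amax_adp", 0.149),
    p("sh_plt", "amax_aa", 0.116), p("sh_plasma", "amax_col", 0.116)
  )
}

#' Build a simulation configuration
#'
#' Validates and freezes everything [generate_cohort()] needs: cohort size
#' and sex split, per-variable marginal targets, the target Spearman matrix
#' (converted internally to the Gaussian-copula Pearson scale via
#' `2*sin(pi*rho/6)` and repaired to the nearest positive-definite
#' correlation matrix when the targets are jointly infeasible) and an
#' optional MCAR missingness rate capped at 3%.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param female_fraction Proportion of female subjects in `[0, 1]`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param marginals Marginal table as returned by [default_marginals()].
#' @param rank_correlation Long-form target Spearman tibble
#'   (`var1`, `var2`, `rho`) as returned by [default_rank_correlations()],
#'   or a full named symmetric matrix over the marginal variables.
#' @param missing_rate MCAR cell-masking probability in `[0, 0.03]`.
#' @return An object of class `ps_sim_config`.
#' @export
simulation_config <- function(n_subjects = 251,
                              female_fraction = 125 / 251,
                              seed = 1L,
                              marginals = default_marginals(),
                              rank_correlation = default_rank_correlations(),
                              missing_rate = 0) {
  assert_number(n_subjects, "n_subjects", lower = 2)
  if (n_subjects != round(n_subjects)) {
    ps_abort("`n_subjects` must be a whole number.", "ps_bad_argument")
  }
  assert_number(female_fraction, "female_fraction", 0, 1)
  assert_number(seed, "seed")
  assert_number(missing_rate, "missing_rate", 0, 0.03)
  stopifnot(is.data.frame(marginals),
            all(c("variable", "set", "family", "q25_f", "med_f", "q75_f",
                  "q25_m", "med_m", "q75_m", "shift", "lower", "upper")
                %in% names(marginals)))
  if (anyDuplicated(marginals$variable)) {
    ps_abort("duplicate variable names in `marginals`.", "ps_bad_argument")
  }

  vars <- marginals$variable
  R_s <- build_spearman_matrix(rank_correlation, vars)
  R_pearson <- 2 * sin(pi * R_s / 6)
  diag(R_pearson) <- 1
  repaired <- FALSE
  ev <- eigen(R_pearson, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    npd <- try(Matrix::nearPD(R_pearson, corr = TRUE, keepDiag = TRUE),
               silent = TRUE)
    if (inherits(npd, "try-error")) {
      off <- which(abs(R_pearson) == max(abs(R_pearson - diag(nrow(R_pearson)))),
                   arr.ind = TRUE)[1, ]
      ps_abort(
        sprintf(paste0("target rank-correlation matrix cannot be repaired to ",
                       "positive definite; inspect entries involving '%s'/'%s'."),
                vars[off[1]], vars[off[2]]),
        "ps_bad_correlation")
    }
    R_pearson <- as.matrix(npd$mat)
    dimnames(R_pearson) <- list(vars, vars)
    repaired <- TRUE
  }

  structure(
    list(n_subjects = as.integer(n_subjects),
         female_fraction = female_fraction,
         seed = as.integer(seed),
         marginals = tibble::as_tibble(marginals),
         rank_correlation = R_s,
         copula_pearson = R_pearson,
         pd_repaired = repaired,
         missing_rate = missing_rate),
    class = "ps_sim_config")
}

# assemble a full symmetric Spearman matrix from long-form pairs or pass
# through (after validation) a user-supplied matrix
build_spearman_matrix <- function(rank_correlation, vars) {
  if (is.matrix(rank_correlation)) {
    R <- rank_correlation
    if (is.null(dimnames(R)) || !all(vars %in% rownames(R))) {
      ps_abort("matrix `rank_correlation` must carry all variable names.",
               "ps_bad_argument")
    }
    R <- R[vars, vars]
  } else {
    stopifnot(is.data.frame(rank_correlation),
              all(c("var1", "var2", "rho") %in% names(rank_correlation)))
    unknown <- setdiff(c(rank_correlation$var1, rank_correlation$var2), vars)
    if (length(unknown)) {
      ps_abort(paste0("rank_correlation names unknown variables: ",
                      paste(unique(unknown), collapse = ", ")),
               "ps_bad_argument")
    }
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    for (i in seq_len(nrow(rank_correlation))) {
      a <- rank_correlation$var1[i]; b <- rank_correlation$var2[i]
      R[a, b] <- R[b, a] <- rank_correlation$rho[i]
    }
  }
  if (any(abs(R) > 1) || any(abs(diag(R) - 1) > 1e-12) ||
      max(abs(R - t(R))) > 1e-12) {
    ps_abort("rank correlations must be symmetric, unit-diagonal, in [-1, 1].",
             "ps_bad_correlation")
  }
  R
}

# quantile function of one configured marginal, per sex
marginal_quantile <- function(u, spec, sex) {
  q25 <- if (sex == "female") spec$q25_f else spec$q25_m
  med <- if (sex == "female") spec$med_f else spec$med_m
  q75 <- if (sex == "female") spec$q75_f else spec$q75_m
  iqr <- q75 - q25
  switch(spec$family,
    normal = qnorm(u, mean = med, sd = iqr / (2 * 0.6745)),
    lognormal = {
      medp <- med - spec$shift
      if (medp <= 0) ps_abort(
        sprintf("lognormal marginal '%s': median must exceed shift.",
                spec$variable), "ps_bad_argument")
      sdlog <- asinh(iqr / (2 * medp)) / 0.6745
      spec$shift + qlnorm(u, meanlog = log(medp), sdlog = sdlog)
    },
    beta = {
      lo <- spec$lower; up <- spec$upper
      m <- (med - lo) / (up - lo)
      s <- (iqr / (2 * 0.6745)) / (up - lo)
      common <- m * (1 - m) / s^2 - 1
      if (common <= 0) ps_abort(
        sprintf("beta marginal '%s': IQR too wide for its bounds.",
                spec$variable), "ps_bad_argument")
      lo + (up - lo) * stats::qbeta(u, m * common, (1 - m) * common)
    },
    ps_abort(sprintf("unknown marginal family '%s'.", spec$family),
             "ps_bad_argument")
  )
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` rows from the Gaussian copula defined by a
#' [simulation_config()]: multivariate-normal scores under the configured
#' Pearson matrix are mapped through `pnorm()` to uniforms and then through
#' each variable's (sex-specific) quantile function.  Counts and
#' concentrations are truncated at zero and percentage variables at 100,
#' both far in the tails of the configured marginals.  Identical
#' configuration and seed give a bitwise-identical table.
#'
#' @param config A `ps_sim_config` object.
#' @param seed Optional seed overriding `config$seed`, so replicate draws
#'   can share one validated configuration.
#' @return A `ps_cohort` tibble: `subject_id`, `sex`, then one numeric
#'   column per configured variable.  The variable-set map and the
#'   generating config are attached as attributes (`variable_sets`,
#'   `sim_config`).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_subjects = 50, seed = 1))
#' dplyr::count(cohort, sex)
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "ps_sim_config")) {
    ps_abort("`config` must come from simulation_config().", "ps_bad_argument")
  }
  n <- config$n_subjects
  vars <- config$marginals$variable
  p <- length(vars)
  L <- chol(config$copula_pearson)

  out <- with_seed(seed, {
    n_f <- round(config$female_fraction * n)
    sex <- sample(rep(c("female", "male"), c(n_f, n - n_f)))
    Z <- matrix(rnorm(n * p), n, p) %*% L
    U <- pnorm(Z)
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
    for (j in seq_len(p)) {
      spec <- as.list(config$marginals[j, ])
      for (s in c("female", "male")) {
        idx <- sex == s
        if (any(idx)) X[idx, j] <- marginal_quantile(U[idx, j], spec, s)
      }
    }
    list(sex = sex, X = X)
  })

  X <- out$X
  # physical bounds: non-negative analytes, percentages capped at 100
  X <- pmax(X, 0)
  pct_vars <- vars[config$marginals$units %in% c("%", "% positive")]
  for (v in pct_vars) X[, v] <- pmin(X[, v], 100)

  cohort <- tibble::tibble(
    subject_id = sprintf("S%0*d", nchar(n), seq_len(n)),
    sex = factor(out$sex, levels = c("female", "male"))
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(X))
  attr(cohort, "variable_sets") <-
    split(config$marginals$variable, config$marginals$set)
  attr(cohort, "sim_config") <- config
  class(cohort) <- c("ps_cohort", class(cohort))

  if (config$missing_rate > 0) {
    cohort <- inject_missing(cohort, config$missing_rate,
                             seed = derive_seed(seed, 101L))
  }
  cohort
}

#' Variable-set map of a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or any data frame
#'   carrying a `variable_sets` attribute).
#' @return Named list mapping set name to character vector of column names.
#' @export
variable_sets <- function(cohort) {
  vs <- attr(cohort, "variable_sets")
  if (is.null(vs)) {
    ps_abort("no `variable_sets` attribute on this table.", "ps_bad_argument")
  }
  vs
}

#' Column dictionary sidecar
#'
#' Machine-readable description of every measurement column of a generated
#' cohort: name, units and variable set.
#'
#' @param cohort A `ps_cohort` tibble.
#' @return A tibble with columns `name`, `units`, `set`.
#' @export
column_dictionary <- function(cohort) {
  cfg <- attr(cohort, "sim_config")
  if (is.null(cfg)) {
    ps_abort("cohort carries no simulation config.", "ps_bad_argument")
  }
  dplyr::select(cfg$marginals, name = "variable", "units", "set")
}

#' Mask cells completely at random
#'
#' Independently masks each eligible measurement cell with probability
#' `rate`; `subject_id`, `sex` and `age` are never masked.  Rates above 3%
#' are rejected: variables missing that often are outside the imputation
#' policy the preprocessing stage implements.
#'
#' @param cohort A cohort tibble.
#' @param rate Per-cell masking probability in `[0, 0.03]`.
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missing <- function(cohort, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0 || rate > 0.03) {
    ps_abort(paste0("`rate` must lie in [0, 0.03]: variables missing 3% or ",
                    "more are not imputed and cannot be simulated here."),
             "ps_rate_too_high")
  }
  if (rate == 0) return(cohort)
  protected <- c("subject_id", "sex", "age")
  eligible <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                      protected)
  with_seed(seed, {
    for (v in eligible) {
      hit <- stats::runif(nrow(cohort)) < rate
      cohort[[v]][hit] <- NA_real_
    }
  })
  cohort
}
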