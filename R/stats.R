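#' Hodges-Lehmann group comparison with Mann-Whitney test
#'
#' The Hodges-Lehmann estimate of the location shift between two samples -
#' the median of all pairwise differences `x_i - y_j` - with the matching
#' Mann-Whitney (Wilcoxon rank-sum) two-sided p-value and 95% confidence
#' interval. The p-value and CI are exact when the combined sample size is
#' at most 20 and the data are tie-free, and use the normal approximation
#' with continuity and tie correction otherwise.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param metric Optional label carried into the result.
#' @param conf_level Confidence level. Default 0.95.
#' @return Object of class `group_comparison`: list with `metric`,
#'   `hl_estimate`, `ci95` (length 2), `p_mannwhitney`, `n_per_group`,
#'   `exact` (whether the exact distribution was used).
#' @examples
#' hodges_lehmann(c(2, 3, 4), c(1, 2, 3))$hl_estimate
#' @export
hodges_lehmann <- function(x, y, metric = NA_character_, conf_level = 0.95) {
  if (length(x) < 2L || length(y) < 2L)
    oq_error("each sample needs at least 2 observations", "octaquant_empty_sample")
  diffs <- as.vector(outer(x, y, "-"))
  est <- stats::median(diffs)
  exact <- (length(x) + length(y) <= 20L) &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, conf.int = TRUE, conf.level = conf_level,
                       exact = exact, correct = TRUE))
  structure(list(metric = metric, hl_estimate = est,
                 ci95 = unname(as.numeric(wt$conf.int)),
                 p_mannwhitney = unname(wt$p.value),
                 n_per_group = c(n_x = length(x), n_y = length(y)),
                 exact = exact),
            class = "group_comparison")
}

#' Longitudinal four-timepoint test
#'
#' Tests whether a metric changes across the four visits (preoperative,
#' month 1, month 3, month 6). Each timepoint's values are first screened
#' with a Shapiro-Wilk normality test (after centering); if any timepoint
#' rejects at `normality_alpha` - or is degenerate (constant) - the
#' nonparametric Friedman rank test is used, otherwise a repeated-measures
#' ANOVA with an eye stratum. The result reports which test ran.
#'
#' @param values Numeric matrix, eyes x 4 timepoints (columns ordered
#'   pre, m1, m3, m6). No missing cells are allowed; nothing is imputed.
#' @param normality_alpha Screening level. Default 0.05.
#' @param metric Optional label.
#' @return Object of class `longitudinal_test`: list with `metric`,
#'   `test` ("friedman" or "rm_anova"), `statistic`, `df`, `p`,
#'   `timepoint_means`, `timepoint_se`, `shapiro_p`.
#' @export
longitudinal_test <- function(values, normality_alpha = 0.05,
                              metric = NA_character_) {
  values <- as.matrix(values)
  if (ncol(values) != 4L)
    oq_error("expected four timepoints", "octaquant_bad_grid")
  if (any(!is.finite(values)))
    oq_error("missing or non-finite cells in the timepoint grid",
             "octaquant_missing_cells")
  if (nrow(values) < 3L)
    oq_error("need at least 3 eyes", "octaquant_bad_grid")
  # no within-eye variation at all: no test can reject; report the
  # degenerate Friedman result directly (friedman.test errors on all-ties)
  if (all(apply(values, 1, function(r) length(unique(r)) == 1L))) {
    return(structure(list(metric = metric, test = "friedman", statistic = 0,
                          df = ncol(values) - 1L, p = 1,
                          timepoint_means = colMeans(values),
                          timepoint_se = apply(values, 2, stats::sd) /
                            sqrt(nrow(values)),
                          shapiro_p = rep(NA_real_, 4L)),
                     class = "longitudinal_test"))
  }
  shapiro_p <- apply(values, 2, function(col) {
    if (stats::sd(col) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(col - mean(col))$p.value
  })
  use_friedman <- any(shapiro_p < normality_alpha)
  if (use_friedman) {
    ft <- stats::friedman.test(values)
    stat <- unname(ft$statistic); df <- unname(ft$parameter)
    p <- unname(ft$p.value)
    test <- "friedman"
  } else {
    n <- nrow(values)
    tp <- colnames(values) %||% paste0("t", 1:4)
    d <- data.frame(y = as.vector(values),
                    time = factor(rep(tp, each = n), levels = tp),
                    eye = factor(rep(seq_len(n), times = 4L)))
    fit <- stats::aov(y ~ time + Error(eye), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    i <- match("time", trimws(rownames(tab)))
    stat <- tab[i, "F value"]; df <- tab[i, "Df"]
    p <- tab[i, "Pr(>F)"]
    test <- "rm_anova"
  }
  structure(list(metric = metric, test = test, statistic = stat, df = df,
                 p = p,
                 timepoint_means = colMeans(values),
                 timepoint_se = apply(values, 2, stats::sd) / sqrt(nrow(values)),
                 shapiro_p = shapiro_p),
            class = "longitudinal_test")
}

#' Univariate logistic regression for the responder outcome
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single
#' predictor, reporting the odds ratio at a stated per-unit scaling (e.g.
#' "per 0.01 units greater" is `scale = 0.01`; "per 0.1 units reduced" is
#' `scale = -0.1`) with its Wald confidence interval and p-value. Complete
#' or quasi-complete separation is flagged rather than silently reported.
#'
#' @param records Data.frame with the outcome column and the predictor.
#' @param variable Name of the predictor column (numeric, or a factor whose
#'   first level is the reference).
#' @param scale Per-unit scaling of the reported OR (numeric predictors
#'   only). Default 1.
#' @param outcome Name of the logical/0-1 outcome column. Default
#'   `"responder"`.
#' @return Object of class `logistic_result`: list with `variable`,
#'   `scale`, `or_estimate`, `ci95`, `p`, `beta`, `se`, `n`, `stage`,
#'   `flag` (`"ok"`, `"separation"`, or `"degenerate"`).
#' @export
fit_univariate_logistic <- function(records, variable, scale = 1,
                                    outcome = "responder") {
  y <- records[[outcome]]
  x <- records[[variable]]
  if (is.null(y) || is.null(x))
    oq_error("outcome or predictor column missing", "octaquant_bad_column")
  if (length(unique(x)) < 2L)
    return(structure(list(variable = variable, scale = scale,
                          or_estimate = NA_real_, ci95 = c(NA_real_, NA_real_),
                          p = NA_real_, beta = NA_real_, se = NA_real_,
                          n = length(y), stage = "univariate",
                          flag = "degenerate"),
                     class = "logistic_result"))
  d <- data.frame(.y = as.integer(y), .x = x)
  fit <- suppressWarnings(stats::glm(.y ~ .x, data = d, family = stats::binomial()))
  co <- summary(fit)$coefficients
  idx <- grep("^\\.x", rownames(co))[1]
  beta <- co[idx, "Estimate"]; se <- co[idx, "Std. Error"]
  p <- co[idx, "Pr(>|z|)"]
  eff_scale <- if (is.numeric(x)) scale else 1
  or <- exp(beta * eff_scale)
  ci <- sort(exp((beta + c(-1, 1) * stats::qnorm(0.975) * se) * eff_scale))
  flag <- if (abs(beta) > 15 || se > 100) "separation" else "ok"
  structure(list(variable = variable, scale = eff_scale, or_estimate = or,
                 ci95 = ci, p = unname(p), beta = unname(beta),
                 se = unname(se), n = nrow(d), stage = "univariate",
                 flag = flag),
            class = "logistic_result")
}

#' Backward-selected multivariate logistic model
#'
#' Screens candidate predictors by univariate p-value (`p < alpha_enter`,
#' default 0.1), fits the entrants jointly, then iteratively drops the
#' largest-p term until every remaining term has `p < alpha_stay` (default
#' 0.05) or a single term remains. Ties in p-values are broken by
#' lexicographic variable name so the path does not depend on input order.
#' Two multivariate outputs are reported: every entrant adjusted for the
#' others at entry (the full entry model), and the final retained model.
#'
#' @param records Data.frame with the outcome and candidate columns.
#' @param candidates Character vector of candidate predictor columns.
#' @param scales Optional named numeric vector of per-unit OR scalings.
#' @param alpha_enter Univariate screening level. Default 0.1.
#' @param alpha_stay Multivariate retention level. Default 0.05.
#' @param outcome Outcome column name. Default `"responder"`.
#' @return List with `univariate` (list of `logistic_result`),
#'   `entry_model` and `final_model` (data.frames of adjusted ORs), and
#'   `selection_path` (variables in drop order). A `status` field warns
#'   when the sample is small relative to the entrant count.
#' @export
backward_select <- function(records, candidates, scales = NULL,
                            alpha_enter = 0.1, alpha_stay = 0.05,
                            outcome = "responder") {
  get_scale <- function(v) if (!is.null(scales) && v %in% names(scales))
    scales[[v]] else 1
  uni <- lapply(candidates, function(v)
    fit_univariate_logistic(records, v, scale = get_scale(v), outcome = outcome))
  names(uni) <- candidates
  entered <- candidates[vapply(uni, function(u)
    !is.na(u$p) && u$p < alpha_enter, logical(1))]
  entered <- sort(entered)
  status <- "ok"
  if (length(entered) == 0L)
    return(list(univariate = uni, entry_model = empty_mv(), final_model = empty_mv(),
                selection_path = character(0), status = "no_entrants"))
  n_events <- sum(as.integer(records[[outcome]]))
  if (n_events < 5L * length(entered)) status <- "few_events_per_variable"
  mv_fit <- function(vars) {
    d <- records[, c(outcome, vars), drop = FALSE]
    names(d)[1] <- ".y"
    d$.y <- as.integer(d$.y)
    suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
  }
  mv_table <- function(fit, vars) {
    co <- summary(fit)$coefficients
    rows <- lapply(vars, function(v) {
      idx <- grep(paste0("^`?", v), rownames(co))[1]
      sc <- if (is.numeric(records[[v]])) get_scale(v) else 1
      beta <- co[idx, "Estimate"]; se <- co[idx, "Std. Error"]
      ci <- sort(exp((beta + c(-1, 1) * stats::qnorm(0.975) * se) * sc))
      data.frame(variable = v, or = exp(beta * sc), ci_lo = ci[1],
                 ci_hi = ci[2], p = co[idx, "Pr(>|z|)"],
                 stage = "multivariate")
    })
    do.call(rbind, rows)
  }
  entry_fit <- mv_fit(entered)
  entry_tab <- mv_table(entry_fit, entered)
  current <- entered
  path <- character(0)
  repeat {
    tab <- mv_table(mv_fit(current), current)
    if (all(tab$p < alpha_stay) || length(current) == 1L) break
    ord <- order(-tab$p, tab$variable)  # largest p first; ties by name
    drop_var <- tab$variable[ord[1]]
    path <- c(path, drop_var)
    current <- setdiff(current, drop_var)
  }
  final_tab <- mv_table(mv_fit(current), current)
  list(univariate = uni, entry_model = entry_tab, final_model = final_tab,
       selection_path = path, status = status)
}

empty_mv <- function() data.frame(variable = character(0), or = numeric(0),
                                  ci_lo = numeric(0), ci_hi = numeric(0),
                                  p = numeric(0), stage = character(0))
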