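#' Run the full cohort statistical endpoint suite
#'
#' Reproduces, on a cohort table, the complete set of statistical
#' endpoints of a longitudinal two-plexus OCTA study: study-vs-fellow-eye
#' Hodges-Lehmann/Mann-Whitney comparisons per plexus and metric at the
#' preoperative visit, Friedman (or repeated-measures ANOVA) longitudinal
#' tests over the four visits, univariate and backward-selected logistic
#' regressions of the responder outcome (BCVA gain >= 0.1 LogMAR), and
#' ROC/Youden cut-point analyses with BCa bootstrap intervals for every
#' preoperative metric and every preoperative-to-month-6 change. All seeds
#' and settings are recorded in the returned report, so a rerun with the
#' same cohort and settings is identical.
#'
#' @param cohort Long-format cohort data.frame as produced by
#'   [simulate_cohort()] (columns `eye_id`, `group`, `plexus`,
#'   `timepoint`, `vdi`, `vad`, `vsd`, `responder`, ...).
#' @param n_boot Bootstrap iterations for the ROC stage. Default 10000.
#' @param seed Bootstrap seed for the ROC stage. Default 9780.
#' @param cutpoint_rule `"youden"` (default) or `"topleft"`.
#' @param alpha Significance level used for flagging. Default 0.05.
#' @return Object of class `endpoint_report`: list of data.frames
#'   `group_comparisons`, `longitudinal`, `logistic_univariate`,
#'   `logistic_entry`, `logistic_final`, `roc`, plus `settings`.
#' @export
run_endpoint_suite <- function(cohort, n_boot = 10000L, seed = 9780L,
                               cutpoint_rule = c("youden", "topleft"),
                               alpha = 0.05) {
  cutpoint_rule <- match.arg(cutpoint_rule)
  metrics <- c("vdi", "vad", "vsd")
  plexuses <- c("SCP", "DCP")
  need <- c("eye_id", "group", "plexus", "timepoint", metrics, "responder")
  if (!all(need %in% names(cohort)))
    oq_error("cohort table is missing required columns", "octaquant_bad_column")

  slab <- function(gr, pl, tp) {
    d <- cohort[cohort$group == gr & cohort$plexus == pl &
                  cohort$timepoint == tp, ]
    d[order(d$eye_id), ]
  }

  ## study vs fellow eye, preoperative (fellow - study orientation)
  comp <- list()
  for (pl in plexuses) for (m in metrics) {
    hl <- hodges_lehmann(slab("fellow", pl, "pre")[[m]],
                         slab("RRD", pl, "pre")[[m]],
                         metric = paste(pl, m, sep = "_"))
    comp[[length(comp) + 1L]] <- data.frame(
      plexus = pl, metric = m, hl_estimate = hl$hl_estimate,
      ci_lo = hl$ci95[1], ci_hi = hl$ci95[2], p = hl$p_mannwhitney,
      n_per_group = unname(hl$n_per_group[1]),
      significant = hl$p_mannwhitney < alpha)
  }
  comp <- do.call(rbind, comp)

  ## longitudinal course in the study eye
  longi <- list()
  for (pl in plexuses) for (m in metrics) {
    grid <- sapply(c("pre", "m1", "m3", "m6"),
                   function(tp) slab("RRD", pl, tp)[[m]])
    lt <- longitudinal_test(grid, metric = paste(pl, m, sep = "_"))
    longi[[length(longi) + 1L]] <- data.frame(
      plexus = pl, metric = m, test = lt$test, statistic = lt$statistic,
      p = lt$p,
      mean_pre = lt$timepoint_means[1], mean_m1 = lt$timepoint_means[2],
      mean_m3 = lt$timepoint_means[3], mean_m6 = lt$timepoint_means[4],
      significant = lt$p < alpha)
  }
  longi <- do.call(rbind, longi)
  rownames(longi) <- NULL

  ## per-eye predictor table for the outcome analyses
  pred <- eye_predictor_table(cohort)
  octa_vars <- grep("^(pre|chg)_", names(pred), value = TRUE)
  # OR scalings: VDI per unit; VAD/VSD per 0.01 units; VDI change per 0.1
  # units reduced (negative scale flips the direction of the reported OR)
  scales <- vapply(octa_vars, function(v) {
    if (grepl("vdi", v)) { if (grepl("^chg", v)) -0.1 else 1 } else 0.01
  }, numeric(1))
  clinical <- intersect(c("age", "rrd_duration_class", "pvr"), names(pred))
  candidates <- c(clinical, octa_vars)
  sel <- backward_select(pred, candidates, scales = scales,
                         alpha_enter = 0.1, alpha_stay = alpha)
  uni <- do.call(rbind, lapply(sel$univariate, function(u) data.frame(
    variable = u$variable, scale = u$scale, or = u$or_estimate,
    ci_lo = u$ci95[1], ci_hi = u$ci95[2], p = u$p, flag = u$flag,
    significant = !is.na(u$p) && u$p < alpha)))
  rownames(uni) <- NULL

  ## ROC / Youden with BCa bootstrap for each OCTA variable
  roc <- do.call(rbind, lapply(octa_vars, function(v) {
    r <- roc_youden(pred[[v]], pred$responder, n_boot = n_boot, seed = seed,
                    rule = cutpoint_rule, variable = v)
    data.frame(variable = v, auc = r$auc, auc_se = r$auc_se,
               auc_ci_lo = r$ci95_bca[1], auc_ci_hi = r$ci95_bca[2],
               p_vs_half = r$p_vs_half, youden = r$youden,
               youden_ci_lo = r$youden_ci95_bca[1],
               youden_ci_hi = r$youden_ci95_bca[2],
               criterion = r$criterion, direction = r$direction,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  rownames(roc) <- NULL

  structure(list(group_comparisons = comp, longitudinal = longi,
                 logistic_univariate = uni,
                 logistic_entry = sel$entry_model,
                 logistic_final = sel$final_model,
                 selection_path = sel$selection_path,
                 roc = roc,
                 settings = list(n_boot = as.integer(n_boot),
                                 boot_seed = as.integer(seed),
                                 cutpoint_rule = cutpoint_rule,
                                 alpha = alpha,
                                 cohort_seed = attr(cohort, "seed"))),
            class = "endpoint_report")
}

# One row per eye: responder flag, clinical covariates, preoperative
# metrics and pre -> m6 changes per plexus.
eye_predictor_table <- function(cohort) {
  base <- cohort[cohort$group == "RRD" & cohort$plexus == "SCP" &
                   cohort$timepoint == "pre", ]
  base <- base[order(base$eye_id), ]
  keep <- intersect(c("eye_id", "responder", "age", "sex",
                      "rrd_duration_class", "pvr", "extent_quadrants",
                      "lens_status", "bcva_logmar_pre", "bcva_logmar_m6"),
                    names(base))
  pred <- base[, keep]
  for (pl in c("SCP", "DCP")) for (m in c("vdi", "vad", "vsd")) {
    pre <- cohort[cohort$group == "RRD" & cohort$plexus == pl &
                    cohort$timepoint == "pre", ]
    m6 <- cohort[cohort$group == "RRD" & cohort$plexus == pl &
                   cohort$timepoint == "m6", ]
    pre <- pre[order(pre$eye_id), ]; m6 <- m6[order(m6$eye_id), ]
    pred[[sprintf("pre_%s_%s", tolower(pl), m)]] <- pre[[m]]
    pred[[sprintf("chg_%s_%s", tolower(pl), m)]] <- m6[[m]] - pre[[m]]
  }
  rownames(pred) <- NULL
  pred
}

#' Serialize an endpoint report to deterministic CSV text
#'
#' @param report An `endpoint_report`.
#' @return Named character vector, one CSV document per table; identical
#'   inputs and settings give byte-identical output.
#' @export
serialize_report <- function(report) {
  stopifnot(inherits(report, "endpoint_report"))
  tabs <- c("group_comparisons", "longitudinal", "logistic_univariate",
            "logistic_entry", "logistic_final", "roc")
  out <- vapply(tabs, function(nm) {
    df <- report[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    con <- textConnection("txt", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paste(txt, collapse = "\n")
  }, character(1))
  c(out, settings = paste(names(report$settings),
                          vapply(report$settings, function(s)
                            paste(format(s), collapse = ","), character(1)),
                          sep = "=", collapse = ";"))
}

#' Write an endpoint report to a directory of CSV files
#'
#' @param report An `endpoint_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  ser <- serialize_report(report)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(ser)) {
    p <- file.path(dir, paste0(nm, if (nm == "settings") ".txt" else ".csv"))
    writeLines(ser[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
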