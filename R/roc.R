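#' ROC curve, Youden-optimal cut-point, and BCa bootstrap intervals
#'
#' Builds the empirical ROC of a continuous score against a binary label,
#' computes the area under the curve (equal to the Mann-Whitney
#' U-statistic divided by `n1 * n0`, with midrank handling of ties), finds
#' the optimal cut-point, and attaches bias-corrected and accelerated
#' (BCa) bootstrap confidence intervals for the AUC and the Youden index.
#'
#' The cut-point maximizes the Youden index `J = sensitivity +
#' specificity - 1` by default, which coincides with the point nearest the
#' top-left corner of the ROC plot under equal axis scaling; the Euclidean
#' nearest-top-left rule is available via `rule = "topleft"`. The
#' criterion is reported as the midpoint between adjacent observed scores
#' with its direction (`">"` when larger scores indicate the positive
#' class, `"<="` otherwise); the orientation is chosen from the data so
#' that AUC >= 0.5 and is recorded in the result.
#'
#' Bootstrap resampling is stratified by class (both classes are always
#' present in a resample); the p-value against AUC = 0.5 is the two-sided
#' bootstrap tail probability. `method = "delong"` instead computes the
#' AUC p-value from the DeLong variance estimate.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary outcome (logical or 0/1); `TRUE`/1 is the positive
#'   class.
#' @param n_boot Bootstrap iterations. Default 10000.
#' @param seed Bootstrap RNG seed. Default 9780.
#' @param rule `"youden"` (default) or `"topleft"`.
#' @param method `"bootstrap"` (default) or `"delong"` for the AUC
#'   p-value.
#' @param variable Optional label carried into the result.
#' @return Object of class `roc_result`: list with `variable`, `auc`,
#'   `auc_se`, `ci95_bca`, `p_vs_half`, `youden`, `youden_ci95_bca`,
#'   `criterion`, `direction`, `sensitivity`, `specificity`, `n_boot`,
#'   `boot_seed`, `n_pos`, `n_neg`, `rule`.
#' @examples
#' r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 200)
#' c(r$auc, r$youden)
#' @export
roc_youden <- function(scores, labels, n_boot = 10000L, seed = 9780L,
                       rule = c("youden", "topleft"),
                       method = c("bootstrap", "delong"),
                       variable = NA_character_) {
  rule <- match.arg(rule); method <- match.arg(method)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) || any(is.na(labels)))
    oq_error("scores and labels must be complete and equal length",
             "octaquant_bad_input")
  if (!any(labels) || all(labels))
    oq_error("both classes must be present", "octaquant_single_class")
  auc_raw <- auc_rank(scores, labels)
  direction <- if (auc_raw >= 0.5) ">" else "<="
  sc <- if (direction == ">") scores else -scores
  auc <- auc_rank(sc, labels)
  cp <- best_cutpoint(sc, labels, rule)
  criterion <- if (direction == ">") cp$threshold else -cp$threshold
  n1 <- sum(labels); n0 <- sum(!labels)
  # bootstrap (stratified by class) of AUC and Youden
  boot <- with_seed(seed, {
    pos <- sc[labels]; neg <- sc[!labels]
    t(vapply(seq_len(n_boot), function(i) {
      bs <- c(sample(pos, n1, replace = TRUE), sample(neg, n0, replace = TRUE))
      bl <- c(rep(TRUE, n1), rep(FALSE, n0))
      c(auc_rank(bs, bl), best_cutpoint(bs, bl, rule)$youden)
    }, numeric(2)))
  })
  jack <- t(vapply(seq_along(sc), function(i) {
    c(auc_rank(sc[-i], labels[-i]), best_cutpoint(sc[-i], labels[-i], rule)$youden)
  }, numeric(2)))
  ci_auc <- bca_interval(boot[, 1], auc, jack[, 1])
  ci_youden <- bca_interval(boot[, 2], cp$youden, jack[, 2])
  p_vs_half <- if (method == "delong") {
    delong_p(sc, labels, auc)
  } else {
    p <- 2 * min(mean(boot[, 1] <= 0.5), mean(boot[, 1] >= 0.5))
    min(max(p, 1 / n_boot), 1)
  }
  structure(list(variable = variable, auc = auc,
                 auc_se = stats::sd(boot[, 1]),
                 ci95_bca = ci_auc, p_vs_half = p_vs_half,
                 youden = cp$youden, youden_ci95_bca = ci_youden,
                 criterion = criterion, direction = direction,
                 sensitivity = cp$sensitivity, specificity = cp$specificity,
                 n_boot = as.integer(n_boot), boot_seed = as.integer(seed),
                 n_pos = n1, n_neg = n0, rule = rule),
            class = "roc_result")
}

# AUC via midranks: (sum of positive ranks - n1(n1+1)/2) / (n1 n0),
# identical to the Mann-Whitney U divided by n1*n0.
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive sweep over the midpoints between adjacent distinct scores
# (plus open extremes): sens/spec for "positive iff score > t".
best_cutpoint <- function(scores, labels, rule = "youden") {
  u <- sort(unique(scores))
  thr <- if (length(u) == 1L) u[1] - 0.5 else
    c(u[1] - 0.5, (u[-length(u)] + u[-1]) / 2)
  n1 <- sum(labels); n0 <- sum(!labels)
  pos <- sort(scores[labels]); neg <- sort(scores[!labels])
  sens <- (n1 - findInterval(thr, pos)) / n1   # positives strictly above t
  spec <- findInterval(thr, neg) / n0          # negatives at or below t
  j <- sens + spec - 1
  pick <- if (rule == "youden") which.max(j)
          else which.min((1 - sens)^2 + (1 - spec)^2)
  list(threshold = thr[pick], youden = j[pick],
       sensitivity = sens[pick], specificity = spec[pick])
}

# BCa interval from a bootstrap sample, the point estimate, and the
# leave-one-out jackknife replicates.
bca_interval <- function(boot, estimate, jack, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (!length(boot)) return(c(NA_real_, NA_real_))
  alpha <- (1 - conf) / 2
  prop <- (sum(boot < estimate) + 0.5 * sum(boot == estimate)) / length(boot)
  prop <- min(max(prop, 1 / (length(boot) + 1)), 1 - 1 / (length(boot) + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack)
  num <- sum((jm - jack)^3); den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  unname(stats::quantile(boot, c(a1, a2), type = 6))
}

# DeLong variance of the AUC via placement values; two-sided p vs 0.5.
delong_p <- function(scores, labels, auc) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  s2 <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  if (s2 <= 0) return(if (abs(auc - 0.5) < 1e-12) 1 else 0)
  2 * stats::pnorm(-abs(auc - 0.5) / sqrt(s2))
}
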