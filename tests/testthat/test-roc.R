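test_that("perfectly separated scores give AUC 1 and Youden 1", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), n_boot = 200)
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)

  r4 <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 200)
  expect_equal(r4$auc, 1.0)
  expect_equal(r4$direction, ">")
  expect_equal(r4$criterion, 2.5)   # midpoint between adjacent scores
})

test_that("AUC equals the Mann-Whitney U statistic over n1*n0 exactly", {
  set.seed(64)
  for (i in 1:5) {
    n <- 200
    pos <- round(rnorm(n, 0.6), 1)   # rounding forces ties
    neg <- round(rnorm(n, 0.0), 1)
    scores <- c(pos, neg); labels <- rep(c(1, 0), each = n)
    r <- roc_youden(scores, labels, n_boot = 50)
    u <- suppressWarnings(wilcox.test(pos, neg)$statistic)
    expect_identical(r$auc, unname(u) / (n * n))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(60); labels <- runif(60) < plogis(scores)
  if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
  r <- roc_youden(scores, labels, n_boot = 50)
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("the optimal cut-point maximizes Youden J over an exhaustive sweep", {
  set.seed(19)
  for (i in 1:10) {
    scores <- round(rnorm(40), 1)
    labels <- runif(40) < plogis(2 * scores)
    if (!any(labels) || all(labels)) next
    r <- roc_youden(scores, labels, n_boot = 50)
    # brute force over every candidate threshold and both directions
    thr <- sort(unique(scores))
    cand <- c(min(thr) - 1, (thr[-length(thr)] + thr[-1]) / 2, max(thr) + 1)
    best <- -Inf
    for (t in cand) for (dir in c(1, -1)) {
      sc <- dir * scores; tt <- dir * t
      sens <- sum(sc > tt & labels) / sum(labels)
      spec <- sum(sc <= tt & !labels) / sum(!labels)
      best <- max(best, sens + spec - 1)
    }
    expect_equal(r$youden, best)
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }
})

test_that("BCa intervals contain the estimate and tighten with sample size", {
  set.seed(55)
  widths <- sapply(c(20, 200), function(n) {
    mean(sapply(1:20, function(s) {
      pos <- rnorm(n, 1); neg <- rnorm(n)
      r <- roc_youden(c(pos, neg), rep(c(1, 0), each = n),
                      n_boot = 400, seed = s)
      expect_gte(r$auc, r$ci95_bca[1] - 1e-9)
      expect_lte(r$auc, r$ci95_bca[2] + 1e-9)
      diff(r$ci95_bca)
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("bootstrap is reproducible and the degenerate cases error", {
  scores <- rnorm(30); labels <- rep(c(0, 1), 15)
  a <- roc_youden(scores, labels, n_boot = 300, seed = 9780)
  b <- roc_youden(scores, labels, n_boot = 300, seed = 9780)
  expect_identical(a, b)
  expect_error(roc_youden(1:10, rep(1, 10)), class = "octaquant_single_class")
})

test_that("the DeLong and top-left options behave sensibly", {
  set.seed(31)
  pos <- rnorm(50, 1.2); neg <- rnorm(50)
  scores <- c(pos, neg); labels <- rep(c(1, 0), each = 50)
  rd <- roc_youden(scores, labels, n_boot = 100, method = "delong")
  expect_lt(rd$p_vs_half, 0.01)
  rt <- roc_youden(scores, labels, n_boot = 100, rule = "topleft")
  expect_true(rt$youden <= roc_youden(scores, labels, n_boot = 100)$youden + 1e-12)
})
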