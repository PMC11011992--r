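test_that("Hodges-Lehmann estimate is the median of all pairwise differences", {
  expect_equal(hodges_lehmann(c(1, 2, 3), c(1, 2, 3))$hl_estimate, 0)
  expect_equal(hodges_lehmann(c(2, 3, 4), c(1, 2, 3))$hl_estimate, 1)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1))
    h <- hodges_lehmann(x, y)
    expect_identical(h$hl_estimate, brute_hl(x, y))
    expect_gte(h$hl_estimate, h$ci95[1])
    expect_lte(h$hl_estimate, h$ci95[2])
    expect_equal(h$p_mannwhitney,
                 wilcox.test(x, y, exact = length(c(x, y)) <= 20)$p.value)
  }
  expect_error(hodges_lehmann(numeric(0), 1:3), class = "octaquant_empty_sample")
})

test_that("longitudinal test degrades to statistic 0, p 1 on identical columns", {
  grid <- matrix(rep(c(1, 5, 9), 4), ncol = 4)
  lt <- longitudinal_test(grid)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p, 1)
  expect_equal(lt$test, "friedman")
})

test_that("Friedman statistic matches the hand-computed rank formula", {
  # strictly increasing rows: ranks 1..4 in every row
  grid <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40, 5, 6, 7, 8),
                 nrow = 3, byrow = TRUE)
  grid <- grid + matrix(rexp(12, 10), 3, 4) * 0  # keep exact
  lt <- longitudinal_test(grid, normality_alpha = 0.99)  # force friedman
  expect_equal(lt$test, "friedman")
  expect_equal(lt$statistic, brute_friedman(grid))
  expect_equal(lt$statistic, 9)  # 12/(3*4*5) * (9+36+81+144) - 45

  set.seed(3)
  g2 <- matrix(rlnorm(32), 8, 4)
  lt2 <- longitudinal_test(g2, normality_alpha = 0.999)
  expect_equal(lt2$statistic, brute_friedman(g2))
})

test_that("normality screen routes Gaussian grids to repeated-measures ANOVA", {
  set.seed(12)
  grid <- matrix(rnorm(23 * 4, mean = 18.6, sd = 1), 23, 4)
  lt <- longitudinal_test(grid)
  if (all(lt$shapiro_p >= 0.05)) {
    expect_equal(lt$test, "rm_anova")
    expect_true(lt$p > 0 && lt$p <= 1)
  }
  skewed <- matrix(rlnorm(23 * 4, sdlog = 1.5), 23, 4)
  expect_equal(longitudinal_test(skewed)$test, "friedman")
  expect_error(longitudinal_test(matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 2, 4)),
               class = "octaquant_missing_cells")
})

test_that("univariate logistic OR equals the closed-form 2x2 odds ratio", {
  d <- data.frame(
    responder = rep(c(TRUE, FALSE), c(15, 15)),
    exposed = rep(c(1, 0, 1, 0), c(10, 5, 5, 10)))
  r <- fit_univariate_logistic(d, "exposed")
  expect_equal(r$or_estimate, 4.0, tolerance = 1e-6)   # ad/bc = 100/25
  expect_true(r$ci95[1] < 4 && r$ci95[2] > 4)

  d$flat <- 1
  expect_equal(fit_univariate_logistic(d, "flat")$flag, "degenerate")

  d$sep <- as.numeric(d$responder)
  expect_equal(fit_univariate_logistic(d, "sep")$flag, "separation")
})

test_that("OR scaling converts per-unit effects as stated", {
  set.seed(4)
  d <- data.frame(x = rnorm(400))
  d$responder <- runif(400) < plogis(0.5 * d$x)
  r1 <- fit_univariate_logistic(d, "x", scale = 1)
  r2 <- fit_univariate_logistic(d, "x", scale = 0.01)
  expect_equal(r2$or_estimate, r1$or_estimate^0.01, tolerance = 1e-10)
  r3 <- fit_univariate_logistic(d, "x", scale = -0.1)
  expect_equal(r3$or_estimate, r1$or_estimate^-0.1, tolerance = 1e-10)
  expect_true(r3$ci95[1] <= r3$or_estimate && r3$or_estimate <= r3$ci95[2])
})

test_that("backward selection keeps signal, drops noise, ignores input order", {
  set.seed(21)
  n <- 300
  d <- data.frame(x_signal = rnorm(n), x_noise = rnorm(n))
  d$responder <- runif(n) < plogis(-0.3 + 1.2 * d$x_signal)
  sel <- backward_select(d, c("x_signal", "x_noise"))
  if ("x_noise" %in% sel$entry_model$variable) {
    expect_equal(sel$selection_path[1], "x_noise")
  }
  expect_true("x_signal" %in% sel$final_model$variable)
  expect_false("x_noise" %in% sel$final_model$variable)

  sel_rev <- backward_select(d, c("x_noise", "x_signal"))
  expect_identical(sel$final_model, sel_rev$final_model)

  # a single entrant's multivariate OR equals its univariate OR
  sel1 <- backward_select(d, "x_signal")
  expect_equal(sel1$final_model$or, sel1$univariate$x_signal$or_estimate,
               tolerance = 1e-10)

  # nothing below the entry threshold: stage reported empty
  d2 <- data.frame(responder = rep(c(TRUE, FALSE), 50), z = rnorm(100) * 0 + 1)
  d2$z <- rnorm(100)
  d2$responder <- runif(100) < 0.4
  sel2 <- backward_select(d2, "z", alpha_enter = 1e-6)
  expect_equal(nrow(sel2$final_model), 0L)
  expect_equal(sel2$status, "no_entrants")
})

test_that("logistic regression recovers generating odds ratios at scale", {
  set.seed(99)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  beta <- log(2)
  d$responder <- runif(n) < plogis(-0.5 + beta * d$x)
  r <- fit_univariate_logistic(d, "x")
  expect_lt(abs(r$or_estimate - 2) / 2, 0.1)

  # null coefficient: OR near 1
  d$responder <- runif(n) < 0.35
  r0 <- fit_univariate_logistic(d, "x")
  expect_true(r0$or_estimate > 0.9 && r0$or_estimate < 1.1)
})
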