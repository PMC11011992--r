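test_that("the endpoint suite is byte-identical across reruns", {
  coh <- simulate_cohort(cohort_sim_params(seed = 17))
  a <- run_endpoint_suite(coh, n_boot = 300, seed = 9780)
  b <- run_endpoint_suite(coh, n_boot = 300, seed = 9780)
  expect_identical(serialize_report(a), serialize_report(b))
  expect_equal(nrow(a$group_comparisons), 6L)
  expect_equal(nrow(a$longitudinal), 6L)
  expect_equal(nrow(a$roc), 12L)
  expect_true(all(a$roc$auc >= 0 & a$roc$auc <= 1))
})

test_that("the per-eye predictor table pairs preoperative and month-6 values", {
  coh <- simulate_cohort(cohort_sim_params(seed = 23))
  pred <- octaquant:::eye_predictor_table(coh)
  expect_equal(nrow(pred), 23L)
  one <- coh[coh$eye_id == "eye05" & coh$group == "RRD" & coh$plexus == "DCP", ]
  expect_equal(pred$pre_dcp_vdi[pred$eye_id == "eye05"],
               one$vdi[one$timepoint == "pre"])
  expect_equal(pred$chg_dcp_vdi[pred$eye_id == "eye05"],
               one$vdi[one$timepoint == "m6"] - one$vdi[one$timepoint == "pre"])
})

test_that("group comparisons in a null cohort reject at the nominal rate", {
  # same generating distribution for study and fellow eyes: every rejection
  # is a type-I error; rate pooled over the 6 plexus x metric comparisons
  eq_means <- list(
    SCP = list(RRD = c(vdi = 19, vad = 0.43, vsd = 0.17),
               fellow = c(vdi = 19, vad = 0.43, vsd = 0.17)),
    DCP = list(RRD = c(vdi = 19, vad = 0.38, vsd = 0.15),
               fellow = c(vdi = 19, vad = 0.38, vsd = 0.15)))
  eq_sds <- list(
    SCP = list(RRD = c(vdi = 1, vad = 0.02, vsd = 0.01),
               fellow = c(vdi = 1, vad = 0.02, vsd = 0.01)),
    DCP = list(RRD = c(vdi = 0.5, vad = 0.03, vsd = 0.01),
               fellow = c(vdi = 0.5, vad = 0.03, vsd = 0.01)))
  flags <- unlist(lapply(1:150, function(s) {
    coh <- simulate_cohort(cohort_sim_params(
      metric_means = eq_means, metric_sds = eq_sds, seed = 1000 + s))
    pre <- coh[coh$timepoint == "pre", ]
    sapply(c("SCP", "DCP"), function(pl) sapply(c("vdi", "vad", "vsd"),
      function(m) {
        x <- pre[pre$plexus == pl & pre$group == "fellow", m]
        y <- pre[pre$plexus == pl & pre$group == "RRD", m]
        hodges_lehmann(x, y)$p_mannwhitney < 0.05
      }))
  }))
  rate <- mean(flags)   # 900 pooled null comparisons
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})

test_that("a strong preoperative VDI effect yields high AUC at cohort scale", {
  cf <- c(intercept = qlogis(8 / 23), vdi_pre = 2.5, vsd_pre = 0,
          d_vdi = 0, d_vsd = 0)
  aucs <- sapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_sim_params(responder_coefs = cf,
                                             seed = 5000 + s))
    pred <- octaquant:::eye_predictor_table(coh)
    if (!any(pred$responder) || all(pred$responder)) return(NA)
    octaquant:::auc_rank(pred$pre_scp_vdi, pred$responder)
  })
  expect_gte(mean(aucs > 0.8, na.rm = TRUE), 0.8)
})

test_that("reports can be written to disk and read back", {
  coh <- simulate_cohort(cohort_sim_params(seed = 29))
  rep <- run_endpoint_suite(coh, n_boot = 100, seed = 9780)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("group_comparisons.csv", "roc.csv", "settings.txt")))))
  back <- utils::read.csv(file.path(dir, "roc.csv"))
  expect_equal(nrow(back), 12L)
  expect_equal(back$auc, rep$roc$auc, tolerance = 1e-9)
})
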