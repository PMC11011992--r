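img8 <- function(px) {
  img <- enface_angiogram(px)
  img$meta$bit_depth <- "8-bit"
  img
}

test_that("global threshold matches the exhaustive between-class-variance oracle", {
  cfg_fixed <- quant_config(global_threshold_method = "fixed",
                            fixed_global_level = 10)
  expect_false(any(global_binarize(img8(matrix(5, 20, 20)), cfg_fixed)$mask))

  bim <- matrix(50, 24, 24); bim[runif(576) < 0.3] <- 200
  g <- global_binarize(img8(bim))
  expect_identical(g$mask, bim == 200)
  expect_equal(g$params_used$level, brute_otsu(bim))

  cb <- matrix(ifelse(outer(1:20, 1:20, "+") %% 2 == 0, 0, 255), 20, 20)
  cfg128 <- quant_config(global_threshold_method = "fixed",
                         fixed_global_level = 128)
  expect_identical(global_binarize(img8(cb), cfg128)$mask, cb == 255)

  set.seed(5)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    expect_equal(global_binarize(img8(px))$params_used$level, brute_otsu(px))
  }
})

test_that("adaptive threshold equals the sliding-window local-mean oracle", {
  const <- img8(matrix(100, 20, 20))
  expect_false(any(adaptive_binarize(const, quant_config(adaptive_offset = 1))$mask))
  expect_true(all(adaptive_binarize(const, quant_config(adaptive_offset = -1))$mask))

  px <- matrix(10, 16, 16); px[7:9, 7:9] <- 200
  cfg <- quant_config(adaptive_window_px = 7, adaptive_offset = 0)
  got <- adaptive_binarize(img8(px), cfg)$mask
  expect_identical(got, px >= brute_local_mean(px, 7) - 1e-7)

  set.seed(9)
  px <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  cfg <- quant_config(adaptive_window_px = 7, adaptive_offset = 0)
  got <- adaptive_binarize(img8(px), cfg)$mask
  expect_identical(got, px >= brute_local_mean(px, 7) - 1e-7)

  expect_error(adaptive_binarize(img8(matrix(0, 16, 16)),
                                 quant_config(adaptive_window_px = 17)),
               class = "octaquant_bad_window")
})

test_that("vesselness responds to tubes, suppresses blobs, stays near structures", {
  expect_false(any(vesselness_binarize(img8(matrix(7, 32, 32)))$mask))

  # bright 3-px bar: Hessian oracle says the interior is a bright ridge
  px <- matrix(0, 32, 32); px[15:17, 4:28] <- 255
  cfg <- quant_config(vesselness_scales_px = c(1, 2), vesselness_cut = 0.9)
  mask <- vesselness_binarize(img8(px), cfg)$mask
  expect_true(all(mask[16, 8:24]))              # bar centerline detected
  far <- mask[-(11:21), ]                       # > 2 max scales from the bar
  expect_false(any(far))

  l2 <- brute_hessian_l2(px, 2)
  expect_true(all(l2[16, 8:24] < 0))            # oracle agrees: bright ridge

  # isolated bright pixel: tube response dominates blob response
  blob <- matrix(0, 32, 32); blob[16, 16] <- 255
  rb <- octaquant:::vesselness_response(blob, 2)
  rt <- octaquant:::vesselness_response(px, 2)
  expect_lt(max(rb), max(rt))

  expect_error(vesselness_binarize(img8(matrix(0, 16, 16)),
                                   quant_config(vesselness_scales_px = 5)),
               class = "octaquant_bad_scale")
})

test_that("combination rules follow their boolean definitions", {
  f <- matrix(FALSE, 8, 8)
  cfg0 <- quant_config(min_component_px = 0)
  expect_false(any(combine_binarizations(f, f, f, cfg0)$mask))

  set.seed(3)
  m <- random_mask(8, 8)
  for (rule in c("adaptive_gate", "union", "majority")) {
    cfg <- quant_config(combine_rule = rule, min_component_px = 0)
    expect_identical(combine_binarizations(m, m, m, cfg)$mask, m)
  }

  g <- random_mask(8, 8); h <- random_mask(8, 8); a <- random_mask(8, 8)
  votes <- g + h + a
  cfg <- quant_config(combine_rule = "majority", min_component_px = 0)
  expect_identical(combine_binarizations(g, h, a, cfg)$mask, votes >= 2)
  cfg <- quant_config(combine_rule = "adaptive_gate", min_component_px = 0)
  expect_identical(combine_binarizations(g, h, a, cfg)$mask, (g | h) & a)
  cfg <- quant_config(combine_rule = "union", min_component_px = 0)
  expect_identical(combine_binarizations(g, h, a, cfg)$mask, g | h | a)

  expect_error(combine_binarizations(g, h, matrix(FALSE, 4, 4), cfg),
               class = "octaquant_shape_mismatch")
})

test_that("small connected components are removed at the configured size", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE           # 4 px
  m[10:14, 10:14] <- TRUE       # 25 px
  cfg <- quant_config(combine_rule = "union", min_component_px = 10)
  out <- combine_binarizations(m, m, m, cfg)$mask
  expect_false(any(out[2:3, 2:3]))
  expect_true(all(out[10:14, 10:14]))
  expect_equal(count_components(out), 1L)
})

test_that("8-connected labeling counts diagonal touches as one component", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[5, 5] <- TRUE
  expect_equal(count_components(m), 2L)
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})
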