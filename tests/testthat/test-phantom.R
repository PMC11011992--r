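test_that("an empty network yields empty truth and zero density", {
  tr <- generate_network(seed = 1, dim_px = 64, n_trunks = 0,
                         caliber_um_range = c(50, 60))
  expect_equal(nrow(tr$segments), 0L)
  expect_false(any(tr$truth_binary))
  expect_equal(tr$truth_metrics$vad, 0)
  expect_false(tr$truth_metrics$vdi_defined)
})

test_that("phantom generation is deterministic in its seed", {
  a <- generate_network(seed = 42, dim_px = 128, n_trunks = 4,
                        caliber_um_range = c(24, 48))
  b <- generate_network(seed = 42, dim_px = 128, n_trunks = 4,
                        caliber_um_range = c(24, 48))
  expect_identical(a$truth_binary, b$truth_binary)
  expect_identical(a$segments, b$segments)
  c_ <- generate_network(seed = 43, dim_px = 128, n_trunks = 4,
                         caliber_um_range = c(24, 48))
  expect_false(identical(a$truth_binary, c_$truth_binary))
})

test_that("a single straight segment rasterizes to its known area and caliber", {
  # horizontal segment, caliber 5 px, length 100 px, in a 585 x 585 field
  pitch <- 3000 / 585
  segs <- data.frame(x0 = 200, y0 = 300, x1 = 300, y1 = 300,
                     caliber_um = 5 * pitch)
  rast <- octaquant:::rasterize_segments(segs, 585L, pitch)
  vad <- compute_vad(rast$binary)
  expect_lt(abs(vad - 500 / 342225), 0.15 * 500 / 342225)
  v <- compute_vdi(rast$binary, rast$skeleton, pitch)
  expect_lt(abs(v$vdi_px - 5), 0.6)
})

test_that("truth rasters satisfy the containment and range invariants", {
  for (s in 1:3) {
    tr <- generate_network(seed = s, dim_px = 195, n_trunks = 6,
                           caliber_um_range = c(16, 32))
    expect_true(all(tr$truth_binary[tr$truth_skeleton]))
    expect_gte(tr$truth_metrics$vad, 0); expect_lte(tr$truth_metrics$vad, 1)
    expect_lte(tr$truth_metrics$vsd, tr$truth_metrics$vad)
    if (tr$truth_metrics$vdi_defined) expect_gte(tr$truth_metrics$vdi_px, 1)
  }
})

test_that("noise-free rendering is an exact two-level raster of the truth", {
  tr <- generate_network(seed = 5, dim_px = 146, n_trunks = 4,
                         caliber_um_range = c(24, 42))
  img <- render(tr, contrast = 200, psf_sigma_px = 0, speckle_level = 0,
                seed = 1, background = 40)
  expect_setequal(unique(as.vector(img$pixels)), c(40, 240))
  expect_identical(img$pixels == 240, tr$truth_binary)
})

test_that("rendering is deterministic and speckle has the configured mean", {
  tr <- generate_network(seed = 5, dim_px = 146, n_trunks = 4,
                         caliber_um_range = c(24, 42))
  a <- render(tr, seed = 7); b <- render(tr, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, render(tr, seed = 8)$pixels))

  empty <- generate_network(seed = 1, dim_px = 64, n_trunks = 0,
                            caliber_um_range = c(50, 60))
  mns <- sapply(1:10, function(s)
    mean(render(empty, psf_sigma_px = 0, speckle_level = 0.35, seed = s,
                background = 100)$pixels))
  expect_true(all(abs(mns - 100) / 100 < 0.02))
})

test_that("quantification recovers truth VAD on rendered phantoms", {
  for (s in 1:3) {
    tr <- generate_network(seed = s, dim_px = 390)
    img <- render(tr, contrast = 255, psf_sigma_px = 0, speckle_level = 0)
    m <- quantify(img)
    expect_lt(abs(m$vad - tr$truth_metrics$vad), 0.02)
  }
})
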