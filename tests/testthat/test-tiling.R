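test_that("tile grids follow ceiling division", {
  g <- compute_tile_grid(126976, 126976, 2048)
  expect_identical(c(g$rows, g$cols, g$total), c(62L, 62L, 3844L))
  g2 <- compute_tile_grid(126976, 31744, 2048)
  expect_identical(c(g2$rows, g2$cols, g2$total), c(62L, 16L, 992L))
  expect_identical(compute_tile_grid(2048, 2048, 2048)$total, 1L)
  expect_identical(compute_tile_grid(2049, 2048, 2048)$rows, 2L)
  expect_error(compute_tile_grid(0, 10, 4), "positive")
})

test_that("otsu threshold maximizes between-class variance (brute-force oracle)", {
  # two equal spikes: every t in [50, 199] is optimal; smallest wins
  h <- integer(256)
  h[51] <- 100
  h[201] <- 100
  t <- otsu_threshold(h)
  expect_identical(as.integer(t), 50L)
  expect_identical(as.integer(t), as.integer(brute_otsu(h)))

  # bimodal gaussian mixture lands between the modes
  set.seed(11)
  vals <- pmin(pmax(round(c(rnorm(5e4, 60, 10), rnorm(5e4, 190, 10))), 0), 255)
  hg <- tabulate(vals + 1L, nbins = 256L)
  tg <- otsu_threshold(hg)
  expect_gte(as.numeric(tg), 100)
  expect_lte(as.numeric(tg), 150)
  expect_identical(as.integer(tg), as.integer(brute_otsu(hg)))

  # random histograms agree with the exhaustive scan
  set.seed(22)
  for (i in 1:20) {
    hr <- as.integer(rpois(256, lambda = runif(1, 0.5, 20)))
    if (sum(hr) == 0) hr[sample(256, 1)] <- 1L
    expect_identical(as.integer(otsu_threshold(hr)), as.integer(brute_otsu(hr)))
  }

  # degenerate single-bin histogram
  hd <- integer(256)
  hd[101] <- 50
  td <- otsu_threshold(hd)
  expect_identical(as.integer(td), 100L)
  expect_true(attr(td, "degenerate"))

  expect_error(otsu_threshold(integer(256)), "at least one pixel")
  expect_error(otsu_threshold(integer(10)), "256")
})

test_that("tissue fraction counts pixels at or below the threshold", {
  white <- array(255, c(8, 8, 3))
  expect_equal(tissue_fraction(white, 200), 0)
  half <- array(255, c(8, 8, 3))
  half[1:4, , ] <- 100
  expect_equal(tissue_fraction(half, 200), 0.5)

  # an OKC tile judged at the slide-level threshold is mostly tissue
  sl <- make_slide(slide_spec(1, 2, 64, c("OKC", "BACKGROUND"), seed = 3))
  th <- as.numeric(otsu_threshold(gray_histogram(sl$image)))
  okc <- make_tile(texture_params("OKC", seed = 3), 64)
  g <- rgb_to_gray(okc)
  expect_gt(tissue_fraction(okc, th), 0.5)
  # independent pixel count
  expect_equal(tissue_fraction(okc, th), sum(g <= th) / length(g))
})

test_that("tile_slide applies slide-level QC with grid conservation", {
  cm <- c("OKC", "OKC", "BACKGROUND", "OKC", "OKC", "BACKGROUND")
  sl <- make_slide(slide_spec(2, 3, 64, cm, seed = 2, slide_id = "qc"))
  rec <- tile_slide(sl$image, tiling_config(tile_size = 64), "qc")
  expect_identical(nrow(rec), 6L)
  expect_identical(sum(rec$qc_status == "KEPT"), 4L)
  expect_identical(sum(rec$qc_status == "DISCARDED_WHITE"), 2L)
  # QC matches the planted ground truth cell for cell
  joined <- dplyr::left_join(rec, sl$manifest[, c("row", "col", "true_class")],
    by = c("row", "col")
  )
  expect_identical(
    joined$qc_status == "KEPT",
    joined$true_class != "BACKGROUND"
  )
})

test_that("tiling partitions the padded raster disjointly", {
  set.seed(33)
  raster <- array(runif(50 * 70 * 3, 0, 255), c(50, 70, 3))
  rec <- tile_slide(raster, tiling_config(tile_size = 16), "p")
  g <- compute_tile_grid(50, 70, 16)
  expect_identical(nrow(rec), g$total)
  # each padded-raster pixel covered exactly once
  cover <- matrix(0L, g$rows * 16, g$cols * 16)
  for (i in seq_len(nrow(rec))) {
    cover[(rec$y0[i] + 1):rec$y1[i], (rec$x0[i] + 1):rec$x1[i]] <-
      cover[(rec$y0[i] + 1):rec$y1[i], (rec$x0[i] + 1):rec$x1[i]] + 1L
  }
  expect_true(all(cover == 1L))
  # PARTIAL edge policy clips boxes to the raster instead
  rec2 <- tile_slide(raster, tiling_config(tile_size = 16, edge_policy = "PARTIAL"), "p")
  expect_lte(max(rec2$y1), 50)
  expect_lte(max(rec2$x1), 70)
})

test_that("raising the tissue cutoff never increases the kept count", {
  sl <- make_slide(slide_spec(3, 3, 32,
    sample(c("OKC", "NONKC", "BACKGROUND"), 9, replace = TRUE),
    seed = 8
  ))
  kept <- purrr::map_int(c(0, 0.05, 0.2, 0.5, 0.9), function(mtf) {
    rec <- tile_slide(sl$image, tiling_config(tile_size = 32, min_tissue_fraction = mtf))
    sum(rec$qc_status == "KEPT")
  })
  expect_true(all(diff(kept) <= 0))
})

test_that("white padding beyond the edge never counts as tissue", {
  # 20x20 dark raster tiled at 16: edge tiles are padded with white
  raster <- array(50, c(20, 20, 3))
  rec <- tile_slide(raster, tiling_config(tile_size = 16), "e")
  expect_identical(nrow(rec), 4L)
  corner <- rec[rec$row == 1 & rec$col == 1, ]
  # only 4x4 of the 16x16 padded tile is real tissue
  expect_equal(corner$tissue_fraction, 16 / 256)
})

test_that("optional low-information heuristics mark blurry or dark tiles", {
  sl <- make_slide(slide_spec(1, 2, 32, c("OKC", "NONKC"), seed = 4))
  # an absurdly high blur cutoff marks every kept tile low-info
  rec <- tile_slide(sl$image, tiling_config(tile_size = 32, blur_cutoff = 1e9))
  expect_true(all(rec$qc_status == "DISCARDED_LOWINFO"))
  rec2 <- tile_slide(sl$image, tiling_config(tile_size = 32, dark_floor = 300))
  expect_true(all(rec2$qc_status == "DISCARDED_LOWINFO"))
  rec3 <- tile_slide(sl$image, tiling_config(tile_size = 32))
  expect_true(all(rec3$qc_status == "KEPT"))
})
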