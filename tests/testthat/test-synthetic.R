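test_that("tile generation is deterministic and class-faithful", {
  p <- texture_params("OKC", seed = 7)
  expect_identical(make_tile(p, 64), make_tile(p, 64))

  okc <- make_tile(texture_params("OKC", seed = 1), 64)
  nonkc <- make_tile(texture_params("NONKC", seed = 1), 64)
  expect_lt(mean(okc), 200)
  expect_lt(mean(nonkc), 200)

  bg <- make_tile(texture_params("BACKGROUND", noise_sd = 0), 32)
  expect_true(all(bg >= 240))
  expect_length(unique(as.vector(bg)), 1)
  expect_equal(tissue_fraction(bg, 200), 0)
  expect_equal(tissue_fraction(bg, 239), 0)

  expect_error(texture_params("CYST"), "class_name")
})

test_that("OKC and non-KC tiles differ in banded autocorrelation structure", {
  p_okc <- texture_params("OKC", seed = 1)
  okc <- rgb_to_gray(make_tile(p_okc, 64))
  nonkc <- rgb_to_gray(make_tile(texture_params("NONKC", seed = 1), 64))
  # full-period lag: stripes realign for OKC, so its autocorrelation is
  # high; the blotchy texture decays smoothly and sits well apart
  ac_okc <- direct_row_autocorr(okc, p_okc$band_period)
  ac_nonkc <- direct_row_autocorr(nonkc, p_okc$band_period)
  expect_gt(abs(ac_okc - ac_nonkc), 0.2)
  expect_gt(ac_okc, 0.7)
})

test_that("simple intensity/autocorrelation features separate the classes", {
  ds <- make_labeled_dataset(100, tile_size = 64, seed = 42)
  feats <- purrr::map_dfr(ds$image, function(img) {
    g <- rgb_to_gray(img)
    tibble::tibble(mean_int = mean(g), ac = direct_row_autocorr(g, 8))
  })
  feats$y <- as.integer(ds$label == "OKC")
  fit <- suppressWarnings(glm(y ~ mean_int + ac, family = binomial(), data = feats))
  acc <- mean((fitted(fit) >= 0.5) == (feats$y == 1))
  expect_gte(acc, 0.95)
})

test_that("slides assemble to the specified geometry with a faithful manifest", {
  cm <- c("OKC", "OKC", "BACKGROUND", "OKC", "OKC", "BACKGROUND")
  sp <- slide_spec(2, 3, 64, cm, seed = 3, slide_id = "s1")
  sl <- make_slide(sp)
  expect_identical(dim(sl$image), c(128L, 192L, 3L))
  expect_identical(nrow(sl$manifest), 6L)
  expect_identical(sl$manifest$true_class, cm)
  expect_equal(sl$manifest$x1 - sl$manifest$x0, rep(64, 6))

  # the published 62x62 grid count, checked at a miniature tile size
  big <- make_slide(slide_spec(62, 62, 2, rep("BACKGROUND", 3844), seed = 1))
  expect_identical(nrow(big$manifest), 3844L)

  expect_error(slide_spec(0, 3, 64, character(0)), "at least 1")
  expect_error(slide_spec(2, 3, 64, rep("OKC", 5)), "exactly")
})

test_that("all-background slides yield no kept tiles downstream", {
  sp <- slide_spec(2, 3, 32, rep("BACKGROUND", 6), seed = 5)
  sl <- make_slide(sp)
  rec <- tile_slide(sl$image, tiling_config(tile_size = 32))
  expect_identical(nrow(rec), 6L)
  expect_identical(sum(rec$qc_status == "KEPT"), 0L)
})

test_that("labeled datasets are balanced and reproducible", {
  ds <- make_labeled_dataset(10, tile_size = 32, seed = 1)
  expect_identical(nrow(ds), 20L)
  expect_identical(as.vector(table(ds$label)), c(10L, 10L))
  ds2 <- make_labeled_dataset(10, tile_size = 32, seed = 1)
  expect_identical(ds, ds2)
  # imbalance ratio exactly 1 regardless of size
  ds3 <- make_labeled_dataset(500, tile_size = 4, seed = 2)
  expect_identical(sum(ds3$label == "OKC"), sum(ds3$label == "NONKC"))
})

test_that("slides and manifests round-trip through disk", {
  dir <- withr::local_tempdir()
  sp <- slide_spec(2, 2, 16, rep(c("OKC", "NONKC"), 2), seed = 9, slide_id = "rt")
  sl <- make_slide(sp)
  img_path <- file.path(dir, "rt.png")
  man_path <- file.path(dir, "rt.csv")
  write_image(sl$image, img_path)
  write_manifest(sl$manifest, man_path)
  back <- read_image(img_path)
  expect_equal(back, sl$image, tolerance = 1e-8)
  man <- read_manifest(man_path)
  expect_equal(man$true_class, sl$manifest$true_class)
})
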