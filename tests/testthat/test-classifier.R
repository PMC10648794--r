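test_that("augmentation with zero ranges is the identity and draws are seeded", {
  tile <- make_tile(texture_params("OKC", seed = 1), 32)
  none <- augmentation_config(0, 0, 0, 0, 0, horizontal_flip = FALSE)
  expect_identical(augment(tile, none, draw_seed = 5), tile)
  cfg <- augmentation_config()
  a1 <- augment(tile, cfg, draw_seed = 9)
  a2 <- augment(tile, cfg, draw_seed = 9)
  expect_identical(a1, a2)
  a3 <- augment(tile, cfg, draw_seed = 10)
  expect_false(identical(a1, a3))
})

test_that("rotation-only augmentation matches a naive per-pixel oracle", {
  set.seed(4)
  tile <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  cfg <- augmentation_config(
    rotation_range = 30, width_shift = 0, height_shift = 0,
    shear_range = 0, zoom_range = 0, horizontal_flip = FALSE
  )
  out <- augment(tile, cfg, draw_seed = 21)
  # replicate the single uniform draw, then rotate by direct loops
  theta <- withr::with_seed(21, runif(1, -30, 30)) * pi / 180
  cx <- (16 + 1) / 2
  oracle <- array(0, dim(tile))
  for (yy in 1:16) {
    for (xx in 1:16) {
      # inverse rotation of the centred output coordinate
      px <- xx - cx
      py <- yy - cx
      xi <- cos(theta) * px + sin(theta) * py + cx
      yi <- -sin(theta) * px + cos(theta) * py + cx
      xi <- min(max(xi, 1), 16)
      yi <- min(max(yi, 1), 16)
      x0 <- min(floor(xi), 15)
      y0 <- min(floor(yi), 15)
      fx <- xi - x0
      fy <- yi - y0
      for (ch in 1:3) {
        oracle[yy, xx, ch] <-
          (1 - fy) * (1 - fx) * tile[y0, x0, ch] +
          (1 - fy) * fx * tile[y0, x0 + 1, ch] +
          fy * (1 - fx) * tile[y0 + 1, x0, ch] +
          fy * fx * tile[y0 + 1, x0 + 1, ch]
      }
    }
  }
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("the assembled default model reports the published parameter split", {
  fx <- fixture_pipeline()
  m <- assemble_model(fx$extractor, fx$pca, fx$selection, head_spec(64), seed = 1)
  expect_identical(m$trainable_params, 12929L)
  expect_identical(m$frozen_params, 115137L)
  expect_identical(m$trainable_params + m$frozen_params, 128066L)
  g <- glance(m)
  expect_identical(g$total_params, 128066L)
})

test_that("stage mismatches are rejected naming the stage", {
  fx <- fixture_pipeline()
  bad_sel <- structure(list(indices = c(1L, 500L), n_selected = 2L), class = "kc_selection")
  expect_error(assemble_model(fx$extractor, fx$pca, bad_sel), "selection")
  bad_pca <- fit_pca(matrix(rnorm(40), 10, 4), 2)
  expect_error(assemble_model(fx$extractor, bad_pca, fx$selection), "PCA")
})

test_that("head training reaches high validation accuracy on separable tiles", {
  fx <- fixture_pipeline()
  h <- fx$model$history
  expect_identical(nrow(h), 20L)
  expect_gte(dplyr::last(h$val_accuracy), 0.95)
  # 80-20 split honoured
  expect_identical(length(fx$model$split$train), 800L)
  expect_identical(length(fx$model$split$val), 200L)
})

test_that("training leaves the frozen stages bitwise unchanged", {
  fx <- fixture_pipeline()
  expect_identical(fx$model$extractor$params, fx$extractor$params)
  expect_identical(fx$model$pca, fx$pca)
  expect_identical(fx$model$selection, fx$selection)
})

test_that("predictions equal the stagewise composition of frozen stages and head", {
  fx <- fixture_pipeline()
  ns <- asNamespace("kcscreen")
  tiles <- fx$dataset$image[1:8]
  preds <- predict_tiles(fx$model, tiles)
  f <- extract_features(fx$extractor, tiles)
  z <- pca_transform(fx$pca, f)[, fx$selection$indices, drop = FALSE]
  manual <- as.vector(ns$net_forward(
    fx$model$head_layers, fx$model$head_params, z,
    keep_cache = FALSE
  )$out)
  expect_equal(preds$prob_okc, manual, tolerance = 1e-6)
  # duplicated tile, identical probability; order preserved
  p2 <- predict_tiles(fx$model, list(tiles[[3]], tiles[[3]]))
  expect_identical(p2$prob_okc[1], p2$prob_okc[2])
  expect_identical(nrow(predict_tiles(fx$model, list())), 0L)
})

test_that("shuffled labels yield chance-level validation accuracy", {
  arch <- small_architecture()
  ds <- make_labeled_dataset(75, tile_size = 16, seed = 55)
  ext <- pretrain_extractor(ds, ds$label, architecture = arch, epochs = 0, seed = 1)
  f <- extract_features(ext, ds)
  pca <- fit_pca(f, 8)
  accs <- purrr::map_dbl(1:5, function(s) {
    yshuf <- withr::with_seed(s, sample(as.character(ds$label)))
    rf <- relieff_weights(pca_transform(pca, f), yshuf, relieff_config(k_neighbors = 5))
    m <- assemble_model(ext, pca, top_k_indices(rf, 4), head_spec(8), seed = s)
    m <- train_head(m, ds, yshuf, training_config(epochs = 10, seed = s))
    dplyr::last(m$history$val_accuracy)
  })
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("degenerate training splits are rejected", {
  arch <- small_architecture()
  ds <- make_labeled_dataset(5, tile_size = 16, seed = 6)
  ext <- pretrain_extractor(ds, ds$label, architecture = arch, epochs = 0, seed = 1)
  f <- extract_features(ext, ds)
  pca <- fit_pca(f, 4)
  rf <- relieff_weights(pca_transform(pca, f), ds$label, relieff_config(k_neighbors = 2))
  m <- assemble_model(ext, pca, top_k_indices(rf, 4), head_spec(8))
  okc <- ds[ds$label == "OKC", ]
  expect_error(
    train_head(m, okc, okc$label, training_config(epochs = 1)),
    "both classes"
  )
  expect_error(
    train_head(m, ds, ds$label, training_config(split_unit = "SLIDE")),
    "slide_ids"
  )
})

test_that("head training is bit-reproducible under fixed seeds", {
  arch <- small_architecture()
  ds <- make_labeled_dataset(20, tile_size = 16, seed = 91)
  ext <- pretrain_extractor(ds, ds$label, architecture = arch, epochs = 1, seed = 14)
  f <- extract_features(ext, ds)
  pca <- fit_pca(f, 6)
  rf <- relieff_weights(pca_transform(pca, f), ds$label, relieff_config(k_neighbors = 3))
  sel <- top_k_indices(rf, 4)
  run <- function() {
    m <- assemble_model(ext, pca, sel, head_spec(8), seed = 2)
    train_head(m, ds, ds$label, training_config(epochs = 3, seed = 2),
      augmentation = augmentation_config(seed = 3)
    )
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$head_params, m2$head_params)
})
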