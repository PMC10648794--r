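# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Full trained pipeline on separable synthetic textures: pretrained
# extractor (160 tiles, 4 epochs), 1000-tile labeled set, PCA to 200,
# ReliefF ranking, trained head (20 epochs, augmented training tiles).
fixture_pipeline <- function() {
  if (!is.null(.fixture_env$pipeline)) {
    return(.fixture_env$pipeline)
  }
  pre <- make_labeled_dataset(80, tile_size = 64, seed = 101)
  ext <- pretrain_extractor(pre, pre$label, epochs = 4, batch_size = 32, seed = 101)
  ds <- make_labeled_dataset(500, tile_size = 64, seed = 202)
  feats <- extract_features(ext, ds)
  pca <- fit_pca(feats, 200)
  rf <- relieff_weights(pca_transform(pca, feats), ds$label, relieff_config(k_neighbors = 10))
  sel <- top_k_indices(rf, 200)
  model <- assemble_model(ext, pca, sel, head_spec(64), seed = 303)
  model <- train_head(
    model, ds, ds$label,
    training_config(epochs = 20, batch_size = 32, seed = 404),
    augmentation = augmentation_config(seed = 505)
  )
  .fixture_env$pipeline <- list(
    pretrain = pre, extractor = ext, dataset = ds, features = feats,
    pca = pca, relieff = rf, selection = sel, model = model
  )
  .fixture_env$pipeline
}

# A small architecture (16 x 16 input) for tests that exercise the training
# machinery without needing the full-size network.
small_architecture <- function() {
  build_architecture(
    list(
      layer_conv2d(6, 3),
      layer_maxpool(),
      layer_depthwise_conv2d(3),
      layer_conv2d(8, 1),
      layer_global_avg_pool(),
      layer_flatten(),
      layer_reduce_select(4),
      layer_dense(8, "relu"),
      layer_dense(1, "sigmoid")
    ),
    input_shape = c(16L, 16L, 3L),
    n_components = 8L, n_selected = 4L
  )
}

# Planted-truth evaluation cohort: 2 OKC-majority and 2 non-KC slides.
fixture_cohort_decisions <- function(model, threshold = 0.2) {
  purrr::map_dfr(1:4, function(i) {
    kind <- if (i <= 2) "OKC" else "NONKC"
    spec <- random_slide_spec(paste0("s", i), kind,
      grid_rows = 4, grid_cols = 4,
      tile_size = 64, seed = 9000 + i
    )
    sl <- make_slide(spec)
    rec <- tile_slide(sl$image, tiling_config(tile_size = 64), paste0("s", i))
    rec <- dplyr::left_join(rec, sl$manifest[, c("row", "col", "true_class")],
      by = c("row", "col")
    )
    kept <- dplyr::filter(rec, qc_status == "KEPT")
    tiles <- purrr::map(seq_len(nrow(kept)), ~ tile_pixels(sl$image, kept[.x, ]))
    preds <- predict_tiles(model, tiles)
    d <- decide_slide(preds, aggregation_config(threshold), slide_id = paste0("s", i))
    d$planted <- kind
    d
  })
}
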