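## Pretraining and feature extraction for the convolutional backbone.
##
## The backbone is trained in a first stage with a temporary dense head;
## after pretraining its weights are frozen and the flattened global-average
## pooled activations become the "CNN features" that PCA and ReliefF operate
## on. This two-stage wiring is the only coherent way to combine a trained
## network with offline, non-differentiable PCA/ReliefF fits.

extractor_layer_indices <- function(architecture) {
  kinds <- purrr::map_chr(architecture$layers, "kind")
  flat <- which(kinds == "FLATTEN")
  if (length(flat) == 0L) {
    stop("architecture has no FLATTEN layer", call. = FALSE)
  }
  seq_len(flat[1])
}

## Map labels to 0/1 with OKC (or the second factor level, or 1) positive.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if ("OKC" %in% levels(labels)) {
      return(as.numeric(labels == "OKC"))
    }
    return(as.numeric(labels == levels(labels)[2]))
  }
  if (is.character(labels)) {
    return(as.numeric(labels == "OKC"))
  }
  as.numeric(labels != 0)
}

#' Pretrain the convolutional feature extractor
#'
#' Trains the extractor jointly with a temporary two-layer dense head on
#' labeled tiles (Adam, binary cross-entropy), then freezes the
#' convolutional weights. With `epochs = 0` the extractor is returned
#' initialized but untrained; features still have the correct
#' dimensionality.
#'
#' @param tiles List of `64 x 64 x 3` arrays (or a tibble with an `image`
#'   list-column).
#' @param labels Tile labels; OKC is the positive class.
#' @param architecture A [build_architecture()] spec.
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param temp_hidden_units Width of the temporary pretraining head.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `kc_extractor` with frozen weights and a `history` tibble
#'   (epoch, loss, accuracy).
#' @export
pretrain_extractor <- function(tiles, labels,
                               architecture = build_architecture(),
                               epochs = 10L, batch_size = 32L,
                               learning_rate = 0.001,
                               temp_hidden_units = 64L,
                               seed = 1L) {
  tiles <- as_image_list(tiles)
  y <- as_binary_labels(labels)
  stopifnot(length(tiles) == length(y))
  idx <- extractor_layer_indices(architecture)
  ext_layers <- architecture$layers[idx]
  feature_dim <- architecture$feature_dim

  if (epochs > 0 && length(unique(y)) < 2L) {
    stop("pretraining requires tiles from both classes", call. = FALSE)
  }
  check_tile_dims(tiles, architecture$input_shape)

  # temporary head used only during pretraining
  head_layers <- list(
    c(layer_dense(temp_hidden_units, "relu"), list(input_channels = feature_dim)),
    c(layer_dense(1L, "sigmoid"), list(input_channels = temp_hidden_units))
  )
  all_layers <- c(ext_layers, head_layers)
  params <- init_network_params(all_layers, seed = derive_seed(seed, 11L))

  history <- tibble::tibble(epoch = integer(), loss = double(), accuracy = double())
  if (epochs > 0) {
    fit <- train_epochs(all_layers, params, tiles, y,
      epochs = epochs, batch_size = batch_size, lr = learning_rate,
      seed = derive_seed(seed, 12L)
    )
    params <- fit$params
    history <- fit$history
  }

  structure(
    list(
      architecture = architecture,
      layers = ext_layers,
      params = params[seq_along(ext_layers)],
      temp_head_params = params[length(ext_layers) + 1:2],
      feature_dim = feature_dim,
      history = history,
      seed = as.integer(seed)
    ),
    class = "kc_extractor"
  )
}

check_tile_dims <- function(tiles, input_shape) {
  want <- as.integer(input_shape)
  ok <- purrr::every(tiles, ~ identical(dim(.x), want))
  if (!ok) {
    stop(sprintf(
      "all tiles must be %s arrays; resize with resize_image()",
      paste(want, collapse = "x")
    ), call. = FALSE)
  }
}

#' Extract CNN features for a set of tiles
#'
#' Runs the frozen extractor forward; deterministic for fixed weights.
#'
#' @param extractor A `kc_extractor`.
#' @param tiles List of image arrays (or tibble with `image` list-column)
#'   matching the architecture's input shape.
#' @param batch_size Tiles per forward batch.
#' @return An `n_tiles x feature_dim` numeric matrix, rows in input order.
#' @export
extract_features <- function(extractor, tiles, batch_size = 32L) {
  stopifnot(inherits(extractor, "kc_extractor"))
  tiles <- as_image_list(tiles)
  if (length(tiles) == 0L) {
    return(matrix(0, 0L, extractor$feature_dim))
  }
  check_tile_dims(tiles, extractor$architecture$input_shape)
  out <- matrix(0, length(tiles), extractor$feature_dim)
  for (start in seq(1L, length(tiles), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(tiles))
    xb <- stack_images(tiles[idx])
    fw <- net_forward(extractor$layers, extractor$params, xb, keep_cache = FALSE)
    out[idx, ] <- fw$out
  }
  out
}

#' @export
print.kc_extractor <- function(x, ...) {
  cat(
    "<kc_extractor>", x$feature_dim, "features,",
    enumerate_parameters(x$params), "parameters,",
    nrow(x$history), "pretraining epochs\n"
  )
  invisible(x)
}

#' Glance at a pretrained extractor
#'
#' @param x A `kc_extractor`.
#' @param ... Unused.
#' @return One-row tibble: feature dimension, parameter count, epochs, final
#'   training loss/accuracy.
#' @export
glance.kc_extractor <- function(x, ...) {
  tibble::tibble(
    feature_dim = x$feature_dim,
    n_parameters = enumerate_parameters(x$params),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) dplyr::last(x$history$loss) else NA_real_,
    final_accuracy = if (nrow(x$history)) dplyr::last(x$history$accuracy) else NA_real_
  )
}
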