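## Full model assembly and head training.
##
## The assembled classifier is the frozen extractor, the fitted PCA, the
## ReliefF-selected feature subset, and a two-dense-layer head (hidden ReLU
## layer, then one sigmoid unit). Only the head is trainable; training uses
## Adam with binary cross-entropy at the published settings (learning rate
## 0.001, 80-20 train/validation split, Keras-style geometric augmentation
## of the training tiles).

#' Augmentation configuration
#'
#' Defaults mirror the published Keras train-generator settings: rotation
#' range 20 degrees, width/height shifts 0.1 of the tile size, shear 0.2
#' (shear factor), zoom 0.2 (scale drawn in `[0.8, 1.2]`), horizontal flips
#' on.
#'
#' @param rotation_range Max absolute rotation in degrees.
#' @param width_shift,height_shift Max absolute shift as a fraction of size.
#' @param shear_range Max absolute shear factor.
#' @param zoom_range Zoom drawn uniformly in `[1 - z, 1 + z]`.
#' @param horizontal_flip Allow mirror flips with probability 1/2.
#' @param seed Base seed for per-tile draws.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_range = 20,
                                width_shift = 0.1,
                                height_shift = 0.1,
                                shear_range = 0.2,
                                zoom_range = 0.2,
                                horizontal_flip = TRUE,
                                seed = 1L) {
  stopifnot(
    rotation_range >= 0, width_shift >= 0, height_shift >= 0,
    shear_range >= 0, zoom_range >= 0
  )
  structure(
    list(
      rotation_range = rotation_range, width_shift = width_shift,
      height_shift = height_shift, shear_range = shear_range,
      zoom_range = zoom_range, horizontal_flip = horizontal_flip,
      seed = as.integer(seed)
    ),
    class = "augmentation_config"
  )
}

#' Randomly augment one tile
#'
#' Draws a rotation, shifts, shear, zoom and flip uniformly within the
#' configured ranges (deterministically for a given `draw_seed`), composes
#' them into a single affine transform about the tile centre, and resamples
#' with bilinear interpolation (border pixels clamped). With all ranges zero
#' and flips off the output equals the input.
#'
#' @param tile `H x W x 3` array.
#' @param config An [augmentation_config()].
#' @param draw_seed Integer seed for this draw.
#' @return Augmented array of the same shape.
#' @export
augment <- function(tile, config = augmentation_config(), draw_seed = 1L) {
  assert_image(tile, "tile")
  h <- dim(tile)[1]
  w <- dim(tile)[2]
  draws <- local_seed(draw_seed, {
    list(
      theta = stats::runif(1, -config$rotation_range, config$rotation_range) * pi / 180,
      tx = stats::runif(1, -config$width_shift, config$width_shift) * w,
      ty = stats::runif(1, -config$height_shift, config$height_shift) * h,
      shear = stats::runif(1, -config$shear_range, config$shear_range),
      zoom = stats::runif(1, 1 - config$zoom_range, 1 + config$zoom_range),
      flip = config$horizontal_flip && stats::runif(1) < 0.5
    )
  })
  rot <- matrix(c(cos(draws$theta), sin(draws$theta), -sin(draws$theta), cos(draws$theta)), 2)
  shr <- matrix(c(1, 0, draws$shear, 1), 2)
  scl <- diag(c(draws$zoom, draws$zoom))
  flp <- diag(c(if (draws$flip) -1 else 1, 1))
  A <- rot %*% shr %*% scl %*% flp # acts on (x, y) about the centre
  if (draws$theta == 0 && draws$tx == 0 && draws$ty == 0 &&
    draws$shear == 0 && draws$zoom == 1 && !draws$flip) {
    return(tile)
  }
  Ainv <- solve(A)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  grid <- expand.grid(y = seq_len(h), x = seq_len(w))
  px <- grid$x - cx - draws$tx
  py <- grid$y - cy - draws$ty
  xin <- Ainv[1, 1] * px + Ainv[1, 2] * py + cx
  yin <- Ainv[2, 1] * px + Ainv[2, 2] * py + cy
  out <- array(0, dim(tile))
  for (ch in 1:3) {
    out[, , ch] <- matrix(bilinear_sample(tile[, , ch], yin, xin), nrow = h)
  }
  out
}

#' Head specification: two dense layers
#'
#' @param hidden_units Width of the hidden ReLU layer.
#' @param hidden_activation Activation of the hidden layer.
#' @return A `head_spec` list; the output layer is always one sigmoid unit.
#' @export
head_spec <- function(hidden_units = 64L, hidden_activation = "relu") {
  structure(
    list(hidden_units = as.integer(hidden_units), hidden_activation = hidden_activation),
    class = "head_spec"
  )
}

#' Training configuration for the classifier head
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs,batch_size Optimization settings.
#' @param split_fraction Training share of the 80-20 split.
#' @param split_unit `"TILE"` (split tiles at random, the published
#'   protocol) or `"SLIDE"` (keep all tiles of a slide on one side, which
#'   avoids leaking slide identity into validation).
#' @param seed Integer seed for the split, initialization and batch order.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 30L, batch_size = 32L,
                            split_fraction = 0.8, split_unit = c("TILE", "SLIDE"),
                            seed = 1L) {
  split_unit <- match.arg(split_unit)
  stopifnot(learning_rate > 0, split_fraction > 0, split_fraction < 1, epochs >= 0)
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), split_fraction = split_fraction,
      split_unit = split_unit, seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Assemble the full tile classifier
#'
#' Chains the frozen extractor, the fitted PCA (optional: `NULL` ranks raw
#' CNN features instead), the ReliefF selection and a freshly initialized
#' two-dense-layer head, validating that the dimensions line up at every
#' stage.
#'
#' @param extractor A `kc_extractor`.
#' @param pca A `kc_pca` fitted on training features, or `NULL`.
#' @param selection A `kc_selection` from [top_k_indices()].
#' @param head A [head_spec()].
#' @param seed Seed for head initialization.
#' @return A `kc_model` reporting `trainable_params` (head) and
#'   `frozen_params` (extractor); their sum for the default preset is
#'   128,066.
#' @export
assemble_model <- function(extractor, pca, selection, head = head_spec(), seed = 1L) {
  stopifnot(inherits(extractor, "kc_extractor"), inherits(selection, "kc_selection"))
  width_in <- extractor$feature_dim
  if (!is.null(pca)) {
    stopifnot(inherits(pca, "kc_pca"))
    if (length(pca$mean) != width_in) {
      stop(sprintf(
        "stage mismatch at PCA: extractor emits %d features but PCA was fitted on %d",
        width_in, length(pca$mean)
      ), call. = FALSE)
    }
    width_in <- pca$n_components
  }
  if (max(selection$indices) > width_in) {
    stop(sprintf(
      "stage mismatch at selection: index %d exceeds the %d available features",
      max(selection$indices), width_in
    ), call. = FALSE)
  }
  head_layers <- list(
    c(layer_dense(head$hidden_units, head$hidden_activation),
      list(input_channels = selection$n_selected)
    ),
    c(layer_dense(1L, "sigmoid"), list(input_channels = head$hidden_units))
  )
  head_params <- init_network_params(head_layers, seed = derive_seed(seed, 21L))
  structure(
    list(
      extractor = extractor, pca = pca, selection = selection,
      head = head, head_layers = head_layers, head_params = head_params,
      trainable_params = enumerate_parameters(head_params),
      frozen_params = enumerate_parameters(extractor$params),
      history = NULL, trained = FALSE, seed = as.integer(seed)
    ),
    class = "kc_model"
  )
}

## features -> selected feature rows for the head
model_head_input <- function(model, features) {
  z <- if (is.null(model$pca)) features else pca_transform(model$pca, features)
  z[, model$selection$indices, drop = FALSE]
}

#' Train the classifier head
#'
#' Splits the labeled tiles 80-20 (by tile or by slide), augments the
#' training tiles (one seeded draw per tile; validation tiles are left
#' untouched), extracts features through the frozen stages once, and fits
#' the two-layer head with Adam and binary cross-entropy. The extractor,
#' PCA and selection are bitwise unchanged by training.
#'
#' @param model A `kc_model` from [assemble_model()].
#' @param tiles Labeled tiles (list of arrays or tibble with `image`).
#' @param labels Tile labels; OKC positive.
#' @param config A [training_config()].
#' @param augmentation An [augmentation_config()] or `NULL` for none.
#' @param slide_ids Optional per-tile slide identifiers, required for
#'   `split_unit = "SLIDE"`.
#' @return The model with trained head weights and a `history` tibble
#'   (epoch, loss, accuracy, val_loss, val_accuracy).
#' @export
train_head <- function(model, tiles, labels, config = training_config(),
                       augmentation = NULL, slide_ids = NULL) {
  stopifnot(inherits(model, "kc_model"))
  tiles <- as_image_list(tiles)
  y <- as_binary_labels(labels)
  n <- length(tiles)
  stopifnot(length(y) == n)

  idx_train <- local_seed(derive_seed(config$seed, 31L), {
    if (config$split_unit == "SLIDE") {
      if (is.null(slide_ids)) {
        stop("`slide_ids` is required for split_unit = 'SLIDE'", call. = FALSE)
      }
      ids <- unique(slide_ids)
      tr <- sample(ids, max(1L, round(config$split_fraction * length(ids))))
      which(slide_ids %in% tr)
    } else {
      sample(n, round(config$split_fraction * n))
    }
  })
  idx_val <- setdiff(seq_len(n), idx_train)
  if (length(unique(y[idx_train])) < 2L) {
    stop("training split must contain both classes", call. = FALSE)
  }

  train_tiles <- tiles[idx_train]
  if (!is.null(augmentation)) {
    train_tiles <- purrr::imap(train_tiles, function(t, i) {
      augment(t, augmentation, draw_seed = derive_seed(augmentation$seed, i))
    })
  }

  f_train <- model_head_input(model, extract_features(model$extractor, train_tiles))
  f_val <- model_head_input(model, extract_features(model$extractor, tiles[idx_val]))
  y_train <- y[idx_train]
  y_val <- y[idx_val]

  params <- model$head_params
  state <- adam_init(params)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- local_seed(derive_seed(config$seed, 1000L + ep), sample(length(y_train)))
    losses <- c()
    accs <- c()
    for (start in seq(1L, length(y_train), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(y_train))]
      fw <- net_forward(model$head_layers, params, f_train[idx, , drop = FALSE])
      prob <- as.vector(fw$out)
      losses <- c(losses, bce_loss(prob, y_train[idx]))
      accs <- c(accs, mean((prob >= 0.5) == (y_train[idx] == 1)))
      dlogit <- matrix((prob - y_train[idx]) / length(idx), ncol = 1L)
      bw <- net_backward(model$head_layers, params, fw$caches, dlogit, dout_is_logit = TRUE)
      upd <- adam_step(params, bw$grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    val_prob <- if (length(y_val)) {
      as.vector(net_forward(model$head_layers, params, f_val, keep_cache = FALSE)$out)
    } else {
      numeric(0)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep,
      loss = mean(losses),
      accuracy = mean(accs),
      val_loss = if (length(y_val)) bce_loss(val_prob, y_val) else NA_real_,
      val_accuracy = if (length(y_val)) mean((val_prob >= 0.5) == (y_val == 1)) else NA_real_
    )
  }
  model$head_params <- params
  model$history <- dplyr::bind_rows(history)
  class(model$history) <- c("kc_history", class(model$history))
  model$trained <- TRUE
  model$split <- list(train = idx_train, val = idx_val)
  model
}

#' Predict per-tile OKC probabilities
#'
#' @param model A trained `kc_model`.
#' @param tiles Tiles to classify (list of arrays or tibble with `image`
#'   and optionally `tile_id`).
#' @param cutoff Hard-label cutoff on the OKC probability.
#' @return Tibble with `tile_id`, `prob_okc`, `label` (factor NONKC/OKC),
#'   rows in input order.
#' @export
predict_tiles <- function(model, tiles, cutoff = 0.5) {
  stopifnot(inherits(model, "kc_model"))
  ids <- if (is.data.frame(tiles) && "tile_id" %in% names(tiles)) {
    tiles$tile_id
  } else {
    NULL
  }
  tiles <- as_image_list(tiles)
  if (length(tiles) == 0L) {
    return(tibble::tibble(
      tile_id = character(0), prob_okc = double(0),
      label = factor(character(0), levels = c("NONKC", "OKC"))
    ))
  }
  feats <- model_head_input(model, extract_features(model$extractor, tiles))
  prob <- as.vector(net_forward(model$head_layers, model$head_params, feats,
    keep_cache = FALSE
  )$out)
  tibble::tibble(
    tile_id = ids %||% sprintf("tile_%04d", seq_along(tiles)),
    prob_okc = prob,
    label = factor(ifelse(prob >= cutoff, "OKC", "NONKC"), levels = c("NONKC", "OKC"))
  )
}

#' @export
print.kc_model <- function(x, ...) {
  cat(
    "<kc_model>", if (x$trained) "trained," else "untrained,",
    x$trainable_params, "trainable +", x$frozen_params, "frozen parameters\n"
  )
  invisible(x)
}

#' Glance at an assembled classifier
#'
#' @param x A `kc_model`.
#' @param ... Unused.
#' @return One-row tibble with parameter accounting and final validation
#'   metrics (NA until trained).
#' @export
glance.kc_model <- function(x, ...) {
  tibble::tibble(
    trainable_params = x$trainable_params,
    frozen_params = x$frozen_params,
    total_params = x$trainable_params + x$frozen_params,
    trained = x$trained,
    val_loss = if (!is.null(x$history)) dplyr::last(x$history$val_loss) else NA_real_,
    val_accuracy = if (!is.null(x$history)) dplyr::last(x$history$val_accuracy) else NA_real_
  )
}
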