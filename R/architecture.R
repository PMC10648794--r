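## Declarative architecture specification for the compact tile classifier.
##
## The default preset follows the published compact design: two standard
## convolutions with max pooling, a depthwise convolution after each
## (depthwise filters sit between the standard conv layers), a pointwise
## 1x1 convolution up to the feature width, global average pooling and
## flattening into the CNN feature vector. The feature vector is reduced to
## 200 dimensions (PCA, then ReliefF top-feature selection -- a
## parameter-free stage) and classified by two dense layers. Every trainable
## parameter is accounted for by closed forms: a k x k convolution with c_in
## inputs and c_out filters has k*k*c_in*c_out + c_out parameters, its
## depthwise counterpart k*k*c_in + c_in, and a dense layer
## n_in*n_out + n_out. The preset totals 128,066 trainable parameters.

LAYER_KINDS <- c(
  "CONV2D", "DEPTHWISE_CONV2D", "MAXPOOL", "GLOBAL_AVG_POOL",
  "FLATTEN", "REDUCE_SELECT", "DENSE"
)

#' Layer description helpers
#'
#' Constructors for the layer kinds understood by [build_architecture()].
#' `layer_reduce_select()` describes the PCA + ReliefF stage: it changes the
#' feature width but holds no trainable parameters.
#'
#' @param filters,units Output channels / units.
#' @param kernel Square kernel size in pixels.
#' @param activation Activation name (`"relu"`, `"sigmoid"`, `"linear"`).
#' @return A bare layer description list.
#' @export
layer_conv2d <- function(filters, kernel = 3L, activation = "relu") {
  list(kind = "CONV2D", filters = as.integer(filters), kernel = as.integer(kernel), activation = activation)
}

#' @rdname layer_conv2d
#' @export
layer_depthwise_conv2d <- function(kernel = 3L, activation = "relu") {
  list(kind = "DEPTHWISE_CONV2D", kernel = as.integer(kernel), activation = activation)
}

#' @rdname layer_conv2d
#' @export
layer_maxpool <- function() list(kind = "MAXPOOL")

#' @rdname layer_conv2d
#' @export
layer_global_avg_pool <- function() list(kind = "GLOBAL_AVG_POOL")

#' @rdname layer_conv2d
#' @export
layer_flatten <- function() list(kind = "FLATTEN")

#' @rdname layer_conv2d
#' @export
layer_reduce_select <- function(units) list(kind = "REDUCE_SELECT", units = as.integer(units))

#' @rdname layer_conv2d
#' @export
layer_dense <- function(units, activation = "relu") {
  list(kind = "DENSE", units = as.integer(units), activation = activation)
}

default_layer_list <- function(n_selected = 200L, hidden_units = 64L) {
  list(
    layer_conv2d(40, 3),
    layer_maxpool(),
    layer_depthwise_conv2d(3),
    layer_conv2d(160, 3),
    layer_maxpool(),
    layer_depthwise_conv2d(3),
    layer_conv2d(337, 1),
    layer_global_avg_pool(),
    layer_flatten(),
    layer_reduce_select(n_selected),
    layer_dense(hidden_units, "relu"),
    layer_dense(1, "sigmoid")
  )
}

layer_param_count <- function(ly) {
  switch(ly$kind,
    CONV2D = ly$kernel^2 * ly$input_channels * ly$filters + ly$filters,
    DEPTHWISE_CONV2D = ly$kernel^2 * ly$input_channels + ly$input_channels,
    DENSE = ly$input_channels * ly$units + ly$units,
    0L
  )
}

#' Build and validate an architecture specification
#'
#' Chains layer shapes from the input image through flattening, the
#' reduce/select stage and the dense head, rejecting inconsistent
#' configurations with the index of the offending layer. The `"default"`
#' preset totals 128,066 trainable parameters.
#'
#' @param config `"default"` or a list of layer descriptions (see
#'   [layer_conv2d()] and friends).
#' @param input_shape Input image shape, `c(height, width, channels)`.
#' @param n_components Number of PCA components fitted downstream (must not
#'   exceed the flattened feature width).
#' @param n_selected Number of ReliefF-selected features entering the head
#'   (used by the `"default"` preset's reduce/select layer).
#' @param hidden_units Hidden width of the default preset's first dense layer.
#' @return A `kc_architecture` object: validated layers with derived
#'   `input_channels`, `output_shape` and `params`, plus `feature_dim`,
#'   `extractor_params`, `head_params` and `total_params`.
#' @export
build_architecture <- function(config = "default",
                               input_shape = c(64L, 64L, 3L),
                               n_components = 200L,
                               n_selected = 200L,
                               hidden_units = 64L) {
  layers <- if (is.character(config) && length(config) == 1L) {
    switch(config,
      default = default_layer_list(n_selected, hidden_units),
      stop("unknown architecture preset: ", config, call. = FALSE)
    )
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a preset name or a list of layers", call. = FALSE)
  }

  shape <- as.integer(input_shape) # c(H, W, C) then collapses to a width
  spatial <- TRUE
  feature_dim <- NA_integer_
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (!ly$kind %in% LAYER_KINDS) {
      stop(sprintf("layer %d: unknown kind '%s'", i, ly$kind), call. = FALSE)
    }
    bad <- function(msg) {
      stop(sprintf("inconsistent shape chain at layer %d (%s): %s", i, ly$kind, msg),
        call. = FALSE
      )
    }
    if (ly$kind %in% c("CONV2D", "DEPTHWISE_CONV2D", "MAXPOOL", "GLOBAL_AVG_POOL")) {
      if (!spatial) bad("spatial layer after flattening")
    }
    shape <- switch(ly$kind,
      CONV2D = {
        layers[[i]]$input_channels <- shape[3]
        c(shape[1], shape[2], ly$filters)
      },
      DEPTHWISE_CONV2D = {
        layers[[i]]$input_channels <- shape[3]
        shape
      },
      MAXPOOL = {
        if (shape[1] %% 2L != 0L || shape[2] %% 2L != 0L) {
          bad(sprintf("spatial size %dx%d is not divisible by 2", shape[1], shape[2]))
        }
        c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      },
      GLOBAL_AVG_POOL = {
        spatial <- FALSE
        shape[3]
      },
      FLATTEN = {
        if (spatial) {
          spatial <- FALSE
          prod(shape)
        } else {
          shape[1]
        }
      },
      REDUCE_SELECT = {
        if (spatial) bad("reduce/select requires flattened features")
        if (ly$units > shape[1]) {
          bad(sprintf("cannot select %d of %d features", ly$units, shape[1]))
        }
        layers[[i]]$input_channels <- shape[1]
        ly$units
      },
      DENSE = {
        if (spatial) bad("dense layer requires flattened features")
        layers[[i]]$input_channels <- shape[1]
        ly$units
      }
    )
    layers[[i]]$output_shape <- shape
    if (layers[[i]]$kind == "FLATTEN") feature_dim <- shape[1]
    if (is.na(feature_dim) && layers[[i]]$kind == "GLOBAL_AVG_POOL" &&
      i == length(layers)) {
      feature_dim <- shape[1]
    }
    layers[[i]]$params <- layer_param_count(layers[[i]])
  }

  kinds <- purrr::map_chr(layers, "kind")
  flat_at <- which(kinds == "FLATTEN")
  extractor_idx <- if (length(flat_at)) seq_len(flat_at[1]) else seq_along(layers)
  params_per <- purrr::map_int(layers, ~ as.integer(.x$params))
  if (!is.na(feature_dim) && n_components > feature_dim) {
    stop(sprintf(
      "n_components (%d) exceeds the flattened feature width (%d)",
      n_components, feature_dim
    ), call. = FALSE)
  }

  structure(
    list(
      layers = layers,
      input_shape = as.integer(input_shape),
      feature_dim = feature_dim,
      n_components = as.integer(n_components),
      extractor_params = sum(params_per[extractor_idx]),
      head_params = sum(params_per[-extractor_idx]),
      total_params = sum(params_per)
    ),
    class = "kc_architecture"
  )
}

#' Count trainable parameters of an architecture
#'
#' Sums the per-layer closed forms. An empty specification counts zero.
#'
#' @param spec A `kc_architecture` object or a bare list of layer
#'   descriptions that already carry `input_channels`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(spec) {
  layers <- if (inherits(spec, "kc_architecture")) spec$layers else spec
  if (length(layers) == 0L) {
    return(0L)
  }
  sum(purrr::map_int(layers, ~ as.integer(layer_param_count(.x))))
}

#' Enumerate the parameters actually allocated in a built network
#'
#' Independent cross-check of [count_trainable_parameters()]: sums the
#' lengths of every weight and bias array in a parameter list created by the
#' network builder.
#'
#' @param params Parameter list as produced by the internal builder (one
#'   entry per layer; `NULL` for parameter-free layers).
#' @return Integer count of stored parameter values.
#' @export
enumerate_parameters <- function(params) {
  sum(purrr::map_int(params, function(p) {
    if (is.null(p)) 0L else as.integer(length(p$w) + length(p$b))
  }))
}

#' @export
print.kc_architecture <- function(x, ...) {
  cat("<kc_architecture> input", paste(x$input_shape, collapse = "x"), "\n")
  print(tidy(x), n = Inf)
  cat(
    "extractor:", x$extractor_params, " head:", x$head_params,
    " total:", x$total_params, "parameters\n"
  )
  invisible(x)
}

#' Tidy an architecture into a per-layer tibble
#'
#' @param x A `kc_architecture`.
#' @param ... Unused.
#' @return Tibble with one row per layer: kind, kernel, output shape, and
#'   trainable parameter count.
#' @export
tidy.kc_architecture <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$layers),
    kind = purrr::map_chr(x$layers, "kind"),
    kernel = purrr::map_int(x$layers, ~ as.integer(.x$kernel %||% NA_integer_)),
    output_shape = purrr::map_chr(x$layers, ~ paste(.x$output_shape, collapse = "x")),
    params = purrr::map_int(x$layers, ~ as.integer(.x$params))
  )
}
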