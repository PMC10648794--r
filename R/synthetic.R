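## Synthetic tiles and slides with known per-tile ground truth.
##
## Real keratocyst histology cannot be emulated at desk scale; the classes
## here differ by controlled texture statistics only. OKC tiles carry a
## banded stripe pattern echoing the palisaded basal layer at the level of
## image statistics, non-KC tiles a blotchy low-frequency texture, and
## background tiles are near-white. That is enough to make every downstream
## stage testable with known answers.

SYNTH_CLASSES <- c("OKC", "NONKC", "BACKGROUND")

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. Keeps every generator a pure function of its
## spec without clobbering the session RNG.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a stage/cell seed from a parent seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Texture parameters for one synthetic tile class
#'
#' Defaults define the generator's study conditions: OKC tiles are darker
#' (base 130) with stripes of period 8 px, non-KC tiles are lighter (base
#' 150) with blotches on a 16 px scale, background tiles are near-white
#' (base 250) with low noise.
#'
#' @param class_name One of `"OKC"`, `"NONKC"`, `"BACKGROUND"`.
#' @param base_intensity Mean gray level, 0-255.
#' @param band_period Stripe period (OKC) or blotch scale (non-KC) in pixels.
#' @param noise_sd Standard deviation of additive pixel noise.
#' @param seed Integer seed; identical parameters always give identical pixels.
#' @return A `texture_params` list.
#' @export
texture_params <- function(class_name,
                           base_intensity = NULL,
                           band_period = NULL,
                           noise_sd = NULL,
                           seed = 1L) {
  if (length(class_name) != 1L || !class_name %in% SYNTH_CLASSES) {
    stop("`class_name` must be one of ", paste(SYNTH_CLASSES, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- switch(class_name,
    OKC = list(base_intensity = 130, band_period = 8, noise_sd = 10),
    NONKC = list(base_intensity = 150, band_period = 16, noise_sd = 10),
    BACKGROUND = list(base_intensity = 250, band_period = 8, noise_sd = 3)
  )
  p <- list(
    class_name = class_name,
    base_intensity = base_intensity %||% defaults$base_intensity,
    band_period = band_period %||% defaults$band_period,
    noise_sd = noise_sd %||% defaults$noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    p$band_period > 0,
    p$base_intensity >= 0, p$base_intensity <= 255,
    p$noise_sd >= 0
  )
  structure(p, class = "texture_params")
}

#' Generate one synthetic tile
#'
#' @param params A [texture_params()] object.
#' @param tile_size Side length in pixels.
#' @return A `tile_size x tile_size x 3` integer-valued array, 0-255.
#' @export
make_tile <- function(params, tile_size = 64L) {
  if (!inherits(params, "texture_params")) {
    params <- do.call(texture_params, params)
  }
  stopifnot(tile_size >= 1)
  n <- as.integer(tile_size)
  local_seed(params$seed, {
    gray <- switch(params$class_name,
      OKC = {
        # square-wave stripes along rows: a palisade-like banding; the dark
        # phase covers 5/8 of the period so tissue dominates the tile under
        # any threshold between the two stripe modes
        phase <- ((seq_len(n) - 1L) %% params$band_period) < 5 * params$band_period / 8
        band <- ifelse(phase, -45, 45)
        matrix(rep(params$base_intensity + band, n), nrow = n)
      },
      NONKC = {
        # blotchy low-frequency field: coarse gaussian grid, upsampled
        hc <- max(2L, ceiling(n / params$band_period) + 1L)
        coarse <- matrix(params$base_intensity + stats::rnorm(hc * hc, 0, 35), hc)
        pos <- (seq_len(n) - 0.5) * hc / n + 0.5
        grid <- expand.grid(y = pos, x = pos)
        matrix(bilinear_sample(coarse, grid$y, grid$x), nrow = n)
      },
      BACKGROUND = matrix(params$base_intensity, n, n)
    )
    gray <- gray + stats::rnorm(n * n, 0, params$noise_sd)
    # RGB from one gray field plus small per-channel jitter that vanishes
    # with the noise level (so noise_sd = 0 stays exactly constant)
    jitter_sd <- 0.2 * params$noise_sd
    img <- array(0, c(n, n, 3L))
    for (ch in 1:3) {
      img[, , ch] <- gray + stats::rnorm(n * n, 0, jitter_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))
    img
  })
}

#' Specification of a synthetic composite slide
#'
#' @param grid_rows,grid_cols Number of tile cells along each axis.
#' @param tile_size Cell side length in pixels.
#' @param class_map Character vector (row-major) or matrix of per-cell classes,
#'   each one of `"OKC"`, `"NONKC"`, `"BACKGROUND"`; exactly
#'   `grid_rows * grid_cols` entries.
#' @param seed Integer seed for all cell textures.
#' @param slide_id Identifier carried into the manifest.
#' @return A `slide_spec` list.
#' @export
slide_spec <- function(grid_rows, grid_cols, tile_size, class_map,
                       seed = 1L, slide_id = "slide") {
  if (grid_rows < 1 || grid_cols < 1) {
    stop("`grid_rows` and `grid_cols` must be at least 1", call. = FALSE)
  }
  cm <- if (is.matrix(class_map)) as.vector(t(class_map)) else as.character(class_map)
  if (length(cm) != grid_rows * grid_cols) {
    stop("`class_map` must have exactly grid_rows * grid_cols entries", call. = FALSE)
  }
  if (!all(cm %in% SYNTH_CLASSES)) {
    stop("`class_map` entries must be one of ", paste(SYNTH_CLASSES, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      tile_size = as.integer(tile_size), class_map = cm,
      seed = as.integer(seed), slide_id = slide_id
    ),
    class = "slide_spec"
  )
}

#' Assemble a synthetic slide raster and its ground-truth manifest
#'
#' Tiles are generated cell by cell with [make_tile()] (each cell gets a seed
#' derived from the slide seed) and placed on a
#' `grid_rows*tile_size x grid_cols*tile_size` canvas.
#'
#' @param spec A [slide_spec()].
#' @return A list with `image` (the raster array) and `manifest`, a tibble
#'   with columns `slide_id, row, col, x0, y0, x1, y1, true_class`
#'   (0-based half-open pixel boxes; `x` along width, `y` along height).
#' @export
make_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  ts <- spec$tile_size
  h <- spec$grid_rows * ts
  w <- spec$grid_cols * ts
  raster <- array(0, c(h, w, 3L))
  rows <- integer(0)
  cols <- integer(0)
  classes <- character(0)
  cell <- 0L
  for (r in seq_len(spec$grid_rows) - 1L) {
    for (cc in seq_len(spec$grid_cols) - 1L) {
      cell <- cell + 1L
      cls <- spec$class_map[cell]
      tile <- make_tile(
        texture_params(cls, seed = derive_seed(spec$seed, cell)),
        tile_size = ts
      )
      raster[r * ts + seq_len(ts), cc * ts + seq_len(ts), ] <- tile
      rows <- c(rows, r)
      cols <- c(cols, cc)
      classes <- c(classes, cls)
    }
  }
  manifest <- tibble::tibble(
    slide_id = spec$slide_id,
    row = rows, col = cols,
    x0 = cols * ts, y0 = rows * ts,
    x1 = cols * ts + ts, y1 = rows * ts + ts,
    true_class = classes
  )
  list(image = raster, manifest = manifest)
}

#' Random slide specification for a planted-truth cohort
#'
#' Builds a [slide_spec()] whose cell classes are drawn so the slide's
#' ground-truth label is known: a fixed share of cells is background, and
#' among tissue cells the OKC share is high for planted-OKC slides (default
#' 0.5, comfortably above the 20% decision threshold) and low for
#' planted-non-KC slides (default 0.05, below the 15% lower band edge).
#'
#' @param slide_id Identifier.
#' @param kind Planted slide label, `"OKC"` or `"NONKC"`.
#' @param grid_rows,grid_cols,tile_size Slide geometry.
#' @param okc_share Share of tissue cells that are OKC.
#' @param background_share Share of all cells that are background.
#' @param seed Integer seed.
#' @return A [slide_spec()].
#' @export
random_slide_spec <- function(slide_id, kind = c("OKC", "NONKC"),
                              grid_rows = 4L, grid_cols = 4L, tile_size = 64L,
                              okc_share = NULL, background_share = 0.25,
                              seed = 1L) {
  kind <- match.arg(kind)
  okc_share <- okc_share %||% if (kind == "OKC") 0.5 else 0.05
  n <- grid_rows * grid_cols
  local_seed(derive_seed(seed, 1L), {
    n_bg <- round(background_share * n)
    n_tissue <- n - n_bg
    n_okc <- round(okc_share * n_tissue)
    classes <- c(
      rep("BACKGROUND", n_bg),
      rep("OKC", n_okc),
      rep("NONKC", n_tissue - n_okc)
    )
    slide_spec(grid_rows, grid_cols, tile_size,
      class_map = sample(classes),
      seed = derive_seed(seed, 2L), slide_id = slide_id
    )
  })
}

#' Balanced labeled tile dataset
#'
#' Stands in for a pathologist-labeled tile set: `n_per_class` OKC and
#' `n_per_class` non-KC tiles at default texture parameters, shuffled,
#' reproducible under `seed`.
#'
#' @param n_per_class Tiles per class (at least 1).
#' @param tile_size Tile side length in pixels.
#' @param seed Integer seed.
#' @return A tibble with columns `tile_id`, `label` (factor, levels
#'   `NONKC`, `OKC`) and `image` (list-column of arrays).
#' @export
make_labeled_dataset <- function(n_per_class, tile_size = 64L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("OKC", "NONKC"), each = n_per_class)
  images <- purrr::map(seq_along(labels), function(i) {
    make_tile(
      texture_params(labels[i], seed = derive_seed(seed, i)),
      tile_size = tile_size
    )
  })
  ord <- local_seed(derive_seed(seed, 0L), sample(length(labels)))
  tibble::tibble(
    tile_id = sprintf("tile_%04d", seq_along(labels)),
    label = factor(labels[ord], levels = c("NONKC", "OKC")),
    image = images[ord]
  )
}

#' Write a slide manifest CSV
#'
#' @param manifest Tibble as produced by [make_slide()] or [tile_slide()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
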