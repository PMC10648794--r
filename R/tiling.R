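## Slide tiling and Otsu-based tissue QC.
##
## A slide raster is cut into fixed-size square tiles (ceiling division, edge
## tiles padded white by default), a single Otsu threshold is computed from
## the whole-slide grayscale histogram, and every tile's tissue fraction --
## the share of pixels at or below that threshold -- decides whether it is
## kept or discarded as white/uninformative.

#' Tiling configuration
#'
#' @param tile_size Tile side length in pixels (default 2048, the scanner
#'   pipeline's native tile size; tests typically use 64).
#' @param min_tissue_fraction Minimum tissue fraction for a tile to be kept.
#' @param edge_policy `"PAD_WHITE"` (edge tiles padded to square with white)
#'   or `"PARTIAL"` (edge tiles kept at their clipped size).
#' @param white_cap Upper cap on the effective tissue threshold. On slides
#'   that are almost entirely background, Otsu splits the white noise itself
#'   and would call half the pixels tissue; capping the threshold keeps
#'   near-white pixels classified as background.
#' @param blur_cutoff Optional variance-of-Laplacian cutoff; tiles below it
#'   are marked `DISCARDED_LOWINFO`. `NULL` disables the heuristic.
#' @param dark_floor Optional mean-intensity floor; tiles darker than it are
#'   marked `DISCARDED_LOWINFO`. `NULL` disables the heuristic.
#' @return A `tiling_config` list.
#' @export
tiling_config <- function(tile_size = 2048L,
                          min_tissue_fraction = 0.05,
                          edge_policy = c("PAD_WHITE", "PARTIAL"),
                          white_cap = 235,
                          blur_cutoff = NULL,
                          dark_floor = NULL) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(
    tile_size >= 1,
    min_tissue_fraction >= 0, min_tissue_fraction <= 1
  )
  structure(
    list(
      tile_size = as.integer(tile_size),
      min_tissue_fraction = min_tissue_fraction,
      edge_policy = edge_policy,
      white_cap = white_cap,
      blur_cutoff = blur_cutoff,
      dark_floor = dark_floor
    ),
    class = "tiling_config"
  )
}

#' Tile grid for a slide of given pixel dimensions
#'
#' Ceiling division: a 126,976 x 126,976 slide at tile size 2048 gives a
#' 62 x 62 grid of 3844 tiles.
#'
#' @param height,width Slide dimensions in pixels.
#' @param tile_size Tile side length in pixels.
#' @return A one-row tibble with `rows`, `cols`, `tile_size`, `total`.
#' @export
compute_tile_grid <- function(height, width, tile_size) {
  if (height < 1 || width < 1 || tile_size < 1) {
    stop("`height`, `width` and `tile_size` must all be positive", call. = FALSE)
  }
  rows <- ceiling(height / tile_size)
  cols <- ceiling(width / tile_size)
  tibble::tibble(
    rows = as.integer(rows), cols = as.integer(cols),
    tile_size = as.integer(tile_size),
    total = as.integer(rows * cols)
  )
}

#' Grayscale histogram of an image
#'
#' @param x An RGB array or a grayscale matrix on the 0-255 scale.
#' @return Integer vector of 256 counts for rounded intensities 0..255.
#' @export
gray_histogram <- function(x) {
  gray <- if (is.matrix(x)) x else rgb_to_gray(x)
  vals <- pmin(pmax(round(gray), 0), 255)
  tabulate(as.vector(vals) + 1L, nbins = 256L)
}

#' Otsu threshold from a 256-bin grayscale histogram
#'
#' Returns the intensity `t` in 0..255 that maximizes the between-class
#' variance of the split into pixels `<= t` and `> t`. When several
#' thresholds tie, the smallest is returned. A histogram with a single
#' occupied bin has zero between-class variance everywhere; that bin's value
#' is returned with attribute `degenerate = TRUE`.
#'
#' @param counts Integer vector of 256 histogram counts (intensities 0..255).
#' @return The threshold as a single number with attribute `degenerate`.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0)) {
    stop("`counts` must be 256 non-negative histogram counts", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("histogram must contain at least one pixel", call. = FALSE)
  levels <- 0:255
  if (sum(counts > 0) == 1L) {
    t <- levels[counts > 0]
    return(structure(t, degenerate = TRUE))
  }
  p <- counts / n
  omega <- cumsum(p) # class probability of {<= t}
  mu <- cumsum(p * levels) # cumulative first moment
  mu_total <- mu[256]
  # between-class variance for each candidate threshold t = 0..255
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_total * omega - mu)^2 / denom, 0)
  structure(levels[which.max(sigma_b)], degenerate = FALSE)
}

#' Tissue fraction of a tile
#'
#' Tissue is defined as pixels whose grayscale value is at or below the
#' threshold (darker than background).
#'
#' @param tile RGB array or grayscale matrix, 0-255 scale.
#' @param threshold Intensity threshold.
#' @return Proportion in `[0, 1]`.
#' @export
tissue_fraction <- function(tile, threshold) {
  gray <- if (is.matrix(tile)) tile else rgb_to_gray(tile)
  if (length(gray) < 1) stop("tile must be non-empty", call. = FALSE)
  mean(gray <= threshold)
}

## variance of the 4-neighbour Laplacian, a standard blur score
laplacian_variance <- function(gray) {
  h <- nrow(gray)
  w <- ncol(gray)
  if (h < 3 || w < 3) {
    return(0)
  }
  core <- gray[2:(h - 1), 2:(w - 1)]
  lap <- gray[1:(h - 2), 2:(w - 1)] + gray[3:h, 2:(w - 1)] +
    gray[2:(h - 1), 1:(w - 2)] + gray[2:(h - 1), 3:w] - 4 * core
  stats::var(as.vector(lap))
}

#' Partition a slide into QC'd tile records
#'
#' Computes the tile grid by ceiling division, a single Otsu threshold from
#' the whole-slide grayscale histogram (capped at `white_cap`), and emits one
#' record per grid cell with its tissue fraction and QC status. Exactly
#' `rows * cols` records are emitted; kept tiles are those whose tissue
#' fraction reaches `min_tissue_fraction` (and that pass the optional
#' blur/darkness heuristics).
#'
#' @param raster An `H x W x 3` slide image, 0-255 scale.
#' @param config A [tiling_config()].
#' @param slide_id Identifier carried into the records.
#' @return A tibble with columns `slide_id, row, col, x0, y0, x1, y1,
#'   tissue_fraction, qc_status` plus attributes `otsu_threshold` and
#'   `effective_threshold`. Boxes are 0-based half-open, clipped to the
#'   unpadded raster only under `edge_policy = "PARTIAL"`.
#' @export
tile_slide <- function(raster, config = tiling_config(), slide_id = "slide") {
  assert_image(raster, "raster")
  stopifnot(inherits(config, "tiling_config"))
  h <- dim(raster)[1]
  w <- dim(raster)[2]
  ts <- config$tile_size
  grid <- compute_tile_grid(h, w, ts)

  gray <- rgb_to_gray(raster)
  otsu <- otsu_threshold(gray_histogram(gray))
  eff <- min(as.numeric(otsu), config$white_cap)

  cells <- tidyr::expand_grid(row = seq_len(grid$rows) - 1L, col = seq_len(grid$cols) - 1L)
  rec <- purrr::pmap_dfr(cells, function(row, col) {
    y0 <- row * ts
    x0 <- col * ts
    y1 <- min(y0 + ts, h)
    x1 <- min(x0 + ts, w)
    gtile <- gray[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    npix <- if (config$edge_policy == "PAD_WHITE") ts * ts else length(gtile)
    # white padding never counts as tissue, so sum over real pixels only
    frac <- sum(gtile <= eff) / npix
    status <- if (frac < config$min_tissue_fraction) {
      "DISCARDED_WHITE"
    } else if ((!is.null(config$blur_cutoff) && laplacian_variance(gtile) < config$blur_cutoff) ||
      (!is.null(config$dark_floor) && mean(gtile) < config$dark_floor)) {
      "DISCARDED_LOWINFO"
    } else {
      "KEPT"
    }
    tibble::tibble(
      slide_id = slide_id, row = row, col = col,
      x0 = x0, y0 = y0,
      x1 = if (config$edge_policy == "PAD_WHITE") x0 + ts else x1,
      y1 = if (config$edge_policy == "PAD_WHITE") y0 + ts else y1,
      tissue_fraction = frac, qc_status = status
    )
  })
  attr(rec, "otsu_threshold") <- as.numeric(otsu)
  attr(rec, "effective_threshold") <- eff
  rec
}

#' Extract the pixel tile for one tile record
#'
#' @param raster The slide image the record refers to.
#' @param record One-row tile record (as returned by [tile_slide()]).
#' @param pad_value Intensity used for white padding beyond the raster edge.
#' @return An RGB array of the record's box size.
#' @export
tile_pixels <- function(raster, record, pad_value = 255) {
  assert_image(raster, "raster")
  h <- dim(raster)[1]
  w <- dim(raster)[2]
  ys <- (record$y0 + 1):record$y1
  xs <- (record$x0 + 1):record$x1
  out <- array(pad_value, c(length(ys), length(xs), 3L))
  yin <- ys[ys <= h]
  xin <- xs[xs <= w]
  out[seq_along(yin), seq_along(xin), ] <- raster[yin, xin, , drop = FALSE]
  out
}
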