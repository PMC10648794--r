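## Images are plain numeric arrays H x W x 3 with intensities on the 0-255
## scale. PNG/TIFF round-trips go through the png/tiff packages (0-1 scale on
## disk, rescaled at the boundary).

#' Validate an RGB image array
#'
#' @param x An `H x W x 3` numeric array with intensities in `[0, 255]`.
#' @param arg Name used in error messages.
#' @return The validated array, invisibly unchanged.
#' @keywords internal
assert_image <- function(x, arg = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) {
    stop(sprintf("`%s` must have at least one pixel", arg), call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no missing values", arg), call. = FALSE)
  }
  invisible(x)
}

#' Convert an RGB image to grayscale
#'
#' Uses the standard luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image An `H x W x 3` array on the 0-255 scale.
#' @return An `H x W` numeric matrix of grayscale intensities.
#' @export
rgb_to_gray <- function(image) {
  assert_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Read and write images
#'
#' `read_image()` reads a PNG (or TIFF, if the tiff package is installed) into
#' an `H x W x 3` array on the 0-255 scale; `write_image()` is the inverse.
#' Grayscale and alpha channels are expanded/dropped to RGB.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @return `read_image()`: an `H x W x 3` array. `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  } else if (dim(raw)[3] > 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  }
  raw * 255
}

#' @rdname read_image
#' @param image An `H x W x 3` array on the 0-255 scale.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  scaled <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, target = path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::writeTIFF(scaled, path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

## Bilinear sampling at fractional coordinates, clamped to the image border.
## `ys`, `xs` are equal-length vectors of row/column positions (1-based).
bilinear_sample <- function(channel, ys, xs) {
  h <- nrow(channel)
  w <- ncol(channel)
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L)
  x0 <- pmin(floor(xs), w - 1L)
  if (h == 1L) y0 <- rep(1, length(ys))
  if (w == 1L) x0 <- rep(1, length(xs))
  fy <- ys - y0
  fx <- xs - x0
  y1 <- pmin(y0 + 1, h)
  x1 <- pmin(x0 + 1, w)
  idx <- function(r, c) channel[cbind(r, c)]
  (1 - fy) * (1 - fx) * idx(y0, x0) +
    (1 - fy) * fx * idx(y0, x1) +
    fy * (1 - fx) * idx(y1, x0) +
    fy * fx * idx(y1, x1)
}

#' Resize an RGB image with bilinear interpolation
#'
#' @param image An `H x W x 3` array.
#' @param size Target side length in pixels; output is `size x size x 3`.
#' @return The resized array on the same intensity scale.
#' @export
resize_image <- function(image, size) {
  assert_image(image)
  stopifnot(size >= 1)
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (h == size && w == size) {
    return(image)
  }
  # align centres of the source and target pixel grids
  ys <- (seq_len(size) - 0.5) * h / size + 0.5
  xs <- (seq_len(size) - 0.5) * w / size + 0.5
  grid <- expand.grid(y = ys, x = xs)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], grid$y, grid$x),
      nrow = size
    )
  }
  out
}

## Stack a list of H x W x 3 images into the internal batch layout
## (H, W, N, C) used by the network code.
stack_images <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1]])
  n <- length(images)
  out <- array(0, c(d[1], d[2], n, d[3]))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!identical(dim(img), d)) {
      stop("all images in a batch must share dimensions", call. = FALSE)
    }
    out[, , i, ] <- img
  }
  out
}

## Accept either a list of image arrays or a data frame with an `image`
## list-column (as produced by make_labeled_dataset()).
as_image_list <- function(tiles) {
  if (is.data.frame(tiles)) {
    if (!"image" %in% names(tiles)) {
      stop("tile data frame must have an `image` list-column", call. = FALSE)
    }
    tiles <- tiles$image
  }
  if (!is.list(tiles)) stop("`tiles` must be a list of image arrays", call. = FALSE)
  tiles
}
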