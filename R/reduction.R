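## Dimensionality reduction (PCA) and ReliefF feature ranking.
##
## PCA is fitted by exact eigen-decomposition of the sample covariance of
## the training features (deterministic, no randomized solver), with each
## component's sign fixed so its largest-magnitude loading is positive.
## ReliefF is the binary variant: for each sampled instance the k nearest
## hits and k nearest misses (Euclidean distance, ties broken by index)
## update every feature's weight by the range-normalized value difference,
## averaged over m iterations and k neighbors. Weights of range-normalized
## features therefore live in [-1, 1]; a perfectly separating feature
## reaches 1.

#' Fit principal components on training features
#'
#' @param x Numeric feature matrix, samples in rows.
#' @param n_components Number of leading components to keep; at most
#'   `min(nrow(x), ncol(x))`.
#' @return A `kc_pca` with `mean` (training column means), `components`
#'   (`n_components x d`, orthonormal rows ordered by decreasing explained
#'   variance) and `explained_variance`.
#' @export
fit_pca <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  if (n_components < 1L || n_components > min(n, d)) {
    stop(sprintf(
      "`n_components` must be in [1, %d] for a %d x %d matrix",
      min(n, d), n, d
    ), call. = FALSE)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  comp <- t(eg$vectors[, seq_len(n_components), drop = FALSE])
  # sign convention: largest-magnitude loading of each component positive
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(
    list(
      mean = mu,
      components = comp,
      explained_variance = pmax(eg$values[seq_len(n_components)], 0),
      n_components = as.integer(n_components)
    ),
    class = "kc_pca"
  )
}

#' Project features onto fitted principal components
#'
#' @param model A `kc_pca`.
#' @param x Feature matrix (or single row vector) with the training feature
#'   width.
#' @return Matrix with `n_components` columns.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "kc_pca"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop(sprintf(
      "feature width %d does not match the fitted width %d",
      ncol(x), length(model$mean)
    ), call. = FALSE)
  }
  sweep(x, 2, model$mean) %*% t(model$components)
}

#' @export
print.kc_pca <- function(x, ...) {
  cat(
    "<kc_pca>", x$n_components, "components over",
    length(x$mean), "features\n"
  )
  invisible(x)
}

#' Glance at a fitted PCA
#'
#' @param x A `kc_pca`.
#' @param ... Unused.
#' @return One-row tibble with dimensions and total explained variance.
#' @export
glance.kc_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_features = length(x$mean),
    total_explained_variance = sum(x$explained_variance)
  )
}

#' ReliefF configuration
#'
#' @param k_neighbors Nearest hits/misses per instance (default 10).
#' @param n_iterations Number of sampled instances m; `NULL` (default) means
#'   one deterministic pass over every training instance in index order.
#' @param seed Seed used only when `n_iterations` is smaller than the sample
#'   count and instances must be subsampled.
#' @return A `relieff_config` list.
#' @export
relieff_config <- function(k_neighbors = 10L, n_iterations = NULL, seed = 1L) {
  stopifnot(k_neighbors >= 1, is.null(n_iterations) || n_iterations >= 1)
  structure(
    list(
      k_neighbors = as.integer(k_neighbors),
      n_iterations = if (is.null(n_iterations)) NULL else as.integer(n_iterations),
      seed = as.integer(seed)
    ),
    class = "relieff_config"
  )
}

#' ReliefF feature weights for a binary classification task
#'
#' For each of m sampled instances R, the k nearest same-class neighbors
#' (hits H) and k nearest other-class neighbors (misses M) are found by
#' Euclidean distance, excluding R itself; every feature weight is updated
#' by `-diff(f, R, H)/(m k) + diff(f, R, M)/(m k)`, where `diff` is the
#' absolute value difference normalized by the feature's training range.
#' Weights start at zero; a zero-range (constant) feature keeps weight 0.
#'
#' @param x Feature matrix (samples x features).
#' @param y Binary labels (factor, character, or 0/1).
#' @param config A [relieff_config()].
#' @return A `kc_relieff` with `weights` (one per feature) and the config.
#' @export
relieff_weights <- function(x, y, config = relieff_config()) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  yb <- as_binary_labels(y)
  n <- nrow(x)
  d <- ncol(x)
  if (length(yb) != n) stop("`y` must match the rows of `x`", call. = FALSE)
  classes <- unique(yb)
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  k <- config$k_neighbors
  if (k >= min(table(yb))) {
    stop("`k_neighbors` must be smaller than the smallest class", call. = FALSE)
  }

  rng <- unname(apply(x, 2, function(col) diff(range(col))))
  inv_rng <- ifelse(rng > 0, 1 / rng, 0) # zero-range features contribute 0

  m <- config$n_iterations %||% n
  targets <- if (m >= n) {
    rep_len(seq_len(n), m) # deterministic index-order pass(es)
  } else {
    local_seed(config$seed, sample(n, m))
  }

  # squared Euclidean distances, computed blockwise
  sq <- rowSums(x^2)
  w <- numeric(d)
  for (i in targets) {
    d2 <- sq + sq[i] - 2 * as.vector(x %*% x[i, ])
    d2[i] <- Inf
    same <- yb == yb[i]
    same[i] <- FALSE
    hits <- which(same)[order(d2[same], which(same))[seq_len(k)]]
    diffc <- yb != yb[i]
    misses <- which(diffc)[order(d2[diffc], which(diffc))[seq_len(k)]]
    hit_diff <- colSums(abs(x[hits, , drop = FALSE] -
      matrix(x[i, ], k, d, byrow = TRUE)))
    miss_diff <- colSums(abs(x[misses, , drop = FALSE] -
      matrix(x[i, ], k, d, byrow = TRUE)))
    w <- w + (miss_diff - hit_diff) * inv_rng / (m * k)
  }
  structure(list(weights = w, config = config, n_samples = n), class = "kc_relieff")
}

#' Select the top-weighted features
#'
#' @param weights A `kc_relieff` object or bare numeric weight vector.
#' @param n_selected How many features to keep.
#' @return A `kc_selection`: `indices` (1-based, importance-descending, ties
#'   broken by lower index) and `n_selected`.
#' @export
top_k_indices <- function(weights, n_selected) {
  w <- if (inherits(weights, "kc_relieff")) weights$weights else as.numeric(weights)
  if (n_selected < 1L || n_selected > length(w)) {
    stop(sprintf("`n_selected` must be in [1, %d]", length(w)), call. = FALSE)
  }
  ord <- order(-w, seq_along(w))
  structure(
    list(indices = ord[seq_len(n_selected)], n_selected = as.integer(n_selected)),
    class = "kc_selection"
  )
}

#' Tidy ReliefF weights into a ranked tibble
#'
#' @param x A `kc_relieff`.
#' @param ... Unused.
#' @return Tibble with `feature`, `weight`, `rank` (1 = most relevant).
#' @export
tidy.kc_relieff <- function(x, ...) {
  ord <- order(-x$weights, seq_along(x$weights))
  rank <- integer(length(x$weights))
  rank[ord] <- seq_along(ord)
  tibble::tibble(
    feature = seq_along(x$weights),
    weight = x$weights,
    rank = rank
  )
}

#' @export
print.kc_relieff <- function(x, ...) {
  cat(
    "<kc_relieff>", length(x$weights), "features, k =", x$config$k_neighbors,
    ", m =", x$config$n_iterations %||% x$n_samples, "\n"
  )
  invisible(x)
}
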