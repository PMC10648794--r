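## Minimal convolutional-network engine.
##
## Batches live in layout (H, W, N, C). Standard convolutions are lowered to
## a single matrix product via im2col (the product runs in BLAS); depthwise
## convolutions and pooling use shift-accumulate slicing, which vectorizes
## over the whole batch. Gradients are exact (checked against finite
## differences in the test suite). Only what the compact classifier needs is
## implemented: k x k "same" convolutions with stride 1, depthwise
## convolutions, 2 x 2 max pooling, global average pooling, dense layers,
## ReLU/sigmoid, binary cross-entropy and Adam.

## ---- im2col standard convolution ----------------------------------------

## taps enumerated row-offset fastest, matching aperm(w, c(3,1,2,4)) flatten
conv_im2col <- function(x, k) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  if (k == 1L) {
    return(matrix(x, ncol = C))
  }
  p <- (k - 1L) %/% 2L
  P <- array(0, c(H + 2L * p, W + 2L * p, N, C))
  P[p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- vector("list", k * k)
  t <- 0L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      t <- t + 1L
      s <- P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
      dim(s) <- c(H * W * N, C)
      cols[[t]] <- s
    }
  }
  do.call(cbind, cols)
}

conv_forward <- function(x, w, b) {
  d <- dim(x)
  k <- dim(w)[1]
  cin <- dim(w)[3]
  cout <- dim(w)[4]
  stopifnot(d[4] == cin)
  xcol <- conv_im2col(x, k)
  wmat <- matrix(aperm(w, c(3, 1, 2, 4)), nrow = k * k * cin)
  ymat <- xcol %*% wmat
  ymat <- ymat + rep(b, each = nrow(ymat))
  dim(ymat) <- c(d[1], d[2], d[3], cout)
  list(out = ymat, cache = list(xcol = xcol, dim = d, k = k))
}

conv_backward <- function(dy, w, cache) {
  d <- cache$dim
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- cache$k
  cout <- dim(w)[4]
  dymat <- matrix(dy, ncol = cout)
  db <- colSums(dymat)
  dwmat <- crossprod(cache$xcol, dymat)
  dw <- aperm(array(dwmat, c(C, k, k, cout)), c(2, 3, 1, 4))
  wmat <- matrix(aperm(w, c(3, 1, 2, 4)), nrow = k * k * C)
  dxcol <- tcrossprod(dymat, wmat)
  if (k == 1L) {
    dx <- dxcol
    dim(dx) <- c(H, W, N, C)
  } else {
    p <- (k - 1L) %/% 2L
    dP <- array(0, c(H + 2L * p, W + 2L * p, N, C))
    t <- 0L
    for (dj in 0:(k - 1L)) {
      for (di in 0:(k - 1L)) {
        t <- t + 1L
        block <- dxcol[, (t - 1L) * C + seq_len(C)]
        dim(block) <- c(H, W, N, C)
        dP[di + seq_len(H), dj + seq_len(W), , ] <-
          dP[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] + block
      }
    }
    dx <- dP[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
    dim(dx) <- c(H, W, N, C)
  }
  list(dx = dx, dw = dw, db = db)
}

## ---- depthwise convolution ----------------------------------------------

dwconv_forward <- function(x, w, b) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(w)[1]
  stopifnot(dim(w)[3] == C)
  p <- (k - 1L) %/% 2L
  P <- array(0, c(H + 2L * p, W + 2L * p, N, C))
  P[p + seq_len(H), p + seq_len(W), , ] <- x
  y <- array(rep(b, each = H * W * N), c(H, W, N, C))
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      slice <- P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
      y <- y + slice * rep(w[di + 1L, dj + 1L, ], each = H * W * N)
    }
  }
  list(out = y, cache = list(P = P, dim = d, k = k))
}

dwconv_backward <- function(dy, w, cache) {
  d <- cache$dim
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- cache$k
  p <- (k - 1L) %/% 2L
  db <- colSums(matrix(dy, ncol = C))
  dw <- array(0, dim(w))
  dP <- array(0, dim(cache$P))
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      slice <- cache$P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
      dw[di + 1L, dj + 1L, ] <- colSums(matrix(slice * dy, ncol = C))
      dP[di + seq_len(H), dj + seq_len(W), , ] <-
        dP[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] +
        dy * rep(w[di + 1L, dj + 1L, ], each = H * W * N)
    }
  }
  dx <- dP[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  dim(dx) <- c(H, W, N, C)
  list(dx = dx, dw = dw, db = db)
}

## ---- 2x2 max pooling (stride 2; even H, W enforced at build time) -------

maxpool_forward <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  a <- x[ro, co, , , drop = FALSE]
  b <- x[re, co, , , drop = FALSE]
  cc <- x[ro, ce, , , drop = FALSE]
  dd <- x[re, ce, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # gradient routed to the first maximal element in fixed order a,b,c,d
  ma <- a == m
  mb <- (b == m) & !ma
  mc <- (cc == m) & !(ma | mb)
  md <- (dd == m) & !(ma | mb | mc)
  dim(m) <- c(H %/% 2L, W %/% 2L, d[3], d[4])
  list(out = m, cache = list(ma = ma, mb = mb, mc = mc, md = md, dim = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dim
  H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dx <- array(0, d)
  dx[ro, co, , ] <- dy * cache$ma
  dx[re, co, , ] <- dy * cache$mb
  dx[ro, ce, , ] <- dy * cache$mc
  dx[re, ce, , ] <- dy * cache$md
  dx
}

## ---- global average pooling: (H,W,N,C) -> features (N x C) --------------

gap_forward <- function(x) {
  d <- dim(x)
  f <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  list(out = f, cache = list(dim = d))
}

gap_backward <- function(df, cache) {
  d <- cache$dim
  array(rep(as.vector(df), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

## ---- dense / activations / loss -----------------------------------------

dense_forward <- function(x, w, b) {
  y <- sweep(x %*% w, 2, b, "+")
  list(out = y, cache = list(x = x))
}

dense_backward <- function(dy, w, cache) {
  list(dx = tcrossprod(dy, w), dw = crossprod(cache$x, dy), db = colSums(dy))
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = list(mask = x > 0))
relu_backward <- function(dy, cache) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

## mean binary cross-entropy and its gradient wrt the pre-sigmoid logit
bce_loss <- function(prob, y, eps = 1e-15) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- network assembly ----------------------------------------------------

he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

## Initialize parameter arrays for an architecture layer list. Layers carry
## `kind`, `filters`/`units`, `kernel`, `activation`, `input_channels`.
init_network_params <- function(layers, seed) {
  local_seed(seed, {
    purrr::map(layers, function(ly) {
      switch(ly$kind,
        CONV2D = {
          k <- ly$kernel
          cin <- ly$input_channels
          list(
            w = array(he_init(k * k * cin * ly$filters, k * k * cin), c(k, k, cin, ly$filters)),
            b = rep(0, ly$filters)
          )
        },
        DEPTHWISE_CONV2D = {
          k <- ly$kernel
          cin <- ly$input_channels
          list(
            w = array(he_init(k * k * cin, k * k), c(k, k, cin)),
            b = rep(0, cin)
          )
        },
        DENSE = list(
          w = matrix(he_init(ly$input_channels * ly$units, ly$input_channels),
            nrow = ly$input_channels
          ),
          b = rep(0, ly$units)
        ),
        NULL
      )
    })
  })
}

apply_activation <- function(x, act) {
  switch(act %||% "linear",
    relu = relu_forward(x),
    sigmoid = list(out = sigmoid(x), cache = list(out_sig = NULL)),
    linear = list(out = x, cache = NULL),
    stop("unknown activation: ", act, call. = FALSE)
  )
}

## Forward pass. `x` is (H,W,N,C) for convolutional stacks or a feature
## matrix when the first layer is DENSE. Returns list(out, caches).
net_forward <- function(layers, params, x, keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    pr <- params[[i]]
    step <- switch(ly$kind,
      CONV2D = conv_forward(x, pr$w, pr$b),
      DEPTHWISE_CONV2D = dwconv_forward(x, pr$w, pr$b),
      MAXPOOL = maxpool_forward(x),
      GLOBAL_AVG_POOL = gap_forward(x),
      FLATTEN = list(out = x, cache = NULL),
      DENSE = dense_forward(x, pr$w, pr$b),
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    )
    x <- step$out
    act_cache <- NULL
    if (ly$kind %in% c("CONV2D", "DEPTHWISE_CONV2D", "DENSE") &&
      !is.null(ly$activation) && ly$activation != "linear") {
      if (ly$activation == "sigmoid") {
        x <- sigmoid(x)
        act_cache <- list(sig_out = x)
      } else {
        a <- apply_activation(x, ly$activation)
        x <- a$out
        act_cache <- a$cache
      }
    }
    if (keep_cache) caches[[i]] <- list(layer = step$cache, act = act_cache)
  }
  list(out = x, caches = caches)
}

## Backward pass from `dout` (gradient wrt final output, post-activation for
## all but a sigmoid head, where the caller passes the pre-sigmoid gradient
## via `dout_is_logit`). Returns list(grads, dx).
net_backward <- function(layers, params, caches, dout, dout_is_logit = FALSE) {
  grads <- vector("list", length(layers))
  dy <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    pr <- params[[i]]
    ch <- caches[[i]]
    if (!is.null(ly$activation) && ly$activation != "linear" &&
      ly$kind %in% c("CONV2D", "DEPTHWISE_CONV2D", "DENSE")) {
      if (ly$activation == "relu") {
        dy <- relu_backward(dy, ch$act)
      } else if (ly$activation == "sigmoid") {
        if (!(dout_is_logit && i == length(layers))) {
          s <- ch$act$sig_out
          dy <- dy * s * (1 - s)
        }
      }
    }
    res <- switch(ly$kind,
      CONV2D = conv_backward(dy, pr$w, ch$layer),
      DEPTHWISE_CONV2D = dwconv_backward(dy, pr$w, ch$layer),
      MAXPOOL = list(dx = maxpool_backward(dy, ch$layer)),
      GLOBAL_AVG_POOL = list(dx = gap_backward(dy, ch$layer)),
      FLATTEN = list(dx = dy),
      DENSE = dense_backward(dy, pr$w, ch$layer)
    )
    grads[[i]] <- res[c("dw", "db")]
    dy <- res$dx
  }
  list(grads = grads, dx = dy)
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(
    t = 0L,
    m = purrr::map(params, function(p) if (is.null(p)) NULL else list(w = p$w * 0, b = p$b * 0)),
    v = purrr::map(params, function(p) if (is.null(p)) NULL else list(w = p$w * 0, b = p$b * 0))
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in c("w", "b")) {
      g <- grads[[i]][[if (nm == "w") "dw" else "db"]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) / (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

## one SGD-style training epoch over mini-batches; `forward_x` prepares the
## batch input (images -> array, or feature rows)
train_epochs <- function(layers, params, inputs, labels, epochs, batch_size, lr,
                         seed, input_is_matrix = FALSE, progress = NULL) {
  n <- if (input_is_matrix) nrow(inputs) else length(inputs)
  state <- adam_init(params)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- local_seed(derive_seed(seed, 100L + ep), sample(n))
    losses <- c()
    accs <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- if (input_is_matrix) inputs[idx, , drop = FALSE] else stack_images(inputs[idx])
      yb <- labels[idx]
      fw <- net_forward(layers, params, xb)
      prob <- as.vector(fw$out)
      losses <- c(losses, bce_loss(prob, yb))
      accs <- c(accs, mean((prob >= 0.5) == (yb == 1)))
      dlogit <- matrix((prob - yb) / length(yb), ncol = 1L)
      bw <- net_backward(layers, params, fw$caches, dlogit, dout_is_logit = TRUE)
      upd <- adam_step(params, bw$grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, loss = mean(losses), accuracy = mean(accs)
    )
  }
  list(params = params, history = dplyr::bind_rows(history))
}
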