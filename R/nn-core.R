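# Minimal convolutional network engine.
#
# Everything runs on plain R arrays through BLAS matrix products:
# 3x3 stride-1 same-padding convolutions are expressed with im2col, 2x2 mean
# pooling and global average pooling close the spatial axes, dense layers act
# on column-per-sample matrices. Backward passes are hand-derived and checked
# against finite differences in the test suite. Batches are (H, W, C, N)
# arrays; dense activations are (features, N) matrices.

.nn_cache <- new.env(parent = emptyenv())

# Precomputed im2col gather indices for a 3x3 / pad-1 / stride-1 convolution
# over an (H, W, C) input, cached per shape.
conv_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  di <- rep(0:2, times = 3)
  dj <- rep(0:2, each = 3)
  m9 <- matrix(0L, 9L, H * W)
  for (k in 1:9) m9[k, ] <- (oj + dj[k] - 1L) * Hp + (oi + di[k])
  idx <- do.call(rbind, lapply(seq_len(C), function(ch) m9 + (ch - 1L) * Hp * Wp))
  idx_vec <- as.vector(idx)
  uids <- sort(unique(idx_vec))
  obj <- list(idx_vec = idx_vec, uids = uids, Hp = Hp, Wp = Wp)
  assign(key, obj, envir = .nn_cache)
  obj
}

conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  ci <- conv_idx(H, Wd, C)
  xp <- array(0, dim = c(ci$Hp, ci$Wp, C, N))
  xp[2:(H + 1), 2:(Wd + 1), , ] <- x
  dim(xp) <- c(ci$Hp * ci$Wp * C, N)
  cols <- xp[ci$idx_vec, , drop = FALSE]
  dim(cols) <- c(9L * C, H * Wd * N)
  y <- W %*% cols + b
  out_c <- nrow(W)
  dim(y) <- c(out_c, H * Wd, N)
  y <- aperm(y, c(2, 1, 3))
  dim(y) <- c(H, Wd, out_c, N)
  list(out = y, cols = cols, x_dim = d)
}

conv_backward <- function(dy, cache, W) {
  d <- cache$x_dim; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  out_c <- nrow(W)
  dim(dy) <- c(H * Wd, out_c, N)
  dy <- aperm(dy, c(2, 1, 3))
  dim(dy) <- c(out_c, H * Wd * N)
  dW <- dy %*% t(cache$cols)
  db <- rowSums(dy)
  dcols <- crossprod(W, dy)
  ci <- conv_idx(H, Wd, C)
  dim(dcols) <- c(9L * C * H * Wd, N)
  acc <- rowsum(dcols, ci$idx_vec)
  dxp <- matrix(0, ci$Hp * ci$Wp * C, N)
  dxp[ci$uids, ] <- acc
  dim(dxp) <- c(ci$Hp, ci$Wp, C, N)
  dx <- dxp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("mean pooling needs even spatial dims", call. = FALSE)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  y <- (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
          x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
  list(out = y, x_dim = d)
}

pool_backward <- function(dy, cache) {
  d <- cache$x_dim
  dx <- array(0, dim = d)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  q <- dy / 4
  dx[io, jo, , ] <- q
  dx[io + 1L, jo, , ] <- q
  dx[io, jo + 1L, , ] <- q
  dx[io + 1L, jo + 1L, , ] <- q
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  h <- colMeans(m)
  dim(h) <- c(d[3], d[4])
  list(out = h, x_dim = d)
}

gap_backward <- function(dh, cache) {
  d <- cache$x_dim
  hw <- d[1] * d[2]
  dx <- rep(as.vector(dh) / hw, each = hw)
  dim(dx) <- d
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  ii <- rep(seq_len(d[1]), each = 2L)
  jj <- rep(seq_len(d[2]), each = 2L)
  list(out = x[ii, jj, , , drop = FALSE], x_dim = d)
}

upsample_backward <- function(dy, cache) {
  d <- cache$x_dim
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  dy[io, jo, , , drop = FALSE] + dy[io + 1L, jo, , , drop = FALSE] +
    dy[io, jo + 1L, , , drop = FALSE] + dy[io + 1L, jo + 1L, , , drop = FALSE]
}

dense_forward <- function(h, W, b) {
  list(out = W %*% h + b, h = h)
}

dense_backward <- function(dy, cache, W) {
  list(dW = dy %*% t(cache$h), db = rowSums(dy), dx = crossprod(W, dy))
}

# Batch normalization over a (features, N) matrix: per-feature batch
# statistics, learnable gain W (gamma) and shift b (beta). Used at the
# entrance of the projection head, where training batches always exist, so
# no running statistics are kept.
bnorm_forward <- function(x, W, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- xc / s
  list(out = xhat * W + b, xhat = xhat, s = s)
}

bnorm_backward <- function(dy, cache, W) {
  xhat <- cache$xhat
  dxhat <- dy * W
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$s
  list(dW = rowSums(dy * xhat), db = rowSums(dy), dx = dx)
}

## ---- sequential nets ----------------------------------------------------

nn_conv <- function(name, in_ch, out_ch) {
  list(name = name, kind = "conv", in_ch = in_ch, out_ch = out_ch)
}
nn_relu <- function(name) list(name = name, kind = "relu")
nn_pool <- function(name) list(name = name, kind = "pool")
nn_gap <- function(name) list(name = name, kind = "gap")
nn_upsample <- function(name) list(name = name, kind = "upsample")
nn_dense <- function(name, in_dim, out_dim) {
  list(name = name, kind = "dense", in_dim = in_dim, out_dim = out_dim)
}
nn_bnorm <- function(name, dim) list(name = name, kind = "bnorm", dim = dim)

# He-normal initialization of all parameterized layers, seeded.
nn_init <- function(layers, seed) {
  with_seed(seed, {
    layers <- lapply(layers, function(ly) {
      if (ly$kind == "conv") {
        fan_in <- 9L * ly$in_ch
        ly$W <- matrix(stats::rnorm(ly$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                       ly$out_ch, fan_in)
        ly$b <- numeric(ly$out_ch)
      } else if (ly$kind == "dense") {
        ly$W <- matrix(stats::rnorm(ly$out_dim * ly$in_dim, 0, sqrt(2 / ly$in_dim)),
                       ly$out_dim, ly$in_dim)
        ly$b <- numeric(ly$out_dim)
      } else if (ly$kind == "bnorm") {
        ly$W <- rep(1, ly$dim)
        ly$b <- numeric(ly$dim)
      }
      ly
    })
  })
  structure(list(layers = layers), class = "nn_net")
}

net_forward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    if (ly$kind == "conv") {
      cf <- conv_forward(x, ly$W, ly$b)
      caches[[l]] <- cf[c("cols", "x_dim")]
      x <- cf$out
    } else if (ly$kind == "relu") {
      caches[[l]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (ly$kind == "pool") {
      pf <- pool_forward(x)
      caches[[l]] <- pf["x_dim"]
      x <- pf$out
    } else if (ly$kind == "gap") {
      gf <- gap_forward(x)
      caches[[l]] <- gf["x_dim"]
      x <- gf$out
    } else if (ly$kind == "upsample") {
      uf <- upsample_forward(x)
      caches[[l]] <- uf["x_dim"]
      x <- uf$out
    } else if (ly$kind == "dense") {
      df <- dense_forward(x, ly$W, ly$b)
      caches[[l]] <- df["h"]
      x <- df$out
    } else if (ly$kind == "bnorm") {
      bf <- bnorm_forward(x, ly$W, ly$b)
      caches[[l]] <- bf[c("xhat", "s")]
      x <- bf$out
    } else {
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    }
  }
  list(out = x, caches = caches)
}

# Returns gradients named "<layer>.W"/"<layer>.b" plus dx at the input.
net_backward <- function(net, caches, dout) {
  grads <- list()
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    if (ly$kind == "conv") {
      cb <- conv_backward(dout, caches[[l]], ly$W)
      grads[[paste0(ly$name, ".W")]] <- cb$dW
      grads[[paste0(ly$name, ".b")]] <- cb$db
      dout <- cb$dx
    } else if (ly$kind == "relu") {
      dout <- dout * caches[[l]]$mask
    } else if (ly$kind == "pool") {
      dout <- pool_backward(dout, caches[[l]])
    } else if (ly$kind == "gap") {
      dout <- gap_backward(dout, caches[[l]])
    } else if (ly$kind == "upsample") {
      dout <- upsample_backward(dout, caches[[l]])
    } else if (ly$kind == "dense") {
      db <- dense_backward(dout, caches[[l]], ly$W)
      grads[[paste0(ly$name, ".W")]] <- db$dW
      grads[[paste0(ly$name, ".b")]] <- db$db
      dout <- db$dx
    } else if (ly$kind == "bnorm") {
      bb <- bnorm_backward(dout, caches[[l]], ly$W)
      grads[[paste0(ly$name, ".W")]] <- bb$dW
      grads[[paste0(ly$name, ".b")]] <- bb$db
      dout <- bb$dx
    }
  }
  list(grads = grads, dx = dout)
}

net_params <- function(net) {
  out <- list()
  for (ly in net$layers) {
    if (!is.null(ly$W)) {
      out[[paste0(ly$name, ".W")]] <- ly$W
      out[[paste0(ly$name, ".b")]] <- ly$b
    }
  }
  out
}

net_set_params <- function(net, params) {
  net$layers <- lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) {
      wn <- paste0(ly$name, ".W"); bn <- paste0(ly$name, ".b")
      if (is.null(params[[wn]]) || is.null(params[[bn]])) {
        stop("missing parameters for layer ", ly$name, call. = FALSE)
      }
      if (!all(dim(params[[wn]]) == dim(ly$W))) {
        stop("shape mismatch for ", wn, call. = FALSE)
      }
      ly$W <- params[[wn]]; ly$b <- params[[bn]]
    }
    ly
  })
  net
}

## ---- encoders and heads -------------------------------------------------

ENCODER_NAMES <- c("tiny", "tiny_deep", "resnet50")

#' Construct an encoder network
#'
#' `"tiny"` and `"tiny_deep"` are small convolutional encoders designed for
#' CPU-scale experiments on 32-64 px inputs (three or four 3x3 convolution
#' blocks with mean pooling and a global-average-pooled feature vector).
#' `"resnet50"`, the architecture used at full scale, is accepted as a name
#' for configuration compatibility but has no CPU implementation here and
#' raises an error.
#'
#' @param name Encoder name.
#' @param seed Integer seed for He-normal initialization.
#' @return List with the network, its `h_dim`, and `name`.
#' @export
make_encoder <- function(name = "tiny", seed = 1) {
  if (!name %in% ENCODER_NAMES) {
    stop("unknown encoder: ", name, call. = FALSE)
  }
  if (name == "resnet50") {
    stop("encoder 'resnet50' is the full-scale architecture and has no CPU ",
         "implementation in this package; use 'tiny' or 'tiny_deep'",
         call. = FALSE)
  }
  layers <- if (name == "tiny") {
    list(nn_conv("conv1", 3L, 8L), nn_relu("relu1"), nn_pool("pool1"),
         nn_conv("conv2", 8L, 16L), nn_relu("relu2"), nn_pool("pool2"),
         nn_conv("conv3", 16L, 32L), nn_relu("relu3"), nn_gap("gap"))
  } else {
    list(nn_conv("conv1", 3L, 8L), nn_relu("relu1"),
         nn_conv("conv2", 8L, 8L), nn_relu("relu2"), nn_pool("pool1"),
         nn_conv("conv3", 8L, 16L), nn_relu("relu3"), nn_pool("pool2"),
         nn_conv("conv4", 16L, 32L), nn_relu("relu4"), nn_gap("gap"))
  }
  list(net = nn_init(layers, seed), h_dim = 32L, name = name)
}

# Two-layer MLP projection head mapping h to the 128-dim loss space. The
# leading batchnorm decorrelates the h batch so the cosine geometry of z
# has spread at initialization (without it the contrastive loss starts on a
# collapsed plateau); it belongs to the head and is discarded at transfer
# along with the rest of the head.
make_projection_head <- function(in_dim = 32L, hidden = 64L, out_dim = 128L, seed = 1) {
  nn_init(list(nn_bnorm("projbn", in_dim),
               nn_dense("proj1", in_dim, hidden), nn_relu("projrelu"),
               nn_dense("proj2", hidden, out_dim)), seed)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !endsWith(nm, ".b")) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of (H, W, 3) images into an (H, W, 3, N) batch tensor.
stack_images <- function(images) {
  d <- dim(images[[1]])
  out <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

# Per-image, per-channel standardization applied to every view entering an
# encoder. Raw fundus pixels are dominated by global tint/illumination
# nuisance; removing each channel's mean and scale leaves the spatial
# structure, which is the signal the encoders are meant to use.
standardize_channels <- function(img) {
  for (ch in seq_len(dim(img)[3])) {
    v <- img[, , ch]
    img[, , ch] <- (v - mean(v)) / (stats::sd(v) + 1e-6)
  }
  img
}

prep_batch <- function(views) {
  stack_images(lapply(views, standardize_channels))
}
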