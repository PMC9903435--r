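# Minimal reverse-mode neural-network engine.
#
# Activations travel as a list `act` with fields:
#   x    -- matrix, (n_samples * n_positions) rows x n_channels cols,
#           rows sample-major, positions linearized column-major
#   dims -- integer spatial extents (length 3, 2, or 0 for flat features)
#   n    -- number of samples in the batch
# Layers are environments with $params / $grads lists and $fw / $bw
# closures; composite residual blocks wire sub-layers together.  The
# convolution layers call the compiled im2col+GEMM kernels; `f64`
# selects the double-precision path used by gradient checks.

new_act <- function(x, dims, n) list(x = x, dims = as.integer(dims), n = n)

new_layer <- function(type) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$params <- list()
  ly$grads <- list()
  ly$decay <- character(0)   # names of params subject to weight decay
  ly
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_linear <- function(d_in, d_out) {
  ly <- new_layer("linear")
  ly$params <- list(W = he_init(d_in, d_out, d_in),
                    b = numeric(d_out))
  ly$decay <- "W"
  ly$fw <- function(act, training) {
    if (training) ly$cache <- act$x
    y <- act$x %*% ly$params$W
    y <- sweep(y, 2, ly$params$b, "+")
    new_act(y, integer(0), act$n)
  }
  ly$bw <- function(dact) {
    dy <- dact$x
    ly$grads <- list(W = crossprod(ly$cache, dy), b = colSums(dy))
    new_act(tcrossprod(dy, ly$params$W), integer(0), dact$n)
  }
  ly
}

layer_conv <- function(c_in, c_out, nd, k = 3, stride = 1, pad = 1,
                       f64 = FALSE) {
  ly <- new_layer("conv")
  ly$k <- k; ly$stride <- stride; ly$pad <- pad; ly$f64 <- f64
  ly$c_in <- c_in; ly$c_out <- c_out
  kd <- k^nd
  ly$params <- list(W = he_init(c_in * kd, c_out, c_in * kd),
                    b = numeric(c_out))
  ly$decay <- "W"
  ly$need_dx <- TRUE  # FALSE for the stem conv (no trainable layer below)
  ly$fw <- function(act, training) {
    qd <- (act$dims + 2 * ly$pad - ly$k) %/% ly$stride + 1L
    if (any(qd < 1)) {
      stop(sprintf("input spatial dims (%s) too small for conv k=%d s=%d",
                   paste(act$dims, collapse = "x"), ly$k, ly$stride))
    }
    res <- conv_fw(act$x, act$n, act$dims, ly$params$W, ly$params$b,
                   ly$k, ly$stride, ly$pad, ly$f64, training,
                   if (is.null(ly$ws)) NULL else ly$ws)
    ly$ws <- res$ws   # persistent im2col workspace, reused across steps
    if (training) ly$cache <- list(n = act$n, dims = act$dims)
    new_act(res$y, qd, act$n)
  }
  ly$bw <- function(dact) {
    res <- conv_bw(ly$ws, ly$cache$n, ly$cache$dims, ly$params$W,
                   dact$x, ly$k, ly$stride, ly$pad, ly$f64, ly$need_dx,
                   if (is.null(ly$wsd)) NULL else ly$wsd)
    ly$wsd <- res$wsd
    ly$grads <- list(W = res$dW, b = res$db)
    new_act(res$dX, ly$cache$dims, ly$cache$n)
  }
  ly
}

layer_batchnorm <- function(c_ch, momentum = 0.1, eps = 1e-5) {
  ly <- new_layer("batchnorm")
  ly$params <- list(gamma = rep(1, c_ch), beta = numeric(c_ch))
  ly$running_mean <- numeric(c_ch)
  ly$running_var <- rep(1, c_ch)
  ly$momentum <- momentum; ly$eps <- eps
  ly$fw <- function(act, training) {
    x <- act$x
    if (training) {
      st <- col_stats(x)
      mu <- st$mu
      v <- st$var
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
      ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
    }
    istd <- 1 / sqrt(v + ly$eps)
    res <- bn_fw(x, mu, istd, ly$params$gamma, ly$params$beta)
    if (training) ly$cache <- list(xhat = res$xhat, istd = istd)
    new_act(res$y, act$dims, act$n)
  }
  ly$bw <- function(dact) {
    res <- bn_bw(dact$x, ly$cache$xhat, ly$cache$istd, ly$params$gamma)
    ly$grads <- list(gamma = res$dgamma, beta = res$dbeta)
    new_act(res$dX, dact$dims, dact$n)
  }
  ly
}

layer_relu <- function() {
  ly <- new_layer("relu")
  ly$fw <- function(act, training) {
    res <- relu_fw(act$x)
    if (training) ly$cache <- res$mask
    new_act(res$y, act$dims, act$n)
  }
  ly$bw <- function(dact) {
    new_act(relu_bw(dact$x, ly$cache), dact$dims, dact$n)
  }
  ly
}

layer_gelu <- function() {
  ly <- new_layer("gelu")
  ly$fw <- function(act, training) {
    if (training) ly$cache <- act$x
    new_act(act$x * pnorm(act$x), act$dims, act$n)
  }
  ly$bw <- function(dact) {
    x <- ly$cache
    new_act(dact$x * (pnorm(x) + x * dnorm(x)), dact$dims, dact$n)
  }
  ly
}

layer_maxpool <- function() {
  ly <- new_layer("maxpool")
  ly$fw <- function(act, training) {
    if (any(act$dims < 2)) {
      stop(sprintf("input spatial dims (%s) too small for 2x max pooling",
                   paste(act$dims, collapse = "x")))
    }
    res <- maxpool_fw(act$x, act$n, act$dims)
    if (training) ly$cache <- list(idx = res$idx, in_rows = nrow(act$x),
                                   in_dims = act$dims)
    new_act(res$y, act$dims %/% 2L, act$n)
  }
  ly$bw <- function(dact) {
    dx <- maxpool_bw(dact$x, ly$cache$idx, ly$cache$in_rows)
    new_act(dx, ly$cache$in_dims, dact$n)
  }
  ly
}

# Global (adaptive) average pooling: collapses all spatial positions to a
# fixed-length per-sample feature vector.
layer_gap <- function() {
  ly <- new_layer("gap")
  ly$fw <- function(act, training) {
    p <- prod(act$dims)
    grp <- rep(seq_len(act$n), each = p)
    y <- rowsum(act$x, grp, reorder = TRUE) / p
    if (training) ly$cache <- list(p = p, n = act$n, dims = act$dims)
    new_act(y, integer(0), act$n)
  }
  ly$bw <- function(dact) {
    p <- ly$cache$p
    dx <- dact$x[rep(seq_len(ly$cache$n), each = p), , drop = FALSE] / p
    new_act(dx, ly$cache$dims, ly$cache$n)
  }
  ly
}

# Residual basic block: conv-bn-relu-conv-bn, (+ projection shortcut when
# the channel count or resolution changes), add, relu.
block_basic <- function(c_in, c_out, nd, stride = 1, f64 = FALSE) {
  ly <- new_layer("basic_block")
  ly$conv1 <- layer_conv(c_in, c_out, nd, 3, stride, 1, f64)
  ly$bn1 <- layer_batchnorm(c_out)
  ly$relu1 <- layer_relu()
  ly$conv2 <- layer_conv(c_out, c_out, nd, 3, 1, 1, f64)
  ly$bn2 <- layer_batchnorm(c_out)
  ly$proj <- if (stride != 1 || c_in != c_out) {
    list(conv = layer_conv(c_in, c_out, nd, 1, stride, 0, f64),
         bn = layer_batchnorm(c_out))
  } else NULL
  ly$sub <- c(list(ly$conv1, ly$bn1, ly$conv2, ly$bn2),
              if (!is.null(ly$proj)) list(ly$proj$conv, ly$proj$bn))
  ly$fw <- function(act, training) {
    out <- ly$bn2$fw(ly$conv2$fw(
      ly$relu1$fw(ly$bn1$fw(ly$conv1$fw(act, training), training), training),
      training), training)
    sc <- if (is.null(ly$proj)) act else
      ly$proj$bn$fw(ly$proj$conv$fw(act, training), training)
    res <- add_relu(out$x, sc$x)
    if (training) ly$cache <- res$mask
    new_act(res$y, out$dims, out$n)
  }
  ly$bw <- function(dact) {
    dy <- new_act(relu_bw(dact$x, ly$cache), dact$dims, dact$n)
    d_main <- ly$conv1$bw(ly$bn1$bw(ly$relu1$bw(
      ly$conv2$bw(ly$bn2$bw(dy)))))
    d_sc <- if (is.null(ly$proj)) dy else
      ly$proj$conv$bw(ly$proj$bn$bw(dy))
    new_act(d_main$x + d_sc$x, d_main$dims, d_main$n)
  }
  ly
}

# Residual bottleneck block (1x1 reduce, 3x3, 1x1 expand x4), used by the
# 50-layer 2D network.
block_bottleneck <- function(c_in, c_mid, nd, stride = 1, f64 = FALSE) {
  c_out <- 4 * c_mid
  ly <- new_layer("bottleneck_block")
  ly$conv1 <- layer_conv(c_in, c_mid, nd, 1, 1, 0, f64)
  ly$bn1 <- layer_batchnorm(c_mid)
  ly$relu1 <- layer_relu()
  ly$conv2 <- layer_conv(c_mid, c_mid, nd, 3, stride, 1, f64)
  ly$bn2 <- layer_batchnorm(c_mid)
  ly$relu2 <- layer_relu()
  ly$conv3 <- layer_conv(c_mid, c_out, nd, 1, 1, 0, f64)
  ly$bn3 <- layer_batchnorm(c_out)
  ly$proj <- if (stride != 1 || c_in != c_out) {
    list(conv = layer_conv(c_in, c_out, nd, 1, stride, 0, f64),
         bn = layer_batchnorm(c_out))
  } else NULL
  ly$sub <- c(list(ly$conv1, ly$bn1, ly$conv2, ly$bn2, ly$conv3, ly$bn3),
              if (!is.null(ly$proj)) list(ly$proj$conv, ly$proj$bn))
  ly$fw <- function(act, training) {
    h <- ly$relu1$fw(ly$bn1$fw(ly$conv1$fw(act, training), training),
                     training)
    h <- ly$relu2$fw(ly$bn2$fw(ly$conv2$fw(h, training), training), training)
    out <- ly$bn3$fw(ly$conv3$fw(h, training), training)
    sc <- if (is.null(ly$proj)) act else
      ly$proj$bn$fw(ly$proj$conv$fw(act, training), training)
    res <- add_relu(out$x, sc$x)
    if (training) ly$cache <- res$mask
    new_act(res$y, out$dims, out$n)
  }
  ly$bw <- function(dact) {
    dy <- new_act(relu_bw(dact$x, ly$cache), dact$dims, dact$n)
    d <- ly$conv3$bw(ly$bn3$bw(dy))
    d <- ly$conv2$bw(ly$bn2$bw(ly$relu2$bw(d)))
    d_main <- ly$conv1$bw(ly$bn1$bw(ly$relu1$bw(d)))
    d_sc <- if (is.null(ly$proj)) dy else
      ly$proj$conv$bw(ly$proj$bn$bw(dy))
    new_act(d_main$x + d_sc$x, d_main$dims, d_main$n)
  }
  ly
}

# Run a list of layers forward / backward.
seq_fw <- function(layers, act, training) {
  for (ly in layers) act <- ly$fw(act, training)
  act
}

seq_bw <- function(layers, dact) {
  for (ly in rev(layers)) dact <- ly$bw(dact)
  dact
}

# Flatten a layer tree into the list of primitive layers with parameters.
collect_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (!is.null(ly$sub)) out <- c(out, collect_layers(ly$sub))
    else if (length(ly$params)) out <- c(out, list(ly))
  }
  out
}
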