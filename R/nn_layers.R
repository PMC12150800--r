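# Minimal trainable-layer toolkit used by the segmentation network.
# Tensors are (H, W, C, N) arrays. Every layer is an environment exposing
# forward(x, train), backward(dy), a `pnames` vector naming its parameter
# arrays (gradients live in "d<name>") and optionally `children`. Layers
# cache whatever the backward pass needs; forward must therefore be called
# before backward within a step.

sigmoid <- function(x) 1 / (1 + exp(-x))

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$pnames <- character()
  e$children <- list()
  e
}

#' @noRd
nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = k %/% 2L) {
  e <- new_layer("conv")
  e$stride <- stride; e$pad <- pad
  e$w <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               c(k, k, cin, cout))
  e$b <- numeric(cout)
  e$pnames <- c("w", "b")
  e$forward <- function(x, train = TRUE) {
    e$x <- x
    conv2d_fwd(x, e$w, e$b, e$stride, e$pad)
  }
  e$backward <- function(dy) {
    g <- conv2d_bwd(e$x, e$w, dy, e$stride, e$pad)
    e$dw <- g$dw; e$db <- g$db
    g$dx
  }
  e
}

nn_dwconv <- function(c, k = 3L, stride = 1L, pad = k %/% 2L) {
  e <- new_layer("dwconv")
  e$stride <- stride; e$pad <- pad
  e$w <- array(stats::rnorm(k * k * c, sd = sqrt(2 / (k * k))), c(k, k, c))
  e$b <- numeric(c)
  e$pnames <- c("w", "b")
  e$forward <- function(x, train = TRUE) {
    e$x <- x
    dwconv2d_fwd(x, e$w, e$b, e$stride, e$pad)
  }
  e$backward <- function(dy) {
    g <- dwconv2d_bwd(e$x, e$w, dy, e$stride, e$pad)
    e$dw <- g$dw; e$db <- g$db
    g$dx
  }
  e
}

# Batch normalization per channel; train mode uses batch statistics and
# updates running statistics with the given momentum (running <- momentum *
# running + (1 - momentum) * batch), eval mode uses the running statistics.
nn_bn <- function(c, eps = 1e-3, momentum = 0.99) {
  e <- new_layer("bn")
  e$eps <- eps; e$momentum <- momentum
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$rmean <- numeric(c); e$rvar <- rep(1, c)
  e$seen <- FALSE
  e$pnames <- c("gamma", "beta")
  e$snames <- c("rmean", "rvar", "seen")
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) {
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      m <- colMeans(xm)
      v <- colMeans(xm * xm) - m * m
      v[v < 0] <- 0
      if (!e$seen) {
        # seed the running statistics from the first batch so evaluation
        # mode is usable long before the slow EMA (momentum 0.99) converges
        e$rmean <- m
        e$rvar <- v
        e$seen <- TRUE
      } else {
        e$rmean <- e$momentum * e$rmean + (1 - e$momentum) * m
        e$rvar <- e$momentum * e$rvar + (1 - e$momentum) * v
      }
    } else {
      m <- e$rmean; v <- e$rvar
    }
    istd <- 1 / sqrt(v + e$eps)
    xhat <- (x - bcast_ch(m, d)) * bcast_ch(istd, d)
    if (train) { e$xhat <- xhat; e$istd <- istd; e$d <- d }
    xhat * bcast_ch(e$gamma, d) + bcast_ch(e$beta, d)
  }
  e$backward <- function(dy) {
    d <- e$d
    nper <- d[1] * d[2] * d[4]
    sum_ch <- function(a) colSums(matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3]))
    e$dgamma <- sum_ch(dy * e$xhat)
    e$dbeta <- sum_ch(dy)
    gi <- e$gamma * e$istd
    m_dy <- e$dbeta / nper
    m_dyxhat <- e$dgamma / nper
    bcast_ch(gi, d) * (dy - bcast_ch(m_dy, d) - e$xhat * bcast_ch(m_dyxhat, d))
  }
  e
}

# Stateless activations with cached inputs.
nn_act <- function(fun = c("swish", "relu", "sigmoid")) {
  fun <- match.arg(fun)
  e <- new_layer(paste0("act_", fun))
  e$forward <- function(x, train = TRUE) {
    if (fun == "swish") {
      s <- sigmoid(x); e$x <- x; e$s <- s
      x * s
    } else if (fun == "relu") {
      e$pos <- x > 0
      x * e$pos
    } else {
      e$y <- sigmoid(x)
      e$y
    }
  }
  e$backward <- function(dy) {
    if (fun == "swish") dy * (e$s * (1 + e$x * (1 - e$s)))
    else if (fun == "relu") dy * e$pos
    else dy * e$y * (1 - e$y)
  }
  e
}

# Nearest-neighbour 2x upsampling; backward sum-pools 2x2 blocks.
nn_upsample2 <- function() {
  e <- new_layer("up2")
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    e$d <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  }
  e$backward <- function(dy) {
    d <- e$d
    o1 <- seq(1L, 2L * d[1], 2L); o2 <- seq(1L, 2L * d[2], 2L)
    dy[o1, o2, , , drop = FALSE] + dy[o1 + 1L, o2, , , drop = FALSE] +
      dy[o1, o2 + 1L, , , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , , drop = FALSE]
  }
  e
}

# Transposed convolution with stride 2, realized as zero-stuffing followed
# by a k x k convolution (fractionally-strided convolution).
nn_tconv <- function(cin, cout, k = 3L) {
  e <- new_layer("tconv")
  e$conv <- nn_conv(cin, cout, k = k, stride = 1L)
  e$children <- list(e$conv)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    e$d <- d
    z <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
    z[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , ] <- x
    e$conv$forward(z, train)
  }
  e$backward <- function(dy) {
    dz <- e$conv$backward(dy)
    d <- e$d
    dz[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , , drop = FALSE]
  }
  e
}

# Mobile inverted bottleneck block: depthwise 3x3 (optionally strided) +
# batch norm + Swish, then pointwise 1x1 + batch norm + Swish, with a
# residual connection when input and output shapes match (stride 1 and
# cin == cout).
nn_mbconv <- function(cin, cout, stride = 1L, bn_eps = 1e-3, bn_momentum = 0.99) {
  e <- new_layer("mbconv")
  e$residual <- (stride == 1L && cin == cout)
  e$dw <- nn_dwconv(cin, 3L, stride)
  e$bn1 <- nn_bn(cin, bn_eps, bn_momentum)
  e$a1 <- nn_act("swish")
  e$pw <- nn_conv(cin, cout, 1L)
  e$bn2 <- nn_bn(cout, bn_eps, bn_momentum)
  e$a2 <- nn_act("swish")
  e$children <- list(e$dw, e$bn1, e$a1, e$pw, e$bn2, e$a2)
  e$forward <- function(x, train = TRUE) {
    h <- e$a1$forward(e$bn1$forward(e$dw$forward(x, train), train), train)
    y <- e$a2$forward(e$bn2$forward(e$pw$forward(h, train), train), train)
    if (e$residual) y + x else y
  }
  e$backward <- function(dy) {
    dh <- e$dw$backward(e$bn1$backward(e$a1$backward(
      e$pw$backward(e$bn2$backward(e$a2$backward(dy))))))
    if (e$residual) dh + dy else dh
  }
  e
}

# Concurrent spatial and channel squeeze & excitation. Channel branch:
# global average pool -> bottleneck MLP (reduction r) -> sigmoid gates per
# channel. Spatial branch: 1x1 convolution -> sigmoid gate per pixel.
# Fusion is additive: y = x * s_channel + x * s_spatial.
nn_scse <- function(c, r = 2L) {
  e <- new_layer("scse")
  cr <- max(1L, c %/% r)
  e$w1 <- matrix(stats::rnorm(cr * c, sd = sqrt(2 / c)), cr, c)
  e$b1 <- numeric(cr)
  e$w2 <- matrix(stats::rnorm(c * cr, sd = sqrt(2 / cr)), c, cr)
  e$b2 <- numeric(c)
  e$pnames <- c("w1", "b1", "w2", "b2")
  e$sconv <- nn_conv(c, 1L, 1L)
  e$children <- list(e$sconv)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    e$x <- x; e$d <- d
    hw <- d[1] * d[2]
    z <- matrix(colSums(matrix(x, hw, d[3] * d[4])), d[3], d[4]) / hw
    h <- e$w1 %*% z + e$b1
    h[h < 0] <- 0
    sc <- sigmoid(e$w2 %*% h + e$b2)
    e$z <- z; e$h <- h; e$sc <- sc
    q <- e$sconv$forward(x, train)
    ss <- sigmoid(q)
    e$ss <- ss
    ssb <- ss[, , rep(1L, d[3]), , drop = FALSE]
    e$ssb <- ssb
    x * bcast_ch(sc, d) + x * ssb
  }
  e$backward <- function(dy) {
    d <- e$d
    hw <- d[1] * d[2]
    dx <- dy * bcast_ch(e$sc, d) + dy * e$ssb
    # channel-excitation branch
    m <- dy * e$x
    dsc <- matrix(colSums(matrix(m, hw, d[3] * d[4])), d[3], d[4])
    dpre2 <- dsc * e$sc * (1 - e$sc)
    e$dw2 <- dpre2 %*% t(e$h)
    e$db2 <- rowSums(dpre2)
    dh <- t(e$w2) %*% dpre2
    dpre1 <- dh * (e$h > 0)
    e$dw1 <- dpre1 %*% t(e$z)
    e$db1 <- rowSums(dpre1)
    dz <- t(e$w1) %*% dpre1
    dx <- dx + bcast_ch(dz, d) / hw
    # spatial-excitation branch
    dss <- rowSums(aperm(m, c(1, 2, 4, 3)), dims = 3)          # (H, W, N)
    dq <- array(dss, c(d[1], d[2], 1L, d[4])) * e$ss * (1 - e$ss)
    dx + e$sconv$backward(dq)
  }
  e
}

# Depth-first collection of all layers with parameters.
collect_layers <- function(x) {
  out <- list()
  walk <- function(l) {
    if (length(l$pnames)) out[[length(out) + 1L]] <<- l
    for (ch in l$children) walk(ch)
  }
  if (is.list(x)) lapply(x, walk) else walk(x)
  out
}

n_params <- function(layers) {
  sum(vapply(layers, function(l)
    sum(vapply(l$pnames, function(p) length(l[[p]]), numeric(1))), numeric(1)))
}

# Snapshot / restore of all parameters and normalization statistics.
collect_state <- function(layers) {
  lapply(layers, function(l) {
    nm <- c(l$pnames, l$snames %||% character())
    stats::setNames(lapply(nm, function(p) l[[p]]), nm)
  })
}

restore_state <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) layers[[i]][[p]] <- state[[i]][[p]]
  }
  invisible(NULL)
}

# Adam optimizer with decoupled-from-schedule L2 weight decay added to the
# gradient (lambda * w), standard moment coefficients.
adam_init <- function(layers, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- lapply(layers, function(l)
    stats::setNames(lapply(l$pnames, function(p)
      list(m = 0 * l[[p]], v = 0 * l[[p]])), l$pnames))
  list(state = st, t = 0L, weight_decay = weight_decay,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, layers, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$pnames) {
      g <- l[[paste0("d", p)]]
      if (is.null(g)) next
      if (opt$weight_decay > 0 && p %in% c("w", "w1", "w2"))
        g <- g + opt$weight_decay * l[[p]]
      s <- opt$state[[i]][[p]]
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g * g
      opt$state[[i]][[p]] <- s
      l[[p]] <- l[[p]] - lr * (s$m / c1) / (sqrt(s$v / c2) + opt$eps)
    }
  }
  opt
}
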