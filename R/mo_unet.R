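#' Network configuration for the multi-output U-Net
#'
#' The network has one shared MBConv encoder and one scSE-attention decoder
#' per marker; a selection unit routes the encoder features to the decoders
#' configured for the input sequence (hard routing keyed on the batch's
#' sequence tag).
#'
#' @param input_size Edge length of the square input slices; must be
#'   divisible by `2^length(encoder_stage_widths)`.
#' @param encoder_stage_widths Channel counts per downsampling stage (each
#'   stage halves the spatial size).
#' @param markers Ordered decoder list.
#' @param routing Named list: sequence tag -> markers decoded from it.
#' @param use_pretrained_encoder Load autoencoder-pretrained encoder weights
#'   when building the model.
#' @param se_reduction Channel reduction ratio of the scSE blocks.
#' @param bn_eps,bn_momentum Batch-normalization epsilon and momentum.
#' @return A `network_config`.
#' @export
network_config <- function(input_size = 64L,
                           encoder_stage_widths = c(8L, 16L, 32L),
                           markers = csvd_markers(),
                           routing = default_routing(),
                           use_pretrained_encoder = TRUE,
                           se_reduction = 2L,
                           bn_eps = 1e-3, bn_momentum = 0.99) {
  n_stages <- length(encoder_stage_widths)
  if (n_stages < 2L) stop("need at least 2 encoder stages")
  if (any(encoder_stage_widths <= 0)) stop("stage widths must be positive")
  if (input_size %% (2^n_stages) != 0)
    stop("input_size must be divisible by 2^n_stages")
  routed <- unique(unlist(routing))
  if (!all(markers %in% routed))
    stop("every marker must appear in at least one routing entry: missing ",
         paste(setdiff(markers, routed), collapse = ", "))
  if (!all(names(routing) %in% csvd_sequences())) stop("unknown sequence in routing")
  structure(list(input_size = as.integer(input_size),
                 encoder_stage_widths = as.integer(encoder_stage_widths),
                 n_stages = n_stages, markers = markers, routing = routing,
                 use_pretrained_encoder = use_pretrained_encoder,
                 se_reduction = as.integer(se_reduction),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "network_config")
}

#' Build the shared MBConv encoder
#'
#' A stem convolution followed by one strided MBConv block per stage
#' (depthwise separable 3x3 + pointwise 1x1, Swish activations, residual
#' connections whenever shapes match). The forward pass returns the skip
#' feature grids (one per resolution, starting at input resolution) and the
#' bottleneck grid; spatial size halves at each stage.
#'
#' @param config A [network_config()].
#' @return An encoder object with `forward(x, train)` and
#'   `backward(d_bottleneck, d_skips)`.
#' @export
build_encoder <- function(config) {
  w <- config$encoder_stage_widths
  n <- config$n_stages
  e <- new_layer("encoder")
  e$stem <- nn_conv(1L, w[1], 3L)
  e$stem_bn <- nn_bn(w[1], config$bn_eps, config$bn_momentum)
  e$stem_act <- nn_act("swish")
  e$stages <- lapply(seq_len(n), function(i) {
    cin <- if (i == 1L) w[1] else w[i - 1L]
    nn_mbconv(cin, w[i], stride = 2L, config$bn_eps, config$bn_momentum)
  })
  e$children <- c(list(e$stem, e$stem_bn, e$stem_act), e$stages)
  e$n_stages <- n
  e$widths <- w
  e$forward <- function(x, train = TRUE) {
    s0 <- e$stem_act$forward(e$stem_bn$forward(e$stem$forward(x, train), train), train)
    skips <- vector("list", n)
    skips[[1L]] <- s0
    h <- s0
    for (i in seq_len(n)) {
      h <- e$stages[[i]]$forward(h, train)
      if (i < n) skips[[i + 1L]] <- h
    }
    list(skips = skips, bottleneck = h)
  }
  e$backward <- function(d_bottleneck, d_skips) {
    dh <- d_bottleneck
    for (i in rev(seq_len(n))) {
      dh <- e$stages[[i]]$backward(dh)
      if (i > 1L && !is.null(d_skips[[i]])) dh <- dh + d_skips[[i]]
    }
    if (!is.null(d_skips[[1L]])) dh <- dh + d_skips[[1L]]
    e$stem$backward(e$stem_bn$backward(e$stem_act$backward(dh)))
  }
  e
}

# Channel concatenation along dim 3 with a matching backward split.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# One marker decoder: per stage nearest-neighbour upsampling, concatenation
# with the encoder skip at that scale, 3x3 convolution + BN + Swish, and an
# scSE attention block; a 1x1 convolution + sigmoid head emits the
# probability map at input resolution.
build_decoder <- function(config) {
  w <- config$encoder_stage_widths
  n <- config$n_stages
  e <- new_layer("decoder")
  skip_w <- c(w[1], w[seq_len(n - 1L)])      # widths of skips[[1..n]]
  prev <- w[n]
  e$stages <- vector("list", n)
  for (j in seq_len(n)) {
    sw <- skip_w[n + 1L - j]
    st <- new_layer("dec_stage")
    st$up <- nn_upsample2()
    st$conv <- nn_conv(prev + sw, sw, 3L)
    st$bn <- nn_bn(sw, config$bn_eps, config$bn_momentum)
    st$act <- nn_act("swish")
    st$scse <- nn_scse(sw, config$se_reduction)
    st$children <- list(st$up, st$conv, st$bn, st$act, st$scse)
    e$stages[[j]] <- st
    prev <- sw
  }
  e$head <- nn_conv(prev, 1L, 1L)
  # start near the foreground prior (lesions are rare) instead of p = 0.5;
  # avoids the early background-collapse phase under class imbalance
  e$head$b[] <- -4
  e$head_act <- nn_act("sigmoid")
  e$children <- c(e$stages, list(e$head, e$head_act))
  e$forward <- function(skips, bottleneck, train = TRUE) {
    h <- bottleneck
    e$split <- integer(n)
    for (j in seq_len(n)) {
      st <- e$stages[[j]]
      u <- st$up$forward(h, train)
      e$split[j] <- dim(u)[3]
      h <- st$scse$forward(st$act$forward(st$bn$forward(
        st$conv$forward(cat_channels(u, skips[[n + 1L - j]]), train),
        train), train), train)
    }
    e$head_act$forward(e$head$forward(h, train), train)
  }
  e$backward <- function(dp) {
    dh <- e$head$backward(e$head_act$backward(dp))
    d_skips <- vector("list", n)
    for (j in rev(seq_len(n))) {
      st <- e$stages[[j]]
      dcat <- st$conv$backward(st$bn$backward(st$act$backward(
        st$scse$backward(dh))))
      cu <- e$split[j]
      du <- dcat[, , seq_len(cu), , drop = FALSE]
      d_skips[[n + 1L - j]] <- dcat[, , -seq_len(cu), , drop = FALSE]
      dh <- st$up$backward(du)
    }
    list(d_bottleneck = dh, d_skips = d_skips)
  }
  e
}

#' Build the multi-output U-Net
#'
#' One shared encoder, four marker-specific decoders with scSE attention,
#' and a selection unit that routes the encoded features to the decoders
#' configured for the input sequence. Optionally loads autoencoder-pretrained
#' encoder parameters.
#'
#' @param config A [network_config()].
#' @param pretrained_encoder Optional encoder (from
#'   [pretrain_autoencoder()]) whose parameters are copied in; stage widths
#'   must match.
#' @return A `mo_unet` model object.
#' @export
build_mo_unet <- function(config, pretrained_encoder = NULL) {
  stopifnot(inherits(config, "network_config"))
  model <- new_layer("mo_unet")
  model$config <- config
  model$encoder <- build_encoder(config)
  model$decoders <- stats::setNames(
    lapply(config$markers, function(m) build_decoder(config)), config$markers)
  model$children <- c(list(model$encoder), model$decoders)
  if (!is.null(pretrained_encoder)) {
    if (!identical(pretrained_encoder$widths, model$encoder$widths))
      stop("pretrained encoder stage widths do not match the configuration")
    restore_state(collect_layers(model$encoder),
                  collect_state(collect_layers(pretrained_encoder)))
  }
  class(model) <- c("mo_unet", class(model))
  model
}

#' @export
print.mo_unet <- function(x, ...) {
  cat("<mo_unet> stages:", paste(x$config$encoder_stage_widths, collapse = "-"),
      "| decoders:", paste(names(x$decoders), collapse = ", "),
      "| parameters:", n_params(collect_layers(x)), "\n")
  invisible(x)
}

# Coerce a matrix / (H,W,N) / (H,W,1,N) input to (H,W,1,N).
as_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2], 1L, d[3])
  }
  x
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the network configuration together with every
#' parameter and normalization statistic; loading rebuilds the model from
#' its embedded configuration and restores the state.
#'
#' @param model A `mo_unet`.
#' @param path File path (RDS format).
#' @return `load_mo_unet` returns the rebuilt model.
#' @export
save_mo_unet <- function(model, path) {
  saveRDS(list(config = model$config,
               state = collect_state(collect_layers(model))), path)
  invisible(path)
}

#' @rdname save_mo_unet
#' @export
load_mo_unet <- function(path) {
  ck <- readRDS(path)
  model <- build_mo_unet(ck$config)
  restore_state(collect_layers(model), ck$state)
  model
}

#' Forward pass with sequence routing
#'
#' Runs the shared encoder once and only the decoders routed from
#' `sequence_tag`; markers not routed from this sequence are absent from the
#' result (not zero-filled). All returned maps are probabilities in (0, 1)
#' at input resolution.
#'
#' @param model A `mo_unet`.
#' @param x Input batch: matrix, (H,W,N) or (H,W,1,N) array of slices.
#' @param sequence_tag Sequence of the batch; must be in the routing table.
#' @param train Use batch statistics (training) or running statistics
#'   (deterministic evaluation) in the normalization layers.
#' @return Named list of probability arrays, one per routed marker.
#' @export
forward_route <- function(model, x, sequence_tag, train = FALSE) {
  markers <- model$config$routing[[sequence_tag]]
  if (is.null(markers)) stop("unknown sequence tag: ", sequence_tag)
  x <- as_batch(x)
  enc <- model$encoder$forward(x, train)
  model$last_enc <- enc
  model$last_markers <- markers
  out <- lapply(markers, function(m)
    model$decoders[[m]]$forward(enc$skips, enc$bottleneck, train))
  stats::setNames(out, markers)
}

# Backward pass for the markers of the last routed forward; dps is a named
# list of gradients w.r.t. the emitted probability maps. Returns gradient
# w.r.t. the input batch (rarely needed; grads are stored in the layers).
model_backward <- function(model, dps) {
  n <- model$encoder$n_stages
  d_b <- NULL
  d_s <- vector("list", n)
  for (m in names(dps)) {
    g <- model$decoders[[m]]$backward(dps[[m]])
    d_b <- if (is.null(d_b)) g$d_bottleneck else d_b + g$d_bottleneck
    for (i in seq_len(n)) {
      d_s[[i]] <- if (is.null(d_s[[i]])) g$d_skips[[i]]
                  else d_s[[i]] + g$d_skips[[i]]
    }
  }
  model$encoder$backward(d_b, d_s)
}

#' Pretrain the encoder as an autoencoder
#'
#' Trains encoder + transposed-convolution decoder to reconstruct the input
#' slices under mean-squared error, and returns the encoder for transfer
#' into [build_mo_unet()]. The reconstruction decoder mirrors the encoder
#' stages with fractionally-strided (transposed) convolutions.
#'
#' @param images List of 2D slices or an (H,W,1,N) array.
#' @param config A [network_config()].
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Fixed learning rate for the reconstruction task.
#' @return List with `encoder` (loadable into [build_mo_unet()]) and
#'   `history` (per-epoch reconstruction MSE).
#' @export
pretrain_autoencoder <- function(images, config, epochs = 10L, batch_size = 6L,
                                 lr = 1e-3) {
  if (is.list(images)) {
    arr <- array(0, c(dim(images[[1]]), 1L, length(images)))
    for (i in seq_along(images)) arr[, , 1L, i] <- images[[i]]
    images <- arr
  }
  images <- as_batch(images)
  n_img <- dim(images)[4]
  if (n_img < 1L) stop("need at least one training image")
  w <- config$encoder_stage_widths
  n <- config$n_stages
  enc <- build_encoder(config)
  dec <- new_layer("ae_decoder")
  dec$blocks <- list()
  prev <- w[n]
  for (j in rev(seq_len(n))) {
    cout <- if (j > 1L) w[j - 1L] else w[1]
    blk <- new_layer("ae_block")
    blk$t <- nn_tconv(prev, cout)
    blk$bn <- nn_bn(cout, config$bn_eps, config$bn_momentum)
    blk$act <- nn_act("swish")
    blk$children <- list(blk$t, blk$bn, blk$act)
    dec$blocks[[length(dec$blocks) + 1L]] <- blk
    prev <- cout
  }
  dec$head <- nn_conv(prev, 1L, 1L)
  dec$children <- c(dec$blocks, list(dec$head))
  layers <- collect_layers(list(enc, dec))
  opt <- adam_init(layers, weight_decay = 0)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    mse_sum <- 0
    nb <- 0L
    for (start in seq(1L, n_img, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_img)]
      x <- images[, , , idx, drop = FALSE]
      h <- enc$forward(x, train = TRUE)$bottleneck
      for (blk in dec$blocks)
        h <- blk$act$forward(blk$bn$forward(blk$t$forward(h, TRUE), TRUE), TRUE)
      yhat <- dec$head$forward(h, TRUE)
      diff <- yhat - x
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop("non-finite reconstruction loss at epoch ", ep)
      mse_sum <- mse_sum + loss
      nb <- nb + 1L
      dh <- dec$head$backward(2 * diff / length(diff))
      for (blk in rev(dec$blocks))
        dh <- blk$t$backward(blk$bn$backward(blk$act$backward(dh)))
      enc$backward(dh, vector("list", n))
      opt <- adam_step(opt, layers, lr)
    }
    history[ep] <- mse_sum / nb
  }
  list(encoder = enc, history = history)
}
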