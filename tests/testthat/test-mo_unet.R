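mini_config <- function(markers = c("WMH", "lacune"),
                        routing = list(FLAIR = c("WMH", "lacune"))) {
  network_config(input_size = 16L, encoder_stage_widths = c(4L, 6L),
                 markers = markers, routing = routing)
}

test_that("encoder halves spatial size per stage and exposes matching skips", {
  nc <- network_config(input_size = 64L, encoder_stage_widths = c(4L, 6L, 8L))
  set.seed(1)
  enc <- build_encoder(nc)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  out <- enc$forward(x, train = TRUE)
  expect_identical(vapply(out$skips, function(s) dim(s)[1], numeric(1)),
                   c(64, 32, 16))
  expect_identical(dim(out$bottleneck)[1:2], c(8L, 8L))
  expect_identical(dim(out$bottleneck)[3], 8L)
})

test_that("depthwise separable stages undercut dense convolutions in parameters", {
  c_in <- 16L; c_out <- 16L
  sep <- csvdseg:::n_params(csvdseg:::collect_layers(list(
    csvdseg:::nn_dwconv(c_in, 3L), csvdseg:::nn_conv(c_in, c_out, 1L))))
  dense <- csvdseg:::n_params(csvdseg:::collect_layers(list(
    csvdseg:::nn_conv(c_in, c_out, 3L))))
  expect_lt(sep, dense)
})

test_that("Swish activation passes through zero and matches x * sigmoid(x)", {
  a <- csvdseg:::nn_act("swish")
  x <- array(c(0, -2, 3, 0.5), c(2, 2, 1, 1))
  y <- a$forward(x)
  expect_equal(y[1, 1, 1, 1], 0)
  expect_equal(y, x / (1 + exp(-x)))
})

test_that("model gradients agree with finite differences", {
  nc <- mini_config()
  set.seed(7)
  model <- build_mo_unet(nc)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- list(WMH = array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 1, 2)),
            lacune = array(rbinom(16 * 16 * 2, 1, 0.1), c(16, 16, 1, 2)))
  lossfun <- function() {
    pr <- forward_route(model, x, "FLAIR", train = TRUE)
    total_loss(y$WMH, pr$WMH) + total_loss(y$lacune, pr$lacune)
  }
  pr <- forward_route(model, x, "FLAIR", train = TRUE)
  dps <- lapply(stats::setNames(names(y), names(y)), function(m)
    csvdseg:::.loss_and_grad(y[[m]], pr[[m]], 1e-7, 1)$dp)
  csvdseg:::model_backward(model, dps)
  layers <- csvdseg:::collect_layers(model)
  set.seed(3)
  for (li in sample(seq_along(layers), 6)) {
    l <- layers[[li]]
    p <- l$pnames[1]
    idx <- sample(length(l[[p]]), 1)
    g_an <- l[[paste0("d", p)]][idx]
    eps <- 1e-5
    orig <- l[[p]][idx]
    l[[p]][idx] <- orig + eps; f1 <- lossfun()
    l[[p]][idx] <- orig - eps; f2 <- lossfun()
    l[[p]][idx] <- orig
    g_num <- (f1 - f2) / (2 * eps)
    expect_lt(abs(g_an - g_num), 1e-4 * max(1, abs(g_num)))
  }
})

test_that("sequence routing emits exactly the configured markers", {
  nc <- network_config(input_size = 16L, encoder_stage_widths = c(4L, 6L))
  set.seed(2)
  model <- build_mo_unet(nc)
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  fl <- forward_route(model, x, "FLAIR")
  expect_setequal(names(fl), c("WMH", "lacune"))
  sw <- forward_route(model, x, "SWI")
  expect_identical(names(sw), "CMB")
  expect_null(sw$WMH)
  t1 <- forward_route(model, x, "T1")
  expect_setequal(names(t1), c("EPVS", "lacune"))
  expect_error(forward_route(model, x, "T2"), "unknown sequence")
  # batch, shape and range contracts
  for (m in names(fl)) {
    expect_identical(dim(fl[[m]]), c(16L, 16L, 1L, 3L))
    expect_true(all(fl[[m]] > 0 & fl[[m]] < 1))
  }
  z <- forward_route(model, array(0, c(16, 16, 1, 2)), "SWI")
  expect_true(all(is.finite(z$CMB)) && all(z$CMB > 0 & z$CMB < 1))
})

test_that("evaluation-mode forwards are deterministic and encoder is shared", {
  nc <- mini_config()
  set.seed(5)
  model <- build_mo_unet(nc)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  invisible(forward_route(model, x, "FLAIR", train = TRUE))  # seed BN stats
  a <- forward_route(model, x, "FLAIR", train = FALSE)
  b <- forward_route(model, x, "FLAIR", train = FALSE)
  expect_identical(a, b)
  # the same encoder object serves every route
  w_before <- model$encoder$stem$w
  model$encoder$stem$w <- w_before * 2
  c1 <- forward_route(model, x, "FLAIR", train = FALSE)
  expect_false(identical(a$WMH, c1$WMH))
  model$encoder$stem$w <- w_before
})

test_that("scSE spatial branch vanishes when its excitation map is zeroed", {
  set.seed(4)
  blk <- csvdseg:::nn_scse(6L, 2L)
  x <- array(runif(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  y <- blk$forward(x, train = TRUE)
  sc <- blk$sc
  # force the spatial gate to (numerically) zero; channel branch untouched
  blk$sconv$b[] <- -1e6
  y0 <- blk$forward(x, train = TRUE)
  expect_equal(y0, x * csvdseg:::bcast_ch(sc, dim(x)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y, y0)))
})

test_that("halving every stage width at least halves the parameter count", {
  n_full <- csvdseg:::n_params(csvdseg:::collect_layers(
    build_mo_unet(network_config(input_size = 32L,
                                 encoder_stage_widths = c(8L, 16L, 32L)))))
  n_half <- csvdseg:::n_params(csvdseg:::collect_layers(
    build_mo_unet(network_config(input_size = 32L,
                                 encoder_stage_widths = c(4L, 8L, 16L)))))
  expect_lte(2 * n_half, n_full)
})

test_that("autoencoder pretraining reduces reconstruction error and transfers", {
  nc <- mini_config()
  set.seed(9)
  imgs <- lapply(1:20, function(i) matrix(runif(256, 0, 1), 16, 16))
  ae <- pretrain_autoencoder(imgs, nc, epochs = 6L)
  expect_lt(ae$history[length(ae$history)], ae$history[1])

  # near-zero loss is attainable on constant-zero images
  zeros <- lapply(1:10, function(i) matrix(0, 16, 16))
  set.seed(10)
  ae0 <- pretrain_autoencoder(zeros, nc, epochs = 30L, lr = 5e-3)
  expect_lt(ae0$history[length(ae0$history)], 1e-3)

  # transferring the encoder reproduces its features exactly
  set.seed(11)
  model <- build_mo_unet(nc, pretrained_encoder = ae$encoder)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  f1 <- ae$encoder$forward(x, train = FALSE)
  f2 <- model$encoder$forward(x, train = FALSE)
  expect_identical(f1$bottleneck, f2$bottleneck)
  bad <- build_encoder(network_config(input_size = 16L,
                                      encoder_stage_widths = c(3L, 5L)))
  expect_error(build_mo_unet(nc, pretrained_encoder = bad), "widths")
})

test_that("checkpoints round-trip parameters and running statistics", {
  nc <- mini_config()
  set.seed(12)
  model <- build_mo_unet(nc)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  invisible(forward_route(model, x, "FLAIR", train = TRUE))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path), add = TRUE)
  save_mo_unet(model, path)
  m2 <- load_mo_unet(path)
  expect_identical(forward_route(model, x, "FLAIR", train = FALSE),
                   forward_route(m2, x, "FLAIR", train = FALSE))
})

test_that("network configuration invariants are enforced", {
  expect_error(network_config(encoder_stage_widths = 8L), "2 encoder stages")
  expect_error(network_config(input_size = 50L), "divisible")
  expect_error(network_config(routing = list(FLAIR = "WMH")), "routing entry")
})
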