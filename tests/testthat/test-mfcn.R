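test_that("the probability map has the input shape and normalised pixels", {
  net <- build_mfcn(network_spec(base_channels = 4), seed = 1)
  img <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 20)
  pm <- mfcn_forward(net, img)
  expect_equal(dim(pm), c(64, 64, 2))
  expect_true(all(abs(pm[, , 1] + pm[, , 2] - 1) < 1e-5))
  expect_true(all(pm >= 0))
  # All-zero input: finite outputs, no NaN/Inf.
  pm0 <- mfcn_forward(net, matrix(0L, 64, 64))
  expect_true(all(is.finite(pm0)))
  # Non-divisible sizes are reflect-padded and cropped back.
  pm_odd <- mfcn_forward(net, matrix(100L, 50, 70))
  expect_equal(dim(pm_odd), c(50, 70, 2))
})

test_that("the parameter count matches layer-by-layer arithmetic", {
  spec <- network_spec(inception_kernels = c(3, 5), branch_factors = c(4, 8),
                       base_channels = 8, channel_growth = 2)
  net <- build_mfcn(spec, seed = 0)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  # Branch 1 (kernel 3, factor 4, channels 8 then 16):
  #   inception conv 3x3 1->8, down 8->16, up 16->8, up 8->8, score 1x1 8->2.
  b1 <- conv_n(3, 1, 8) + bn_n(8) + conv_n(3, 8, 16) + bn_n(16) +
    (2 * 2 * 16 * 8 + 8) + bn_n(8) + (2 * 2 * 8 * 8 + 8) + bn_n(8) +
    conv_n(1, 8, 2)
  # Branch 2 (kernel 5, factor 8, channels 8, 16, 32).
  b2 <- conv_n(5, 1, 8) + bn_n(8) + conv_n(3, 8, 16) + bn_n(16) +
    conv_n(3, 16, 32) + bn_n(32) +
    (2 * 2 * 32 * 16 + 16) + bn_n(16) + (2 * 2 * 16 * 8 + 8) + bn_n(8) +
    (2 * 2 * 8 * 8 + 8) + bn_n(8) + conv_n(1, 8, 2)
  ens <- conv_n(1, 4, 2)
  expect_equal(mfcn_param_count(net), b1 + b2 + ens)
})

test_that("analytic gradients agree with finite differences", {
  spec <- network_spec(inception_kernels = c(3, 5), branch_factors = c(4, 8),
                       base_channels = 2, channel_growth = 2)
  net <- build_mfcn(spec, seed = 1)
  set.seed(2)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), dim = c(16, 16, 2))
  lossfun <- function(net) {
    fwd <- granuleseg:::mfcn_forward_full(net, x, mode = "train", keep = TRUE)
    ce <- granuleseg:::weighted_ce(fwd$probs, y, 0.6, 1.7)
    list(loss = ce$loss, fwd = fwd, ce = ce)
  }
  r <- lossfun(net)
  bwd <- granuleseg:::mfcn_backward_full(net, r$fwd, r$ce$dlogits,
                                         mode = "train")
  for (nm in c("b1_incep.w", "b1_incep.g", "b2_down2.w", "b1_up1.w",
               "ens.w", "b2_score.b")) {
    g <- bwd$grads[[nm]]
    for (k in seq_len(min(3, length(g)))) {
      eps <- 1e-5
      n2 <- net
      n2$params[[nm]][k] <- n2$params[[nm]][k] + eps
      lp <- lossfun(n2)$loss
      n2$params[[nm]][k] <- n2$params[[nm]][k] - 2 * eps
      lm <- lossfun(n2)$loss
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[k]) / max(1e-6, abs(num) + abs(g[k])), 1e-4)
    }
  }
})

test_that("training is deterministic and reduces the loss", {
  set.seed(10)
  px <- matrix(80L, 32, 32)
  px[10:20, 10:20] <- 200L
  lab <- matrix(0L, 32, 32)
  lab[10:20, 10:20] <- 1L
  pair <- list(image = gray_image(px, 20), labels = lab)
  cfg <- run_config(network = tiny_spec(), epochs = 50, batch_size = 1,
                    seed = 9)
  net <- build_mfcn(cfg$network, seed = cfg$seed)
  s1 <- mfcn_train(net, list(pair), cfg)
  s2 <- mfcn_train(net, list(pair), cfg)
  expect_identical(glance(s1)$final_loss, glance(s2)$final_loss)
  expect_identical(s1$network$params, s2$network$params)
  expect_equal(nrow(tidy(s1)), 50)
  expect_lt(glance(s1)$final_epoch_loss, glance(s1)$first_epoch_loss)
})

test_that("an all-background problem has a near-zero optimum", {
  pair <- list(image = gray_image(matrix(90L, 32, 32), 20),
               labels = matrix(0L, 32, 32))
  cfg <- run_config(network = tiny_spec(), epochs = 150, batch_size = 1,
                    seed = 3)
  st <- mfcn_train(build_mfcn(cfg$network, seed = 3), list(pair), cfg)
  expect_lt(glance(st)$final_loss, 0.1)
  expect_lt(glance(st)$final_loss, tidy(st)$loss[1])
})

test_that("prediction masks are monotone in the threshold with strict ties", {
  net <- build_mfcn(tiny_spec(), seed = 5)
  img <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 20)
  areas <- vapply(c(0.2, 0.5, 0.8),
                  function(th) sum(predict_mask(net, img, th)), numeric(1))
  expect_true(all(diff(areas) <= 0))
  pm <- mfcn_forward(net, img)
  th <- pm[1, 1, 2]  # threshold equal to a pixel's probability -> background
  if (th > 0 && th < 1) {
    expect_equal(predict_mask(net, img, th)[1, 1], 0L)
  }
  expect_error(predict_mask(net, img, 0), "\\(0, 1\\)")
})

test_that("the network is translation-equivariant at the common stride", {
  net <- build_mfcn(tiny_spec(), seed = 6)
  f <- 8  # largest branch factor of the tiny spec
  set.seed(11)
  base <- matrix(0L, 96, 96)
  patch <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  a <- base; a[33:48, 33:48] <- patch
  b <- base; b[(33 + f):(48 + f), (33 + f):(48 + f)] <- patch
  pa <- mfcn_forward(net, a)
  pb <- mfcn_forward(net, b)
  # Compare interiors away from the zero-padding boundary.
  core <- 25:64
  expect_equal(pa[core, core, 2], pb[core + f, core + f, 2], tolerance = 1e-8)
})

test_that("branch receptive fields grow strictly with the branch factor", {
  net <- build_mfcn(network_spec(base_channels = 4), seed = 7)
  rf <- vapply(1:3, function(b) mfcn_receptive_field(net, b), integer(1))
  expect_true(all(diff(rf) > 0))
})

test_that("checkpoints restore an identical network", {
  net <- build_mfcn(tiny_spec(), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_mfcn(net, path)
  back <- load_mfcn(path)
  img <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 20)
  expect_identical(mfcn_forward(net, img), mfcn_forward(back, img))
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("invalid architecture specs are rejected", {
  expect_error(network_spec(inception_kernels = c(3, 4, 7)), "odd")
  expect_error(network_spec(branch_factors = c(4, 8)), "per branch")
  expect_error(network_spec(branch_factors = c(6, 8, 16)), "power of 2")
  expect_error(mfcn_train(build_mfcn(tiny_spec(), 0), list()), "empty")
})
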