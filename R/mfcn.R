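#' Architecture specification of the multi-branch FCN
#'
#' The MFCN has three modules. (1) A multi-scale inception front end: the
#' input passes through parallel stride-2 convolutions with different
#' kernel sizes (3x3, 5x5, 7x7 by default), each seeding one branch, so the
#' branches start from coarse- and fine-grained features. (2) A
#' multi-branch sampling module: each branch is an encoder–decoder that
#' continues down-sampling by strided 3x3 convolutions until its total
#' reduction (4x, 8x, 16x including the inception stride) is reached, then
#' up-samples symmetrically with 2x transposed convolutions back to full
#' resolution, ending in a 2-channel score map. There are no skip
#' connections within a branch. (3) A multi-scale ensemble module: the
#' per-branch score maps are sliced per class, concatenated, and fused by a
#' 1x1 convolution, followed by a channel softmax.
#'
#' @param inception_kernels Odd kernel sizes, one per branch.
#' @param branch_factors Total down/up-sampling per branch; each must be
#'   `inception_stride` times a power of two.
#' @param base_channels Feature channels after the inception stage.
#' @param channel_growth Channel multiplier per down-sampling level.
#' @param inception_stride Stride of the inception convolutions.
#' @return A list of class `network_spec`. The class count is fixed at 2
#'   (background, granule).
#' @export
network_spec <- function(inception_kernels = c(3, 5, 7),
                         branch_factors = c(4, 8, 16),
                         base_channels = 16,
                         channel_growth = 2,
                         inception_stride = 2) {
  if (length(inception_kernels) != length(branch_factors)) {
    abort("need one inception kernel per branch")
  }
  if (any(inception_kernels %% 2 != 1)) abort("inception kernels must be odd")
  m <- log2(branch_factors / inception_stride)
  if (any(m < 0) || any(m != round(m))) {
    abort("each branch factor must be inception_stride times a power of 2")
  }
  if (base_channels < 1 || channel_growth < 1) {
    abort("`base_channels` and `channel_growth` must be >= 1")
  }
  structure(list(
    inception_kernels = as.integer(inception_kernels),
    branch_factors = as.integer(branch_factors),
    base_channels = as.integer(base_channels),
    channel_growth = channel_growth,
    inception_stride = as.integer(inception_stride),
    n_classes = 2L
  ), class = "network_spec")
}

build_arch <- function(spec) {
  nb <- length(spec$branch_factors)
  branches <- vector("list", nb)
  for (b in seq_len(nb)) {
    f <- spec$branch_factors[b]
    L <- as.integer(round(log2(f)))
    ch <- as.integer(round(spec$base_channels * spec$channel_growth^(0:(L - 1))))
    k <- spec$inception_kernels[b]
    layers <- list(list(
      name = sprintf("b%d_incep", b), type = "conv", k = k,
      stride = spec$inception_stride, pad = (k - 1) %/% 2,
      cin = 1L, cout = ch[1], bn = TRUE, relu = TRUE))
    if (L >= 2) {
      for (l in 2:L) {
        layers[[length(layers) + 1]] <- list(
          name = sprintf("b%d_down%d", b, l), type = "conv", k = 3L,
          stride = 2L, pad = 1L, cin = ch[l - 1], cout = ch[l],
          bn = TRUE, relu = TRUE)
      }
      for (l in L:2) {
        layers[[length(layers) + 1]] <- list(
          name = sprintf("b%d_up%d", b, l), type = "tconv",
          cin = ch[l], cout = ch[l - 1], bn = TRUE, relu = TRUE)
      }
    }
    layers[[length(layers) + 1]] <- list(
      name = sprintf("b%d_up1", b), type = "tconv",
      cin = ch[1], cout = ch[1], bn = TRUE, relu = TRUE)
    layers[[length(layers) + 1]] <- list(
      name = sprintf("b%d_score", b), type = "conv", k = 1L, stride = 1L,
      pad = 0L, cin = ch[1], cout = 2L, bn = FALSE, relu = FALSE)
    branches[[b]] <- layers
  }
  ensemble <- list(name = "ens", type = "conv", k = 1L, stride = 1L, pad = 0L,
                   cin = 2L * nb, cout = 2L, bn = FALSE, relu = FALSE)
  list(branches = branches, ensemble = ensemble)
}

#' Build an MFCN with freshly initialised parameters
#'
#' Convolution weights use He initialisation; batch-norm scales start at 1.
#' Construction is deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `mfcn`.
#' @export
build_mfcn <- function(spec = network_spec(), seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  arch <- build_arch(spec)
  params <- list()
  stats <- list()
  with_seed(seed, {
    all_layers <- c(do.call(c, arch$branches), list(arch$ensemble))
    for (L in all_layers) {
      p <- if (L$type == "conv") conv_init(L$k, L$cin, L$cout) else
        tconv_init(L$cin, L$cout)
      params[[paste0(L$name, ".w")]] <- p$w
      params[[paste0(L$name, ".b")]] <- p$b
      if (isTRUE(L$bn)) {
        bp <- bn_init(L$cout)
        params[[paste0(L$name, ".g")]] <- bp$gamma
        params[[paste0(L$name, ".be")]] <- bp$beta
        stats[[paste0(L$name, ".rm")]] <- bp$run_mean
        stats[[paste0(L$name, ".rv")]] <- bp$run_var
      }
    }
  })
  structure(list(spec = spec, arch = arch, params = params, stats = stats),
            class = "mfcn")
}

#' @export
print.mfcn <- function(x, ...) {
  cat(sprintf(
    "<mfcn> %d branch(es), kernels [%s], factors [%s], base %d channels, %d parameters\n",
    length(x$spec$branch_factors),
    paste(x$spec$inception_kernels, collapse = ", "),
    paste(x$spec$branch_factors, collapse = ", "),
    x$spec$base_channels, mfcn_param_count(x)))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' Counts convolution weights and biases plus batch-norm scales and shifts.
#'
#' @param net An [build_mfcn()] network.
#' @return Integer parameter count.
#' @export
mfcn_param_count <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# Forward through one layer sequence. `mode` is "train" (batch statistics),
# "eval" (running statistics) or "probe" ("eval" plus linearised ReLU in
# the backward pass, used for receptive-field measurement).
seq_forward <- function(net, layers, x, mode, keep) {
  training <- identical(mode, "train")
  caches <- if (keep) vector("list", length(layers)) else NULL
  stats <- net$stats
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    xin <- x
    z <- if (L$type == "conv") {
      .conv2d_fwd(x, net$params[[paste0(L$name, ".w")]],
                  net$params[[paste0(L$name, ".b")]], L$stride, L$pad)
    } else {
      .tconv2_fwd(x, net$params[[paste0(L$name, ".w")]],
                  net$params[[paste0(L$name, ".b")]])
    }
    if (isTRUE(L$bn)) {
      gamma <- net$params[[paste0(L$name, ".g")]]
      beta <- net$params[[paste0(L$name, ".be")]]
      if (training) {
        st <- .bn_stats(z)
        mu <- st$mean; v <- st$var
        mom <- 0.1
        stats[[paste0(L$name, ".rm")]] <-
          (1 - mom) * stats[[paste0(L$name, ".rm")]] + mom * mu
        stats[[paste0(L$name, ".rv")]] <-
          (1 - mom) * stats[[paste0(L$name, ".rv")]] + mom * v
      } else {
        mu <- stats[[paste0(L$name, ".rm")]]
        v <- stats[[paste0(L$name, ".rv")]]
      }
      inv <- 1 / sqrt(v + 1e-5)
      r <- .bn_act_fwd(z, mu, inv, gamma, beta, isTRUE(L$relu),
                       keep && training)
      if (keep) {
        caches[[li]] <- list(xin = xin, xhat = r$xhat, y = r$y, inv = inv)
      }
      x <- r$y
    } else {
      a <- if (isTRUE(L$relu)) relu_fwd(z) else z
      if (keep) caches[[li]] <- list(xin = xin, pre_relu = z)
      x <- a
    }
  }
  list(y = x, caches = caches, stats = stats)
}

seq_backward <- function(net, layers, caches, dy, mode) {
  grads <- list()
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    cc <- caches[[li]]
    if (isTRUE(L$bn)) {
      gname <- paste0(L$name, ".g")
      if (mode == "train") {
        r <- .bn_act_bwd(dy, cc$y, cc$xhat, net$params[[gname]], cc$inv,
                         isTRUE(L$relu))
        grads[[gname]] <- r$dgamma
        grads[[paste0(L$name, ".be")]] <- r$dbeta
        dy <- r$dx
      } else {
        # Eval-mode batch norm is a per-channel affine map; in probe mode
        # the rectifier is linearised (mask skipped).
        scale <- net$params[[gname]] * cc$inv
        dy <- .bn_eval_bwd(dy, cc$y, scale, isTRUE(L$relu) && mode != "probe")
      }
    } else if (isTRUE(L$relu) && mode != "probe") {
      dy <- relu_bwd(dy, cc$pre_relu)
    }
    wname <- paste0(L$name, ".w")
    if (L$type == "conv") {
      r <- .conv2d_bwd(cc$xin, net$params[[wname]], dy, L$stride, L$pad)
    } else {
      r <- .tconv2_bwd(cc$xin, net$params[[wname]], dy)
    }
    if (mode == "train") {
      grads[[wname]] <- r$dw
      grads[[paste0(L$name, ".b")]] <- r$db
    }
    dy <- r$dx
  }
  list(grads = grads, dx = dy)
}

# Full forward pass on a normalised input array [H, W, 1, N].
mfcn_forward_full <- function(net, x, mode = "eval", keep = FALSE) {
  nb <- length(net$arch$branches)
  branch_out <- vector("list", nb)
  stats <- net$stats
  for (b in seq_len(nb)) {
    net$stats <- stats
    r <- seq_forward(net, net$arch$branches[[b]], x, mode, keep)
    branch_out[[b]] <- r
    stats <- r$stats
  }
  d <- dim(branch_out[[1]]$y)
  # Slice per class, then concatenate: background scores of all branches,
  # then granule scores of all branches.
  z <- array(0, dim = c(d[1], d[2], 2 * nb, d[4]))
  for (b in seq_len(nb)) {
    z[, , b, ] <- branch_out[[b]]$y[, , 1, ]
    z[, , nb + b, ] <- branch_out[[b]]$y[, , 2, ]
  }
  logits <- .conv2d_fwd(z, net$params[["ens.w"]], net$params[["ens.b"]], 1L, 0L)
  probs <- softmax2(logits)
  list(probs = probs, logits = logits, z = z,
       branch_out = branch_out, stats = stats)
}

mfcn_backward_full <- function(net, fwd, dlogits, mode = "train") {
  nb <- length(net$arch$branches)
  r <- .conv2d_bwd(fwd$z, net$params[["ens.w"]], dlogits, 1L, 0L)
  grads <- list()
  if (mode == "train") {
    grads[["ens.w"]] <- r$dw
    grads[["ens.b"]] <- r$db
  }
  dz <- r$dx
  dx_total <- NULL
  for (b in seq_len(nb)) {
    d <- dim(fwd$branch_out[[b]]$y)
    dsb <- array(0, dim = d)
    dsb[, , 1, ] <- dz[, , b, ]
    dsb[, , 2, ] <- dz[, , nb + b, ]
    rb <- seq_backward(net, net$arch$branches[[b]],
                       fwd$branch_out[[b]]$caches, dsb, mode)
    grads <- c(grads, rb$grads)
    dx_total <- if (is.null(dx_total)) rb$dx else dx_total + rb$dx
  }
  list(grads = grads, dx = dx_total)
}

# Reflect-pad a matrix on the bottom/right to multiples of `f`.
pad_to_multiple <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / f) * f
  W2 <- ceiling(W / f) * f
  if (H2 == H && W2 == W) return(list(m = m, H = H, W = W))
  if (H2 - H >= H || W2 - W >= W) abort("image too small to pad")
  ri <- c(seq_len(H), H - seq_len(H2 - H))
  ci <- c(seq_len(W), W - seq_len(W2 - W))
  list(m = m[ri, ci], H = H, W = W)
}

normalize_input <- function(px) px / 127.5 - 1

#' Run the network on one micrograph
#'
#' Inputs whose height or width is not divisible by the largest branch
#' factor are reflect-padded and the output cropped back, so the returned
#' probability map always matches the input size.
#'
#' @param net A trained or freshly built [build_mfcn()] network.
#' @param img A [gray_image] or intensity matrix (pre-equalized; apply
#'   [equalize_histogram()] first, as at training time).
#' @return Array `[H, W, 2]` of class `probability_map`; channel 1 is
#'   background probability, channel 2 granule probability. Each pixel's
#'   probabilities sum to 1.
#' @export
mfcn_forward <- function(net, img) {
  px <- as_pixels(img)
  f <- max(net$spec$branch_factors)
  p <- pad_to_multiple(px, f)
  x <- array(normalize_input(p$m), dim = c(nrow(p$m), ncol(p$m), 1, 1))
  fwd <- mfcn_forward_full(net, x, mode = "eval", keep = FALSE)
  out <- fwd$probs[seq_len(p$H), seq_len(p$W), , 1, drop = FALSE]
  dim(out) <- c(p$H, p$W, 2)
  structure(out, class = c("probability_map", "array"))
}

#' Threshold the granule probability into a binary mask
#'
#' A pixel is foreground when its granule-class probability strictly
#' exceeds `threshold` (ties go to background).
#'
#' @param net An [build_mfcn()] network.
#' @param img A [gray_image] or intensity matrix.
#' @param threshold Probability threshold in (0, 1).
#' @return Integer 0/1 matrix.
#' @export
predict_mask <- function(net, img, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1)")
  pm <- mfcn_forward(net, img)
  m <- matrix(as.integer(pm[, , 2] > threshold), nrow = dim(pm)[1])
  m
}

#' Measure the architectural receptive field of one branch
#'
#' Back-propagates a unit gradient from the centre pixel of the branch's
#' score map to the input, with the rectifier linearised, and reports the
#' spatial extent of the non-zero input gradient. Branches with larger
#' down-sampling factors have strictly larger receptive fields.
#'
#' @param net An [build_mfcn()] network.
#' @param branch Branch index.
#' @param size Probe image size (a multiple of the largest branch factor).
#' @return Width in pixels of the input-gradient support.
#' @export
mfcn_receptive_field <- function(net, branch, size = 8 * max(net$spec$branch_factors)) {
  x <- array(0, dim = c(size, size, 1, 1))
  layers <- net$arch$branches[[branch]]
  fwd <- seq_forward(net, layers, x, mode = "probe", keep = TRUE)
  dy <- array(0, dim = dim(fwd$y))
  dy[size / 2, size / 2, 2, 1] <- 1
  bwd <- seq_backward(net, layers, fwd$caches, dy, mode = "probe")
  g <- abs(bwd$dx[, , 1, 1])
  nz <- which(g > 1e-12, arr.ind = TRUE)
  if (nrow(nz) == 0) return(0L)
  as.integer(max(max(nz[, 1]) - min(nz[, 1]), max(nz[, 2]) - min(nz[, 2])) + 1L)
}

#' Save or load a trained network
#'
#' The checkpoint is the network's serialised parameters plus a JSON
#' sidecar describing the architecture.
#'
#' @param net An `mfcn` object.
#' @param path Checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `save_mfcn()` returns `path` invisibly; `load_mfcn()` the network.
#' @export
save_mfcn <- function(net, path) {
  saveRDS(net[c("spec", "params", "stats")], path)
  jsonlite::write_json(unclass(net$spec), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mfcn
#' @export
load_mfcn <- function(path) {
  x <- readRDS(path)
  spec <- do.call(network_spec, x$spec[setdiff(names(x$spec), "n_classes")])
  net <- build_mfcn(spec, seed = 0L)
  net$params <- x$params
  net$stats <- x$stats
  net
}
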